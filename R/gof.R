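#' Goodness-of-fit distance thresholds
#'
#' Band boundaries for scoring the respirator-to-skin distance field:
#' distances above `gap_min` gap from the skin, distances below `indent_max`
#' substantially indent it (beyond what facial soft tissue comfortably
#' accommodates), and the closed range between them is an adequate seal. The
#' conformity band `|d| <= conform_band` is the criterion used in the
#' deformation sensitivity sweep.
#'
#' @param gap_min gap threshold (mm, default 0; gap is `d > gap_min`).
#' @param indent_max indentation threshold (mm, default -3; indentation is
#'   `d < indent_max`).
#' @param conform_band half-width of the conformity band (mm, default 1).
#' @return object of class `gof_thresholds`.
#' @export
gof_thresholds <- function(gap_min = 0, indent_max = -3, conform_band = 1) {
  stopifnot(indent_max < gap_min, conform_band > 0)
  structure(list(gap_min = gap_min, indent_max = indent_max,
                 conform_band = conform_band),
            class = "gof_thresholds")
}

#' Goodness-of-fit band percentages
#'
#' Scores a signed-distance map into the three fit bands — gap
#' (`d > gap_min`, open), indentation (`d < indent_max`, open) and adequate
#' seal (the closed remainder `indent_max <= d <= gap_min`) — plus the
#' conformity percentage (`|d| <= conform_band`, inclusive). Percentages are
#' of total query weight (surface area by default) and the three bands
#' partition to exactly 100.
#'
#' @param map a [signed_distance_map()].
#' @param thresholds a [gof_thresholds()].
#' @return object of class `gof_report`: `pct_gap`, `pct_indent`, `pct_seal`,
#'   `pct_conform`, `thresholds`, `summary` (a [summarize_distances()] result).
#' @export
gof_metrics <- function(map, thresholds = gof_thresholds()) {
  d <- map$distance
  w <- map$weight
  if (length(d) == 0L) stop("empty distance map")
  W <- sum(w)
  pct <- function(sel) 100 * sum(w[sel]) / W
  structure(list(
    pct_gap = pct(d > thresholds$gap_min),
    pct_indent = pct(d < thresholds$indent_max),
    pct_seal = pct(d >= thresholds$indent_max & d <= thresholds$gap_min),
    pct_conform = pct(abs(d) <= thresholds$conform_band),
    thresholds = thresholds,
    summary = summarize_distances(map)),
    class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  th <- x$thresholds
  cat(sprintf("gof_report (percent of respirator area):\n"))
  cat(sprintf("  gap (> %g mm):        %6.1f\n", th$gap_min, x$pct_gap))
  cat(sprintf("  seal [%g, %g] mm:     %6.1f\n", th$indent_max, th$gap_min, x$pct_seal))
  cat(sprintf("  indentation (< %g mm): %5.1f\n", th$indent_max, x$pct_indent))
  cat(sprintf("  conformity (|d| <= %g mm): %.1f\n", th$conform_band, x$pct_conform))
  cat(sprintf("  95%% interval width: %.2f mm\n", x$summary$ci_width))
  invisible(x)
}

#' Select the optimal deformation level
#'
#' The optimum combines high conformity with a tight distance distribution:
#' the level with maximum conformity wins; levels within 0.05 percentage
#' points of the maximum are tied and resolved by the smaller 95%-interval
#' width; any remaining tie goes to the stiffer (higher-index, or rigid)
#' level. Applied to a printed per-level conformity sweep this reproduces the
#' per-participant optima directly.
#'
#' @param conformities numeric vector of per-level conformity percentages.
#' @param ci_widths optional numeric vector of per-level 95%-interval widths
#'   (mm); defaults to all equal (tie-break then falls through to stiffness).
#' @param levels optional list of [deformation_level()]s, parallel to
#'   `conformities`; defaults to delta 1..8 + rigid when the length matches,
#'   else delta 1..n.
#' @param tie_tolerance conformity tie tolerance in percentage points
#'   (default 0.05).
#' @return list of class `delta_selection`: `level` (the chosen
#'   [deformation_level()]), `index` (position in the input), `conformity`,
#'   `ci_width`.
#' @export
select_delta_optimum <- function(conformities, ci_widths = NULL, levels = NULL,
                                 tie_tolerance = 0.05) {
  n <- length(conformities)
  if (n == 0L) stop("no deformation levels supplied")
  if (is.null(ci_widths)) ci_widths <- rep(0, n)
  stopifnot(length(ci_widths) == n)
  if (is.null(levels)) {
    levels <- if (n == 9L) default_levels() else lapply(seq_len(n), function(k)
      deformation_level(min(k, 8L)))
  }
  stopifnot(length(levels) == n)
  tied <- which(conformities >= max(conformities) - tie_tolerance)
  tied <- tied[ci_widths[tied] <= min(ci_widths[tied])]
  # stiffer wins the residual tie: rigid counts as stiffest
  stiffness_rank <- vapply(levels, function(l) if (l$rigid) Inf else l$stiffness,
                           numeric(1))
  pick <- tied[which.max(stiffness_rank[tied])]
  structure(list(level = levels[[pick]], index = pick,
                 conformity = conformities[pick], ci_width = ci_widths[pick]),
            class = "delta_selection")
}

#' @export
print.delta_selection <- function(x, ...) {
  cat(sprintf("delta_selection: %s (conformity %.1f%%, 95%% width %.2f mm)\n",
              x$level$label, x$conformity, x$ci_width))
  invisible(x)
}
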