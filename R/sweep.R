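#' Deformation sensitivity sweep
#'
#' For each deformation level, the respirator internal surface is aligned and
#' deformed toward the unloaded face ([nonrigid_icp()]), then rigidly
#' registered onto the loaded face; signed distances of the respirator
#' vertices to the loaded face are scored into goodness-of-fit bands. The
#' optimum level is chosen by [select_delta_optimum()].
#'
#' Inputs are assumed already aligned to a common frame (see
#' [align_cascade()]).
#'
#' @param respirator_internal respirator internal surface ([surface_mesh()]).
#' @param unloaded_face,loaded_face subject facial scans ([surface_mesh()]).
#' @param levels list of [deformation_level()]s (default delta 1..8 + rigid).
#' @param settings an [icp_settings()].
#' @param thresholds a [gof_thresholds()].
#' @param weighting passed to [signed_distances()].
#' @return object of class `delta_sweep`: `table` (data.frame, one row per
#'   level: label, stiffness, pct_gap, pct_indent, pct_seal, pct_conform,
#'   ci_width, p_low, p_high, mean_abs), `reports` (per-level `gof_report`s),
#'   `maps` (per-level [signed_distance_map()]s), `optimum` (a
#'   `delta_selection`), `levels`.
#' @export
run_delta_sweep <- function(respirator_internal, unloaded_face, loaded_face,
                            levels = default_levels(),
                            settings = icp_settings(),
                            thresholds = gof_thresholds(),
                            weighting = "area") {
  if (length(levels) == 0L) stop("no deformation levels supplied")
  reports <- vector("list", length(levels))
  maps <- vector("list", length(levels))
  s_pre <- no_recenter(settings)  # inputs are already in the common frame
  for (i in seq_along(levels)) {
    lv <- levels[[i]]
    def <- nonrigid_icp(respirator_internal, unloaded_face, lv, s_pre)
    onto_loaded <- icp_align(def$mesh, loaded_face, s_pre)
    placed <- apply_transform(def$mesh, onto_loaded$transform)
    maps[[i]] <- signed_distances(placed, loaded_face, weighting = weighting)
    reports[[i]] <- gof_metrics(maps[[i]], thresholds)
  }
  tab <- data.frame(
    level = vapply(levels, function(l) l$label, character(1)),
    stiffness = vapply(levels, function(l) l$stiffness, numeric(1)),
    pct_gap = vapply(reports, function(r) r$pct_gap, numeric(1)),
    pct_indent = vapply(reports, function(r) r$pct_indent, numeric(1)),
    pct_seal = vapply(reports, function(r) r$pct_seal, numeric(1)),
    pct_conform = vapply(reports, function(r) r$pct_conform, numeric(1)),
    ci_width = vapply(reports, function(r) r$summary$ci_width, numeric(1)),
    p_low = vapply(reports, function(r) r$summary$p_low, numeric(1)),
    p_high = vapply(reports, function(r) r$summary$p_high, numeric(1)),
    mean_abs = vapply(reports, function(r) r$summary$mean_abs, numeric(1)))
  optimum <- select_delta_optimum(tab$pct_conform, tab$ci_width, levels)
  structure(list(table = tab, reports = reports, maps = maps,
                 optimum = optimum, levels = levels),
            class = "delta_sweep")
}

#' @export
print.delta_sweep <- function(x, ...) {
  cat("delta_sweep: conformity by deformation level\n")
  print(x$table[, c("level", "pct_conform", "ci_width", "pct_gap", "pct_seal",
                    "pct_indent")],
        row.names = FALSE, digits = 4)
  cat("optimum: ")
  print(x$optimum)
  invisible(x)
}

#' @export
plot.delta_sweep <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  k <- seq_len(nrow(x$table))
  graphics::plot(k, x$table$pct_conform, type = "b", pch = 19,
                 xaxt = "n", xlab = "deformation level",
                 ylab = "conformity (% area, |d| <= 1 mm)", ...)
  graphics::axis(1, at = k, labels = x$table$level, las = 2, cex.axis = 0.8)
  graphics::abline(v = x$optimum$index, lty = 2, col = "grey40")
  graphics::plot(k, x$table$ci_width, type = "b", pch = 19,
                 xaxt = "n", xlab = "deformation level",
                 ylab = "95% interval width (mm)")
  graphics::axis(1, at = k, labels = x$table$level, las = 2, cex.axis = 0.8)
  graphics::abline(v = x$optimum$index, lty = 2, col = "grey40")
  invisible(x)
}

#' Write a sweep table as CSV
#' @param sweep a `delta_sweep`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sweep_csv <- function(sweep, path) {
  tab <- sweep$table
  tab$optimum <- seq_len(nrow(tab)) == sweep$optimum$index
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Soft-tissue displacement from loaded/unloaded scans
#'
#' Rigidly aligns the loaded facial scan (respirator in situ) to the unloaded
#' scan, then measures the signed distance of every loaded-face vertex to the
#' unloaded surface: negative values are tissue pressed inward by the
#' respirator (indentation), positive values are lateral bulging. The 2.5th
#' and 97.5th percentiles of the distribution summarise the negative and
#' positive soft-tissue displacement.
#'
#' @param unloaded_face,loaded_face facial scans of the same subject.
#' @param settings an [icp_settings()]; the default trims 20% of
#'   correspondences so the alignment locks onto the undeformed majority of
#'   the face rather than averaging over the displaced regions.
#' @param weighting passed to [signed_distances()].
#' @return list of class `tissue_displacement`: `map` (a
#'   [signed_distance_map()]), `summary` (a `distance_summary`), `transform`.
#' @export
tissue_displacement <- function(unloaded_face, loaded_face,
                                settings = icp_settings(trim_fraction = 0.2),
                                weighting = "area") {
  icp <- icp_align(loaded_face, unloaded_face, settings)
  placed <- apply_transform(loaded_face, icp$transform)
  map <- signed_distances(placed, unloaded_face, weighting = weighting)
  structure(list(map = map, summary = summarize_distances(map),
                 transform = icp$transform),
            class = "tissue_displacement")
}

#' @export
print.tissue_displacement <- function(x, ...) {
  cat(sprintf(
    "tissue_displacement: negative (indentation) %.2f mm, positive (bulge) %.2f mm\n",
    x$summary$p_low, x$summary$p_high))
  invisible(x)
}

#' Predict respirator fit at a deformation level
#'
#' Deforms the respirator internal surface onto the unloaded face at the given
#' level (typically the sweep optimum) and scores the resulting signed
#' distances into goodness-of-fit bands. This is the final fit prediction.
#'
#' @param unloaded_face subject facial scan ([surface_mesh()]), aligned.
#' @param respirator_internal respirator internal surface, aligned.
#' @param level a [deformation_level()] or a `delta_selection`.
#' @param settings an [icp_settings()].
#' @param thresholds a [gof_thresholds()].
#' @param weighting passed to [signed_distances()].
#' @return a `gof_report` with attribute `map` (the underlying
#'   [signed_distance_map()]) and `deformation` (the [nonrigid_icp()] result).
#' @export
predict_fit <- function(unloaded_face, respirator_internal, level,
                        settings = icp_settings(),
                        thresholds = gof_thresholds(),
                        weighting = "area") {
  if (inherits(level, "delta_selection")) level <- level$level
  def <- nonrigid_icp(respirator_internal, unloaded_face, level,
                      no_recenter(settings))
  map <- signed_distances(def$mesh, unloaded_face, weighting = weighting)
  rep <- gof_metrics(map, thresholds)
  attr(rep, "map") <- map
  attr(rep, "deformation") <- def
  rep
}

#' Fit a respirator to a face
#'
#' The end-to-end model fit: aligns all scans into the reference frame
#' ([align_cascade()]), runs the deformation sensitivity sweep against the
#' loaded face ([run_delta_sweep()]), selects the optimal deformation level,
#' quantifies soft-tissue displacement from the loaded/unloaded pair
#' ([tissue_displacement()]), and predicts the final goodness of fit by
#' deforming the respirator at the optimum onto the unloaded face
#' ([predict_fit()]).
#'
#' @param unloaded_face,loaded_face subject facial scans ([surface_mesh()]).
#' @param respirator_whole,respirator_internal respirator geometry.
#' @param reference_head,reference_head_with_respirator reference alignment
#'   targets.
#' @param levels list of [deformation_level()]s (default delta 1..8 + rigid).
#' @param settings an [icp_settings()].
#' @param thresholds a [gof_thresholds()].
#' @param weighting `"area"` or `"count"` vertex weighting.
#' @return object of class `respirator_fit` with elements `cascade`, `sweep`
#'   (a `delta_sweep`), `optimum`, `gof` (final `gof_report` at the optimum),
#'   `displacement` (a `tissue_displacement`), and the call.
#' @examples
#' scene <- make_scene(scene_params(resolution = 40))
#' fit <- respirator_fit(scene$unloaded_face, scene$loaded_face,
#'                       scene$respirator_whole, scene$respirator_internal,
#'                       scene$reference_head,
#'                       scene$reference_head_with_respirator,
#'                       levels = lapply(c(1, 4, 8), deformation_level))
#' summary(fit)
#' @export
respirator_fit <- function(unloaded_face, loaded_face,
                           respirator_whole, respirator_internal,
                           reference_head, reference_head_with_respirator,
                           levels = default_levels(),
                           settings = icp_settings(),
                           thresholds = gof_thresholds(),
                           weighting = "area") {
  cascade <- align_cascade(unloaded_face, loaded_face, respirator_whole,
                           respirator_internal, reference_head,
                           reference_head_with_respirator, settings)
  sweep <- run_delta_sweep(cascade$meshes$respirator_internal,
                           cascade$meshes$unloaded_face,
                           cascade$meshes$loaded_face,
                           levels = levels, settings = settings,
                           thresholds = thresholds, weighting = weighting)
  gof <- predict_fit(cascade$meshes$unloaded_face,
                     cascade$meshes$respirator_internal,
                     sweep$optimum, settings, thresholds, weighting)
  disp <- tissue_displacement(cascade$meshes$unloaded_face,
                              cascade$meshes$loaded_face,
                              weighting = weighting)
  structure(list(cascade = cascade, sweep = sweep, optimum = sweep$optimum,
                 gof = gof, displacement = disp, thresholds = thresholds,
                 settings = settings, call = match.call()),
            class = "respirator_fit")
}

#' @export
print.respirator_fit <- function(x, ...) {
  cat("respirator_fit\n")
  cat(sprintf("  optimum level: %s (conformity %.1f%%)\n",
              x$optimum$level$label, x$optimum$conformity))
  cat(sprintf("  predicted fit: seal %.1f%%, gap %.1f%%, indentation %.1f%%\n",
              x$gof$pct_seal, x$gof$pct_gap, x$gof$pct_indent))
  cat(sprintf("  soft-tissue displacement: %.2f / %.2f mm\n",
              x$displacement$summary$p_low, x$displacement$summary$p_high))
  invisible(x)
}

#' @export
summary.respirator_fit <- function(object, ...) {
  print(object)
  cat("\nsweep table:\n")
  print(object$sweep$table[, c("level", "pct_conform", "ci_width", "pct_gap",
                               "pct_seal", "pct_indent")],
        row.names = FALSE, digits = 4)
  invisible(object$sweep$table)
}

#' @export
coef.respirator_fit <- function(object, ...) {
  c(conformity = object$optimum$conformity,
    ci_width = object$optimum$ci_width,
    pct_seal = object$gof$pct_seal,
    pct_gap = object$gof$pct_gap,
    pct_indent = object$gof$pct_indent,
    displacement_low = object$displacement$summary$p_low,
    displacement_high = object$displacement$summary$p_high)
}

#' @export
plot.respirator_fit <- function(x, ...) plot(x$sweep, ...)

#' @export
predict.respirator_fit <- function(object, level = NULL, ...) {
  if (is.null(level)) return(object$gof)
  if (!inherits(level, "deformation_level")) level <- deformation_level(level)
  predict_fit(object$cascade$meshes$unloaded_face,
              object$cascade$meshes$respirator_internal,
              level, object$settings, object$thresholds)
}

#' @export
residuals.respirator_fit <- function(object, ...) {
  attr(object$gof, "map")$distance
}
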