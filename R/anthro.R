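#' Landmark set for facial anthropometry
#'
#' Named 3D points (mm) on a facial scan. Required names: `exocanthion_left`,
#' `exocanthion_right` (outer eye corners), `alare_left`, `alare_right`
#' (nostril flanks), `sellion` (nose-bridge root), `pronasale` (nose tip),
#' `subnasale` (base of the nose), `menton` (chin surrogate for the lower
#' facial third).
#'
#' @param points named list of length-3 numeric vectors, or a 3-column matrix
#'   with rownames.
#' @return object of class `landmark_set` (named list of points).
#' @export
landmark_set <- function(points) {
  if (is.matrix(points)) {
    nm <- rownames(points)
    points <- lapply(seq_len(nrow(points)), function(i) as.numeric(points[i, ]))
    names(points) <- nm
  }
  stopifnot(!is.null(names(points)), all(nzchar(names(points))))
  points <- lapply(points, as.numeric)
  if (any(lengths(points) != 3L)) stop("each landmark must be a 3D point")
  if (any(!vapply(points, function(p) all(is.finite(p)), logical(1))))
    stop("landmarks contain non-finite coordinates")
  structure(points, class = "landmark_set")
}

#' Read landmarks from a JSON file
#'
#' Expects a JSON object mapping landmark name to an `[x, y, z]` array in mm.
#'
#' @param path JSON file path.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  landmark_set(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write landmarks to JSON
#' @param landmarks a [landmark_set()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(unclass(landmarks), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

lm_dist <- function(landmarks, a, b) {
  for (nm in c(a, b))
    if (is.null(landmarks[[nm]])) stop("missing landmark: ", nm)
  sqrt(sum((landmarks[[a]] - landmarks[[b]])^2))
}

#' Facial anthropometrics from landmarks
#'
#' Point-to-point Euclidean distances between landmark pairs:
#' \describe{
#'   \item{bio_ocular_width}{exocanthion to exocanthion}
#'   \item{alar_width}{alare to alare}
#'   \item{dorsal_nasal_length}{sellion to pronasale}
#'   \item{lower_third_face_height}{subnasale to menton surrogate (facial
#'     scans rarely include the full facial height, so the lower third is
#'     used)}
#' }
#'
#' @param landmarks a [landmark_set()].
#' @return object of class `anthropometric_profile`, a named numeric vector
#'   of the four measurements (mm). Degenerate (zero) distances raise an
#'   error, since coincident landmarks indicate a mis-picked set.
#' @export
measure_profile <- function(landmarks) {
  p <- c(bio_ocular_width = lm_dist(landmarks, "exocanthion_left", "exocanthion_right"),
         alar_width = lm_dist(landmarks, "alare_left", "alare_right"),
         dorsal_nasal_length = lm_dist(landmarks, "sellion", "pronasale"),
         lower_third_face_height = lm_dist(landmarks, "subnasale", "menton"))
  if (any(p == 0))
    stop("degenerate anthropometric (coincident landmarks): ",
         paste(names(p)[p == 0], collapse = ", "))
  structure(p, class = c("anthropometric_profile", "numeric"))
}

#' Association between goodness of fit and an anthropometric
#'
#' Shapiro-Wilk normality checks on both variables followed by a Pearson
#' correlation with a two-sided test; significance at the 5% level.
#'
#' @param gof_values numeric vector of per-subject goodness-of-fit
#'   percentages.
#' @param measurements numeric vector of per-subject anthropometric values
#'   (mm), same length, n >= 3.
#' @return object of class `correlation_result`: `r`, `p_value`, `n`,
#'   `normality_p` (named, one per variable), `significant`.
#' @export
association <- function(gof_values, measurements) {
  stopifnot(length(gof_values) == length(measurements))
  n <- length(gof_values)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(gof_values) == 0 || stats::sd(measurements) == 0)
    stop("undefined correlation: a variable has zero variance")
  norm_p <- c(gof = shapiro.test(gof_values)$p.value,
              anthropometric = shapiro.test(measurements)$p.value)
  ct <- suppressWarnings(cor.test(measurements, gof_values, method = "pearson"))
  structure(list(r = unname(ct$estimate), p_value = ct$p.value, n = n,
                 normality_p = norm_p,
                 significant = ct$p.value <= 0.05),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result: r = %.3f, p = %.4g, n = %d%s\n",
              x$r, x$p_value, x$n,
              if (x$significant) "  (significant at 5%)" else ""))
  cat(sprintf("  Shapiro-Wilk p: gof %.3f, anthropometric %.3f\n",
              x$normality_p[1], x$normality_p[2]))
  invisible(x)
}

#' Correlate goodness of fit against a table of anthropometrics
#'
#' Runs [association()] for every anthropometric column and returns a tidy
#' table, exportable as CSV.
#'
#' @param gof_values numeric vector of per-subject GoF percentages.
#' @param profiles data.frame or matrix, one row per subject, one column per
#'   anthropometric (mm).
#' @param gof_name label for the GoF variable in the output.
#' @return data.frame: anthropometric, gof_parameter, r, p, n, significant.
#' @export
association_table <- function(gof_values, profiles, gof_name = "pct_seal") {
  profiles <- as.data.frame(profiles)
  rows <- lapply(names(profiles), function(nm) {
    a <- association(gof_values, profiles[[nm]])
    data.frame(anthropometric = nm, gof_parameter = gof_name,
               r = a$r, p = a$p_value, n = a$n, significant = a$significant)
  })
  do.call(rbind, rows)
}
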