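#' ICP control settings
#'
#' @param max_iterations maximum correspondence/refit cycles (default 300;
#'   point-to-point ICP converges linearly and needs headroom).
#' @param rms_tolerance stop once the RMS correspondence distance changes by
#'   less than this between iterations (mm, default 1e-7; looser values stop
#'   inside the slow tail of the iteration with the alignment still visibly
#'   off).
#' @param trim_fraction fraction of the worst correspondences dropped each
#'   iteration before the transform refit, in `[0, 1)`; robustifies against
#'   outliers and partially overlapping surfaces (default 0).
#' @param initial_transform a [rigid_transform()] applied to the source before
#'   iteration begins (default identity).
#' @param centroid_init align source and target centroids on top of the
#'   initial transform (default `TRUE`). Disable when the inputs are already
#'   in a common frame: re-centring pre-aligned surfaces of different extent
#'   (e.g. a respirator patch against a whole face) throws away the alignment.
#' @return an object of class `icp_settings`.
#' @export
icp_settings <- function(max_iterations = 300L, rms_tolerance = 1e-7,
                         trim_fraction = 0, initial_transform = rt_identity(),
                         centroid_init = TRUE) {
  stopifnot(max_iterations >= 1L, rms_tolerance > 0,
            trim_fraction >= 0, trim_fraction < 1,
            inherits(initial_transform, "rigid_transform"))
  structure(list(max_iterations = as.integer(max_iterations),
                 rms_tolerance = rms_tolerance,
                 trim_fraction = trim_fraction,
                 initial_transform = initial_transform,
                 centroid_init = isTRUE(centroid_init)),
            class = "icp_settings")
}

# copy of settings with centroid initialisation off, for pre-aligned inputs
no_recenter <- function(settings) {
  settings$centroid_init <- FALSE
  settings
}

#' Least-squares rigid fit of matched point sets (Kabsch)
#'
#' Closed-form rotation + translation minimising the sum of squared distances
#' between matched points. Reflections are excluded: the returned rotation has
#' determinant +1.
#'
#' @param source_points,target_points n x 3 matrices of matched points, n >= 3,
#'   not all collinear.
#' @return a [rigid_transform()] mapping source onto target.
#' @export
kabsch_fit <- function(source_points, target_points) {
  S <- as.matrix(source_points)
  Tm <- as.matrix(target_points)
  if (nrow(S) != nrow(Tm)) stop("point counts differ")
  if (nrow(S) < 3L) stop("need at least 3 point pairs")
  sc <- colMeans(S)
  tc <- colMeans(Tm)
  Sc <- sweep(S, 2L, sc)
  Tc <- sweep(Tm, 2L, tc)
  if (svd(Sc, nu = 0, nv = 0)$d[2] < 1e-10 * max(1, sqrt(sum(Sc^2))))
    stop("singular configuration: source points are (nearly) collinear")
  H <- crossprod(Sc, Tc)
  sv <- svd(H)
  V <- sv$v
  if (det(V %*% t(sv$u)) < 0) V[, 3] <- -V[, 3]
  R <- V %*% t(sv$u)
  rigid_transform(R, tc - as.vector(R %*% sc), validate = FALSE)
}

#' Rigid iterative closest point alignment
#'
#' Aligns `source` onto `target` by alternating nearest-neighbour
#' correspondence (source vertex to nearest target vertex) with a closed-form
#' rigid refit ([kabsch_fit()]), starting from centroid alignment. The RMS
#' correspondence distance is non-increasing across iterations.
#'
#' @param source,target [surface_mesh()] objects (non-empty).
#' @param settings an [icp_settings()].
#' @return an object of class `icp_result`: `transform` (cumulative
#'   [rigid_transform()] source -> target), `rms_history` (mm, one entry per
#'   iteration), `iterations`, and `converged` (`FALSE` if the iteration cap
#'   was reached before the RMS settled; not an error).
#' @export
icp_align <- function(source, target, settings = icp_settings()) {
  if (n_vertices(source) == 0L || n_vertices(target) == 0L)
    stop("ICP requires non-empty meshes")
  src <- source$vertices
  tgt <- target$vertices
  tr <- settings$initial_transform
  if (settings$centroid_init)
    tr <- rt_compose(
      rigid_transform(diag(3), colMeans(tgt) - colMeans(rt_apply(tr, src)),
                      validate = FALSE),
      tr)
  n_keep <- max(3L, ceiling((1 - settings$trim_fraction) * nrow(src)))
  rms_history <- numeric(0)
  converged <- FALSE
  prev_rms <- Inf
  for (it in seq_len(settings$max_iterations)) {
    moved <- rt_apply(tr, src)
    nn <- nearest_points(moved, tgt)
    keep <- if (n_keep < nrow(src)) {
      order(nn$distance)[seq_len(n_keep)]
    } else seq_len(nrow(src))
    rms <- sqrt(mean(nn$distance[keep]^2))
    rms_history <- c(rms_history, rms)
    if (abs(prev_rms - rms) < settings$rms_tolerance) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
    step <- kabsch_fit(moved[keep, , drop = FALSE],
                       tgt[nn$index[keep], , drop = FALSE])
    tr <- rt_compose(step, tr)
  }
  structure(list(transform = tr, rms_history = rms_history,
                 iterations = length(rms_history), converged = converged),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("icp_result: %d iterations, final RMS %.6g mm, converged: %s\n",
              x$iterations, x$rms_history[x$iterations], x$converged))
  print(x$transform)
  invisible(x)
}

#' Multi-step alignment cascade into the reference frame
#'
#' Brings all subject meshes into the frame of a common reference head:
#' \enumerate{
#'   \item the unloaded and loaded facial scans are each rigidly ICP-aligned
#'     to the reference head;
#'   \item the respirator whole geometry is rigidly ICP-aligned to the
#'     reference head scanned with the respirator in situ (a rough placement
#'     of the respirator onto the face);
#'   \item the step-2 transform is applied to the respirator internal surface,
#'     carrying it into the same frame.
#' }
#'
#' @param unloaded_face,loaded_face subject facial scans ([surface_mesh()]).
#' @param respirator_whole,respirator_internal respirator geometry meshes.
#' @param reference_head,reference_head_with_respirator reference target
#'   meshes (without / with the respirator in situ).
#' @param settings an [icp_settings()] shared by all alignments.
#' @return list with `meshes` (the four subject meshes, aligned) and
#'   `transforms` (`unloaded`, `loaded`, `respirator` [rigid_transform()]s)
#'   plus the per-step `icp` results.
#' @export
align_cascade <- function(unloaded_face, loaded_face,
                          respirator_whole, respirator_internal,
                          reference_head, reference_head_with_respirator,
                          settings = icp_settings()) {
  icp_unloaded <- icp_align(unloaded_face, reference_head, settings)
  icp_loaded <- icp_align(loaded_face, reference_head, settings)
  icp_resp <- icp_align(respirator_whole, reference_head_with_respirator, settings)
  list(
    meshes = list(
      unloaded_face = apply_transform(unloaded_face, icp_unloaded$transform),
      loaded_face = apply_transform(loaded_face, icp_loaded$transform),
      respirator_whole = apply_transform(respirator_whole, icp_resp$transform),
      respirator_internal = apply_transform(respirator_internal, icp_resp$transform)),
    transforms = list(unloaded = icp_unloaded$transform,
                      loaded = icp_loaded$transform,
                      respirator = icp_resp$transform),
    icp = list(unloaded = icp_unloaded, loaded = icp_loaded,
               respirator = icp_resp))
}
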