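#' Reduce a skeleton to dotprops (points + local tangents)
#'
#' Dotprops are the point-cloud reduction NBLAST scores operate on: the
#' skeleton is resampled to roughly equidistant points along its cable, and
#' each point gets the dominant principal direction of its `k` nearest
#' neighbours as a unit tangent, plus a colinearity score
#' `alpha = (l1 - l2) / (l1 + l2 + l3)` from the eigenvalues of the local
#' covariance (1 on a straight segment, ~0 in an isotropic blob).
#'
#' @param skeleton A skeleton node table (see [read_swc()]).
#' @param resample_step Target spacing between points along the cable, nm.
#' @param k Neighbourhood size for the local PCA. Clamped (with a warning) to
#'   the number of points when the cloud is smaller than `k`.
#' @return A `dotprops` object: list with `points` (n x 3 matrix, nm),
#'   `tangents` (n x 3 unit vectors), `alpha` (n colinearity scores in
#'   [0, 1]) and `k`.
#' @export
skeleton_to_dotprops <- function(skeleton, resample_step = 1000, k = 5) {
  pts <- resample_skeleton(skeleton, resample_step)
  dotprops_from_points(pts, k = k)
}

#' Build dotprops directly from a point cloud
#'
#' @param points An n x 3 numeric matrix of coordinates (nm).
#' @param k Neighbourhood size for the local PCA.
#' @return A `dotprops` object (see [skeleton_to_dotprops()]).
#' @export
dotprops_from_points <- function(points, k = 5) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("dotprops need at least 2 points", call. = FALSE)
  if (k > n) {
    warning("k = ", k, " exceeds point count ", n, "; clamping", call. = FALSE)
    k <- n
  }
  d2 <- as.matrix(stats::dist(points))^2
  tangents <- matrix(0, n, 3L)
  alpha <- numeric(n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(k)]
    p <- points[nb, , drop = FALSE]
    cv <- stats::cov(p)
    eg <- eigen(cv, symmetric = TRUE)
    tangents[i, ] <- eg$vectors[, 1L]
    ev <- pmax(eg$values, 0)
    tot <- sum(ev)
    alpha[i] <- if (tot > 0) (ev[1L] - ev[2L]) / tot else 0
  }
  # unit-normalise; fix an orientation convention (first nonzero coord > 0)
  # so results are deterministic across LAPACK sign choices
  nrm <- sqrt(rowSums(tangents^2))
  tangents <- tangents / nrm
  for (i in seq_len(n)) {
    v <- tangents[i, ]
    j <- which(abs(v) > 1e-12)[1L]
    if (!is.na(j) && v[j] < 0) tangents[i, ] <- -v
  }
  structure(list(points = points, tangents = tangents, alpha = alpha, k = k),
            class = "dotprops")
}

#' Resample a skeleton along its cable
#'
#' Walks every parent-child edge and emits points spaced `step` apart,
#' keeping branch points and leaves.
#'
#' @param skeleton A skeleton node table.
#' @param step Spacing, nm.
#' @return An n x 3 matrix of points.
#' @export
resample_skeleton <- function(skeleton, step = 1000) {
  idx <- match(skeleton$parent_id, skeleton$node_id)
  has_parent <- which(!is.na(idx))
  pts <- list(as.matrix(skeleton[skeleton$parent_id == -1L, c("x", "y", "z")]))
  for (i in has_parent) {
    a <- c(skeleton$x[idx[i]], skeleton$y[idx[i]], skeleton$z[idx[i]])
    b <- c(skeleton$x[i], skeleton$y[i], skeleton$z[i])
    len <- sqrt(sum((b - a)^2))
    if (len == 0) next
    nseg <- max(1L, round(len / step))
    tt <- seq_len(nseg) / nseg
    pts[[length(pts) + 1L]] <-
      cbind(a[1] + tt * (b[1] - a[1]),
            a[2] + tt * (b[2] - a[2]),
            a[3] + tt * (b[3] - a[3]))
  }
  out <- do.call(rbind, pts)
  colnames(out) <- c("x", "y", "z")
  out[!duplicated(round(out, 6)), , drop = FALSE]
}

#' @export
print.dotprops <- function(x, ...) {
  cat("<dotprops> ", nrow(x$points), " points, k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a dotprops object into a point table
#'
#' @param x A `dotprops` object.
#' @param ... Unused.
#' @return A tibble with point coordinates, tangent components and `alpha`.
#' @export
tidy.dotprops <- function(x, ...) {
  p <- x$points
  tg <- x$tangents
  al <- x$alpha
  tibble::tibble(
    x = p[, 1L], y = p[, 2L], z = p[, 3L],
    tx = tg[, 1L], ty = tg[, 2L], tz = tg[, 3L],
    alpha = al
  )
}

#' Mirror points across a sagittal midline plane
#'
#' Reflects x coordinates across `midline_x`, leaving y and z untouched:
#' `x' = 2 * midline_x - x`. Used to bring left-side neurons into register
#' with the right cohort before NBLAST pairing. An exact involution.
#'
#' @param points An n x 3 matrix, a data frame with `x`,`y`,`z`, or a
#'   `dotprops` object.
#' @param midline_x The sagittal plane position, nm.
#' @return The same kind of object with x mirrored (dotprops tangents have
#'   their x component negated to stay consistent).
#' @export
mirror_points <- function(points, midline_x) {
  if (inherits(points, "dotprops")) {
    points$points[, 1L] <- 2 * midline_x - points$points[, 1L]
    points$tangents[, 1L] <- -points$tangents[, 1L]
    return(points)
  }
  if (is.data.frame(points)) {
    points$x <- 2 * midline_x - points$x
    return(points)
  }
  points[, 1L] <- 2 * midline_x - points[, 1L]
  points
}
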