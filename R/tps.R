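#' Fit an unregularized 3D thin-plate-spline transform
#'
#' Fits the classic landmark-interpolating thin-plate spline with radial
#' kernel U(r) = r (the 3D biharmonic kernel) and an affine part, solving the
#' standard bordered linear system exactly (no stiffness/regularization), so
#' every source landmark maps exactly onto its paired target. This is the
#' one-step landmark registration used to carry skeletons from one dataset's
#' space into another's.
#'
#' @param src m x 3 matrix of source landmarks (nm), m >= 4, not all coplanar.
#' @param dst m x 3 matrix of paired target landmarks (nm).
#' @return A `tps_transform` with the source landmarks, the 3 x 4 affine part
#'   and the m x 3 warp coefficients. Apply with [apply_tps()].
#' @export
fit_tps <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  m <- nrow(src)
  if (m < 4L) stop("thin-plate spline needs at least 4 landmarks", call. = FALSE)
  if (nrow(dst) != m) stop("src and dst landmark counts differ", call. = FALSE)
  K <- tps_kernel(src, src)
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  Y <- rbind(dst, matrix(0, 4L, 3L))
  sol <- tryCatch(solve(L, Y), error = function(e) {
    stop("singular thin-plate-spline system (coplanar or duplicated landmarks)",
         call. = FALSE)
  })
  structure(
    list(
      src = src,
      dst = dst,
      warp = sol[seq_len(m), , drop = FALSE],
      affine = t(sol[m + 1:4, , drop = FALSE]) # 3 x 4: [b | A]
    ),
    class = "tps_transform"
  )
}

# U(r) = r kernel matrix between two landmark sets
tps_kernel <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Apply a thin-plate-spline transform to points
#'
#' @param tps A `tps_transform` from [fit_tps()].
#' @param points An n x 3 matrix, a data frame with `x`,`y`,`z` columns, or a
#'   `dotprops` object (tangents are re-derived from transformed tangent tips
#'   and re-normalised).
#' @return Transformed object of the same kind as `points`.
#' @export
apply_tps <- function(tps, points) {
  if (inherits(points, "dotprops")) {
    p2 <- apply_tps(tps, points$points)
    # transform tangents via finite offset so the local rotation is honoured
    eps <- 10 # nm
    tips <- apply_tps(tps, points$points + eps * points$tangents)
    tan2 <- tips - p2
    nrm <- sqrt(rowSums(tan2^2))
    nrm[nrm == 0] <- 1
    points$points <- p2
    points$tangents <- tan2 / nrm
    return(points)
  }
  df_in <- is.data.frame(points)
  mat <- if (df_in) as.matrix(points[, c("x", "y", "z")]) else as.matrix(points)
  U <- tps_kernel(mat, tps$src)
  out <- cbind(1, mat) %*% t(tps$affine) + U %*% tps$warp
  if (df_in) {
    points$x <- out[, 1L]; points$y <- out[, 2L]; points$z <- out[, 3L]
    return(points)
  }
  colnames(out) <- c("x", "y", "z")
  out
}

#' @export
print.tps_transform <- function(x, ...) {
  cat("<tps_transform> ", nrow(x$src), " landmarks\n", sep = "")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' One-row summary of a thin-plate-spline fit
#'
#' @param x A `tps_transform`.
#' @param ... Unused.
#' @return A tibble with landmark count, the maximum landmark interpolation
#'   residual (should be ~0 for this exact-interpolation spline) and the
#'   Frobenius norm of the warp coefficients (0 for a purely affine map).
#' @export
glance.tps_transform <- function(x, ...) {
  resid <- apply_tps(x, x$src) - x$dst
  tibble::tibble(
    n_landmarks = nrow(x$src),
    max_residual = max(abs(resid)),
    warp_norm = sqrt(sum(x$warp^2))
  )
}
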