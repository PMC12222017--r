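#' NBLAST score functions
#'
#' The raw NBLAST score sums, over the query's points, a score of the
#' distance to and tangent alignment with the nearest target point. The
#' published scoring tables are dataset assets; the package default is the
#' parametric surrogate
#' `s(d, dp) = dp * exp(-d^2 / (2 sigma^2)) - c`,
#' which is positive for nearby well-aligned points and tends to `-c` at
#' large distance, giving the same sign structure as the tabulated log-odds
#' scores. A tabulated (distance-bin x dot-product-bin) scoring matrix can be
#' loaded with [read_score_matrix()] and passed anywhere a score function is
#' accepted.
#'
#' @param sigma Distance scale, nm.
#' @param cost Constant offset subtracted per point (the mismatch penalty).
#' @return A score function `f(dist, dotprod)` with attributes used to route
#'   scoring through the compiled fast path.
#' @export
nblast_score_fn <- function(sigma = 3000, cost = 0.1) {
  f <- function(dist, dotprod) dotprod * exp(-dist^2 / (2 * sigma^2)) - cost
  attr(f, "kind") <- "parametric"
  attr(f, "sigma") <- sigma
  attr(f, "cost") <- cost
  f
}

#' Load a tabulated NBLAST scoring matrix
#'
#' File format: delimiter-separated; first row the distance-bin right edges
#' (nm), first column the absolute-dot-product-bin right edges, body the
#' log-odds scores. Queries beyond the last distance bin take the last
#' column's score.
#'
#' @param path Path to the scoring-matrix file.
#' @return A score function `f(dist, dotprod)` usable by [nblast_raw()].
#' @export
read_score_matrix <- function(path) {
  raw <- as.matrix(utils::read.table(path, header = FALSE))
  dist_edges <- raw[1L, -1L]
  dot_edges <- raw[-1L, 1L]
  scores <- raw[-1L, -1L, drop = FALSE]
  f <- function(dist, dotprod) {
    di <- pmin(findInterval(dist, dist_edges, left.open = TRUE) + 1L,
               length(dist_edges))
    pj <- pmin(findInterval(dotprod, dot_edges, left.open = TRUE) + 1L,
               length(dot_edges))
    scores[cbind(pj, di)]
  }
  attr(f, "kind") <- "tabulated"
  f
}

#' Raw (asymmetric) NBLAST score between two dotprops
#'
#' For each query point, finds the nearest target point and scores the
#' (distance, |tangent dot product|) pair; the raw score is the sum over
#' query points. Asymmetric by construction: `nblast_raw(a, b)` differs from
#' `nblast_raw(b, a)`.
#'
#' @param query,target `dotprops` objects.
#' @param score_fn A score function (default [nblast_score_fn()]).
#' @return A single raw score.
#' @seealso [nblast()] for the symmetric mean-normalized score.
#' @export
nblast_raw <- function(query, target, score_fn = nblast_score_fn()) {
  stopifnot(inherits(query, "dotprops"), inherits(target, "dotprops"))
  if (nrow(query$points) == 0L || nrow(target$points) == 0L) {
    stop("empty dotprops", call. = FALSE)
  }
  if (identical(attr(score_fn, "kind"), "parametric")) {
    return(.nblast_raw_param_cpp(query$points, query$tangents,
                                 target$points, target$tangents,
                                 attr(score_fn, "sigma"),
                                 attr(score_fn, "cost")))
  }
  nn <- .nn_dotprod_cpp(query$points, query$tangents,
                        target$points, target$tangents)
  sum(score_fn(nn$dist, nn$dotprod))
}

#' Mean-normalized NBLAST score
#'
#' The symmetric similarity used for matching:
#' `(raw(a,b)/raw(a,a) + raw(b,a)/raw(b,b)) / 2`.
#' Equals 1 exactly when the two clouds are identical point-for-point and
#' decreases with morphological difference (it can go negative for unrelated
#' neurons under score functions with a mismatch penalty).
#'
#' @inheritParams nblast_raw
#' @param a,b `dotprops` objects.
#' @return A single normalized score.
#' @export
nblast <- function(a, b, score_fn = nblast_score_fn()) {
  (nblast_raw(a, b, score_fn) / nblast_raw(a, a, score_fn) +
     nblast_raw(b, a, score_fn) / nblast_raw(b, b, score_fn)) / 2
}

#' All-by-all mean-normalized NBLAST
#'
#' @param cohort Named list of `dotprops` (>= 2). Names become row/column ids.
#' @param targets Optional second named list: scores `cohort` x `targets`
#'   instead of all-by-all (used for mirrored-left vs right pairing). The
#'   result is then not symmetric and has kind attribute `"mean_normalized"`
#'   still, since each entry is the symmetric pair score.
#' @param score_fn A score function.
#' @return An `nblast_scores` matrix (class on top of matrix) with unit
#'   diagonal when `targets` is `NULL`.
#' @export
nblast_allbyall <- function(cohort, targets = NULL, score_fn = nblast_score_fn()) {
  if (is.null(names(cohort))) names(cohort) <- as.character(seq_along(cohort))
  self_sym <- is.null(targets)
  if (self_sym) targets <- cohort
  if (length(cohort) + length(targets) < 2L) {
    stop("need at least 2 dotprops", call. = FALSE)
  }
  n <- length(cohort); m <- length(targets)
  if (identical(attr(score_fn, "kind"), "parametric")) {
    out <- .nblast_mean_matrix_cpp(
      lapply(cohort, function(d) d$points),
      lapply(cohort, function(d) d$tangents),
      lapply(targets, function(d) d$points),
      lapply(targets, function(d) d$tangents),
      attr(score_fn, "sigma"), attr(score_fn, "cost"),
      NULL, self_sym
    )
    dimnames(out) <- list(names(cohort), names(targets))
  } else {
    self_q <- vapply(cohort, function(d) nblast_raw(d, d, score_fn), numeric(1))
    self_t <- if (self_sym) self_q else
      vapply(targets, function(d) nblast_raw(d, d, score_fn), numeric(1))
    out <- matrix(NA_real_, n, m, dimnames = list(names(cohort), names(targets)))
    for (i in seq_len(n)) {
      jstart <- if (self_sym) i else 1L
      for (j in seq.int(jstart, m)) {
        if (self_sym && j == i) { out[i, j] <- 1; next }
        s <- (nblast_raw(cohort[[i]], targets[[j]], score_fn) / self_q[i] +
                nblast_raw(targets[[j]], cohort[[i]], score_fn) / self_t[j]) / 2
        out[i, j] <- s
        if (self_sym) out[j, i] <- s
      }
    }
  }
  structure(out, class = c("nblast_scores", "matrix", "array"),
            kind = "mean_normalized")
}

# mean-normalized scores for a masked subset of a query x target grid;
# NA where the mask is FALSE
nblast_allbyall_masked <- function(cohort, targets, score_fn, mask) {
  if (identical(attr(score_fn, "kind"), "parametric")) {
    out <- .nblast_mean_matrix_cpp(
      lapply(cohort, function(d) d$points),
      lapply(cohort, function(d) d$tangents),
      lapply(targets, function(d) d$points),
      lapply(targets, function(d) d$tangents),
      attr(score_fn, "sigma"), attr(score_fn, "cost"),
      mask, FALSE
    )
  } else {
    self_q <- vapply(cohort, function(d) nblast_raw(d, d, score_fn), numeric(1))
    self_t <- vapply(targets, function(d) nblast_raw(d, d, score_fn), numeric(1))
    out <- matrix(NA_real_, length(cohort), length(targets))
    for (i in seq_along(cohort)) {
      for (j in seq_along(targets)) {
        if (!mask[i, j]) next
        out[i, j] <- (nblast_raw(cohort[[i]], targets[[j]], score_fn) / self_q[i] +
                        nblast_raw(targets[[j]], cohort[[i]], score_fn) / self_t[j]) / 2
      }
    }
  }
  dimnames(out) <- list(names(cohort), names(targets))
  out
}

#' Tidy an NBLAST score matrix into long form
#'
#' @param x An `nblast_scores` matrix.
#' @param ... Unused.
#' @return A tibble with `query`, `target`, `score`.
#' @export
tidy.nblast_scores <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    query = rep(rownames(m), times = ncol(m)),
    target = rep(colnames(m), each = nrow(m)),
    score = as.vector(m)
  )
}

#' Cut a hierarchical clustering of a similarity matrix
#'
#' Converts a symmetric similarity matrix to distance `1 - score`, builds a
#' dendrogram (`stats::hclust`) and cuts it at the given height. Also accepts
#' a plain distance matrix (set `similarity = FALSE`), which is how rank
#' vectors are clustered.
#'
#' @param score_matrix Square symmetric matrix (similarities or distances).
#' @param height Cut height on the dendrogram.
#' @param linkage `stats::hclust` method; default `"ward.D2"`, with
#'   `"average"` the documented fallback.
#' @param similarity If `TRUE` (default) the matrix holds similarities and is
#'   converted to `pmax(1 - s, 0)` distances first.
#' @return Named integer vector of cluster labels (deterministic given the
#'   input).
#' @export
cluster_cut <- function(score_matrix, height, linkage = "ward.D2",
                        similarity = TRUE) {
  m <- unclass(score_matrix)
  if (nrow(m) != ncol(m)) stop("score matrix must be square", call. = FALSE)
  d <- if (similarity) stats::as.dist(pmax(1 - m, 0)) else stats::as.dist(m)
  hc <- stats::hclust(d, method = linkage)
  stats::cutree(hc, h = height)
}
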