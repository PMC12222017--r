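#' Sensory information-flow ranking over the synaptic graph
#'
#' Ranks every neuron by how directly it receives input from each sensory
#' modality, using a stochastic threshold-traversal: step 0 activates that
#' modality's seed neurons; at each later step every inactive neuron whose
#' active-input fraction (by synapse weight) is `f` becomes active with
#' probability `min(1, f / f_max)`. The step at which a neuron first
#' activates is recorded, the traversal is repeated `runs` times, and the
#' rank is the mean activation step. A low rank means a more direct
#' connection from that modality. Runs in which a neuron never activates
#' within `max_step` steps contribute `max_step + 1`, so ranks stay finite
#' and type means stay defined.
#'
#' In the limit `f_max -> 0` every neuron with any active input activates
#' with probability 1, and ranks reduce to unweighted breadth-first-search
#' hop counts from the seed set.
#'
#' @param edges Edge table (`pre_id`, `post_id`, `weight`).
#' @param seeds Tibble (`neuron_id`, `modality`) or named list of neuron-id
#'   vectors per modality; every modality needs at least one seed.
#' @param f_max Activation threshold: input fraction at which activation
#'   becomes certain. In (0, 1]; default 0.3.
#' @param runs Number of stochastic repetitions (default 100).
#' @param max_step Step cap per run (default 20).
#' @param seed RNG seed; given the same seed and runs, results are
#'   bit-reproducible.
#' @param exclude Neuron ids to leave out of the ranking (e.g. sensory
#'   descending neurons whose rank would be trivially confounded).
#' @return A tibble `neuron_id` x one column per modality holding the mean
#'   activation step (seeds are 0 in their own modality).
#' @export
information_flow_rank <- function(edges, seeds, f_max = 0.3, runs = 100,
                                  max_step = 20, seed = 1, exclude = NULL) {
  if (!(f_max > 0 && f_max <= 1)) stop("f_max must be in (0, 1]", call. = FALSE)
  if (runs < 1) stop("runs must be >= 1", call. = FALSE)
  if (is.data.frame(seeds)) {
    seeds <- split(as.character(seeds$neuron_id), seeds$modality)
  }
  if (any(lengths(seeds) == 0L)) {
    stop("every modality needs a non-empty seed set", call. = FALSE)
  }
  ids <- sort(unique(c(as.character(edges$pre_id), as.character(edges$post_id),
                       unlist(seeds))))
  n <- length(ids)
  # column-normalised weighted adjacency: W[i, j] = fraction of j's input from i
  i <- match(as.character(edges$pre_id), ids)
  j <- match(as.character(edges$post_id), ids)
  W <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(edges$weight),
                            dims = c(n, n))
  tot_in <- Matrix::colSums(W)
  W <- W %*% Matrix::Diagonal(x = ifelse(tot_in > 0, 1 / tot_in, 0))
  set.seed(seed)
  out <- tibble::tibble(neuron_id = ids)
  for (mod in names(seeds)) {
    seed_idx <- match(unique(seeds[[mod]]), ids)
    acc <- numeric(n)
    for (r in seq_len(runs)) {
      step_at <- rep.int(max_step + 1L, n)
      active <- logical(n)
      active[seed_idx] <- TRUE
      step_at[seed_idx] <- 0L
      for (s in seq_len(max_step)) {
        f <- as.numeric(Matrix::crossprod(W, active)) # active-input fraction
        p <- pmin(1, f / f_max)
        p[active] <- 0
        if (!any(p > 0)) break # nothing can ever fire again
        fire <- stats::runif(n) < p
        active[fire] <- TRUE
        step_at[fire] <- s
      }
      acc <- acc + step_at
    }
    out[[mod]] <- acc / runs
  }
  if (!is.null(exclude)) out <- out[!out$neuron_id %in% exclude, ]
  out
}

#' Average an information-flow rank matrix by cell type
#'
#' @param ranks Rank tibble from [information_flow_rank()].
#' @param type_map Tibble (`neuron_id`, `type_label`); every ranked neuron
#'   must be present.
#' @return A tibble `type_label` x modality columns with arithmetic-mean
#'   ranks.
#' @export
average_rank_by_type <- function(ranks, type_map) {
  missing <- setdiff(ranks$neuron_id, type_map$neuron_id)
  if (length(missing) > 0L) {
    stop("no type for ranked neuron(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  ranks |>
    dplyr::inner_join(type_map[, c("neuron_id", "type_label")],
                      by = "neuron_id") |>
    dplyr::group_by(.data$type_label) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                     .groups = "drop")
}

#' Cluster types by their sensory rank vectors
#'
#' Hierarchically clusters the rows of a type-by-modality rank matrix on
#' Euclidean distance and cuts the dendrogram at `height` — the procedure
#' behind grouping descending-neuron types by shared sensory access.
#'
#' @param type_ranks Tibble from [average_rank_by_type()] (first column the
#'   type label, the rest numeric ranks).
#' @param height Dendrogram cut height.
#' @param linkage `stats::hclust` method (default `"ward.D2"`).
#' @return Tibble (`type_label`, `cluster`).
#' @export
cluster_by_rank <- function(type_ranks, height, linkage = "ward.D2") {
  m <- as.matrix(type_ranks[, -1L, drop = FALSE])
  rownames(m) <- type_ranks[[1L]]
  m[!is.finite(m)] <- max(m[is.finite(m)], 0) + 1
  d <- as.matrix(stats::dist(m))
  labels <- cluster_cut(d, height = height, linkage = linkage,
                        similarity = FALSE)
  tibble::tibble(type_label = rownames(m), cluster = unname(labels))
}
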