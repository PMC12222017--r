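#' Build a thresholded partner graph around focal neurons
#'
#' Reproduces the two-stage partner retrieval used for connectivity graphs:
#' first, partners of the focal set passing both `weight >= theta_w` and
#' `percent of the focal neuron's output > theta_pct` are retained; second,
#' motor, sensory and sensory-ascending partners connected with
#' `weight >= theta_sens` are added back (these classes systematically make
#' fewer synapses per neuron, individually, than their population-level
#' effect). The all-by-all adjacency over the retained node set is then
#' converted to input percent of the receiving neuron.
#'
#' Percent-of-output is measured against the focal neuron's total output
#' synapse count in the whole dataset, not within the retained subgraph.
#'
#' @param focal Character vector of focal neuron ids (non-empty).
#' @param edges Edge table (`pre_id`, `post_id`, `weight`).
#' @param classes Tibble (`neuron_id`, `neuron_class`) covering all
#'   endpoints.
#' @param theta_w Initial weight threshold (default 10, inclusive).
#' @param theta_pct Percent-of-output threshold (default 0.5, strict).
#' @param theta_sens Add-back weight threshold for MN/SN/SA partners
#'   (default 5, inclusive).
#' @return A `partner_graph`: list with `nodes` (tibble `neuron_id`,
#'   `neuron_class`, `is_focal`), `edges` (tibble `pre_id`, `post_id`,
#'   `weight`, `input_pct`), and the thresholds used.
#' @export
build_partner_graph <- function(focal, edges, classes,
                                theta_w = 10, theta_pct = 0.5,
                                theta_sens = 5) {
  if (length(focal) == 0L) stop("focal set is empty", call. = FALSE)
  edges <- dplyr::mutate(edges,
                         pre_id = as.character(.data$pre_id),
                         post_id = as.character(.data$post_id))
  out_tot <- edges |>
    dplyr::group_by(.data$pre_id) |>
    dplyr::summarise(total_out = sum(.data$weight), .groups = "drop")
  cls <- stats::setNames(classes$neuron_class, classes$neuron_id)

  focal_edges <- edges |>
    dplyr::filter(.data$pre_id %in% focal | .data$post_id %in% focal) |>
    dplyr::left_join(out_tot, by = "pre_id") |>
    dplyr::mutate(pct_out = 100 * .data$weight / .data$total_out)
  initial <- focal_edges |>
    dplyr::filter(.data$weight >= theta_w, .data$pct_out > theta_pct)
  partners <- setdiff(unique(c(initial$pre_id, initial$post_id)), focal)

  # add-back: MN/SN/SA partners of the retained set at the lower threshold
  retained <- union(focal, partners)
  addback <- edges |>
    dplyr::filter(.data$weight >= theta_sens) |>
    dplyr::filter((.data$pre_id %in% retained &
                     cls[.data$post_id] %in% c("MN", "SN", "SA")) |
                    (.data$post_id %in% retained &
                       cls[.data$pre_id] %in% c("MN", "SN", "SA")))
  nodes <- union(retained, unique(c(addback$pre_id, addback$post_id)))

  sub <- edges |>
    dplyr::filter(.data$pre_id %in% nodes, .data$post_id %in% nodes)
  in_tot <- edges |> # input percent uses the neuron's full input count
    dplyr::group_by(.data$post_id) |>
    dplyr::summarise(total_in = sum(.data$weight), .groups = "drop")
  sub <- sub |>
    dplyr::left_join(in_tot, by = "post_id") |>
    dplyr::mutate(input_pct = 100 * .data$weight / .data$total_in) |>
    dplyr::select("pre_id", "post_id", "weight", "input_pct")

  structure(
    list(
      nodes = tibble::tibble(
        neuron_id = nodes,
        neuron_class = unname(cls[nodes]),
        is_focal = nodes %in% focal
      ),
      edges = sub,
      thresholds = c(theta_w = theta_w, theta_pct = theta_pct,
                     theta_sens = theta_sens)
    ),
    class = "partner_graph"
  )
}

#' @export
print.partner_graph <- function(x, ...) {
  cat("<partner_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (thresholds: w>=", x$thresholds["theta_w"],
      ", pct>", x$thresholds["theta_pct"],
      ", add-back>=", x$thresholds["theta_sens"], ")\n", sep = "")
  invisible(x)
}

#' Average a partner graph's input percents by cell type
#'
#' @param graph A `partner_graph`.
#' @param type_map Tibble (`neuron_id`, `type_label`) covering all nodes.
#' @return Tibble `pre_type`, `post_type`, `input_pct` (mean of member-level
#'   values), `weight` (summed).
#' @export
average_by_type <- function(graph, type_map) {
  missing <- setdiff(graph$nodes$neuron_id, type_map$neuron_id)
  if (length(missing) > 0L) {
    stop("untyped node(s): ", paste(utils::head(missing, 5L), collapse = ", "),
         call. = FALSE)
  }
  tm <- stats::setNames(type_map$type_label, type_map$neuron_id)
  graph$edges |>
    dplyr::mutate(pre_type = unname(tm[.data$pre_id]),
                  post_type = unname(tm[.data$post_id])) |>
    dplyr::group_by(.data$pre_type, .data$post_type) |>
    dplyr::summarise(input_pct = mean(.data$input_pct),
                     weight = sum(.data$weight), .groups = "drop")
}

#' Class composition of a focal set's partners
#'
#' Synapse-weighted fraction of input (or output) partners per neuron class —
#' the summary behind partner-composition pie charts.
#'
#' @param focal Focal neuron ids.
#' @param edges Edge table.
#' @param classes Tibble (`neuron_id`, `neuron_class`).
#' @param direction `"in"` (partners presynaptic to the focal set) or
#'   `"out"`.
#' @return Tibble `neuron_class`, `weight`, `fraction` (sums to 1); empty
#'   when the focal set has no partners.
#' @export
class_composition <- function(focal, edges, classes,
                              direction = c("in", "out")) {
  direction <- match.arg(direction)
  cls <- stats::setNames(classes$neuron_class, classes$neuron_id)
  e <- if (direction == "in") {
    edges[as.character(edges$post_id) %in% focal, ]
  } else {
    edges[as.character(edges$pre_id) %in% focal, ]
  }
  partner <- if (direction == "in") as.character(e$pre_id) else
    as.character(e$post_id)
  if (nrow(e) == 0L) {
    return(tibble::tibble(neuron_class = character(0), weight = numeric(0),
                          fraction = numeric(0)))
  }
  tibble::tibble(neuron_class = unname(cls[partner]), weight = e$weight) |>
    dplyr::group_by(.data$neuron_class) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop") |>
    dplyr::mutate(fraction = .data$weight / sum(.data$weight))
}

#' Stereotypy statistics for paired connection weights
#'
#' Compares matched connection weights measured twice (left vs right
#' hemisphere, or the same circuit in two datasets): Pearson correlation and
#' the least-squares slope of b on a constrained through the origin,
#' `slope = sum(a*b) / sum(a^2)`. The free-intercept slope is also reported
#' for reference.
#'
#' @param weights_a,weights_b Equal-length paired weight vectors.
#' @return Tibble `pearson_r`, `slope` (through origin), `slope_free`,
#'   `n`. With fewer than 2 points or zero variance, `pearson_r` is `NA`.
#' @export
stereotypy_stats <- function(weights_a, weights_b) {
  stopifnot(length(weights_a) == length(weights_b))
  n <- length(weights_a)
  r <- if (n < 2L || stats::sd(weights_a) == 0 || stats::sd(weights_b) == 0) {
    NA_real_
  } else {
    stats::cor(weights_a, weights_b)
  }
  slope <- if (sum(weights_a^2) > 0) {
    sum(weights_a * weights_b) / sum(weights_a^2)
  } else {
    NA_real_
  }
  slope_free <- if (n >= 2L && stats::sd(weights_a) > 0) {
    unname(stats::coef(stats::lm(weights_b ~ weights_a))[2L])
  } else {
    NA_real_
  }
  tibble::tibble(pearson_r = r, slope = slope, slope_free = slope_free, n = n)
}

#' Effective multi-hop connectivity from sources to targets
#'
#' Sums, over path lengths 1..`max_hops`, the products of input fractions
#' along all paths from the source set to each target: with `A` the
#' column-normalized (input-fraction) adjacency, the per-target effective
#' weight is the relevant entries of `A + A^2 + ... + A^max_hops` summed over
#' sources.
#'
#' @param sources,targets Neuron id vectors.
#' @param edges Edge table.
#' @param max_hops Maximum path length (default 2).
#' @return Tibble `target_id`, `effective_weight`.
#' @export
effective_connectivity <- function(sources, targets, edges, max_hops = 2) {
  if (max_hops < 1) stop("max_hops must be >= 1", call. = FALSE)
  ids <- sort(unique(c(as.character(edges$pre_id), as.character(edges$post_id),
                       sources, targets)))
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(match(as.character(edges$pre_id), ids),
          match(as.character(edges$post_id), ids))] <- edges$weight
  tot_in <- colSums(A)
  A <- sweep(A, 2L, ifelse(tot_in > 0, tot_in, 1), "/")
  acc <- matrix(0, n, n, dimnames = dimnames(A))
  P <- diag(n)
  for (h in seq_len(max_hops)) {
    P <- P %*% A
    acc <- acc + P
  }
  eff <- colSums(acc[sources, targets, drop = FALSE])
  tibble::tibble(target_id = targets, effective_weight = unname(eff))
}

#' Voxelized synapse density
#'
#' Tiles the bounding box of the (optionally cleft-score-filtered) synapses
#' into isotropic voxels and counts synapses per voxel. The grid is anchored
#' at the floor of the bounding box to voxel multiples, so it is
#' deterministic and translation-covariant.
#'
#' @param synapses Synapse table with `x`, `y`, `z` (nm) and optionally
#'   `cleft_score`.
#' @param voxel Voxel edge length, nm (default 5000 = 5 um).
#' @param cleft_min If supplied, keep only synapses with
#'   `cleft_score > cleft_min` (strict; the conventional filter is 50).
#' @return A `density_grid`: list with `origin` (xyz nm), `voxel`, `counts`
#'   (3D integer array). Sum of counts equals the number of synapses passing
#'   the filter. An empty result warns and returns a zero-size grid.
#' @export
synapse_density <- function(synapses, voxel = 5000, cleft_min = NULL) {
  s <- synapses
  if (!is.null(cleft_min)) s <- s[s$cleft_score > cleft_min, ]
  if (nrow(s) == 0L) {
    warning("no synapses after filtering", call. = FALSE)
    return(structure(list(origin = c(NA, NA, NA), voxel = voxel,
                          counts = array(integer(0), dim = c(0, 0, 0))),
                     class = "density_grid"))
  }
  stopifnot(all(is.finite(s$x)), all(is.finite(s$y)), all(is.finite(s$z)))
  origin <- c(floor(min(s$x) / voxel), floor(min(s$y) / voxel),
              floor(min(s$z) / voxel)) * voxel
  ix <- floor((s$x - origin[1L]) / voxel) + 1L
  iy <- floor((s$y - origin[2L]) / voxel) + 1L
  iz <- floor((s$z - origin[3L]) / voxel) + 1L
  dims <- c(max(ix), max(iy), max(iz))
  counts <- array(0L, dim = dims)
  for (k in seq_along(ix)) {
    counts[ix[k], iy[k], iz[k]] <- counts[ix[k], iy[k], iz[k]] + 1L
  }
  structure(list(origin = origin, voxel = voxel, counts = counts),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat("<density_grid> ", paste(dim(x$counts), collapse = " x "),
      " voxels of ", x$voxel, " nm, ", sum(x$counts), " synapses\n", sep = "")
  invisible(x)
}

#' Tidy a density grid into one row per occupied voxel
#' @param x A `density_grid`.
#' @param ... Unused.
#' @return Tibble `x`, `y`, `z` (voxel centre, nm), `count`.
#' @export
tidy.density_grid <- function(x, ...) {
  if (length(x$counts) == 0L) {
    return(tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          count = integer(0)))
  }
  idx <- which(x$counts > 0, arr.ind = TRUE)
  cx <- x$origin[1L] + (idx[, 1L] - 0.5) * x$voxel
  cy <- x$origin[2L] + (idx[, 2L] - 0.5) * x$voxel
  cz <- x$origin[3L] + (idx[, 3L] - 0.5) * x$voxel
  cn <- x$counts[idx]
  tibble::tibble(x = cx, y = cy, z = cz, count = cn)
}
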