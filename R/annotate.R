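#' Assign soma side relative to the sagittal midline
#'
#' Neurons with a soma get their side from the soma x position; neurons whose
#' soma is lost or out of volume (common for sensory ascending neurons) fall
#' back to the x position where they cross the neck plane. Positions within
#' `delta` of the midline are `center`; with neither position available the
#' side is `unknown`.
#'
#' @param neurons Neuron table with optional `soma_x` and optional
#'   `neck_cross_x` columns (nm).
#' @param midline_x Midline plane, nm.
#' @param delta Half-width of the `center` band, nm (default 2000).
#' @return The neuron table with a `side` column (re)computed.
#' @export
assign_soma_side <- function(neurons, midline_x, delta = 2000) {
  x <- rep(NA_real_, nrow(neurons))
  if ("soma_x" %in% names(neurons)) x <- neurons$soma_x
  if ("neck_cross_x" %in% names(neurons)) {
    x <- ifelse(is.na(x), neurons$neck_cross_x, x)
  }
  side <- dplyr::case_when(
    is.na(x) ~ "unknown",
    x < midline_x - delta ~ "left",
    x > midline_x + delta ~ "right",
    TRUE ~ "center"
  )
  dplyr::mutate(neurons, side = side)
}

#' Per-neuron neuropil synapse fractions
#'
#' Tabulates, for each neuron and synapse role, the fraction of its labelled
#' synapses falling in each neuropil. The convention for which role to use is
#' class-dependent: for brain profiles, presynapses for ascending neurons and
#' postsynapses for descending neurons (dendrites are what is being
#' localized); nerve-cord profiles use the opposite role per class.
#'
#' @param synapses Synapse table with `neuron_id`, `role`, `neuropil`.
#' @param role Which role to profile: `"pre"` or `"post"`.
#' @return A tibble `neuron_id`, `neuropil`, `fraction`; fractions sum to 1
#'   per neuron over labelled synapses.
#' @export
neuropil_fractions <- function(synapses, role) {
  synapses |>
    dplyr::filter(.data$role == .env$role, !is.na(.data$neuropil)) |>
    dplyr::count(.data$neuron_id, .data$neuropil) |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("neuron_id", "neuropil", "fraction")
}

#' Assign a brain neuropil code from synapse fractions
#'
#' The brain rule: a single neuropil is assigned if it holds at least 80% of
#' the neuron's (labelled) synapses; a two-neuropil code
#' `primary_secondary` if the top two together reach 80% and each holds at
#' least 5%; otherwise `multi`. No labelled synapses gives `unassigned`.
#'
#' @param fractions Named numeric vector of neuropil fractions for one
#'   neuron, or a tibble with `neuropil` and `fraction`.
#' @param threshold Majority threshold (default 0.80, inclusive).
#' @param floor_second Minimum share for each of a two-neuropil code
#'   (default 0.05).
#' @return A single code string.
#' @export
assign_brain_neuropil <- function(fractions, threshold = 0.80,
                                  floor_second = 0.05) {
  fr <- as_fraction_vector(fractions)
  if (length(fr) == 0L || sum(fr) == 0) return("unassigned")
  fr <- sort(fr, decreasing = TRUE)
  # deterministic tie-break: alphabetical within equal fractions
  fr <- fr[order(-fr, names(fr))]
  if (fr[1L] >= threshold) return(names(fr)[1L])
  if (length(fr) >= 2L && fr[1L] + fr[2L] >= threshold &&
      fr[1L] >= floor_second && fr[2L] >= floor_second) {
    return(paste(names(fr)[1:2], collapse = "_"))
  }
  "multi"
}

#' Default nerve-cord neuropil code map
#'
#' Maps full neuropil names to the two-letter codes used in annotation. The
#' published code list prints `hl` for both the haltere tectulum and the
#' hind-leg neuropil; this table resolves the collision by giving the haltere
#' tectulum `ht`, and is user-replaceable precisely because that collision is
#' ambiguous in print.
#'
#' @return A named character vector: names are neuropil labels, values codes.
#' @export
vnc_code_map <- function() {
  c(NTct = "nt", WTct = "wt", HTct = "ht", IntTct = "it", LTct = "lt",
    LegNpT1 = "fl", LegNpT2 = "ml", LegNpT3 = "hl", mVAC = "mv",
    Ov = "ov", ANm = "ad")
}

#' Assign a nerve-cord neuropil code from synapse fractions
#'
#' The nerve-cord rule: a single two-letter code if one neuropil holds more
#' than 80% of the profiled synapses; else `ut` (upper tectulum) or `xl`
#' (leg neuropils) if the respective region set sums to more than 80%; else
#' `xn` (multiple neuropils). A neuron with only a soma and soma tract in the
#' nerve cord is coded `XA` regardless of fractions.
#'
#' @param fractions Named fractions or tibble, as
#'   [assign_brain_neuropil()].
#' @param region_sets Named list with `upper_tectulum` and `leg_neuropils`
#'   members (neuropil labels).
#' @param soma_only If `TRUE` the neuron is coded `XA`.
#' @param threshold Majority threshold, strict (default 0.80: "more than
#'   80%").
#' @param code_map Label-to-code map, default [vnc_code_map()].
#' @return A single code string.
#' @export
assign_vnc_neuropil <- function(fractions, region_sets, soma_only = FALSE,
                                threshold = 0.80, code_map = vnc_code_map()) {
  if (isTRUE(soma_only)) return("XA")
  fr <- as_fraction_vector(fractions)
  if (length(fr) == 0L || sum(fr) == 0) return("unassigned")
  fr <- fr[order(-fr, names(fr))]
  if (fr[1L] > threshold) {
    lbl <- names(fr)[1L]
    return(unname(code_map[lbl] %|na|% lbl))
  }
  ut <- sum(fr[names(fr) %in% region_sets$upper_tectulum])
  xl <- sum(fr[names(fr) %in% region_sets$leg_neuropils])
  if (ut > threshold) return("ut")
  if (xl > threshold) return("xl")
  "xn"
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

as_fraction_vector <- function(fractions) {
  if (is.data.frame(fractions)) {
    fr <- stats::setNames(fractions$fraction, fractions$neuropil)
  } else {
    fr <- fractions
  }
  fr <- fr[fr > 0]
  if (length(fr) > 0L && abs(sum(fr) - 1) > 1e-9) fr <- fr / sum(fr)
  fr
}

#' Reconcile neuropil codes across a pair or group of neurons
#'
#' When members of a left-right pair or group get inconsistent codes, the
#' rule is re-applied to the mean of the members' fraction vectors.
#'
#' @param members List of named fraction vectors (or tibbles), one per
#'   member.
#' @param rule `"brain"` or `"vnc"`.
#' @param ... Passed to the underlying rule
#'   ([assign_brain_neuropil()] / [assign_vnc_neuropil()]).
#' @return The group-level code.
#' @export
assign_group_neuropil <- function(members, rule = c("brain", "vnc"), ...) {
  rule <- match.arg(rule)
  vecs <- lapply(members, as_fraction_vector)
  labels <- sort(unique(unlist(lapply(vecs, names))))
  mean_fr <- vapply(labels, function(l) {
    mean(vapply(vecs, function(v) if (l %in% names(v)) v[[l]] else 0,
                numeric(1)))
  }, numeric(1))
  if (rule == "brain") assign_brain_neuropil(mean_fr, ...)
  else assign_vnc_neuropil(mean_fr, ...)
}

#' Annotate every neuron in a table with a neuropil code
#'
#' Applies the class-role convention (presynapses for ascending, postsynapses
#' for descending profiles in the brain; opposite in the nerve cord), then
#' the brain or nerve-cord rule per neuron.
#'
#' @param neurons Neuron table (`neuron_id`, `neuron_class`).
#' @param synapses Synapse table with `neuropil` labels.
#' @param rule `"brain"` or `"vnc"`.
#' @param region_sets Required for the `"vnc"` rule.
#' @param ... Extra rule parameters.
#' @return The neuron table with a `neuropil_code` column.
#' @export
annotate_neuropil <- function(neurons, synapses, rule = c("brain", "vnc"),
                              region_sets = NULL, ...) {
  rule <- match.arg(rule)
  role_for <- function(class) {
    if (rule == "brain") ifelse(class == "DN", "post", "pre")
    else ifelse(class == "DN", "pre", "post")
  }
  fr_pre <- neuropil_fractions(synapses, "pre")
  fr_post <- neuropil_fractions(synapses, "post")
  soma_only <- if ("soma_only" %in% names(neurons)) neurons$soma_only
  else rep(FALSE, nrow(neurons))
  codes <- vapply(seq_len(nrow(neurons)), function(i) {
    role <- role_for(neurons$neuron_class[i])
    fr <- if (role == "pre") fr_pre else fr_post
    fr <- fr[fr$neuron_id == neurons$neuron_id[i], ]
    if (rule == "brain") assign_brain_neuropil(fr, ...)
    else assign_vnc_neuropil(fr, region_sets, soma_only = soma_only[i], ...)
  }, character(1))
  dplyr::mutate(neurons, neuropil_code = codes)
}

#' Longest neurite from an entry point
#'
#' Reduces a skeleton to its single longest path (by cable length) starting
#' at the node nearest the given entry point — the reduction used before
#' tract assignment so only the main longitudinal neurite is compared with
#' the tract centerlines.
#'
#' @param skeleton A skeleton node table.
#' @param entry_point Numeric xyz (nm); must lie within 5 um of some node.
#' @return Matrix of path points (ordered from entry to tip).
#' @export
longest_neurite <- function(skeleton, entry_point) {
  pts <- as.matrix(skeleton[, c("x", "y", "z")])
  d <- sqrt(colSums((t(pts) - entry_point)^2))
  start <- which.min(d)
  if (d[start] > 5000) {
    stop("entry point is ", round(d[start]), " nm from the nearest node (> 5 um)",
         call. = FALSE)
  }
  # undirected adjacency from parent links
  idx <- match(skeleton$parent_id, skeleton$node_id)
  n <- nrow(skeleton)
  adj <- vector("list", n)
  wts <- vector("list", n)
  for (i in which(!is.na(idx))) {
    j <- idx[i]
    w <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    adj[[i]] <- c(adj[[i]], j); wts[[i]] <- c(wts[[i]], w)
    adj[[j]] <- c(adj[[j]], i); wts[[j]] <- c(wts[[j]], w)
  }
  # DFS from entry: track the farthest node by path length, keep parents
  dist <- rep(-1, n); parent <- rep(NA_integer_, n)
  dist[start] <- 0
  stack <- start
  while (length(stack) > 0L) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    nb <- adj[[v]]
    for (k in seq_along(nb)) {
      u <- nb[k]
      if (dist[u] < 0) {
        dist[u] <- dist[v] + wts[[v]][k]
        parent[u] <- v
        stack <- c(stack, u)
      }
    }
  }
  tip <- which.max(dist)
  path <- tip
  while (!is.na(parent[path[1L]])) path <- c(parent[path[1L]], path)
  pts[path, , drop = FALSE]
}

#' Assign a longitudinal tract to a neuron
#'
#' Simplifies the skeleton to its longest neurite from the nerve-cord entry
#' point and assigns the tract whose centerline has the smallest mean
#' closest-point distance to that neurite.
#'
#' @param skeleton A skeleton node table.
#' @param entry_point Numeric xyz of the nerve-cord entry (nm).
#' @param tracts A tibble with `tract` and point columns `x`,`y`,`z`
#'   (polyline per tract, >= 2 points each), or a named list of point
#'   matrices.
#' @return The winning tract name (character).
#' @export
assign_tract <- function(skeleton, entry_point, tracts) {
  if (is.data.frame(tracts)) {
    tracts <- lapply(split(seq_len(nrow(tracts)), tracts$tract),
                     function(i) as.matrix(tracts[i, c("x", "y", "z")]))
  }
  if (length(tracts) == 0L) stop("no tracts supplied", call. = FALSE)
  path <- longest_neurite(skeleton, entry_point)
  dists <- vapply(tracts, function(cl) mean_closest_distance(path, cl),
                  numeric(1))
  names(dists)[which.min(dists)]
}

# mean over path points of distance to the nearest centerline point
mean_closest_distance <- function(path, centerline) {
  nn <- .nn_dotprod_cpp(path, matrix(0, nrow(path), 3L),
                        centerline, matrix(0, nrow(centerline), 3L))
  mean(nn$dist)
}
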