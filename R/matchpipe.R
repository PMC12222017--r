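#' Pair neurons across hemispheres within one dataset
#'
#' Mirrors the left cohort across the midline, scores it against the right
#' cohort with mean-normalized NBLAST, and keeps mutual best matches with a
#' score of at least `theta_pair` as pairs. Neurons whose top two candidate
#' scores differ by less than `delta_group` are ambiguous (typical for
#' population types with several near-identical members per side); they are
#' merged with their candidates into larger groups rather than forced into
#' pairs. Everything else is flagged unpaired.
#'
#' @param ds A `connectome_dataset` with sides assigned.
#' @param score_fn NBLAST score function (default [nblast_score_fn()]).
#' @param theta_pair Minimum mean-normalized score for a pair (default 0.4).
#' @param delta_group Ambiguity gap below which candidates are grouped
#'   (default 0.05).
#' @param resample_step,k Dotprops construction parameters, nm / neighbours.
#' @param dotprops Optional named list of precomputed (unmirrored) `dotprops`
#'   keyed by neuron id, to avoid recomputation across stages.
#' @return An `lr_pairing`: list with `pairs` (tibble `left_id`, `right_id`,
#'   `score`), `groups` (tibble `neuron_id`, `group_id`), `unpaired`
#'   (character), and the score matrix.
#' @export
pair_left_right <- function(ds, score_fn = nblast_score_fn(),
                            theta_pair = 0.4, delta_group = 0.05,
                            resample_step = 1000, k = 5, dotprops = NULL) {
  if (is.null(dotprops)) {
    dotprops <- lapply(ds$skeletons, skeleton_to_dotprops,
                       resample_step = resample_step, k = k)
  }
  left_ids <- ds$neurons$neuron_id[ds$neurons$side == "left"]
  right_ids <- ds$neurons$neuron_id[ds$neurons$side == "right"]
  left_ids <- intersect(left_ids, names(dotprops))
  right_ids <- intersect(right_ids, names(dotprops))
  if (length(left_ids) == 0L || length(right_ids) == 0L) {
    stop("empty cohort on one side", call. = FALSE)
  }
  dp_right <- dotprops[right_ids]
  dp_left <- lapply(dotprops[left_ids], mirror_points,
                    midline_x = ds$atlas$midline_x)
  scores <- nblast_allbyall(dp_left, targets = dp_right, score_fn = score_fn)
  pair_from_scores(scores, theta_pair, delta_group)
}

# core pairing logic on a left x right score matrix (exposed for testing)
pair_from_scores <- function(scores, theta_pair, delta_group) {
  m <- unclass(scores)
  left_ids <- rownames(m); right_ids <- colnames(m)

  top2 <- function(v) sort(v, decreasing = TRUE)[seq_len(min(2L, length(v)))]
  ambiguous_l <- vapply(seq_along(left_ids), function(i) {
    t2 <- top2(m[i, ])
    length(t2) == 2L && t2[1L] - t2[2L] < delta_group && t2[2L] >= theta_pair
  }, logical(1))
  ambiguous_r <- vapply(seq_along(right_ids), function(j) {
    t2 <- top2(m[, j])
    length(t2) == 2L && t2[1L] - t2[2L] < delta_group && t2[2L] >= theta_pair
  }, logical(1))

  best_r <- apply(m, 1L, which.max) # per left neuron
  best_l <- apply(m, 2L, which.max) # per right neuron

  pairs <- list(); grouped <- character(0); group_members <- list()
  for (i in seq_along(left_ids)) {
    j <- best_r[i]
    mutual <- best_l[j] == i
    ok <- m[i, j] >= theta_pair
    if (mutual && ok && !ambiguous_l[i] && !ambiguous_r[j]) {
      pairs[[length(pairs) + 1L]] <-
        tibble::tibble(left_id = left_ids[i], right_id = right_ids[j],
                       score = m[i, j])
    }
  }
  # ambiguous neurons pull in every candidate within delta_group of their top
  for (i in which(ambiguous_l)) {
    cand <- right_ids[m[i, ] >= max(m[i, ]) - delta_group & m[i, ] >= theta_pair]
    group_members[[length(group_members) + 1L]] <- c(left_ids[i], cand)
  }
  for (j in which(ambiguous_r)) {
    cand <- left_ids[m[, j] >= max(m[, j]) - delta_group & m[, j] >= theta_pair]
    group_members[[length(group_members) + 1L]] <- c(right_ids[j], cand)
  }
  group_members <- merge_overlapping(group_members)
  groups <- if (length(group_members) > 0L) {
    tibble::tibble(
      neuron_id = unlist(group_members),
      group_id = rep(sprintf("group_%03d", seq_along(group_members)),
                     lengths(group_members))
    )
  } else {
    tibble::tibble(neuron_id = character(0), group_id = character(0))
  }
  pairs <- if (length(pairs) > 0L) dplyr::bind_rows(pairs) else
    tibble::tibble(left_id = character(0), right_id = character(0),
                   score = numeric(0))
  # a neuron in a group cannot also be in a pair
  pairs <- pairs[!(pairs$left_id %in% groups$neuron_id |
                     pairs$right_id %in% groups$neuron_id), ]
  paired_or_grouped <- c(pairs$left_id, pairs$right_id, groups$neuron_id)
  structure(
    list(pairs = pairs, groups = groups,
         unpaired = setdiff(c(left_ids, right_ids), paired_or_grouped),
         scores = scores),
    class = "lr_pairing"
  )
}

merge_overlapping <- function(sets) {
  sets <- lapply(sets, unique)
  changed <- TRUE
  while (changed && length(sets) > 1L) {
    changed <- FALSE
    for (i in seq_len(length(sets) - 1L)) {
      for (j in seq.int(i + 1L, length(sets))) {
        if (length(intersect(sets[[i]], sets[[j]])) > 0L) {
          sets[[i]] <- union(sets[[i]], sets[[j]])
          sets[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  sets
}

#' @export
print.lr_pairing <- function(x, ...) {
  cat("<lr_pairing> ", nrow(x$pairs), " pairs, ",
      length(unique(x$groups$group_id)), " groups, ",
      length(x$unpaired), " unpaired\n", sep = "")
  invisible(x)
}

#' Tidy a left-right pairing into one row per neuron
#' @param x An `lr_pairing`.
#' @param ... Unused.
#' @return Tibble `neuron_id`, `partner_id`, `score`, `status`, `group_id`.
#' @export
tidy.lr_pairing <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(neuron_id = x$pairs$left_id, partner_id = x$pairs$right_id,
                   score = x$pairs$score, status = "paired",
                   group_id = NA_character_),
    tibble::tibble(neuron_id = x$pairs$right_id, partner_id = x$pairs$left_id,
                   score = x$pairs$score, status = "paired",
                   group_id = NA_character_),
    tibble::tibble(neuron_id = x$groups$neuron_id, partner_id = NA_character_,
                   score = NA_real_, status = "grouped",
                   group_id = x$groups$group_id),
    tibble::tibble(neuron_id = x$unpaired, partner_id = NA_character_,
                   score = NA_real_, status = "unpaired",
                   group_id = NA_character_)
  )
}

#' Connectivity fingerprint of a neuron over partner types
#'
#' For each partner cell type, the summed synapse weight to/from that type
#' normalized by the neuron's total weight in that direction — a direction
#' profile that is invariant to overall synapse-count scale and so comparable
#' across datasets. `"both"` concatenates the input and output profiles.
#'
#' @param neuron_id The focal neuron.
#' @param edges Edge table.
#' @param type_map Tibble (`neuron_id`, `type_label`) typing the partners.
#' @param direction `"in"`, `"out"` or `"both"`.
#' @param type_space Optional character vector fixing the order and universe
#'   of type labels so fingerprints from different datasets align.
#' @return Named numeric vector (zero vector for an isolated neuron).
#' @export
connectivity_fingerprint <- function(neuron_id, edges, type_map,
                                     direction = c("both", "in", "out"),
                                     type_space = NULL) {
  direction <- match.arg(direction)
  if (is.null(type_space)) type_space <- sort(unique(type_map$type_label))
  tm <- stats::setNames(type_map$type_label, type_map$neuron_id)
  one <- function(partner_ids, weights) {
    v <- stats::setNames(numeric(length(type_space)), type_space)
    tot <- sum(weights)
    if (tot > 0) {
      agg <- tapply(weights, tm[partner_ids], sum)
      agg <- agg[!is.na(names(agg))]
      v[names(agg)] <- agg / tot
    }
    v
  }
  if (direction %in% c("in", "both")) {
    e_in <- edges[as.character(edges$post_id) == neuron_id, ]
    vin <- one(as.character(e_in$pre_id), e_in$weight)
  }
  if (direction %in% c("out", "both")) {
    e_out <- edges[as.character(edges$pre_id) == neuron_id, ]
    vout <- one(as.character(e_out$post_id), e_out$weight)
  }
  switch(direction,
         "in" = vin,
         "out" = vout,
         both = c(stats::setNames(vin, paste0("in:", names(vin))),
                  stats::setNames(vout, paste0("out:", names(vout)))))
}

#' Cosine similarity between non-negative vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return `a . b / (|a| |b|)` in [0, 1] for non-negative inputs; defined as
#'   0 when either vector is all zero.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Match neurons across two datasets
#'
#' Transforms dataset A skeletons into dataset B's space with the landmark
#' thin-plate spline, scores same-side candidates by mean-normalized NBLAST,
#' blends in connectivity-fingerprint cosine similarity as
#' `combined = w_m * morph + w_c * conn`, and assigns matches greedily by
#' descending combined score with mutual exclusivity. Candidates below
#' `theta_match` stay unmatched. Matched records get a confidence of 1-5 by
#' binning the combined score (default edges 0.2/0.4/0.6/0.8; above 0.6,
#' i.e. >3, is a high-confidence match).
#'
#' @param ds_a,ds_b `connectome_dataset`s, internally paired.
#' @param tps A `tps_transform` fitted from A's space to B's.
#' @param weights Two non-negative weights `c(w_m, w_c)` summing to 1
#'   (default `c(0.7, 0.3)`: morphology leads, connectivity resolves
#'   ambiguity).
#' @param theta_match Minimum combined score for a match (default 0.3).
#' @param conf_edges Confidence bin edges (default `c(0.2, 0.4, 0.6, 0.8)`).
#' @param score_fn,resample_step,k NBLAST parameters.
#' @param dotprops_a,dotprops_b Optional named lists of precomputed
#'   (untransformed) `dotprops` keyed by neuron id.
#' @return A `match_result`: tibble with class attribute, columns `id_a`,
#'   `id_b`, `morph_score`, `conn_score`, `combined`, `confidence`, `status`;
#'   unmatched neurons of either dataset appear with the other id `NA`.
#' @export
cross_dataset_match <- function(ds_a, ds_b, tps,
                                weights = c(0.7, 0.3), theta_match = 0.3,
                                conf_edges = c(0.2, 0.4, 0.6, 0.8),
                                score_fn = nblast_score_fn(),
                                resample_step = 1000, k = 5,
                                dotprops_a = NULL, dotprops_b = NULL) {
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1", call. = FALSE)
  }
  if (!inherits(tps, "tps_transform")) stop("missing transform", call. = FALSE)
  if (is.null(dotprops_a)) {
    dotprops_a <- lapply(ds_a$skeletons, skeleton_to_dotprops,
                         resample_step = resample_step, k = k)
  }
  if (is.null(dotprops_b)) {
    dotprops_b <- lapply(ds_b$skeletons, skeleton_to_dotprops,
                         resample_step = resample_step, k = k)
  }
  ids_a <- intersect(ds_a$neurons$neuron_id, names(dotprops_a))
  ids_b <- intersect(ds_b$neurons$neuron_id, names(dotprops_b))
  side_a <- stats::setNames(ds_a$neurons$side, ds_a$neurons$neuron_id)[ids_a]
  side_b <- stats::setNames(ds_b$neurons$side, ds_b$neurons$neuron_id)[ids_b]
  dp_a <- lapply(dotprops_a[ids_a], function(d) apply_tps(tps, d))
  dp_b <- dotprops_b[ids_b]

  same_side <- outer(side_a, side_b, `==`) # candidates share a side
  morph <- unclass(nblast_allbyall_masked(dp_a, dp_b, score_fn, same_side))
  morph[!is.finite(morph)] <- -Inf
  dimnames(morph) <- list(ids_a, ids_b)

  type_space <- sort(union(ds_a$neurons$type_label, ds_b$neurons$type_label))
  fp_a <- lapply(ids_a, connectivity_fingerprint, edges = ds_a$edges,
                 type_map = ds_a$neurons, type_space = type_space)
  fp_b <- lapply(ids_b, connectivity_fingerprint, edges = ds_b$edges,
                 type_map = ds_b$neurons, type_space = type_space)

  combined <- morph
  for (i in seq_along(ids_a)) {
    for (j in seq_along(ids_b)) {
      if (!is.finite(morph[i, j])) next
      conn <- cosine_similarity(fp_a[[i]], fp_b[[j]])
      combined[i, j] <- weights[1L] * morph[i, j] + weights[2L] * conn
    }
  }

  # greedy mutual-exclusive assignment by descending combined score
  cand <- which(is.finite(combined) & combined >= theta_match, arr.ind = TRUE)
  ord <- order(combined[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  taken_a <- logical(length(ids_a)); taken_b <- logical(length(ids_b))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    if (taken_a[i] || taken_b[j]) next
    taken_a[i] <- TRUE; taken_b[j] <- TRUE
    comb_ij <- combined[i, j]
    conn <- (comb_ij - weights[1L] * morph[i, j]) / max(weights[2L], 1e-12)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id_a = ids_a[i], id_b = ids_b[j],
      morph_score = morph[i, j],
      conn_score = if (weights[2L] > 0) conn else NA_real_,
      combined = comb_ij,
      confidence = findInterval(comb_ij, conf_edges) + 1L,
      status = "matched"
    )
  }
  matched <- if (length(rows) > 0L) dplyr::bind_rows(rows) else
    tibble::tibble(id_a = character(0), id_b = character(0),
                   morph_score = numeric(0), conn_score = numeric(0),
                   combined = numeric(0), confidence = integer(0),
                   status = character(0))
  un_a <- setdiff(ids_a, matched$id_a)
  un_b <- setdiff(ids_b, matched$id_b)
  out <- dplyr::bind_rows(
    matched,
    tibble::tibble(id_a = un_a, id_b = NA_character_, morph_score = NA_real_,
                   conn_score = NA_real_, combined = NA_real_,
                   confidence = NA_integer_, status = "unmatched"),
    tibble::tibble(id_a = NA_character_, id_b = un_b, morph_score = NA_real_,
                   conn_score = NA_real_, combined = NA_real_,
                   confidence = NA_integer_, status = "unmatched")
  )
  class(out) <- c("match_result", class(out))
  out
}

#' One-row summary of a cross-dataset match result
#' @param x A `match_result`.
#' @param ... Unused.
#' @return Tibble with match counts and score summaries.
#' @export
glance.match_result <- function(x, ...) {
  m <- x[x$status == "matched", ]
  tibble::tibble(
    n_matched = nrow(m),
    n_unmatched_a = sum(x$status == "unmatched" & !is.na(x$id_a)),
    n_unmatched_b = sum(x$status == "unmatched" & !is.na(x$id_b)),
    mean_combined = mean(m$combined),
    n_high_confidence = sum(m$confidence > 3)
  )
}

#' Operationalized reconstruction-quality check
#'
#' A neuron counts as well reconstructed when it is not flagged truncated and
#' its skeleton has at least `min_nodes` nodes. (In expert workflows this is
#' a judgement call; the node floor is the formalization used here.)
#'
#' @param neurons Neuron table with a `flags` column (comma-separated
#'   tokens).
#' @param skeletons Named list of skeletons.
#' @param min_nodes Minimum node count (default 50).
#' @return Logical vector along `neurons` rows.
#' @export
is_well_reconstructed <- function(neurons, skeletons, min_nodes = 50) {
  nn <- vapply(neurons$neuron_id, function(id) {
    if (id %in% names(skeletons)) nrow(skeletons[[id]]) else 0L
  }, integer(1))
  !has_flag(neurons$flags, "truncated") & nn >= min_nodes
}

has_flag <- function(flags, flag) {
  vapply(strsplit(ifelse(is.na(flags), "", flags), ","),
         function(f) flag %in% trimws(f), logical(1))
}

#' Classify cell types as sex-specific, dimorphic or shared
#'
#' Applies the decision cascade, per cell type, in this fixed order:
#' \enumerate{
#'   \item any member flagged neuropeptidergic, ahn (ascending histaminergic)
#'     or abdominal_innervation: `excluded` (these show morphological
#'     variability unrelated to sex, or sit in a poorly reconstructed
#'     region);
#'   \item type unmatched across datasets and not well reconstructed:
#'     `reconstruction_issue`;
#'   \item type unmatched, well reconstructed, and with a left-right partner
#'     in its own dataset: `sex_specific`;
#'   \item matched but mean morphological score below `tau_d`:
#'     `sexually_dimorphic`;
#'   \item matched with unequal member counts across datasets:
#'     `biological_variation` (number differences are not treated as
#'     dimorphism);
#'   \item otherwise `matched_monomorphic`.
#' }
#' A type that is unmatched and well reconstructed but has no left-right
#' partner is routed to `biological_variation` with rationale
#' `one_side_missing`.
#'
#' Match credibility: a match record is treated as a match for classification
#' only if its connectivity similarity reaches `conn_floor`, or its
#' morphology score reaches `tau_d` with both endpoints well reconstructed.
#' Two failure modes motivate this: coincidental pairings of leftover neurons
#' score moderately on morphology but share no partners, and a truncated
#' fragment scores deceptively well against any full neuron on the same
#' tract (the fragment-to-full direction of the mean-normalized score is
#' near 1). A true dimorphic homologue keeps its connectivity fingerprint
#' even when its shape diverges, so it passes the `conn_floor` route. The
#' manual analogue is reviewing low-confidence matches with cosine
#' similarity, and reviewing non-matching neurons to exclude reconstruction
#' problems, before accepting labels.
#'
#' @param matches A `match_result` from [cross_dataset_match()].
#' @param ds_a,ds_b The two datasets (neuron tables supply `type_label` and
#'   `flags`).
#' @param pairing_a,pairing_b `lr_pairing` objects for each dataset.
#' @param tau_d Morphological-difference threshold on the mean-normalized
#'   score (default 0.5).
#' @param conn_floor Minimum connectivity similarity for a match whose
#'   morphology is below `tau_d` to stay credible (default 0.3).
#' @param min_nodes Passed to [is_well_reconstructed()].
#' @return Tibble `type_label`, `label`, `rationale`, `n_a`, `n_b`,
#'   `mean_morph_score` — exactly one row per type.
#' @export
classify_dimorphism <- function(matches, ds_a, ds_b, pairing_a, pairing_b,
                                tau_d = 0.5, conn_floor = 0.3,
                                min_nodes = 50) {
  na_tbl <- ds_a$neurons; nb_tbl <- ds_b$neurons
  # the cascade concerns neck-connective classes; motor/sensory/interneuron
  # scaffolding keeps its types but is not classified
  focal_types <- function(tbl) {
    if ("neuron_class" %in% names(tbl)) {
      tbl$type_label[tbl$neuron_class %in% c("DN", "AN", "SA")]
    } else {
      tbl$type_label
    }
  }
  types <- sort(union(focal_types(na_tbl), focal_types(nb_tbl)))
  wr_a <- is_well_reconstructed(na_tbl, ds_a$skeletons, min_nodes)
  wr_b <- is_well_reconstructed(nb_tbl, ds_b$skeletons, min_nodes)
  has_lr <- function(ids, pairing) {
    any(ids %in% c(pairing$pairs$left_id, pairing$pairs$right_id,
                   pairing$groups$neuron_id))
  }
  exclusion_flags <- c("neuropeptidergic", "ahn", "abdominal_innervation")
  matched <- matches[matches$status == "matched", ]
  wr_id <- c(stats::setNames(wr_a, na_tbl$neuron_id),
             stats::setNames(wr_b, nb_tbl$neuron_id))
  credible <- (!is.na(matched$conn_score) & matched$conn_score >= conn_floor) |
    (matched$morph_score >= tau_d &
       wr_id[matched$id_a] & wr_id[matched$id_b])
  matched <- matched[credible, ]

  rows <- lapply(types, function(ty) {
    mem_a <- na_tbl$neuron_id[na_tbl$type_label == ty]
    mem_b <- nb_tbl$neuron_id[nb_tbl$type_label == ty]
    flags <- c(na_tbl$flags[na_tbl$type_label == ty],
               nb_tbl$flags[nb_tbl$type_label == ty])
    hit <- exclusion_flags[vapply(exclusion_flags,
                                  function(f) any(has_flag(flags, f)),
                                  logical(1))]
    m <- matched[matched$id_a %in% mem_a | matched$id_b %in% mem_b, ]
    mean_morph <- if (nrow(m) > 0) mean(m$morph_score) else NA_real_
    lab <- NULL; why <- NA_character_
    if (length(hit) > 0L) {
      lab <- "excluded"; why <- hit[1L]
    } else if (nrow(m) == 0L) {
      wr <- all(c(wr_a[na_tbl$type_label == ty], wr_b[nb_tbl$type_label == ty]))
      if (!wr) {
        lab <- "reconstruction_issue"; why <- "not_well_reconstructed"
      } else if ((length(mem_a) > 0L && has_lr(mem_a, pairing_a)) ||
                 (length(mem_b) > 0L && has_lr(mem_b, pairing_b))) {
        lab <- "sex_specific"
        why <- if (length(mem_a) > 0L) "absent_in_b" else "absent_in_a"
      } else {
        lab <- "biological_variation"; why <- "one_side_missing"
      }
    } else if (mean_morph < tau_d) {
      lab <- "sexually_dimorphic"; why <- "morphology_below_tau_d"
    } else if (length(mem_a) != length(mem_b)) {
      lab <- "biological_variation"; why <- "unequal_member_counts"
    } else {
      lab <- "matched_monomorphic"; why <- "matched"
    }
    tibble::tibble(type_label = ty, label = lab, rationale = why,
                   n_a = length(mem_a), n_b = length(mem_b),
                   mean_morph_score = mean_morph)
  })
  dplyr::bind_rows(rows)
}

#' Generate new systematic type names
#'
#' Unmatched neurons get fresh systematic names; to keep them distinct from
#' names already assigned in the reference dataset the numbering starts at
#' 999 and counts down.
#'
#' @param n How many names.
#' @param prefix Systematic prefix (class + neuropil/hemilineage code), e.g.
#'   `"DNxl"`.
#' @param start First number (default 999).
#' @return Character vector, e.g. `DNxl999`, `DNxl998`, ...
#' @export
new_type_names <- function(n, prefix, start = 999) {
  if (n < 1) return(character(0))
  paste0(prefix, seq(start, by = -1L, length.out = n))
}
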