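#' Parameters for a full pipeline run
#'
#' Collects every stage's tunables in one validated list. Defaults follow
#' the package-wide conventions: morphology-led matching
#' (`w_m = 0.7, w_c = 0.3`), pairing threshold 0.4 on the mean-normalized
#' NBLAST score, dimorphism threshold 0.5, partner-graph thresholds
#' weight >= 10 / percent output > 0.5 / add-back >= 5, traversal
#' `f_max = 0.3` with 100 runs.
#'
#' @param theta_pair,delta_group Left-right pairing score threshold and
#'   ambiguity gap.
#' @param w_m,w_c Morphology and connectivity weights for cross-dataset
#'   matching (must sum to 1).
#' @param theta_match Minimum combined score for a cross-dataset match.
#' @param conf_edges Confidence bin edges.
#' @param tau_d Dimorphism threshold on the mean-normalized morphology score.
#' @param conn_floor Connectivity-similarity floor for low-morphology matches
#'   to stay credible in classification.
#' @param min_nodes Well-reconstructed node floor.
#' @param theta_w,theta_pct,theta_sens Partner-graph thresholds.
#' @param f_max,runs,max_step Information-flow traversal parameters.
#' @param rank_cut_height Dendrogram cut height for rank-vector clustering.
#' @param linkage Hierarchical-clustering linkage.
#' @param resample_step,k Dotprops parameters (nm, neighbours).
#' @param voxel Synapse-density voxel size, nm.
#' @param side_delta Center band half-width for soma-side assignment, nm.
#' @return A validated `pipeline_params` list.
#' @export
pipeline_params <- function(theta_pair = 0.4, delta_group = 0.05,
                            w_m = 0.7, w_c = 0.3, theta_match = 0.3,
                            conf_edges = c(0.2, 0.4, 0.6, 0.8),
                            tau_d = 0.5, conn_floor = 0.3, min_nodes = 50,
                            theta_w = 10, theta_pct = 0.5, theta_sens = 5,
                            f_max = 0.3, runs = 100, max_step = 20,
                            rank_cut_height = 5, linkage = "ward.D2",
                            resample_step = 1000, k = 5,
                            voxel = 5000, side_delta = 2000) {
  p <- as.list(environment())
  if (abs(w_m + w_c - 1) > 1e-9) {
    stop("w_m + w_c must sum to 1", call. = FALSE)
  }
  if (!(f_max > 0 && f_max <= 1)) stop("f_max must be in (0, 1]", call. = FALSE)
  if (theta_pair < 0 || tau_d < 0 || theta_w < 0 || theta_sens < 0) {
    stop("thresholds must be non-negative", call. = FALSE)
  }
  class(p) <- "pipeline_params"
  p
}

#' Run the full comparative-connectomics pipeline on two datasets
#'
#' Executes the stages in dependency order: anatomical annotation (soma side,
#' nerve-cord neuropil code, tract), left-right pairing per dataset,
#' landmark registration and cross-dataset matching, dimorphism
#' classification; then the independent analyses: information-flow ranking
#' with type averaging and rank clustering, left-right stereotypy statistics
#' over the recovered pairs, and partner class composition.
#'
#' @param ds_a,ds_b Two `connectome_dataset`s (A is transformed into B's
#'   space via the landmark table).
#' @param landmarks Tibble of paired landmark coordinates
#'   (`x_f,y_f,z_f,x_m,y_m,z_m`), A-space first; defaults to
#'   `ds_a$landmarks`.
#' @param seeds Sensory seed table (`dataset_id`, `neuron_id`, `modality`)
#'   for the flow ranking; `NULL` skips that stage.
#' @param tracts Tract centerlines tibble (`tract`, `side`, `x`, `y`, `z`);
#'   `NULL` skips tract assignment.
#' @param params A [pipeline_params()].
#' @param seed Root RNG seed for the stochastic traversal.
#' @param out_dir If non-`NULL`, all result tables are written there as TSV
#'   plus a JSON run summary.
#' @return A `pipeline_run` list: annotated neuron tables, `pairing_a`/`_b`,
#'   `tps`, `matches`, `dimorphism`, `ranks_a`, `type_ranks_a`,
#'   `rank_clusters`, `stereotypy`, `composition`, `summary`.
#' @export
run_pipeline <- function(ds_a, ds_b, landmarks = ds_a$landmarks,
                         seeds = NULL, tracts = NULL,
                         params = pipeline_params(), seed = 1L,
                         out_dir = NULL) {
  stopifnot(inherits(params, "pipeline_params"))
  score_fn <- nblast_score_fn()

  annotate_ds <- function(ds) {
    neu <- assign_soma_side(ds$neurons, ds$atlas$midline_x, params$side_delta)
    neu$side <- ifelse(neu$side == "unknown", ds$neurons$side, neu$side)
    neu <- annotate_neuropil(neu, ds$synapses, rule = "vnc",
                             region_sets = ds$atlas$region_sets)
    if (!is.null(tracts)) {
      tr <- vapply(neu$neuron_id, function(id) {
        sk <- ds$skeletons[[id]]
        if (is.null(sk)) return(NA_character_)
        assign_tract(sk, c(sk$x[1L], sk$y[1L], sk$z[1L]), tracts)
      }, character(1))
      neu$tract <- unname(tr)
    }
    ds$neurons <- neu
    ds
  }
  ds_a <- annotate_ds(ds_a)
  ds_b <- annotate_ds(ds_b)

  dp_a <- lapply(ds_a$skeletons, skeleton_to_dotprops,
                 resample_step = params$resample_step, k = params$k)
  dp_b <- lapply(ds_b$skeletons, skeleton_to_dotprops,
                 resample_step = params$resample_step, k = params$k)

  pairing_a <- pair_left_right(ds_a, score_fn, params$theta_pair,
                               params$delta_group, params$resample_step,
                               params$k, dotprops = dp_a)
  pairing_b <- pair_left_right(ds_b, score_fn, params$theta_pair,
                               params$delta_group, params$resample_step,
                               params$k, dotprops = dp_b)

  if (is.null(landmarks)) stop("no landmark table available", call. = FALSE)
  tps <- fit_tps(as.matrix(landmarks[, c("x_f", "y_f", "z_f")]),
                 as.matrix(landmarks[, c("x_m", "y_m", "z_m")]))
  matches <- cross_dataset_match(ds_a, ds_b, tps,
                                 weights = c(params$w_m, params$w_c),
                                 theta_match = params$theta_match,
                                 conf_edges = params$conf_edges,
                                 score_fn = score_fn,
                                 resample_step = params$resample_step,
                                 k = params$k,
                                 dotprops_a = dp_a, dotprops_b = dp_b)
  dimorphism <- classify_dimorphism(matches, ds_a, ds_b, pairing_a, pairing_b,
                                    tau_d = params$tau_d,
                                    conn_floor = params$conn_floor,
                                    min_nodes = params$min_nodes)

  ranks_a <- type_ranks_a <- rank_clusters <- NULL
  if (!is.null(seeds)) {
    seeds_a <- seeds[seeds$dataset_id == ds_a$dataset_id,
                     c("neuron_id", "modality")]
    ranks_a <- information_flow_rank(ds_a$edges, seeds_a,
                                     f_max = params$f_max, runs = params$runs,
                                     max_step = params$max_step, seed = seed)
    typed <- ds_a$neurons[!is.na(ds_a$neurons$type_label),
                          c("neuron_id", "type_label")]
    ranks_typed <- ranks_a[ranks_a$neuron_id %in% typed$neuron_id, ]
    type_ranks_a <- average_rank_by_type(ranks_typed, typed)
    rank_clusters <- cluster_by_rank(type_ranks_a, params$rank_cut_height,
                                     params$linkage)
  }

  stereotypy <- dplyr::bind_rows(
    dplyr::mutate(pair_weight_stats(pairing_a, ds_a$edges),
                  dataset_id = ds_a$dataset_id),
    dplyr::mutate(pair_weight_stats(pairing_b, ds_b$edges),
                  dataset_id = ds_b$dataset_id)
  )

  dn_a <- ds_a$neurons$neuron_id[ds_a$neurons$neuron_class == "DN"]
  composition <- dplyr::bind_rows(
    dplyr::mutate(class_composition(dn_a, ds_a$edges, ds_a$neurons, "in"),
                  direction = "in"),
    dplyr::mutate(class_composition(dn_a, ds_a$edges, ds_a$neurons, "out"),
                  direction = "out")
  )

  run <- structure(
    list(
      neurons_a = ds_a$neurons, neurons_b = ds_b$neurons,
      pairing_a = pairing_a, pairing_b = pairing_b,
      tps = tps, matches = matches, dimorphism = dimorphism,
      ranks_a = ranks_a, type_ranks_a = type_ranks_a,
      rank_clusters = rank_clusters,
      stereotypy = stereotypy, composition = composition,
      params = params, seed = seed,
      summary = NULL
    ),
    class = "pipeline_run"
  )
  run$summary <- summarize_run(run)
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# left-right output-weight pairs for recovered pairs: for each paired (L, R)
# and each partner type reached by both, the two summed weights
pair_weight_stats <- function(pairing, edges) {
  if (nrow(pairing$pairs) == 0L) {
    return(tibble::tibble(pearson_r = NA_real_, slope = NA_real_,
                          slope_free = NA_real_, n = 0L))
  }
  e <- dplyr::mutate(edges, pre_id = as.character(.data$pre_id))
  out_w <- function(id) {
    ew <- e[e$pre_id == id, ]
    stats::setNames(ew$weight, ew$post_id)
  }
  wa <- numeric(0); wb <- numeric(0)
  for (i in seq_len(nrow(pairing$pairs))) {
    l <- out_w(pairing$pairs$left_id[i])
    r <- out_w(pairing$pairs$right_id[i])
    # align left and right outputs by target rank (strongest first): targets
    # are mirror-distinct neurons, so order is the comparable key
    k <- min(length(l), length(r))
    if (k == 0L) next
    wa <- c(wa, sort(l, decreasing = TRUE)[seq_len(k)])
    wb <- c(wb, sort(r, decreasing = TRUE)[seq_len(k)])
  }
  stereotypy_stats(wa, wb)
}

summarize_run <- function(run) {
  list(
    n_neurons_a = nrow(run$neurons_a),
    n_neurons_b = nrow(run$neurons_b),
    n_pairs_a = nrow(run$pairing_a$pairs),
    n_pairs_b = nrow(run$pairing_b$pairs),
    n_groups_a = length(unique(run$pairing_a$groups$group_id)),
    n_groups_b = length(unique(run$pairing_b$groups$group_id)),
    n_matched = sum(run$matches$status == "matched"),
    n_high_confidence = sum(run$matches$confidence > 3, na.rm = TRUE),
    dimorphism_counts = as.list(table(run$dimorphism$label)),
    seed = run$seed,
    params = unclass(run$params)
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_run>\n",
      "  pairs: ", s$n_pairs_a, " (A) / ", s$n_pairs_b, " (B)\n",
      "  cross-dataset matches: ", s$n_matched,
      " (high confidence: ", s$n_high_confidence, ")\n", sep = "")
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table_file(run$neurons_a, file.path(out_dir, "neurons_a.tsv"))
  write_table_file(run$neurons_b, file.path(out_dir, "neurons_b.tsv"))
  write_table_file(tidy(run$pairing_a), file.path(out_dir, "pairing_a.tsv"))
  write_table_file(tidy(run$pairing_b), file.path(out_dir, "pairing_b.tsv"))
  write_table_file(tibble::as_tibble(run$matches),
                   file.path(out_dir, "matches.tsv"))
  write_table_file(run$dimorphism, file.path(out_dir, "dimorphism.tsv"))
  if (!is.null(run$type_ranks_a)) {
    write_table_file(run$type_ranks_a, file.path(out_dir, "type_ranks.tsv"))
    write_table_file(run$rank_clusters, file.path(out_dir, "rank_clusters.tsv"))
  }
  write_table_file(run$stereotypy, file.path(out_dir, "stereotypy.tsv"))
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Score a pipeline run against planted ground truth
#'
#' Computes the recovery metrics for a run on a synthetic bundle: left-right
#' pair recall and false-pair count, cross-dataset homologue recall and
#' precision (a match is correct when its two neurons share planted type and
#' side), dimorphism-label accuracy with per-label recall, planted neuropil
#' and tract accuracy, and the correlation between planted sensory depth and
#' the computed flow rank.
#'
#' @param run A `pipeline_run`.
#' @param truth Ground-truth list from [generate_connectomes()].
#' @return A one-row tibble of metrics.
#' @export
evaluate_run <- function(run, truth) {
  tn <- truth$neurons
  type_of <- stats::setNames(tn$type_label, tn$neuron_id)
  side_of <- stats::setNames(tn$side, tn$neuron_id)

  # --- left-right pairing (dataset A = female) ---
  pair_metrics <- function(pairing, dsid) {
    tp <- truth$lr_pairs[truth$lr_pairs$dataset_id == dsid, ]
    key <- function(l, r) paste(l, r)
    found <- key(pairing$pairs$left_id, pairing$pairs$right_id)
    want <- key(tp$left_id, tp$right_id)
    recall <- if (length(want) > 0) mean(want %in% found) else NA_real_
    false_pairs <- sum(type_of[pairing$pairs$left_id] !=
                         type_of[pairing$pairs$right_id], na.rm = TRUE)
    c(recall = recall, false_pairs = false_pairs)
  }
  pa <- pair_metrics(run$pairing_a, "f")
  pb <- pair_metrics(run$pairing_b, "m")

  # --- cross-dataset homologues ---
  m <- run$matches[run$matches$status == "matched", ]
  correct <- !is.na(type_of[m$id_a]) &
    type_of[m$id_a] == type_of[m$id_b] &
    side_of[m$id_a] == side_of[m$id_b]
  shared_a <- truth$homologues$id_f
  hom_recall <- mean(shared_a %in% m$id_a[correct])
  hom_precision <- if (nrow(m) > 0) mean(correct) else NA_real_

  # --- dimorphism labels ---
  dm <- dplyr::inner_join(run$dimorphism, truth$dimorphism,
                          by = "type_label", suffix = c("", "_truth"))
  dim_acc <- mean(dm$label == dm$label_truth)
  label_recall <- function(lbl) {
    sub <- dm[dm$label_truth == lbl, ]
    if (nrow(sub) == 0L) return(NA_real_)
    mean(sub$label == lbl)
  }

  # --- neuropil codes and tracts (focal neurons of dataset A and B) ---
  ann <- dplyr::bind_rows(run$neurons_a, run$neurons_b)
  ann <- dplyr::inner_join(ann, tn[, c("neuron_id", "vnc_code", "tract")],
                           by = "neuron_id", suffix = c("", "_truth"))
  npl_acc <- mean(ann$neuropil_code == ann$vnc_code)
  tract_acc <- if ("tract" %in% names(run$neurons_a)) {
    mean(ann$tract == ann$tract_truth, na.rm = TRUE)
  } else {
    NA_real_
  }

  # --- flow rank vs planted depth ---
  rank_depth_cor <- NA_real_
  if (!is.null(run$type_ranks_a)) {
    td <- tn[tn$dataset_id == "f", c("type_label", "modality", "depth")] |>
      dplyr::distinct()
    tr <- dplyr::inner_join(run$type_ranks_a, td, by = "type_label")
    own <- vapply(seq_len(nrow(tr)), function(i) {
      as.numeric(tr[i, tr$modality[i]])
    }, numeric(1))
    rank_depth_cor <- stats::cor(own, tr$depth)
  }

  tibble::tibble(
    pair_recall_a = pa[["recall"]], pair_recall_b = pb[["recall"]],
    false_pairs_a = pa[["false_pairs"]], false_pairs_b = pb[["false_pairs"]],
    homologue_recall = hom_recall, homologue_precision = hom_precision,
    dimorphism_accuracy = dim_acc,
    sex_specific_recall = label_recall("sex_specific"),
    dimorphic_recall = label_recall("sexually_dimorphic"),
    neuropil_accuracy = npl_acc,
    tract_accuracy = tract_acc,
    rank_depth_cor = rank_depth_cor
  )
}
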