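# left-right pairing -------------------------------------------------------

test_that("a mirrored duplicate forms one pair with score ~1", {
  gen <- tiny_bundle()
  atlas <- gen$female$atlas
  sk_r <- gen$female$skeletons[[1]]
  sk_l <- neckmatch:::mirror_skeleton(sk_r, atlas$midline_x)
  ds <- list(
    dataset_id = "toy",
    neurons = tibble::tibble(neuron_id = c("l1", "r1"),
                             side = c("left", "right")),
    skeletons = list(l1 = sk_l, r1 = sk_r),
    atlas = atlas
  )
  out <- pair_left_right(ds)
  expect_equal(nrow(out$pairs), 1)
  expect_equal(out$pairs$left_id, "l1")
  expect_equal(out$pairs$score, 1, tolerance = 1e-6)
})

test_that("two identical left neurons and one right form a group of 3, not a pair", {
  m <- matrix(c(0.9, 0.9), nrow = 2, dimnames = list(c("l1", "l2"), "r1"))
  out <- neckmatch:::pair_from_scores(m, theta_pair = 0.4, delta_group = 0.05)
  expect_equal(nrow(out$pairs), 0)
  expect_equal(sort(out$groups$neuron_id), c("l1", "l2", "r1"))
  expect_equal(length(unique(out$groups$group_id)), 1)
})

test_that("mutual best match below the threshold stays unpaired", {
  m <- matrix(c(0.3, 0.1, 0.1, 0.9), 2, 2,
              dimnames = list(c("l1", "l2"), c("r1", "r2")))
  out <- neckmatch:::pair_from_scores(m, theta_pair = 0.4, delta_group = 0.05)
  expect_equal(out$pairs$left_id, "l2")
  expect_true(all(c("l1", "r1") %in% out$unpaired))
})

test_that("pairing on the synthetic cohort recovers planted pairs without false pairs", {
  gen <- tiny_bundle()
  truth <- gen$truth
  out <- pair_left_right(gen$female)
  want <- paste(truth$lr_pairs$left_id[truth$lr_pairs$dataset_id == "f"],
                truth$lr_pairs$right_id[truth$lr_pairs$dataset_id == "f"])
  got <- paste(out$pairs$left_id, out$pairs$right_id)
  expect_gte(mean(want %in% got), 0.95)
  ttype <- stats::setNames(truth$neurons$type_label, truth$neurons$neuron_id)
  expect_equal(sum(ttype[out$pairs$left_id] != ttype[out$pairs$right_id]), 0)
})

# fingerprints and cosine ----------------------------------------------------

test_that("connectivity fingerprints normalize per direction and type", {
  edges <- tibble::tibble(
    pre_id = c("x", "u1", "u2"), post_id = c("d1", "x", "x"),
    weight = c(10, 6, 2)
  )
  types <- tibble::tibble(neuron_id = c("x", "d1", "u1", "u2"),
                          type_label = c("TX", "TD", "TU", "TU"))
  fin <- connectivity_fingerprint("x", edges, types, "in")
  expect_equal(unname(fin["TU"]), 1)
  fout <- connectivity_fingerprint("x", edges, types, "out")
  expect_equal(unname(fout["TD"]), 1)
  both <- connectivity_fingerprint("x", edges, types, "both")
  expect_equal(unname(both[c("in:TU", "out:TD")]), c(1, 1))
  # scale invariance
  edges2 <- dplyr::mutate(edges, weight = weight * 2)
  expect_equal(connectivity_fingerprint("x", edges2, types, "both"), both)
  # isolated neuron -> zero vector, valid
  iso <- connectivity_fingerprint("d1", edges[0, ], types, "in")
  expect_true(all(iso == 0))
})

test_that("cosine similarity matches the direct formula and handles zeros", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(0, 0), c(1, 1)), 0)
  set.seed(41)
  for (i in 1:5) {
    a <- stats::runif(6); b <- stats::runif(6)
    expect_equal(cosine_similarity(a, b),
                 sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  }
})

# cross-dataset matching -----------------------------------------------------

test_that("matching a dataset against an exact copy matches everything at confidence 5", {
  gen <- tiny_bundle()
  ds <- gen$female
  src <- expand.grid(
    x = seq(-150e3, 150e3, length.out = 3),
    y = seq(0, 300e3, length.out = 4),
    z = seq(0, 100e3, length.out = 3)
  )
  tps <- fit_tps(as.matrix(src), as.matrix(src)) # identity transform
  out <- cross_dataset_match(ds, ds, tps)
  matched <- out[out$status == "matched", ]
  expect_equal(nrow(matched), length(ds$skeletons))
  expect_equal(matched$id_a, matched$id_b)
  expect_true(all(matched$confidence == 5L))
  expect_true(all(matched$combined > 0.9))
})

test_that("weights must sum to one and a transform is mandatory", {
  gen <- tiny_bundle()
  expect_error(cross_dataset_match(gen$female, gen$male, NULL), "transform")
  lat <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1)) * 1000
  tps <- fit_tps(lat, lat)
  expect_error(
    cross_dataset_match(gen$female, gen$male, tps, weights = c(0.8, 0.3)),
    "sum to 1"
  )
})

test_that("greedy mutual-best equals exhaustive optimal assignment when scores are well separated", {
  set.seed(43)
  n <- 6
  # well-separated scores: diagonal dominant by a wide gap
  base <- matrix(stats::runif(n * n, 0, 0.3), n, n)
  diag(base) <- stats::runif(n, 0.7, 1)
  ids <- paste0("t", 1:n)
  dimnames(base) <- list(ids, ids)
  # exhaustive best assignment over all permutations
  perms <- neckmatch_test_perms(n)
  best <- perms[[which.max(vapply(perms, function(p) {
    sum(base[cbind(1:n, p)])
  }, numeric(1)))]]
  # greedy: replicate the package rule (descending score, mutual exclusivity)
  ord <- order(base, decreasing = TRUE)
  taken_r <- taken_c <- logical(n)
  greedy <- integer(n)
  for (o in ord) {
    i <- (o - 1) %% n + 1; j <- (o - 1) %/% n + 1
    if (taken_r[i] || taken_c[j]) next
    taken_r[i] <- taken_c[j] <- TRUE
    greedy[i] <- j
  }
  expect_equal(greedy, best)
})

test_that("swapping the datasets (with the inverted transform) reproduces the match set", {
  gen <- tiny_bundle()
  lm <- gen$landmarks
  tps_ab <- fit_tps(as.matrix(lm[, 1:3]), as.matrix(lm[, 4:6]))
  tps_ba <- fit_tps(as.matrix(lm[, 4:6]), as.matrix(lm[, 1:3]))
  fwd <- cross_dataset_match(gen$female, gen$male, tps_ab)
  rev <- cross_dataset_match(gen$male, gen$female, tps_ba)
  key_f <- paste(fwd$id_a[fwd$status == "matched"],
                 fwd$id_b[fwd$status == "matched"])
  key_r <- paste(rev$id_b[rev$status == "matched"],
                 rev$id_a[rev$status == "matched"])
  # the reverse spline is a refit, not an exact inverse, so demand near-
  # perfect (not bitwise) agreement of the match sets
  overlap <- length(intersect(key_f, key_r)) /
    length(union(key_f, key_r))
  expect_gte(overlap, 0.95)
})

test_that("raising the match threshold never increases the match count", {
  gen <- tiny_bundle()
  lm <- gen$landmarks
  tps <- fit_tps(as.matrix(lm[, 1:3]), as.matrix(lm[, 4:6]))
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7), function(th) {
    out <- cross_dataset_match(gen$female, gen$male, tps, theta_match = th)
    sum(out$status == "matched")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted homologues are matched and sex-specific types stay unmatched", {
  gen <- tiny_bundle()
  lm <- gen$landmarks
  tps <- fit_tps(as.matrix(lm[, 1:3]), as.matrix(lm[, 4:6]))
  out <- cross_dataset_match(gen$female, gen$male, tps)
  m <- out[out$status == "matched", ]
  ttype <- stats::setNames(gen$truth$neurons$type_label,
                           gen$truth$neurons$neuron_id)
  tside <- stats::setNames(gen$truth$neurons$side, gen$truth$neurons$neuron_id)
  correct <- ttype[m$id_a] == ttype[m$id_b] & tside[m$id_a] == tside[m$id_b]
  expect_gte(mean(gen$truth$homologues$id_f %in% m$id_a[correct]), 0.9)
  ss <- gen$truth$dimorphism$type_label[gen$truth$dimorphism$label ==
                                          "sex_specific"]
  expect_false(any(ttype[m$id_a] %in% ss & correct))
})

# dimorphism cascade ----------------------------------------------------------

make_match <- function(id_a, id_b, morph, conn = 1) {
  tibble::tibble(id_a = id_a, id_b = id_b, morph_score = morph,
                 conn_score = conn, combined = 0.7 * morph + 0.3 * conn,
                 confidence = 3L, status = "matched")
}

toy_ds <- function(ids, types, flags = "", dsid = "x") {
  sk <- lapply(ids, function(i) straight_skeleton(60))
  names(sk) <- ids
  list(dataset_id = dsid,
       neurons = tibble::tibble(neuron_id = ids, type_label = types,
                                flags = flags),
       skeletons = sk)
}

toy_pairing <- function(left = character(0), right = character(0)) {
  list(pairs = tibble::tibble(left_id = left, right_id = right,
                              score = rep(0.9, length(left))),
       groups = tibble::tibble(neuron_id = character(0),
                               group_id = character(0)),
       unpaired = character(0))
}

test_that("the exclusion flags dominate the cascade whatever the scores", {
  ds_a <- toy_ds(c("a1", "a2"), c("T1", "T1"), flags = "neuropeptidergic")
  ds_b <- toy_ds(c("b1", "b2"), c("T1", "T1"), flags = "neuropeptidergic")
  matches <- make_match(c("a1", "a2"), c("b1", "b2"), morph = 0.2)
  class(matches) <- c("match_result", class(tibble::tibble()))
  out <- classify_dimorphism(matches, ds_a, ds_b,
                             toy_pairing("a1", "a2"), toy_pairing("b1", "b2"))
  expect_equal(out$label, "excluded")
  expect_equal(out$rationale, "neuropeptidergic")
})

test_that("cascade routes unmatched and matched types per the decision order", {
  # T1: unmatched, well reconstructed, has L-R partner -> sex_specific
  # T2: matched with low morphology but high connectivity -> dimorphic
  # T3: matched, equal counts, high morphology -> monomorphic
  # T4: unmatched, truncated -> reconstruction_issue
  ds_a <- toy_ds(c("a1", "a2", "t2a", "t3a", "t4a"),
                 c("T1", "T1", "T2", "T3", "T4"),
                 flags = c("", "", "", "", "truncated"))
  ds_b <- toy_ds(c("t2b", "t3b", "t4x"), c("T2", "T3", "T4"))
  matches <- dplyr::bind_rows(
    make_match("t2a", "t2b", morph = 0.3, conn = 0.95),
    make_match("t3a", "t3b", morph = 0.9)
  )
  class(matches) <- c("match_result", class(tibble::tibble()))
  out <- classify_dimorphism(matches, ds_a, ds_b,
                             toy_pairing("a1", "a2"), toy_pairing())
  lab <- stats::setNames(out$label, out$type_label)
  expect_equal(unname(lab["T1"]), "sex_specific")
  expect_equal(unname(lab["T2"]), "sexually_dimorphic")
  expect_equal(unname(lab["T3"]), "matched_monomorphic")
  expect_equal(unname(lab["T4"]), "reconstruction_issue")
  # exactly one label per type
  expect_equal(sort(out$type_label), sort(unique(out$type_label)))
})

test_that("a match weak on both channels is not credible and the type reverts to unmatched handling", {
  ds_a <- toy_ds(c("a1", "a2"), c("T1", "T1"))
  ds_b <- toy_ds(c("b1"), c("T9"))
  matches <- make_match("a1", "b1", morph = 0.45, conn = 0)
  class(matches) <- c("match_result", class(tibble::tibble()))
  out <- classify_dimorphism(matches, ds_a, ds_b,
                             toy_pairing("a1", "a2"), toy_pairing())
  expect_equal(out$label[out$type_label == "T1"], "sex_specific")
})

test_that("unequal member counts in a matched type flag biological variation", {
  ds_a <- toy_ds(c("a1", "a2"), c("T1", "T1"))
  ds_b <- toy_ds(c("b1", "b2", "b3"), c("T1", "T1", "T1"))
  matches <- make_match(c("a1", "a2"), c("b1", "b2"), morph = 0.9)
  class(matches) <- c("match_result", class(tibble::tibble()))
  out <- classify_dimorphism(matches, ds_a, ds_b,
                             toy_pairing("a1", "a2"), toy_pairing("b1", "b2"))
  expect_equal(out$label, "biological_variation")
})

test_that("new systematic type names count down from 999", {
  expect_equal(new_type_names(3, "DNxl"), c("DNxl999", "DNxl998", "DNxl997"))
  expect_equal(new_type_names(0, "AN"), character(0))
})
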