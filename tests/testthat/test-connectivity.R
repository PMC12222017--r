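toy_classes <- function(ids, classes) {
  tibble::tibble(neuron_id = ids, neuron_class = classes)
}

test_that("partner-graph thresholds are enforced exactly, including the add-back", {
  # focal F outputs 100 synapses in total
  edges <- tibble::tibble(
    pre_id  = c("F", "F", "F", "F", "X"),
    post_id = c("I1", "I2", "M1", "S1", "F"),
    weight  = c(9, 40, 6, 4, 50)
  )
  classes <- toy_classes(c("F", "I1", "I2", "M1", "S1", "X"),
                         c("DN", "IN", "IN", "MN", "SN", "IN"))
  g <- build_partner_graph("F", edges, classes)
  # I1 fails weight >= 10; I2 passes; M1 (weight 6 >= 5, MN) added back;
  # S1 (weight 4 < 5) stays out; X enters via the initial rule (50 >= 10,
  # 100% of X's output)
  expect_setequal(g$nodes$neuron_id, c("F", "I2", "M1", "X"))
  # mutation on each threshold flips the respective edge in or out
  g2 <- build_partner_graph("F", edges, classes, theta_w = 9)
  expect_true("I1" %in% g2$nodes$neuron_id)
  g3 <- build_partner_graph("F", edges, classes, theta_sens = 4)
  expect_true("S1" %in% g3$nodes$neuron_id)
  g4 <- build_partner_graph("F", edges, classes, theta_sens = 7)
  expect_false("M1" %in% g4$nodes$neuron_id)
  # percent-output threshold is strict and measured against the focal
  # neuron's dataset-wide output (59 synapses here, so I2 carries ~67.8%)
  g5 <- build_partner_graph("F", edges, classes, theta_pct = 70)
  expect_false("I2" %in% g5$nodes$neuron_id)
  g6 <- build_partner_graph("F", edges, classes, theta_pct = 100 * 40 / 59)
  expect_false("I2" %in% g6$nodes$neuron_id) # equality does not pass ">"
})

test_that("raising any threshold never adds nodes or edges", {
  gen <- tiny_bundle()
  ds <- gen$female
  focal <- ds$neurons$neuron_id[ds$neurons$neuron_class == "DN"]
  base <- build_partner_graph(focal, ds$edges, ds$neurons)
  for (arg in list(list(theta_w = 15), list(theta_pct = 2),
                   list(theta_sens = 8))) {
    g <- do.call(build_partner_graph,
                 c(list(focal, ds$edges, ds$neurons), arg))
    expect_lte(nrow(g$edges), nrow(base$edges))
    expect_true(all(g$nodes$neuron_id %in% base$nodes$neuron_id))
  }
})

test_that("input percents match hand computation and column sums stay <= 100", {
  edges <- tibble::tibble(
    pre_id  = c("a", "b", "a", "c", "d"),
    post_id = c("c", "c", "d", "d", "e"),
    weight  = c(30, 10, 20, 20, 5)
  )
  classes <- toy_classes(letters[1:5], rep("IN", 5))
  g <- build_partner_graph(c("a", "b"), edges, classes,
                           theta_w = 1, theta_pct = 0, theta_sens = 1)
  e <- g$edges
  # c receives 30 of 40 from a -> 75%; d receives 20 of 40 from a -> 50%
  expect_equal(e$input_pct[e$pre_id == "a" & e$post_id == "c"], 75)
  expect_equal(e$input_pct[e$pre_id == "a" & e$post_id == "d"], 50)
  sums <- tapply(e$input_pct, e$post_id, sum)
  expect_true(all(sums <= 100 + 1e-6))
})

test_that("type averaging is a mean of member-level percents", {
  g <- list(nodes = tibble::tibble(neuron_id = c("a1", "a2", "b1"),
                                   neuron_class = "IN",
                                   is_focal = TRUE),
            edges = tibble::tibble(pre_id = c("a1", "a2"),
                                   post_id = c("b1", "b1"),
                                   weight = c(4, 2), input_pct = c(2, 4)))
  class(g) <- "partner_graph"
  tm <- tibble::tibble(neuron_id = c("a1", "a2", "b1"),
                       type_label = c("A", "A", "B"))
  out <- average_by_type(g, tm)
  expect_equal(out$input_pct, 3)
  expect_equal(out$weight, 6)
  # member order irrelevant
  g$edges <- g$edges[2:1, ]
  expect_equal(average_by_type(g, tm)$input_pct, 3)
  expect_error(average_by_type(g, tm[-1, ]), "untyped")
})

test_that("class composition is synapse-weighted and sums to one", {
  edges <- tibble::tibble(
    pre_id = c("u1", "u2", "f"), post_id = c("f", "f", "d1"),
    weight = c(30, 10, 5)
  )
  classes <- toy_classes(c("u1", "u2", "f", "d1"), c("DN", "AN", "IN", "MN"))
  comp <- class_composition("f", edges, classes, "in")
  expect_equal(sum(comp$fraction), 1)
  expect_equal(comp$fraction[comp$neuron_class == "DN"], 0.75)
  out <- class_composition("f", edges, classes, "out")
  expect_equal(out$fraction, 1)
  expect_equal(out$neuron_class, "MN")
  empty <- class_composition("u1", edges[3, ], classes, "in")
  expect_equal(nrow(empty), 0)
})

test_that("stereotypy statistics match closed forms", {
  a <- c(1, 2, 3, 4)
  st <- stereotypy_stats(a, 2 * a)
  expect_equal(st$slope, 2)
  expect_equal(st$pearson_r, 1)
  st2 <- stereotypy_stats(a, a)
  expect_equal(st2$slope, 1)
  # printed 4-point toy: slope through origin = sum(ab) / sum(a^2)
  b <- c(2, 3, 7, 9)
  st3 <- stereotypy_stats(a, b)
  expect_equal(st3$slope, sum(a * b) / sum(a^2))
  expect_equal(st3$pearson_r, stats::cor(a, b))
  # degenerate input reports NA rather than erroring
  expect_true(is.na(stereotypy_stats(c(1, 1), c(2, 3))$pearson_r))
})

test_that("left-right weight stereotypy degrades monotonically with weight noise", {
  rs <- vapply(c(0, 3, 10), function(sw) {
    gen <- generate_connectomes(
      synth_config(n_types = 12, frac_sex_specific = 0, frac_dimorphic = 0,
                   frac_count_variable = 0, frac_excluded = 0,
                   frac_recon_issue = 0, sigma_w = sw, max_depth = 2,
                   seed = 99)
    )
    ds <- gen$female
    truth_pairs <- gen$truth$lr_pairs[gen$truth$lr_pairs$dataset_id == "f", ]
    wa <- wb <- numeric(0)
    for (i in seq_len(nrow(truth_pairs))) {
      l <- ds$edges[ds$edges$pre_id == truth_pairs$left_id[i], ]
      r <- ds$edges[ds$edges$pre_id == truth_pairs$right_id[i], ]
      k <- min(nrow(l), nrow(r))
      if (k == 0) next
      wa <- c(wa, sort(l$weight, decreasing = TRUE)[seq_len(k)])
      wb <- c(wb, sort(r$weight, decreasing = TRUE)[seq_len(k)])
    }
    stereotypy_stats(wa, wb)$pearson_r
  }, numeric(1))
  expect_gt(rs[1], 0.9)
  expect_true(all(diff(rs) < 0))
})

test_that("effective connectivity follows the product rule and path enumeration", {
  # A -> B -> C, each link 50% of the target's input
  edges <- tibble::tibble(
    pre_id = c("A", "X", "B", "Y"), post_id = c("B", "B", "C", "C"),
    weight = c(5, 5, 10, 10)
  )
  eff <- effective_connectivity("A", "C", edges, max_hops = 2)
  expect_equal(eff$effective_weight, 0.25)
  # direct-only graph equals input fraction
  d <- effective_connectivity("A", "B", edges, max_hops = 1)
  expect_equal(d$effective_weight, 0.5)
  expect_error(effective_connectivity("A", "B", edges, max_hops = 0),
               "max_hops")
})

test_that("effective connectivity equals brute-force path enumeration on small graphs", {
  set.seed(55)
  for (rep in 1:3) {
    n <- 7
    ids <- paste0("v", 1:n)
    m <- matrix(stats::runif(n * n) < 0.3, n, n)
    diag(m) <- FALSE
    idx <- which(m, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    edges <- tibble::tibble(pre_id = ids[idx[, 1]], post_id = ids[idx[, 2]],
                            weight = sample(1:9, nrow(idx), replace = TRUE))
    A <- matrix(0, n, n, dimnames = list(ids, ids))
    A[cbind(edges$pre_id, edges$post_id)] <- edges$weight
    A <- sweep(A, 2, pmax(colSums(A), 1e-12), "/")
    # enumerate all paths of length 1..3 from v1 to v5 and sum products
    hops <- 3
    target <- "v5"
    total <- 0
    paths <- list(c("v1"))
    for (h in seq_len(hops)) {
      nxt <- list()
      for (p in paths) {
        last <- p[length(p)]
        for (q in ids[A[last, ] > 0]) {
          pr <- prod(A[cbind(c(p, q)[-length(p) - 1], c(p, q)[-1])])
          if (q == target) total <- total + pr
          nxt[[length(nxt) + 1L]] <- c(p, q)
        }
      }
      paths <- nxt
    }
    got <- effective_connectivity("v1", target, edges, max_hops = hops)
    expect_equal(got$effective_weight, total, tolerance = 1e-9)
  }
})

test_that("density grids conserve counts, bin correctly and respect the cleft filter", {
  syn <- tibble::tibble(
    x = c(rep(100, 10), 7000), y = c(rep(100, 10), 100), z = 100,
    cleft_score = c(rep(80, 10), 30)
  )
  g <- synapse_density(syn, voxel = 5000)
  expect_equal(sum(g$counts), 11)
  expect_equal(g$counts[1, 1, 1], 10)
  expect_equal(g$counts[2, 1, 1], 1)
  # cleft filter is strict ">"
  g2 <- synapse_density(syn, voxel = 5000, cleft_min = 50)
  expect_equal(sum(g2$counts), 10)
  g3 <- suppressWarnings(synapse_density(syn, voxel = 5000, cleft_min = 80))
  expect_equal(sum(g3$counts), 0 + sum(syn$cleft_score > 80))
  expect_warning(synapse_density(syn[0, ], voxel = 5000), "no synapses")
})

test_that("density grids are translation-covariant by whole voxels", {
  set.seed(66)
  syn <- tibble::tibble(x = stats::runif(200, 0, 40e3),
                        y = stats::runif(200, 0, 40e3),
                        z = stats::runif(200, 0, 40e3),
                        cleft_score = 100)
  g1 <- synapse_density(syn, voxel = 5000)
  shifted <- dplyr::mutate(syn, x = x + 5000, y = y - 10000)
  g2 <- synapse_density(shifted, voxel = 5000)
  expect_equal(g2$counts, g1$counts)
  expect_equal(g2$origin, g1$origin + c(5000, -10000, 0))
  expect_equal(sum(tidy(g1)$count), 200)
})
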