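# dotprops ---------------------------------------------------------------

test_that("colinear points give axis-aligned tangents with alpha = 1", {
  pts <- cbind(seq(0, 9000, by = 1000), 0, 0)
  dp <- dotprops_from_points(pts, k = 5)
  expect_true(all(abs(abs(dp$tangents[, 1]) - 1) < 1e-9))
  expect_true(all(abs(dp$alpha - 1) < 1e-9))
})

test_that("tangents and alpha match a per-point covariance eigendecomposition", {
  set.seed(7)
  pts <- random_cloud(50)
  k <- 5
  dp <- dotprops_from_points(pts, k = k)
  for (i in c(1, 17, 50)) {
    nb <- order(colSums((t(pts) - pts[i, ])^2))[seq_len(k)]
    eg <- eigen(stats::cov(pts[nb, ]), symmetric = TRUE)
    v <- eg$vectors[, 1]
    expect_equal(abs(sum(v * dp$tangents[i, ])), 1, tolerance = 1e-9)
    ev <- eg$values
    expect_equal(dp$alpha[i], (ev[1] - ev[2]) / sum(ev), tolerance = 1e-9)
  }
})

test_that("tangents on a large circle are orthogonal to the radius vector", {
  theta <- seq(0, 2 * pi, length.out = 200)[-1]
  r <- 100e3 # radius much larger than the sampling step
  pts <- cbind(r * cos(theta), r * sin(theta), 0)
  dp <- dotprops_from_points(pts, k = 5)
  cosang <- abs(rowSums(dp$tangents * pts / r))
  expect_true(all(cosang < sin(5 * pi / 180)))
})

test_that("k larger than the cloud is clamped with a warning; single point errors", {
  pts <- random_cloud(3)
  expect_warning(dp <- dotprops_from_points(pts, k = 5), "clamping")
  expect_equal(dp$k, 3)
  expect_error(dotprops_from_points(pts[1, , drop = FALSE], k = 2),
               "at least 2 points")
})

test_that("skeleton resampling respects the step and keeps total count conserved", {
  sk <- straight_skeleton(11, step = 2000) # 20 um of cable
  pts <- resample_skeleton(sk, step = 1000)
  d <- diff(pts[, 1])
  expect_true(all(abs(d - 1000) < 1))
  expect_equal(nrow(pts), 21)
})

# mirroring ---------------------------------------------------------------

test_that("mirroring raises left-right partner similarity across the whole cohort", {
  gen <- tiny_bundle()
  ds <- gen$female
  pairs <- gen$truth$lr_pairs[gen$truth$lr_pairs$dataset_id == "f", ]
  for (i in seq_len(nrow(pairs))) {
    dl <- skeleton_to_dotprops(ds$skeletons[[pairs$left_id[i]]])
    dr <- skeleton_to_dotprops(ds$skeletons[[pairs$right_id[i]]])
    mirrored <- nblast(mirror_points(dl, ds$atlas$midline_x), dr)
    plain <- nblast(dl, dr)
    expect_gt(mirrored, plain)
  }
})

test_that("mirroring is an exact involution and fixes the midline", {
  set.seed(1)
  pts <- random_cloud(30)
  expect_identical(mirror_points(mirror_points(pts, 5000), 5000), pts)
  onmid <- matrix(c(5000, 1, 2), 1)
  expect_equal(mirror_points(onmid, 5000), onmid)
  # dotprops mirroring flips tangent x and stays unit length
  dp <- random_dotprops(20)
  m <- mirror_points(dp, 0)
  expect_equal(m$points[, 1], -dp$points[, 1])
  expect_equal(abs(rowSums(m$tangents^2)), rep(1, 20), tolerance = 1e-9)
})

# thin-plate spline -------------------------------------------------------

test_that("identity landmarks give an identity map", {
  set.seed(2)
  src <- random_cloud(12)
  tps <- fit_tps(src, src)
  probe <- random_cloud(40)
  expect_equal(apply_tps(tps, probe), probe, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("affine landmark pairs are recovered exactly with ~zero warp", {
  set.seed(3)
  src <- random_cloud(20)
  A <- matrix(c(1.1, 0.05, 0, -0.02, 0.95, 0.1, 0, 0.03, 1.02), 3, 3)
  b <- c(500, -200, 100)
  dst <- src %*% t(A) + matrix(b, 20, 3, byrow = TRUE)
  tps <- fit_tps(src, dst)
  expect_lt(sqrt(sum(tps$warp^2)), 1e-6)
  probe <- random_cloud(30)
  expect_equal(apply_tps(tps, probe),
               probe %*% t(A) + matrix(b, 30, 3, byrow = TRUE),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("random landmarks are interpolated to numerical precision", {
  set.seed(4)
  src <- random_cloud(20)
  dst <- src + random_cloud(20, scale = 2000)
  tps <- fit_tps(src, dst)
  expect_lt(max(abs(apply_tps(tps, src) - dst)), 1e-6)
  expect_lt(glance(tps)$max_residual, 1e-6)
})

test_that("degenerate landmark systems are rejected", {
  expect_error(fit_tps(random_cloud(3), random_cloud(3)), "at least 4")
  flat <- cbind(stats::runif(10), stats::runif(10), 0) # coplanar
  expect_error(fit_tps(flat, flat + 1), "singular|coplanar")
})

# NBLAST ------------------------------------------------------------------

test_that("self-match equals the attainable maximum n * s(0, 1)", {
  set.seed(5)
  dp <- random_dotprops(25)
  fn <- nblast_score_fn()
  expect_equal(nblast_raw(dp, dp, fn), nrow(dp$points) * fn(0, 1),
               tolerance = 1e-12)
  expect_equal(nblast(dp, dp, fn), 1, tolerance = 1e-12)
})

test_that("raw scores equal the exhaustive nearest-neighbour oracle", {
  set.seed(6)
  fn <- nblast_score_fn()
  for (rep in 1:5) {
    a <- random_dotprops(sample(10:50, 1))
    b <- random_dotprops(sample(10:50, 1))
    expect_equal(nblast_raw(a, b, fn), nblast_raw_oracle(a, b, fn),
                 tolerance = 1e-9)
  }
})

test_that("well-separated clouds score non-positive", {
  set.seed(8)
  a <- random_dotprops(30, scale = 5000)
  b <- a
  b$points <- b$points + 1e6 # 1 mm away, >> sigma
  expect_lte(nblast_raw(a, b), 0)
})

test_that("mean-normalized score is symmetric and 1 only for identical clouds", {
  set.seed(9)
  a <- random_dotprops(20)
  b <- random_dotprops(25)
  expect_equal(nblast(a, b), nblast(b, a), tolerance = 1e-12)
  expect_lt(nblast(a, b), 1)
})

test_that("all-by-all matrix has unit diagonal, symmetry, and matches pairwise calls", {
  set.seed(10)
  cohort <- lapply(1:4, function(i) random_dotprops(15))
  names(cohort) <- paste0("n", 1:4)
  m <- nblast_allbyall(cohort)
  expect_equal(unname(diag(unclass(m))), rep(1, 4))
  expect_equal(unclass(m), t(unclass(m)), tolerance = 1e-12)
  expect_equal(m["n1", "n3"], nblast(cohort[[1]], cohort[[3]]),
               tolerance = 1e-12)
})

test_that("a tabulated scoring matrix reproduces binned lookups", {
  f <- withr::local_tempfile(fileext = ".tsv")
  # distance bins (right edges): 1000, 5000, Inf; dotprod bins: 0.5, 1
  writeLines(c("0\t1000\t5000\t100000",
               "0.5\t1\t0.2\t-0.3",
               "1\t2\t0.5\t-0.1"), f)
  fn <- read_score_matrix(f)
  expect_equal(fn(500, 0.4), 1)
  expect_equal(fn(500, 0.9), 2)
  expect_equal(fn(3000, 0.9), 0.5)
  expect_equal(fn(50000, 0.4), -0.3)
  # and the generic (non-parametric) NBLAST path consumes it
  set.seed(11)
  a <- random_dotprops(10)
  expect_equal(nblast_raw(a, a, fn), 10 * fn(0, 1))
})

test_that("increasing jitter monotonically degrades the normalized score in expectation", {
  set.seed(12)
  base <- random_cloud(60, scale = 20000)
  sigmas <- c(100, 1000, 4000)
  means <- vapply(sigmas, function(s) {
    mean(vapply(1:20, function(i) {
      jit <- base + matrix(stats::rnorm(180, sd = s), ncol = 3)
      nblast(dotprops_from_points(base), dotprops_from_points(jit))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

# clustering --------------------------------------------------------------

test_that("cut height 0 separates every item; two blobs split at intermediate height", {
  set.seed(13)
  sim <- diag(6)
  sim[1:3, 1:3] <- 0.9; sim[4:6, 4:6] <- 0.9
  diag(sim) <- 1
  dimnames(sim) <- list(letters[1:6], letters[1:6])
  labs0 <- cluster_cut(sim, height = 0)
  expect_equal(length(unique(labs0)), 6)
  labs <- cluster_cut(sim, height = 0.5)
  expect_equal(length(unique(labs)), 2)
  expect_equal(unname(labs["a"] == labs["b"]), TRUE)
  expect_false(labs["a"] == labs["d"])
})

test_that("average linkage on a toy matrix matches the hand-computed dendrogram", {
  # distances: d(1,2)=1, d(3,4)=2, cross >= 8; average linkage merges
  # {1,2} at 1, {3,4} at 2, all at mean(8,9,9,10) = 9
  d <- matrix(c(0, 1, 8, 9,
                1, 0, 9, 10,
                8, 9, 0, 2,
                9, 10, 2, 0), 4, 4)
  labs_mid <- cluster_cut(d, height = 5, linkage = "average",
                          similarity = FALSE)
  expect_equal(length(unique(labs_mid)), 2)
  labs_hi <- cluster_cut(d, height = 9.5, linkage = "average",
                         similarity = FALSE)
  expect_equal(length(unique(labs_hi)), 1)
  labs_lo <- cluster_cut(d, height = 1.5, linkage = "average",
                         similarity = FALSE)
  expect_equal(length(unique(labs_lo)), 3)
})
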