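# shared fixture builders -----------------------------------------------------

# simple unbranched skeleton along the x axis, n nodes, 1 um spacing
straight_skeleton <- function(n = 10, step = 1000) {
  neckmatch:::new_skeleton(tibble::tibble(
    node_id = seq_len(n), structure = 0L,
    x = (seq_len(n) - 1) * step, y = 0, z = 0,
    radius = -1, parent_id = c(-1L, seq_len(n - 1L))
  ))
}

# Y-shaped skeleton: trunk 1..n1, branch from the trunk tip
branched_skeleton <- function(n1 = 5, n2 = 4, step = 1000) {
  trunk <- tibble::tibble(
    node_id = seq_len(n1), structure = 0L,
    x = (seq_len(n1) - 1) * step, y = 0, z = 0,
    radius = -1, parent_id = c(-1L, seq_len(n1 - 1L))
  )
  branch <- tibble::tibble(
    node_id = n1 + seq_len(n2), structure = 0L,
    x = (n1 - 1) * step, y = seq_len(n2) * step, z = 0,
    radius = -1, parent_id = c(n1, n1 + seq_len(n2 - 1L))
  )
  neckmatch:::new_skeleton(dplyr::bind_rows(trunk, branch))
}

random_cloud <- function(n, scale = 10000) {
  matrix(stats::runif(n * 3, 0, scale), ncol = 3)
}

random_dotprops <- function(n, scale = 10000, k = 5) {
  dotprops_from_points(random_cloud(n, scale), k = k)
}

# brute-force R implementation of the raw NBLAST score, independent of the
# compiled path: explicit all-pairs nearest neighbour + score function
nblast_raw_oracle <- function(query, target, score_fn) {
  total <- 0
  for (i in seq_len(nrow(query$points))) {
    d2 <- colSums((t(target$points) - query$points[i, ])^2)
    j <- which.min(d2)
    dp <- abs(sum(query$tangents[i, ] * target$tangents[j, ]))
    total <- total + score_fn(sqrt(d2[j]), dp)
  }
  total
}

# all permutations of 1..n (for brute-force assignment oracles)
neckmatch_test_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- neckmatch_test_perms(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# tiny synthetic bundle, generated once per test session
tiny_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_types = 8, frac_sex_specific = 0.25,
                          frac_dimorphic = 0.125, frac_count_variable = 0,
                          frac_excluded = 0, frac_recon_issue = 0,
                          max_depth = 2, seed = 42)
      cache <<- generate_connectomes(cfg)
    }
    cache
  }
})
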