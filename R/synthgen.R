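#' Configuration for the synthetic connectome generator
#'
#' Defines the study conditions the generator emulates: a female and a male
#' nerve-cord dataset sharing a catalogue of bilateral cell types, with
#' planted left-right pairs, cross-dataset homologues under a smooth spatial
#' warp, sex-specific and sexually dimorphic types, neuropil-localized
#' synapse clouds, layered sensory connectivity per modality, and a landmark
#' lattice carrying the warp.
#'
#' @param n_types Number of focal (descending/ascending) cell types.
#' @param members_per_side Integer range `c(lo, hi)` of members per side per
#'   type (default 1 and 1: unique pairs).
#' @param frac_sex_specific Fraction of types present in only one dataset
#'   (split evenly female-only / male-only).
#' @param frac_dimorphic Fraction of shared types whose male morphology is
#'   deformed beyond the dimorphism threshold.
#' @param frac_count_variable Fraction of shared types given an extra member
#'   in the male dataset (planted biological variation).
#' @param frac_excluded Fraction of shared types flagged neuropeptidergic
#'   (planted exclusions).
#' @param frac_recon_issue Fraction of types planted as reconstruction
#'   issues: absent from the male dataset and truncated in the female one.
#' @param jitter_sigma Per-node Gaussian jitter between homologous skeletons,
#'   nm.
#' @param dimorphic_angle,dimorphic_scale,dimorphic_shift Arbour deformation
#'   applied to dimorphic types in the male dataset: rotation about the
#'   arbour root (radians), isotropic scale, and z translation (nm).
#' @param warp_scale,warp_shift,warp_amp Cross-dataset deformation: per-axis
#'   affine scale (length 3), translation (length 3, nm) and sinusoidal bump
#'   amplitude (length 3, nm). The bump wavelengths are fixed at one volume
#'   period so the landmark lattice samples them adequately. The x components
#'   of shift and amplitude are unused: the x deformation is a pure scale so
#'   the warp commutes with mirroring and both datasets remain internally
#'   bilaterally symmetric.
#' @param weight_range Uniform range for type-level mean connection weights
#'   (synapse counts).
#' @param sigma_w Gaussian noise on member-level connection weights.
#' @param n_modalities Number of sensory modalities (chains are wired per
#'   modality).
#' @param max_depth Deepest planted sensory layer.
#' @param seeds_per_modality Sensory seed neurons per modality per dataset
#'   (half per side).
#' @param n_synapses Pre- and postsynapse count per focal neuron (each).
#' @param arbour_branches,arbour_steps Arbour size knobs (branch count,
#'   steps of 1 um per branch).
#' @param step Skeleton sampling step, nm.
#' @param turn_sigma Momentum random-walk turning noise (radians-equivalent).
#' @param seed Root RNG seed; all randomness derives from it.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(n_types = 60,
                         members_per_side = c(1L, 1L),
                         frac_sex_specific = 0.10,
                         frac_dimorphic = 0.10,
                         frac_count_variable = 0.05,
                         frac_excluded = 0.05,
                         frac_recon_issue = 1 / 30,
                         jitter_sigma = 200,
                         dimorphic_angle = 1.0,
                         dimorphic_scale = 1.3,
                         dimorphic_shift = 9000,
                         warp_scale = c(1.02, 0.98, 1.03),
                         warp_shift = c(0, 2000, 1000),
                         warp_amp = c(0, 2000, 2500),
                         weight_range = c(15, 50),
                         sigma_w = 2,
                         n_modalities = 4,
                         max_depth = 4,
                         seeds_per_modality = 8,
                         n_synapses = 30,
                         arbour_branches = 3,
                         arbour_steps = 18,
                         step = 1000,
                         turn_sigma = 0.25,
                         seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(frac_sex_specific, frac_dimorphic, frac_count_variable,
          frac_excluded, frac_recon_issue)
  if (any(fr < 0 | fr > 1) || frac_sex_specific + frac_dimorphic > 1) {
    stop("invalid category fractions", call. = FALSE)
  }
  if (jitter_sigma < 0 || sigma_w < 0) stop("sigma must be >= 0", call. = FALSE)
  if (members_per_side[1L] < 1L || members_per_side[2L] < members_per_side[1L]) {
    stop("invalid members_per_side range", call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

# ---- geometry shared by generator and tests -------------------------------

synth_volume <- function() {
  list(x = c(-160e3, 160e3), y = c(0, 300e3), z = c(0, 100e3))
}

#' Default synthetic neuropil atlas
#'
#' Eleven nerve-cord neuropils as non-overlapping y-slabs of the synthetic
#' volume, with the `upper_tectulum` and `leg_neuropils` region sets.
#'
#' @return Atlas list (`regions`, `region_sets`, `midline_x`).
#' @export
synth_atlas <- function() {
  labels <- c("NTct", "WTct", "HTct", "IntTct", "LTct",
              "LegNpT1", "LegNpT2", "LegNpT3", "mVAC", "Ov", "ANm")
  edges <- c(0, 30, 60, 90, 120, 150, 180, 210, 240, 260, 280, 300) * 1e3
  vol <- synth_volume()
  regions <- tibble::tibble(
    label = labels,
    xmin = vol$x[1L], xmax = vol$x[2L],
    ymin = edges[-length(edges)], ymax = edges[-1L],
    zmin = vol$z[1L], zmax = vol$z[2L]
  )
  list(
    regions = regions,
    region_sets = list(
      upper_tectulum = c("NTct", "WTct", "HTct"),
      leg_neuropils = c("LegNpT1", "LegNpT2", "LegNpT3")
    ),
    midline_x = 0
  )
}

#' Default synthetic tract centerlines
#'
#' Five longitudinal tracts on each side: gently curved polylines running
#' the length of the cord at distinct mediolateral/dorsoventral offsets.
#'
#' @return Tibble `tract`, `side`, `x`, `y`, `z` (polyline points, nm).
#' @export
synth_tracts <- function() {
  names <- c("MTD", "ITD", "LTD", "DLV", "ADM")
  x0 <- c(20, 45, 70, 95, 120) * 1e3
  z0 <- c(25, 40, 55, 70, 85) * 1e3
  y <- seq(0, 300e3, by = 2000)
  rows <- lapply(seq_along(names), function(t) {
    x <- x0[t] + 2000 * sin(y / 8e4)
    dplyr::bind_rows(
      tibble::tibble(tract = names[t], side = "right", x = x, y = y, z = z0[t]),
      tibble::tibble(tract = names[t], side = "left", x = -x, y = y, z = z0[t])
    )
  })
  dplyr::bind_rows(rows)
}

tract_centerline <- function(tract_name, side) {
  tr <- synth_tracts()
  tr <- tr[tr$tract == tract_name & tr$side == side, ]
  as.matrix(tr[, c("x", "y", "z")])
}

# the planted female->male deformation: diagonal affine + translation +
# low-frequency sinusoidal displacement (one period over the volume). The x
# component is kept strictly odd (pure scale) so the deformation commutes
# with mirroring about the midline: both synthetic animals stay internally
# bilaterally symmetric up to jitter, as real nervous systems are.
synth_warp <- function(points, cfg) {
  vol <- synth_volume()
  m <- if (is.data.frame(points)) as.matrix(points[, c("x", "y", "z")]) else points
  out <- m
  out[, 1L] <- cfg$warp_scale[1L] * m[, 1L]
  out[, 2L] <- cfg$warp_scale[2L] * m[, 2L] + cfg$warp_shift[2L] +
    cfg$warp_amp[2L] * sin(2 * pi * m[, 3L] / diff(vol$z))
  out[, 3L] <- cfg$warp_scale[3L] * m[, 3L] + cfg$warp_shift[3L] +
    cfg$warp_amp[3L] * sin(2 * pi * m[, 2L] / diff(vol$y))
  out
}

# ---- skeleton growth ------------------------------------------------------

# template skeleton: main neurite following a tract centerline from the neck
# entry (y = 0) down to y_target, then a momentum random-walk arbour inside
# the given box. Returns an swc_skeleton.
grow_template <- function(tract_name, y_target, box, cfg, soma_only = FALSE) {
  cl <- tract_centerline(tract_name, "right")
  y <- seq(0, y_target, by = cfg$step)
  idx <- pmin(findInterval(y, cl[, 2L]) + 1L, nrow(cl))
  ax <- stats::runif(1, 500, 2500); px <- stats::runif(1, 0, 2 * pi)
  az <- stats::runif(1, 500, 2500); pz <- stats::runif(1, 0, 2 * pi)
  main <- cbind(
    cl[idx, 1L] + ax * sin(y / 5e4 + px),
    y,
    cl[idx, 3L] + az * sin(y / 6e4 + pz)
  )
  n_main <- nrow(main)
  nodes <- tibble::tibble(
    node_id = seq_len(n_main), structure = 0L,
    x = as.numeric(main[, 1L]), y = as.numeric(main[, 2L]),
    z = as.numeric(main[, 3L]),
    radius = -1, parent_id = c(-1L, seq_len(n_main - 1L))
  )
  if (!soma_only) {
    arb <- grow_arbour(main[n_main, ], box, cfg, n_min = round(1.3 * n_main))
    arb_nodes <- tibble::tibble(
      node_id = n_main + seq_len(nrow(arb$pts)), structure = 0L,
      x = as.numeric(arb$pts[, 1L]), y = as.numeric(arb$pts[, 2L]),
      z = as.numeric(arb$pts[, 3L]),
      radius = -1,
      parent_id = ifelse(arb$parent == 0L, n_main, n_main + arb$parent)
    )
    nodes <- dplyr::bind_rows(nodes, arb_nodes)
  }
  out <- new_skeleton(nodes)
  attr(out, "n_main") <- n_main
  out
}

# momentum random walk with reflection into the box and away from the midline.
# n_min scales the arbour with the main neurite so terminal/dendritic cable
# dominates total cable, as it does in real neurons.
grow_arbour <- function(start, box, cfg, n_min = 0L) {
  lo <- c(max(box$xmin, 2000), box$ymin, box$zmin)
  hi <- c(box$xmax, box$ymax, box$zmax)
  pts <- matrix(numeric(0), 0L, 3L)
  parent <- integer(0)
  n_branch <- max(1L + stats::rpois(1L, cfg$arbour_branches - 1L),
                  ceiling(n_min / cfg$arbour_steps))
  for (b in seq_len(n_branch)) {
    anchor <- if (nrow(pts) == 0L) 0L else
      sample.int(nrow(pts), 1L)
    pos <- if (anchor == 0L) start else pts[anchor, ]
    dir <- stats::rnorm(3L)
    dir <- dir / sqrt(sum(dir^2))
    prev <- anchor
    for (s in seq_len(cfg$arbour_steps)) {
      dir <- dir + stats::rnorm(3L, sd = cfg$turn_sigma)
      dir <- dir / sqrt(sum(dir^2))
      cand <- pos + cfg$step * dir
      for (d in 1:3) { # reflect at the box walls
        if (cand[d] < lo[d]) { cand[d] <- 2 * lo[d] - cand[d]; dir[d] <- -dir[d] }
        if (cand[d] > hi[d]) { cand[d] <- 2 * hi[d] - cand[d]; dir[d] <- -dir[d] }
      }
      pos <- cand
      pts <- rbind(pts, pos)
      parent <- c(parent, prev)
      prev <- nrow(pts)
    }
  }
  list(pts = pts, parent = parent)
}

jitter_skeleton <- function(skel, sigma) {
  if (sigma <= 0) return(skel)
  n <- nrow(skel)
  skel$x <- skel$x + stats::rnorm(n, sd = sigma)
  skel$y <- skel$y + stats::rnorm(n, sd = sigma)
  skel$z <- skel$z + stats::rnorm(n, sd = sigma)
  skel
}

mirror_skeleton <- function(skel, midline_x = 0) {
  skel$x <- 2 * midline_x - skel$x
  skel
}

transform_skeleton <- function(skel, fn) {
  m <- fn(as.matrix(skel[, c("x", "y", "z")]))
  skel$x <- m[, 1L]; skel$y <- m[, 2L]; skel$z <- m[, 3L]
  skel
}

# dimorphic deformation: rotate the arbour about its root (the main-neurite
# tip) in the x-y plane, scale it, and shift it dorsoventrally
dimorph_skeleton <- function(skel, n_main, cfg) {
  if (nrow(skel) <= n_main) return(skel)
  root <- c(skel$x[n_main], skel$y[n_main], skel$z[n_main])
  idx <- seq(n_main + 1L, nrow(skel))
  p <- cbind(skel$x[idx], skel$y[idx], skel$z[idx])
  p <- sweep(p, 2L, root)
  a <- cfg$dimorphic_angle
  R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3L, 3L,
              byrow = TRUE)
  p <- cfg$dimorphic_scale * (p %*% t(R))
  p <- sweep(p, 2L, root, "+")
  p[, 3L] <- p[, 3L] + cfg$dimorphic_shift
  skel$x[idx] <- p[, 1L]; skel$y[idx] <- p[, 2L]; skel$z[idx] <- p[, 3L]
  skel
}

# ---- the generator --------------------------------------------------------

#' Generate a pair of synthetic connectome datasets with ground truth
#'
#' Builds a female and a male dataset realizing the configuration: per type a
#' template skeleton grown along a planted tract, mirrored and jittered into
#' left/right members, carried into the male dataset by a smooth warp
#' (sex-specific types omitted; dimorphic types deformed beyond the
#' dimorphism threshold), neuropil-localized synapse clouds realizing each
#' type's planted neuropil code, layered sensory connectivity realizing each
#' type's planted modality depth, and a landmark lattice sampling the warp.
#'
#' @param cfg A [synth_config()].
#' @return List with `female` and `male` (`connectome_dataset`s), `truth`
#'   (list of ground-truth tibbles: `types`, `neurons`, `lr_pairs`,
#'   `homologues`, `dimorphism`, `seeds`), and `landmarks` (tibble of paired
#'   coordinates, female -> male).
#' @export
generate_connectomes <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  atlas <- synth_atlas()

  set.seed(cfg$seed)
  types <- plan_types(cfg)
  wiring <- plan_wiring(types, cfg)

  set.seed(cfg$seed + 101L) # morphology substream
  morph <- build_morphology(types, cfg)

  set.seed(cfg$seed + 202L) # synapse substream
  syn <- build_synapses(morph$neurons, types, atlas, cfg)

  set.seed(cfg$seed + 303L) # connectivity substream
  conn <- build_edges(morph$neurons, types, wiring, cfg)

  landmarks <- build_landmarks(cfg)

  all_neurons <- dplyr::bind_rows(
    morph$neurons,
    conn$scaffold_neurons[, names(morph$neurons)]
  )

  mk_ds <- function(dsid) {
    neu <- all_neurons[all_neurons$dataset_id == dsid, ]
    ds <- structure(
      list(
        dataset_id = dsid,
        neurons = neu,
        skeletons = morph$skeletons[intersect(names(morph$skeletons),
                                              neu$neuron_id)],
        synapses = syn[syn$dataset_id == dsid,
                       setdiff(names(syn), "dataset_id")],
        edges = conn$edges[conn$edges$dataset_id == dsid,
                           c("pre_id", "post_id", "weight")],
        atlas = atlas,
        landmarks = if (dsid == "f") landmarks else NULL
      ),
      class = "connectome_dataset"
    )
    ds$validation <- validate_dataset(ds)
    ds
  }

  truth <- build_truth(types, morph$neurons, conn$seeds)
  list(female = mk_ds("f"), male = mk_ds("m"), truth = truth,
       landmarks = landmarks)
}

# assign every type its class, tract, neuropil profile, modality/depth and
# dimorphism category; deterministic given the active RNG state
plan_types <- function(cfg) {
  n <- cfg$n_types
  atlas <- synth_atlas()
  labels <- atlas$regions$label
  tracts <- unique(synth_tracts()$tract)
  modalities <- c("visual", "olfactory", "mechanosensory", "auditory",
                  "gustatory", "thermo_hygro")[seq_len(cfg$n_modalities)]

  i <- seq_len(n)
  types <- tibble::tibble(
    type_idx = i,
    type_label = sprintf("T%03d", i),
    neuron_class = ifelse(i %% 2L == 1L, "DN", ifelse(i %% 10L == 0L, "SA", "AN")),
    tract = tracts[(i - 1L) %% length(tracts) + 1L],
    modality = modalities[(i - 1L) %% cfg$n_modalities + 1L],
    depth = ((i - 1L) %/% cfg$n_modalities) %% cfg$max_depth + 1L,
    members = sample(seq(cfg$members_per_side[1L], cfg$members_per_side[2L]),
                     n, replace = TRUE)
  )

  # neuropil profiles: mostly single-box, with planted ut/xl/xn/XA types
  n_ut <- max(1L, round(n / 15)); n_xl <- max(1L, round(n / 15))
  n_xn <- max(1L, round(n / 20)); n_xa <- if (n >= 20L) 2L else 1L
  profile <- rep("single", n)
  special <- sample(i, n_ut + n_xl + n_xn + n_xa)
  profile[special[seq_len(n_ut)]] <- "ut"
  profile[special[n_ut + seq_len(n_xl)]] <- "xl"
  profile[special[n_ut + n_xl + seq_len(n_xn)]] <- "xn"
  profile[special[n_ut + n_xl + n_xn + seq_len(n_xa)]] <- "XA"
  types$profile <- profile
  types$primary_neuropil <- labels[(i - 1L) %% length(labels) + 1L]
  code_map <- vnc_code_map()
  types$vnc_code <- dplyr::case_when(
    profile == "single" ~ unname(code_map[types$primary_neuropil]),
    TRUE ~ profile
  )

  # dimorphism categories, sampled so every (modality, depth < max) cell
  # keeps at least one shared type available as a chain source
  counts <- c(
    female_specific = round(n * cfg$frac_sex_specific / 2),
    male_specific = round(n * cfg$frac_sex_specific / 2),
    dimorphic = round(n * cfg$frac_dimorphic),
    count_variable = round(n * cfg$frac_count_variable),
    excluded = round(n * cfg$frac_excluded),
    recon_issue = round(n * cfg$frac_recon_issue)
  )
  category <- rep("monomorphic", n)
  cell <- paste(types$modality, types$depth)
  shared_left <- table(cell)
  order_i <- sample(i)
  for (cat in names(counts)) {
    need <- counts[[cat]]
    for (j in order_i) {
      if (need == 0L) break
      if (category[j] != "monomorphic") next
      if (profile[j] == "XA") next # soma-only types stay plain
      removes_shared <- cat %in% c("female_specific", "male_specific",
                                   "recon_issue")
      if (removes_shared && types$depth[j] < cfg$max_depth &&
          shared_left[cell[j]] <= 1L) next
      category[j] <- cat
      need <- need - 1L
      if (removes_shared) shared_left[cell[j]] <- shared_left[cell[j]] - 1L
    }
  }
  types$category <- category
  types
}

# per target type, choose its source types (shared, previous layer, same
# modality); shared across datasets
plan_wiring <- function(types, cfg) {
  w_range <- cfg$weight_range
  removed <- c("female_specific", "male_specific", "recon_issue")
  rows <- lapply(seq_len(nrow(types)), function(j) {
    t <- types[j, ]
    if (t$depth == 1L) {
      return(tibble::tibble(post_type = t$type_label, pre_type = "seeds",
                            base_w = stats::runif(1, w_range[1L], w_range[2L])))
    }
    pool <- types$type_label[types$modality == t$modality &
                               types$depth == t$depth - 1L &
                               !types$category %in% removed]
    if (length(pool) == 0L) { # degenerate config: wire from the seed layer
      return(tibble::tibble(post_type = t$type_label, pre_type = "seeds",
                            base_w = stats::runif(1, w_range[1L], w_range[2L])))
    }
    src <- if (length(pool) == 1L) pool else sample(pool, min(2L, length(pool)))
    tibble::tibble(post_type = t$type_label, pre_type = src,
                   base_w = stats::runif(length(src), w_range[1L], w_range[2L]))
  })
  dplyr::bind_rows(rows)
}

build_morphology <- function(types, cfg) {
  atlas <- synth_atlas()
  skeletons <- list()
  neuron_rows <- list()
  code_map <- vnc_code_map()

  arbour_box_label <- function(t) {
    switch(t$profile,
           single = t$primary_neuropil,
           ut = "WTct", xl = "LegNpT2", xn = t$primary_neuropil,
           XA = NA_character_)
  }

  for (j in seq_len(nrow(types))) {
    t <- types[j, ]
    soma_only <- t$profile == "XA"
    box_label <- arbour_box_label(t)
    box <- if (!is.na(box_label)) {
      as.list(atlas$regions[atlas$regions$label == box_label, ])
    } else {
      NULL
    }
    y_target <- if (soma_only) 120e3 else (box$ymin + box$ymax) / 2
    template <- grow_template(t$tract, y_target, box, cfg, soma_only)
    n_main <- attr(template, "n_main")

    truncated <- t$category == "recon_issue"
    in_f <- t$category != "male_specific"
    in_m <- !t$category %in% c("female_specific", "recon_issue")

    male_template <- template
    if (t$category == "dimorphic") {
      male_template <- dimorph_skeleton(template, n_main, cfg)
    }

    emit <- function(dsid, side, member, base_skel, warp) {
      sk <- base_skel
      if (side == "left") sk <- mirror_skeleton(sk)
      if (warp) sk <- transform_skeleton(sk, function(m) synth_warp(m, cfg))
      sk <- jitter_skeleton(sk, cfg$jitter_sigma)
      if (truncated) sk <- new_skeleton(sk[seq_len(min(30L, nrow(sk))), ])
      id <- sprintf("%s_%s_%s%d", dsid, t$type_label,
                    toupper(substr(side, 1L, 1L)), member)
      skeletons[[id]] <<- sk
      entry <- c(sk$x[1L], sk$y[1L], sk$z[1L])
      has_soma <- t$neuron_class == "AN"
      flags <- character(0)
      if (truncated) flags <- c(flags, "truncated")
      if (t$category == "excluded") flags <- c(flags, "neuropeptidergic")
      neuron_rows[[length(neuron_rows) + 1L]] <<- tibble::tibble(
        neuron_id = id, dataset_id = dsid, side = side, cns_region = "vnc",
        neuron_class = t$neuron_class, type_label = t$type_label,
        group_id = t$type_label,
        soma_x = if (has_soma) entry[1L] else NA_real_,
        soma_y = if (has_soma) entry[2L] else NA_real_,
        soma_z = if (has_soma) entry[3L] else NA_real_,
        neck_cross_x = entry[1L],
        flags = paste(flags, collapse = ","),
        soma_only = soma_only
      )
      invisible(NULL)
    }

    for (member in seq_len(t$members)) {
      if (in_f) {
        emit("f", "right", member, template, warp = FALSE)
        emit("f", "left", member, template, warp = FALSE)
      }
      if (in_m) {
        emit("m", "right", member, male_template, warp = TRUE)
        emit("m", "left", member, male_template, warp = TRUE)
      }
    }
    if (t$category == "count_variable" && in_m) {
      emit("m", "right", t$members + 1L, male_template, warp = TRUE)
    }
  }
  list(neurons = dplyr::bind_rows(neuron_rows), skeletons = skeletons)
}

# synapse clouds realizing each type's planted neuropil profile
build_synapses <- function(neurons, types, atlas, cfg) {
  profile_fracs <- function(t) {
    labels <- atlas$regions$label
    others <- setdiff(labels, t$primary_neuropil)
    switch(t$profile,
      single = stats::setNames(c(0.9, 0.1),
                               c(t$primary_neuropil, others[1L])),
      ut = c(NTct = 0.34, WTct = 0.33, HTct = 0.23, LTct = 0.10),
      xl = c(LegNpT1 = 0.35, LegNpT2 = 0.33, LegNpT3 = 0.22, IntTct = 0.10),
      xn = stats::setNames(c(0.4, 0.3, 0.3),
                           c("NTct", "LTct", "ANm")),
      XA = NULL
    )
  }
  rows <- list()
  sid <- 0L
  tmap <- stats::setNames(seq_len(nrow(types)), types$type_label)
  for (r in seq_len(nrow(neurons))) {
    nr <- neurons[r, ]
    if (!nr$type_label %in% names(tmap)) next
    t <- types[tmap[[nr$type_label]], ]
    fr <- profile_fracs(t)
    if (is.null(fr)) next
    for (role in c("pre", "post")) {
      counts <- round(fr * cfg$n_synapses)
      lab <- rep(names(counts), counts)
      n_s <- length(lab)
      reg <- atlas$regions[match(lab, atlas$regions$label), ]
      sgn <- if (nr$side == "left") -1 else 1
      x <- sgn * stats::runif(n_s, 2000, 150e3)
      y <- stats::runif(n_s, reg$ymin, reg$ymax - 1)
      z <- stats::runif(n_s, reg$zmin, reg$zmax - 1)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        dataset_id = nr$dataset_id,
        synapse_id = paste0(nr$dataset_id, "_syn_", sid + seq_len(n_s)),
        neuron_id = nr$neuron_id, role = role,
        x = x, y = y, z = z,
        cleft_score = stats::runif(n_s, 0, 100),
        neuropil = lab
      )
      sid <- sid + n_s
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(dataset_id = character(0), synapse_id = character(0),
                          neuron_id = character(0), role = character(0),
                          x = numeric(0), y = numeric(0), z = numeric(0),
                          cleft_score = numeric(0), neuropil = character(0)))
  }
  dplyr::bind_rows(rows)
}

# layered sensory wiring: seeds -> depth-1 types -> ... ; plus motor targets
# at the deepest layer (some below the main weight threshold, to exercise
# the add-back rule)
build_edges <- function(neurons, types, wiring, cfg) {
  modalities <- unique(types$modality)
  seed_rows <- list(); mn_rows <- list(); edge_rows <- list()
  half <- cfg$seeds_per_modality / 2

  for (dsid in c("f", "m")) {
    for (mod in modalities) {
      for (side in c("left", "right")) {
        k <- seq_len(ceiling(half))
        seed_rows[[length(seed_rows) + 1L]] <- tibble::tibble(
          neuron_id = sprintf("%s_SN_%s_%s%d", dsid, mod,
                              toupper(substr(side, 1, 1)), k),
          dataset_id = dsid, side = side, cns_region = "vnc",
          neuron_class = "SN", type_label = paste0("SN_", mod),
          group_id = paste0("SN_", mod),
          soma_x = NA_real_, soma_y = NA_real_, soma_z = NA_real_,
          neck_cross_x = NA_real_, flags = "", soma_only = FALSE,
          modality = mod
        )
      }
    }
    for (side in c("left", "right")) {
      k <- seq_len(8L)
      mn_rows[[length(mn_rows) + 1L]] <- tibble::tibble(
        neuron_id = sprintf("%s_MN_%s%02d", dsid,
                            toupper(substr(side, 1, 1)), k),
        dataset_id = dsid, side = side, cns_region = "vnc",
        neuron_class = "MN", type_label = sprintf("MN_%02d", k),
        group_id = sprintf("MN_%02d", k),
        soma_x = NA_real_, soma_y = NA_real_, soma_z = NA_real_,
        neck_cross_x = NA_real_, flags = "", soma_only = FALSE,
        modality = NA_character_
      )
    }
  }
  seeds <- dplyr::bind_rows(seed_rows)
  mns <- dplyr::bind_rows(mn_rows)
  scaffold <- dplyr::bind_rows(seeds, mns)

  all_neurons <- dplyr::bind_rows(
    dplyr::mutate(neurons, modality = NA_character_),
    scaffold
  )

  draw_w <- function(base) max(1, round(base + stats::rnorm(1L, sd = cfg$sigma_w)))

  for (dsid in c("f", "m")) {
    nd <- all_neurons[all_neurons$dataset_id == dsid, ]
    members_of <- split(nd$neuron_id, nd$type_label)
    side_of <- stats::setNames(nd$side, nd$neuron_id)
    for (j in seq_len(nrow(wiring))) {
      w <- wiring[j, ]
      posts <- members_of[[w$post_type]]
      if (is.null(posts)) next
      t_mod <- types$modality[types$type_label == w$post_type]
      pres <- if (w$pre_type == "seeds") {
        seeds$neuron_id[seeds$dataset_id == dsid & seeds$type_label ==
                          paste0("SN_", t_mod)]
      } else {
        members_of[[w$pre_type]]
      }
      if (is.null(pres) || length(pres) == 0L) next
      for (post in posts) {
        same <- pres[side_of[pres] == side_of[post]]
        for (pre in same) {
          edge_rows[[length(edge_rows) + 1L]] <- tibble::tibble(
            dataset_id = dsid, pre_id = pre, post_id = post,
            weight = draw_w(w$base_w / max(1L, length(same)))
          )
        }
      }
    }
    # motor wiring from the deepest layer
    deep <- types$type_label[types$depth == cfg$max_depth]
    mn_ds <- mns[mns$dataset_id == dsid, ]
    for (ty in deep) {
      posts <- members_of[[ty]]
      if (is.null(posts)) next
      for (i in seq_along(posts)) {
        side <- side_of[posts[i]]
        mn_side <- mn_ds$neuron_id[mn_ds$side == side]
        pick <- mn_side[(match(ty, deep) + c(0L, 1L)) %% length(mn_side) + 1L]
        edge_rows[[length(edge_rows) + 1L]] <- tibble::tibble(
          dataset_id = dsid, pre_id = posts[i], post_id = pick,
          weight = c(draw_w(14), max(1, min(9, draw_w(6))))
        )
      }
    }
  }

  edges <- if (length(edge_rows) > 0L) dplyr::bind_rows(edge_rows) else
    tibble::tibble(dataset_id = character(0), pre_id = character(0),
                   post_id = character(0), weight = numeric(0))
  list(
    edges = edges,
    seeds = seeds[, c("dataset_id", "neuron_id", "modality")],
    scaffold_neurons = scaffold
  )
}

build_landmarks <- function(cfg) {
  vol <- synth_volume()
  g <- expand.grid(
    x = seq(vol$x[1L], vol$x[2L], length.out = 4L),
    y = seq(vol$y[1L], vol$y[2L], length.out = 5L),
    z = seq(vol$z[1L], vol$z[2L], length.out = 4L)
  )
  src <- as.matrix(g)
  dst <- synth_warp(src, cfg)
  tibble::tibble(
    x_f = src[, 1L], y_f = src[, 2L], z_f = src[, 3L],
    x_m = dst[, 1L], y_m = dst[, 2L], z_m = dst[, 3L]
  )
}

build_truth <- function(types, neurons, seeds) {
  label_of <- c(
    monomorphic = "matched_monomorphic",
    dimorphic = "sexually_dimorphic",
    female_specific = "sex_specific",
    male_specific = "sex_specific",
    count_variable = "biological_variation",
    excluded = "excluded",
    recon_issue = "reconstruction_issue"
  )
  dimorphism <- tibble::tibble(
    type_label = types$type_label,
    category = types$category,
    label = unname(label_of[types$category])
  )
  focal <- neurons[!is.na(neurons$type_label) &
                     neurons$type_label %in% types$type_label, ]
  tinfo <- types[match(focal$type_label, types$type_label), ]
  neurons_truth <- tibble::tibble(
    neuron_id = focal$neuron_id, dataset_id = focal$dataset_id,
    type_label = focal$type_label, side = focal$side,
    tract = tinfo$tract, vnc_code = tinfo$vnc_code,
    modality = tinfo$modality, depth = tinfo$depth
  )
  # left-right pair truth (types with exactly one member per side)
  lr <- focal |>
    dplyr::group_by(.data$dataset_id, .data$type_label, .data$side) |>
    dplyr::summarise(ids = list(sort(.data$neuron_id)), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "side", values_from = "ids")
  one_one <- lr[lengths(lr$left) == 1L & lengths(lr$right) == 1L, ]
  lr_pairs <- tibble::tibble(
    dataset_id = one_one$dataset_id, type_label = one_one$type_label,
    left_id = unlist(lapply(one_one$left, `[`, 1L)),
    right_id = unlist(lapply(one_one$right, `[`, 1L))
  )
  # cross-dataset homologues by (type, side, member rank)
  hom <- focal |>
    dplyr::group_by(.data$type_label, .data$side, .data$dataset_id) |>
    dplyr::mutate(member = dplyr::row_number(.data$neuron_id)) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(id_cols = c("type_label", "side", "member"),
                       names_from = "dataset_id",
                       values_from = "neuron_id") |>
    dplyr::filter(!is.na(.data$f), !is.na(.data$m))
  list(
    types = types,
    neurons = neurons_truth,
    lr_pairs = lr_pairs,
    homologues = dplyr::rename(hom, id_f = "f", id_m = "m"),
    dimorphism = dimorphism,
    seeds = seeds
  )
}

#' Write a ready-made synthetic fixture bundle to disk
#'
#' `tiny` (8 types, well under a second) serves unit tests; `default`
#' (60 types) is the full study condition.
#'
#' @param dir Output directory.
#' @param size `"tiny"` or `"default"`.
#' @param seed Root seed.
#' @return Invisibly, a list with the two manifest paths and the truth
#'   tables (also written as TSVs under `dir/truth/`).
#' @export
emit_fixture <- function(dir, size = c("tiny", "default"), seed = 1L) {
  size <- match.arg(size)
  cfg <- if (size == "tiny") {
    synth_config(n_types = 8, frac_sex_specific = 0.25, frac_dimorphic = 0.125,
                 frac_count_variable = 0, frac_excluded = 0,
                 frac_recon_issue = 0, n_modalities = 4, max_depth = 2,
                 seed = seed)
  } else {
    synth_config(seed = seed)
  }
  gen <- generate_connectomes(cfg)
  mf <- write_dataset(gen$female, file.path(dir, "female"))
  mm <- write_dataset(gen$male, file.path(dir, "male"))
  tdir <- file.path(dir, "truth")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("neurons", "lr_pairs", "homologues", "dimorphism", "seeds")) {
    write_table_file(gen$truth[[nm]], file.path(tdir, paste0(nm, ".tsv")))
  }
  write_table_file(gen$landmarks, file.path(dir, "landmarks.tsv"))
  invisible(list(female = mf, male = mm, truth = gen$truth,
                 landmarks = gen$landmarks))
}
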