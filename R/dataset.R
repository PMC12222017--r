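#' Assemble and validate a connectome dataset bundle
#'
#' A dataset bundles per-neuron metadata, skeletons, synapse records, an edge
#' list, a neuropil atlas and (optionally) landmark pairs to a partner
#' dataset. `load_dataset()` reads a manifest (YAML or JSON) whose entries
#' name the component files, all relative to the manifest's directory, and
#' validates referential integrity.
#'
#' Manifest keys: `dataset_id`, `neurons`, `synapses`, `edges`, `skeletons`
#' (a directory of `<neuron_id>.swc` files), `atlas`, and optionally
#' `landmarks`.
#'
#' @param manifest Path to a YAML or JSON manifest file.
#' @return A `connectome_dataset`: a list with elements `dataset_id`,
#'   `neurons`, `skeletons` (named list of skeleton tibbles), `synapses`,
#'   `edges`, `atlas`, `landmarks`, and a `validation` tibble of per
#'   class/side counts.
#' @export
load_dataset <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest, call. = FALSE)
  spec <- if (grepl("\\.json$", manifest)) {
    jsonlite::read_json(manifest, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(manifest)
  }
  root <- dirname(manifest)
  pathof <- function(key) file.path(root, spec[[key]])

  neurons <- read_table_file(pathof("neurons"))
  synapses <- read_table_file(pathof("synapses"))
  edges <- read_table_file(pathof("edges"))
  atlas <- read_atlas(pathof("atlas"))
  landmarks <- if (!is.null(spec$landmarks)) read_table_file(pathof("landmarks")) else NULL

  skels <- list()
  if (!is.null(spec$skeletons)) {
    skdir <- pathof("skeletons")
    files <- list.files(skdir, pattern = "\\.swc$", full.names = TRUE)
    skels <- lapply(files, read_swc)
    names(skels) <- sub("\\.swc$", "", basename(files))
  }

  ds <- structure(
    list(
      dataset_id = spec$dataset_id %||% "dataset",
      neurons = as_neuron_table(neurons),
      skeletons = skels,
      synapses = synapses,
      edges = edges,
      atlas = atlas,
      landmarks = landmarks
    ),
    class = "connectome_dataset"
  )
  ds$validation <- validate_dataset(ds)
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_table_file <- function(path) {
  if (!file.exists(path)) stop("component file not found: ", path, call. = FALSE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

write_table_file <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

neuron_sides <- c("left", "right", "center", "unknown")
neuron_classes <- c("DN", "AN", "SA", "MN", "SN", "IN")
neuron_flags <- c("truncated", "well_reconstructed", "neuropeptidergic",
                  "ahn", "abdominal_innervation")

as_neuron_table <- function(neurons) {
  needed <- c("neuron_id", "side", "cns_region", "neuron_class")
  missing <- setdiff(needed, names(neurons))
  if (length(missing) > 0L) {
    stop("neuron table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  neurons$neuron_id <- as.character(neurons$neuron_id)
  bad_side <- setdiff(unique(neurons$side), neuron_sides)
  if (length(bad_side) > 0L) {
    stop("invalid side value(s): ", paste(bad_side, collapse = ", "),
         call. = FALSE)
  }
  bad_class <- setdiff(unique(neurons$neuron_class), neuron_classes)
  if (length(bad_class) > 0L) {
    stop("invalid neuron_class value(s): ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  neurons
}

#' Validate referential integrity of a dataset
#'
#' Checks that neuron ids are unique, that every edge endpoint and synapse
#' record resolves to a neuron, and that every skeleton belongs to a neuron
#' and has at least one node. Validation never mutates the dataset.
#'
#' @param ds A `connectome_dataset`.
#' @return A tibble of neuron counts per (neuron_class, side), attached by
#'   [load_dataset()] as the validation report. Integrity failures raise
#'   errors naming the offending ids; an empty edge table only warns.
#' @export
validate_dataset <- function(ds) {
  neurons <- ds$neurons
  if (anyDuplicated(neurons$neuron_id)) {
    dup <- unique(neurons$neuron_id[duplicated(neurons$neuron_id)])
    stop("duplicate neuron_id: ", paste(utils::head(dup, 5L), collapse = ", "),
         call. = FALSE)
  }
  ids <- neurons$neuron_id
  if (nrow(ds$edges) == 0L) {
    warning("dataset '", ds$dataset_id, "' has no edges", call. = FALSE)
  } else {
    bad <- setdiff(unique(c(as.character(ds$edges$pre_id),
                            as.character(ds$edges$post_id))), ids)
    if (length(bad) > 0L) {
      stop("edge references unknown neuron id(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    if (any(ds$edges$weight < 1)) stop("edge weight < 1", call. = FALSE)
  }
  if (nrow(ds$synapses) > 0L) {
    bad <- setdiff(unique(as.character(ds$synapses$neuron_id)), ids)
    if (length(bad) > 0L) {
      stop("synapse references unknown neuron id(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    if (!all(ds$synapses$role %in% c("pre", "post"))) {
      stop("synapse role must be 'pre' or 'post'", call. = FALSE)
    }
    if (any(!is.finite(ds$synapses$cleft_score))) {
      stop("non-finite cleft_score", call. = FALSE)
    }
  }
  if (length(ds$skeletons) > 0L) {
    bad <- setdiff(names(ds$skeletons), ids)
    if (length(bad) > 0L) {
      stop("skeleton for unknown neuron id(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    nn <- vapply(ds$skeletons, nrow, integer(1))
    if (any(nn < 1L)) stop("empty skeleton present", call. = FALSE)
  }
  dplyr::count(neurons, .data$neuron_class, .data$side, name = "n")
}

#' Read a neuropil atlas definition
#'
#' The atlas file is YAML or JSON with `midline_x` (nm), a `regions` list of
#' axis-aligned boxes (`label`, `xmin..zmax`, nm), and `region_sets` naming at
#' least the `upper_tectulum` and `leg_neuropils` memberships used by the
#' nerve-cord annotation rule.
#'
#' @param path Atlas file path.
#' @return A list with `regions` (tibble), `region_sets` (named list of
#'   character vectors) and `midline_x`.
#' @export
read_atlas <- function(path) {
  spec <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  regions <- dplyr::bind_rows(lapply(spec$regions, tibble::as_tibble))
  sets <- lapply(spec$region_sets, unlist)
  bad <- setdiff(unlist(sets), regions$label)
  if (length(bad) > 0L) {
    stop("region_set member(s) not defined as regions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  check_atlas_overlap(regions)
  list(regions = regions, region_sets = sets,
       midline_x = as.numeric(spec$midline_x))
}

check_atlas_overlap <- function(regions) {
  n <- nrow(regions)
  if (n < 2L) return(invisible(TRUE))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ov <- regions$xmin[i] < regions$xmax[j] && regions$xmax[i] > regions$xmin[j] &&
        regions$ymin[i] < regions$ymax[j] && regions$ymax[i] > regions$ymin[j] &&
        regions$zmin[i] < regions$zmax[j] && regions$zmax[i] > regions$zmin[j]
      if (ov) {
        stop("atlas regions overlap: ", regions$label[i], " and ",
             regions$label[j], call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Label points with the atlas region containing them
#'
#' @param points A data frame with `x`, `y`, `z` columns (nm).
#' @param atlas An atlas as returned by [read_atlas()].
#' @return Character vector of region labels, `NA` where no box contains the
#'   point.
#' @export
locate_in_atlas <- function(points, atlas) {
  out <- rep(NA_character_, nrow(points))
  for (i in seq_len(nrow(atlas$regions))) {
    r <- atlas$regions[i, ]
    inside <- points$x >= r$xmin & points$x < r$xmax &
      points$y >= r$ymin & points$y < r$ymax &
      points$z >= r$zmin & points$z < r$zmax
    out[inside & is.na(out)] <- r$label
  }
  out
}

#' @export
print.connectome_dataset <- function(x, ...) {
  cat("<connectome_dataset> ", x$dataset_id, "\n", sep = "")
  cat("  neurons:  ", nrow(x$neurons), "\n", sep = "")
  cat("  skeletons:", length(x$skeletons), "\n", sep = "")
  cat("  synapses: ", nrow(x$synapses), "\n", sep = "")
  cat("  edges:    ", nrow(x$edges), "\n", sep = "")
  invisible(x)
}

#' Write a dataset bundle to disk
#'
#' Emits the manifest plus component files in the exact layout
#' [load_dataset()] reads: TSV tables, one SWC per skeleton, YAML atlas.
#'
#' @param ds A `connectome_dataset`.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  skdir <- file.path(dir, "skeletons")
  dir.create(skdir, showWarnings = FALSE)
  write_table_file(ds$neurons, file.path(dir, "neurons.tsv"))
  write_table_file(ds$synapses, file.path(dir, "synapses.tsv"))
  write_table_file(ds$edges, file.path(dir, "edges.tsv"))
  for (id in names(ds$skeletons)) {
    write_swc(ds$skeletons[[id]], file.path(skdir, paste0(id, ".swc")))
  }
  atlas_out <- list(
    midline_x = ds$atlas$midline_x,
    regions = lapply(seq_len(nrow(ds$atlas$regions)), function(i) {
      as.list(ds$atlas$regions[i, ])
    }),
    region_sets = lapply(ds$atlas$region_sets, as.list)
  )
  yaml::write_yaml(atlas_out, file.path(dir, "atlas.yaml"))
  manifest <- list(
    dataset_id = ds$dataset_id,
    neurons = "neurons.tsv", synapses = "synapses.tsv", edges = "edges.tsv",
    skeletons = "skeletons", atlas = "atlas.yaml"
  )
  if (!is.null(ds$landmarks)) {
    write_table_file(ds$landmarks, file.path(dir, "landmarks.tsv"))
    manifest$landmarks <- "landmarks.tsv"
  }
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}
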