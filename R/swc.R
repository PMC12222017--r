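#' Read a neuron skeleton from an SWC file
#'
#' Parses the plain-text SWC dialect (seven whitespace-separated columns,
#' `#` comment lines) into a node table. Node ids need not be contiguous;
#' a `parent_id` of -1 marks a root. The tree structure is validated:
#' every parent must exist, every connected component must have exactly one
#' root, and the parent relation must be acyclic.
#'
#' @param path Path to an SWC file.
#' @return A tibble of class `swc_skeleton` with columns `node_id`,
#'   `structure`, `x`, `y`, `z`, `radius`, `parent_id`. Coordinates and radii
#'   are in nanometres; a radius of -1 means unknown. Node order is the file
#'   order.
#' @seealso [write_swc()]
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) {
    stop("SWC file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  lineno <- seq_along(lines)[keep]
  if (length(body) == 0L) {
    stop("SWC parse error: file '", path, "' contains no data lines",
         call. = FALSE)
  }
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    bad <- lineno[which(nf != 7L)[1L]]
    stop("SWC parse error at line ", bad, ": expected 7 fields, got ",
         nf[which(nf != 7L)[1L]], call. = FALSE)
  }
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  )
  if (anyNA(mat)) {
    bad <- lineno[which(rowSums(is.na(mat)) > 0L)[1L]]
    stop("SWC parse error at line ", bad, ": non-numeric field",
         call. = FALSE)
  }
  nodes <- tibble::tibble(
    node_id = as.integer(mat[, 1L]),
    structure = as.integer(mat[, 2L]),
    x = mat[, 3L], y = mat[, 4L], z = mat[, 5L],
    radius = mat[, 6L],
    parent_id = as.integer(mat[, 7L])
  )
  validate_skeleton(nodes, context = path, lineno = lineno)
  new_skeleton(nodes)
}

new_skeleton <- function(nodes) {
  class(nodes) <- c("swc_skeleton", class(tibble::tibble()))
  nodes
}

#' Validate a skeleton node table
#'
#' Checks the `swc_skeleton` invariants: unique node ids, existing parents,
#' exactly one root per connected component, and no cycles in the parent
#' relation. Called by [read_swc()]; exported so programmatically built
#' skeletons can be checked too.
#'
#' @param nodes A node table with `node_id` and `parent_id` columns.
#' @param context Label used in error messages (e.g. a file path).
#' @param lineno Optional file line numbers parallel to the rows.
#' @return `nodes`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_skeleton <- function(nodes, context = "skeleton", lineno = NULL) {
  if (nrow(nodes) == 0L) stop("skeleton has no nodes", call. = FALSE)
  if (anyDuplicated(nodes$node_id)) {
    dup <- nodes$node_id[duplicated(nodes$node_id)][1L]
    stop("SWC parse error in ", context, ": duplicate node id ", dup,
         call. = FALSE)
  }
  is_root <- nodes$parent_id == -1L
  idx <- match(nodes$parent_id, nodes$node_id)
  dangling <- !is_root & is.na(idx)
  if (any(dangling)) {
    i <- which(dangling)[1L]
    where <- if (!is.null(lineno)) paste0(" (line ", lineno[i], ")") else ""
    stop("SWC parse error in ", context, where, ": node ",
         nodes$node_id[i], " references missing parent ",
         nodes$parent_id[i], call. = FALSE)
  }
  # cycle / root-per-component check by walking each node to a root;
  # a walk longer than n nodes implies a cycle
  n <- nrow(nodes)
  comp <- integer(n) # component id = row index of root reached
  for (i in seq_len(n)) {
    j <- i
    steps <- 0L
    while (!is_root[j]) {
      j <- idx[j]
      steps <- steps + 1L
      if (steps > n) {
        stop("SWC parse error in ", context, ": cycle detected involving node ",
             nodes$node_id[i], call. = FALSE)
      }
    }
    comp[i] <- j
  }
  invisible(nodes)
}

#' Write a skeleton to an SWC file
#'
#' Emits canonical SWC: a `#` provenance header, then one line per node
#' sorted by `node_id`. Unknown radii are written as -1. A file written by
#' `write_swc()` and re-read with [read_swc()] round-trips exactly.
#'
#' @param skeleton A skeleton node table (see [read_swc()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(skeleton, path) {
  if (is.null(skeleton) || nrow(skeleton) == 0L) {
    stop("cannot write skeleton: no nodes", call. = FALSE)
  }
  validate_skeleton(skeleton, context = "write_swc input")
  ord <- order(skeleton$node_id)
  s <- skeleton[ord, ]
  lines <- sprintf(
    "%d %d %s %s %s %s %d",
    s$node_id, s$structure,
    format_swc_num(s$x), format_swc_num(s$y), format_swc_num(s$z),
    format_swc_num(s$radius), s$parent_id
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("# SWC skeleton written by neckmatch", lines), con)
  invisible(path)
}

# fixed-format numbers so round-trips are byte-stable
format_swc_num <- function(x) {
  out <- formatC(x, format = "f", digits = 3, drop0trailing = TRUE)
  out[out == "-0"] <- "0"
  out
}

#' Root node id of a skeleton
#' @param skeleton A skeleton node table.
#' @return Integer vector of root node ids (one per connected component).
#' @export
skeleton_roots <- function(skeleton) {
  skeleton$node_id[skeleton$parent_id == -1L]
}

#' Total cable length of a skeleton
#' @param skeleton A skeleton node table.
#' @return Summed parent-child edge length in nanometres.
#' @export
skeleton_cable_length <- function(skeleton) {
  idx <- match(skeleton$parent_id, skeleton$node_id)
  has_parent <- !is.na(idx)
  if (!any(has_parent)) return(0)
  dx <- skeleton$x[has_parent] - skeleton$x[idx[has_parent]]
  dy <- skeleton$y[has_parent] - skeleton$y[idx[has_parent]]
  dz <- skeleton$z[has_parent] - skeleton$z[idx[has_parent]]
  sum(sqrt(dx^2 + dy^2 + dz^2))
}
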