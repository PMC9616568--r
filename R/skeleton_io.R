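# SWC skeleton I/O, annotation tables, and the tri-neuropil selection rule.

#' Read a neuron skeleton from an SWC file
#'
#' Parses the standard 7-column SWC layout (`id type x y z radius parent`,
#' `#` comment lines). Coordinates and radii are multiplied by `unit_scale` on
#' read so that the package-internal unit is micrometres regardless of the raw
#' unit of the reconstruction (e.g. `unit_scale = 0.001` for nanometre data,
#' a dataset-documented voxel factor for voxel data). Fragmented files with
#' several roots are accepted as forests with a warning; EM reconstructions
#' often contain breaks and the downstream distance only needs point sets.
#'
#' @param path path to an SWC file.
#' @param unit_scale positive multiplier applied to coordinates and radii.
#' @param neuron_id identifier for the neuron; defaults to the file stem.
#' @return a `skeleton` object: list with `neuron_id`, `nodes` (data frame with
#'   columns `node_id`, `structure`, `x`, `y`, `z`, `radius`, `parent_id`) and
#'   `unit_scale`.
#' @seealso [write_swc()], [skeleton()]
#' @export
read_swc <- function(path, unit_scale = 1,
                     neuron_id = sub("\\.swc$", "", basename(path), ignore.case = TRUE)) {
  assert_that(file.exists(path), "SWC file not found: %s", path)
  assert_that(is.numeric(unit_scale) && length(unit_scale) == 1L && unit_scale > 0,
              "unit_scale must be a single positive number")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop_("SWC file '%s' contains no data lines", path)
  rows <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad)) {
    stop_("SWC parse error in '%s' at line %d: expected 7 columns, found %d",
          path, rows[bad[1]], lengths(fields)[bad[1]])
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7L, byrow = TRUE)
  nn <- which(apply(is.na(m), 1L, any))
  if (length(nn)) {
    stop_("SWC parse error in '%s' at line %d: non-numeric field", path, rows[nn[1]])
  }
  nodes <- data.frame(
    node_id = as.integer(m[, 1]),
    structure = as.integer(m[, 2]),
    x = m[, 3] * unit_scale,
    y = m[, 4] * unit_scale,
    z = m[, 5] * unit_scale,
    radius = m[, 6] * unit_scale,
    parent_id = as.integer(m[, 7])
  )
  skeleton(neuron_id, nodes, unit_scale = unit_scale)
}

#' Construct and validate a skeleton
#'
#' Checks the SWC structural invariants: at least one node, unique node ids,
#' every non-root parent refers to an existing node, no parent cycles, finite
#' coordinates and non-negative radii.
#'
#' @param neuron_id neuron identifier (coerced to character).
#' @param nodes data frame with columns `node_id`, `structure`, `x`, `y`, `z`,
#'   `radius`, `parent_id` (parent `-1` marks a root).
#' @param unit_scale multiplier that was applied on read (metadata).
#' @return a `skeleton` object.
#' @export
skeleton <- function(neuron_id, nodes, unit_scale = 1) {
  required <- c("node_id", "structure", "x", "y", "z", "radius", "parent_id")
  assert_that(is.data.frame(nodes) && all(required %in% names(nodes)),
              "nodes must be a data frame with columns %s", paste(required, collapse = ", "))
  assert_that(nrow(nodes) >= 1L, "skeleton must contain at least one node")
  assert_that(!anyDuplicated(nodes$node_id), "duplicate node_id in skeleton '%s'", neuron_id)
  assert_that(all(is.finite(nodes$x)) && all(is.finite(nodes$y)) && all(is.finite(nodes$z)),
              "skeleton '%s' has non-finite coordinates", neuron_id)
  assert_that(all(nodes$radius >= 0), "skeleton '%s' has negative radii", neuron_id)
  parents <- nodes$parent_id
  roots <- parents == -1L
  assert_that(any(roots), "skeleton '%s' has no root node (parent_id == -1)", neuron_id)
  dangling <- !roots & !(parents %in% nodes$node_id)
  if (any(dangling)) {
    stop_("skeleton '%s': node %d refers to missing parent %d",
          neuron_id, nodes$node_id[which(dangling)[1]], parents[which(dangling)[1]])
  }
  # cycle check: follow parents with a visit budget of n steps
  idx <- match(parents, nodes$node_id)
  n <- nrow(nodes)
  depth <- rep.int(NA_integer_, n)
  for (i in seq_len(n)) {
    steps <- 0L
    j <- i
    while (!is.na(j) && parents[j] != -1L) {
      if (!is.na(depth[j])) break
      steps <- steps + 1L
      if (steps > n) stop_("skeleton '%s': parent cycle detected at node %d", neuron_id, nodes$node_id[i])
      j <- idx[j]
    }
    depth[i] <- 0L
  }
  if (sum(roots) > 1L) {
    warn_("skeleton '%s' is fragmented: %d roots (accepted as a forest)",
          neuron_id, sum(roots))
  }
  structure(list(neuron_id = as.character(neuron_id), nodes = nodes,
                 unit_scale = unit_scale),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %s: %d nodes, %d root(s)\n", x$neuron_id,
              nrow(x$nodes), sum(x$nodes$parent_id == -1L)))
  invisible(x)
}

#' Extract the node coordinates of a skeleton as a matrix
#'
#' @param s a `skeleton`.
#' @return numeric matrix with one row per node and columns x, y, z (um).
#' @export
skeleton_points <- function(s) {
  assert_that(inherits(s, "skeleton"), "expected a skeleton object")
  cbind(x = s$nodes$x, y = s$nodes$y, z = s$nodes$z)
}

#' Write a skeleton to an SWC file
#'
#' Round-trips with [read_swc()] up to coordinate formatting precision
#' (15 significant digits are written).
#'
#' @param s a `skeleton`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_swc <- function(s, path) {
  assert_that(inherits(s, "skeleton"), "expected a skeleton object")
  assert_that(nrow(s$nodes) >= 1L, "refusing to write an empty skeleton")
  header <- c("# SWC export (pnorg)",
              sprintf("# neuron_id: %s", s$neuron_id),
              "# columns: id type x y z radius parent")
  fmt <- function(v) formatC(v, digits = 15, format = "g")
  body <- sprintf("%d %d %s %s %s %s %d",
                  s$nodes$node_id, s$nodes$structure,
                  fmt(s$nodes$x), fmt(s$nodes$y), fmt(s$nodes$z),
                  fmt(s$nodes$radius), s$nodes$parent_id)
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_("cannot write SWC file to '%s'", path)
  invisible(path)
}

# Closed annotation vocabularies.
ODOR_TYPES <- c("decaying fruit", "yeasty", "fruity", "unknown/mixed",
                "alcoholic fermentation", "general bad/unclassified aversive",
                "plant matter", "animal matter", "pheromones", "hygro/thermo")
VALENCES <- c("attractive", "aversive", "unknown")
TRACTS <- c("mALT", "mlALT", "lALT", "trans-lALT", "unknown")
NEUROPILS <- c("AL", "MB_calyx", "LH")

#' Default glomerulus alias map
#'
#' The community renaming of three historically confused glomeruli:
#' VC3l -> VC3, VC3m -> VC5, VC5 -> VM6, applied simultaneously (a label is
#' looked up once against the original names, so the chain does not cascade).
#'
#' @return named character vector mapping old labels to new labels.
#' @export
default_alias_map <- function() {
  c(VC3l = "VC3", VC3m = "VC5", VC5 = "VM6")
}

apply_alias_map <- function(homotypes, alias_map = default_alias_map()) {
  if (is.null(alias_map) || !length(alias_map)) return(homotypes)
  hit <- homotypes %in% names(alias_map)
  homotypes[hit] <- unname(alias_map[homotypes[hit]])
  homotypes
}

#' Read a neuron annotation table
#'
#' Delimited text (comma or tab, sniffed from the header line) with columns
#' `neuron_id`, `homotype`, `odor_type`, `valence`, `tract`. Odor type,
#' valence and tract must come from the closed vocabularies; the glomerulus
#' alias map is applied by default.
#'
#' @param path path to the delimited file.
#' @param alias_map named character vector of homotype renamings, or `NULL`.
#' @return a `neuron_table` data frame keyed by `neuron_id`.
#' @export
read_annotations <- function(path, alias_map = default_alias_map()) {
  assert_that(file.exists(path), "annotation table not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  neuron_table(df, alias_map = alias_map)
}

#' Construct and validate a neuron annotation table
#'
#' @param df data frame with columns `neuron_id`, `homotype`, `odor_type`,
#'   `valence`, `tract`.
#' @param alias_map named character vector of homotype renamings, or `NULL`.
#' @return a `neuron_table` data frame.
#' @export
neuron_table <- function(df, alias_map = default_alias_map()) {
  required <- c("neuron_id", "homotype", "odor_type", "valence", "tract")
  assert_that(is.data.frame(df) && all(required %in% names(df)),
              "annotation table must have columns %s", paste(required, collapse = ", "))
  df <- df[required]
  df$neuron_id <- as.character(df$neuron_id)
  assert_that(!anyDuplicated(df$neuron_id), "duplicate neuron_id in annotation table")
  df$homotype <- apply_alias_map(as.character(df$homotype), alias_map)
  assert_that(all(nzchar(df$homotype)), "empty homotype label in annotation table")
  bad <- setdiff(unique(df$odor_type), ODOR_TYPES)
  assert_that(!length(bad), "unknown odor_type value(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$valence), VALENCES)
  assert_that(!length(bad), "unknown valence value(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$tract), TRACTS)
  assert_that(!length(bad), "unknown tract value(s): %s", paste(bad, collapse = ", "))
  class(df) <- c("neuron_table", "data.frame")
  df
}

#' Published per-homotype valence assignments
#'
#' The packaged fixture of putative valences compiled from the Drosophila
#' olfaction literature: 17 homotypes with attractive responses and 25 with
#' aversive responses; all other homotypes are of unknown, non-preferential or
#' conflicting valence.
#'
#' @return data frame with columns `homotype` and `valence`.
#' @export
homotype_valences <- function() {
  path <- system.file("extdata", "homotype_valence.csv", package = "pnorg",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Select uPNs that innervate all three neuropils
#'
#' The study population: only neurons with at least one skeleton node inside
#' each of AL, MB calyx and LH are retained. Neurons present in the masks but
#' absent from the annotation table are excluded with a warning.
#'
#' @param table a `neuron_table`.
#' @param masks neuropil mask data frame from [build_masks()] (columns
#'   `neuron_id`, `node_id`, `neuropil`).
#' @return sorted character vector of retained neuron ids.
#' @export
select_upns <- function(table, masks) {
  assert_that(inherits(table, "neuron_table"), "table must be a neuron_table")
  assert_that(is.data.frame(masks) && all(c("neuron_id", "neuropil") %in% names(masks)),
              "masks must be a data frame with neuron_id and neuropil columns")
  masks$neuron_id <- as.character(masks$neuron_id)
  unknown <- setdiff(unique(masks$neuron_id), table$neuron_id)
  if (length(unknown)) {
    warn_("excluding %d neuron(s) absent from the annotation table: %s",
          length(unknown), paste(utils::head(sort(unknown), 5L), collapse = ", "))
    masks <- masks[!masks$neuron_id %in% unknown, , drop = FALSE]
  }
  um <- unique(masks[masks$neuropil %in% NEUROPILS, c("neuron_id", "neuropil")])
  cover <- tapply(um$neuropil, um$neuron_id, function(v) length(unique(v)))
  sort(names(cover)[cover == length(NEUROPILS)])
}
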