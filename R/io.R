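## Plain-text input/output.
##
## Spine table (TSV): columns tree_id, segment_id, position_um, label —
## one row per spine, positions as path distances from the segment's
## proximal (soma-side) end. Topology table (TSV): columns segment_id,
## parent_id (empty for the root), n_spines, and optionally length_um.
## Without a topology table every tree must consist of one segment.

#' Read and write spine tables
#'
#' \code{readSpineTable} parses a spine table (and optional topology table)
#' into \code{\linkS4class{DendriteTree}} objects; \code{writeSpineTable}
#' writes them back. Writing then reading restores the layouts exactly.
#' Malformed rows are reported with their line numbers.
#'
#' @param path spine-table TSV.
#' @param topologyPath optional topology TSV.
#' @return \code{readSpineTable}: named list of
#'   \code{\linkS4class{DendriteTree}}, one per \code{tree_id}.
#' @export
readSpineTable <- function(path, topologyPath = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(tree_id = "character",
                                         segment_id = "character"),
                          stringsAsFactors = FALSE)
  need <- c("tree_id", "segment_id", "position_um", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("spine table misses column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$position_um) | df$position_um < 0)
  if (length(bad))
    stop("invalid position_um at line(s) ",
         paste(bad + 1, collapse = ", "), " of ", path)
  bad <- which(!df$label %in% c(0, 1))
  if (length(bad))
    stop("label must be 0 or 1; offending line(s) ",
         paste(bad + 1, collapse = ", "), " of ", path)
  topo <- NULL
  if (!is.null(topologyPath)) {
    topo <- utils::read.table(topologyPath, header = TRUE, sep = "\t",
                              colClasses = c(segment_id = "character",
                                             parent_id = "character"),
                              na.strings = c("", "NA"),
                              stringsAsFactors = FALSE)
    if (!all(c("segment_id", "parent_id") %in% names(topo)))
      stop("topology table needs columns segment_id, parent_id")
  }
  trees <- list()
  for (tid in unique(df$tree_id)) {
    sub <- df[df$tree_id == tid, , drop = FALSE]
    segIds <- unique(sub$segment_id)
    if (!is.null(topo)) {
      unknown <- setdiff(segIds, topo$segment_id)
      if (length(unknown))
        stop("segment(s) missing from topology: ",
             paste(unknown, collapse = ", "))
      segIds <- topo$segment_id
      parent <- match(topo$parent_id, topo$segment_id)
      if (!is.null(topo$n_spines)) {
        cnt <- vapply(segIds, function(s) sum(sub$segment_id == s), 0)
        off <- which(cnt != topo$n_spines)
        if (length(off))
          warning("n_spines in topology disagrees with the spine table for ",
                  paste(segIds[off], collapse = ", "))
      }
    } else {
      if (length(segIds) > 1)
        stop("tree '", tid, "' has several segments but no topology table")
      parent <- NA_integer_
    }
    segs <- lapply(seq_along(segIds), function(i) {
      rows <- sub[sub$segment_id == segIds[i], , drop = FALSE]
      len <- NA_real_
      if (!is.null(topo) && !is.null(topo$length_um)) len <- topo$length_um[i]
      SpineLayout(rows$position_um, rows$label == 1,
                  segmentId = segIds[i], length = len)
    })
    trees[[tid]] <- DendriteTree(segs, as.integer(parent))
  }
  trees
}

#' @param x a \code{\linkS4class{DendriteTree}},
#'   \code{\linkS4class{SpineLayout}} or list of trees.
#' @param treeId identifier used when \code{x} is a single layout/tree.
#' @rdname readSpineTable
#' @export
writeSpineTable <- function(x, path, treeId = "tree1") {
  if (is(x, "SpineLayout")) x <- DendriteTree(list(x), NA_integer_)
  if (is(x, "DendriteTree")) {
    x <- stats::setNames(list(x), treeId)
  }
  rows <- list()
  for (tid in names(x)) {
    tr <- x[[tid]]
    for (s in tr@segments) {
      if (!nSpines(s)) next
      rows[[length(rows) + 1]] <- data.frame(
        tree_id = tid, segment_id = s@segmentId,
        position_um = s@positions, label = as.integer(s@labeled))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tree_id = character(0), segment_id = character(0),
               position_um = numeric(0), label = integer(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the topology table of a tree
#'
#' @param tree a \code{\linkS4class{DendriteTree}}.
#' @param path output TSV.
#' @export
writeTreeTopology <- function(tree, path) {
  stopifnot(is(tree, "DendriteTree"))
  df <- data.frame(
    segment_id = vapply(tree@segments, function(s) s@segmentId, ""),
    parent_id = ifelse(is.na(tree@parent), NA,
                       vapply(tree@parent, function(p)
                         if (is.na(p)) NA_character_
                         else tree@segments[[p]]@segmentId, "")),
    n_spines = vapply(tree@segments, nSpines, 0),
    length_um = vapply(tree@segments, segmentLength, 0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Convert MATLAB-style spine exports to the spine-table format
#'
#' Parses text files of MATLAB vector assignments — per segment a position
#' vector \code{positions_<id> = [ ... ];} (um) and an input-index vector
#' \code{inputs_<id> = [ ... ];} (1-based indices of the labeled spines),
#' plus an optional \code{parent_<id> = <id>;} scalar wiring the segments —
#' into a \code{\linkS4class{DendriteTree}}. This is the ingestion route
#' for externally exported example data; it performs no analysis of its
#' own.
#'
#' @param path text file with MATLAB-style assignments.
#' @return A \code{\linkS4class{DendriteTree}}.
#' @export
readMatlabSpineData <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("%[^\n]*", "", txt)              # strip comments
  pat <- "([A-Za-z]+)_([A-Za-z0-9]+)\\s*=\\s*(\\[[^]]*\\]|[A-Za-z0-9.]+)\\s*;"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1) stop("no MATLAB-style assignments found in ", path)
  vars <- regmatches(txt, gregexpr(pat, txt, perl = TRUE))[[1]]
  parse_one <- function(v) {
    kind <- sub(pat, "\\1", v); id <- sub(pat, "\\2", v)
    raw <- trimws(gsub("\\[|\\]", "", sub(pat, "\\3", v)))
    nums <- suppressWarnings(as.numeric(strsplit(raw, "[,[:space:]]+")[[1]]))
    nums <- nums[!is.na(nums)]
    list(kind = tolower(kind), id = id, value = nums, raw = raw)
  }
  parsed <- lapply(vars, parse_one)
  ids <- unique(vapply(parsed, `[[`, "", "id"))
  get <- function(kind, id, raw = FALSE) {
    for (p in parsed) if (p$kind == kind && p$id == id)
      return(if (raw) p$raw else p$value)
    NULL
  }
  segs <- list(); parent_ids <- character(0)
  for (id in ids) {
    pos <- get("positions", id)
    if (is.null(pos)) next
    inp <- get("inputs", id)
    lab <- seq_along(pos) %in% inp
    segs[[length(segs) + 1]] <- SpineLayout(pos, lab, segmentId = id)
    par <- get("parent", id, raw = TRUE)
    parent_ids <- c(parent_ids,
                    if (is.null(par) || !nzchar(par)) NA_character_ else par)
  }
  if (!length(segs)) stop("no positions_<id> vectors found in ", path)
  segids <- vapply(segs, function(s) s@segmentId, "")
  parent <- match(parent_ids, segids)
  if (all(is.na(parent)) && length(segs) > 1)
    stop("several segments but no parent_<id> assignments in ", path)
  DendriteTree(segs, as.integer(parent))
}
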