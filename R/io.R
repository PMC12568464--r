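#' Read a molecular graph from an edge-list file
#'
#' Each non-comment line names one edge as two vertex tokens separated by
#' whitespace or a comma.  Lines starting with `#` are comments.  Duplicate
#' edges (in either orientation) and self-loops are rejected with an error
#' naming the offending line.
#'
#' @param path file path.
#' @return An undirected simple `igraph`.
#' @export
readEdgeList <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    stop("no edges in '", path, "'")
  toks <- strsplit(lines, "[,[:space:]]+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad))
    stop("malformed edge line in '", path, "': '", lines[bad[1L]], "'")
  el <- do.call(rbind, toks)
  if (any(el[, 1L] == el[, 2L]))
    stop("self-loop in '", path, "': '",
         lines[which(el[, 1L] == el[, 2L])[1L]], "'")
  key <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  if (anyDuplicated(key))
    stop("duplicate/reversed edge in '", path, "': '",
         lines[which(duplicated(key))[1L]], "'")
  asMolecularGraph(igraph::graph_from_edgelist(el, directed = FALSE))
}

#' Write a graph as an edge-list file
#'
#' @param graph an `igraph`.
#' @param path output path; tab-separated, one edge per line.
#' @export
writeEdgeList <- function(graph, path) {
  graph <- asMolecularGraph(graph)
  el <- igraph::as_edgelist(graph)
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Read a heavy-atom graph from a MOL/SDF file (V2000)
#'
#' Parses the atom and bond blocks of the first molecule in a V2000
#' MOL/SDF file and returns its hydrogen-suppressed connectivity graph:
#' hydrogen atoms (and their bonds) are dropped, bond orders are ignored.
#'
#' @param path file path.
#' @return An undirected simple `igraph`; vertex attribute `element` keeps
#'   the atomic symbols.
#' @export
readMolFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L)
    stop("'", path, "' is not a MOL file (too short)")
  counts <- lines[4L]
  nAtom <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nBond <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(nAtom) || is.na(nBond))
    stop("'", path, "' has a malformed V2000 counts line")
  atomLines <- lines[4L + seq_len(nAtom)]
  elem <- trimws(substr(atomLines, 32L, 34L))
  bondLines <- lines[4L + nAtom + seq_len(nBond)]
  from <- as.integer(substr(bondLines, 1L, 3L))
  to <- as.integer(substr(bondLines, 4L, 6L))
  heavy <- which(elem != "H")
  keep <- from %in% heavy & to %in% heavy
  idx <- match(seq_len(nAtom), heavy)  # old -> new vertex index
  g <- igraph::make_empty_graph(n = length(heavy), directed = FALSE)
  g <- igraph::add_edges(g, rbind(idx[from[keep]], idx[to[keep]]))
  igraph::V(g)$element <- elem[heavy]
  igraph::V(g)$name <- paste0(elem[heavy], seq_along(heavy))
  asMolecularGraph(g)
}

#' Read an edge partition from a JSON or CSV file
#'
#' JSON files map `"dLo,dHi"` keys to counts; CSV files have two columns
#' (pair, count) where the pair column is `"dLo,dHi"` -- with optional
#' parentheses -- and may be quoted.  The format is chosen by extension
#' unless `format` is given.
#'
#' @param path file path.
#' @param format `"json"` or `"csv"`; default guesses from the extension.
#' @return An [EdgePartition-class].
#' @export
readPartition <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    obj <- jsonlite::fromJSON(path)
    keys <- names(obj)
    counts <- as.numeric(unlist(obj))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
      stop("partition CSV must have two columns (pair, count)")
    keys <- as.character(df[[1L]])
    counts <- as.numeric(df[[2L]])
  }
  keys <- gsub("[()[:space:]]", "", keys)
  parts <- strsplit(keys, ",", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed degree-pair key in '", path, "'")
  m <- do.call(rbind, lapply(parts, as.integer))
  EdgePartition(m[, 1L], m[, 2L], counts)
}

#' Write an edge partition to JSON or CSV
#'
#' @param partition an [EdgePartition-class].
#' @param path output path.
#' @param format `"json"` or `"csv"`; default guesses from the extension.
#' @export
writePartition <- function(partition, path, format = c("auto", "json", "csv")) {
  stopifnot(is(partition, "EdgePartition"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  counts <- edgeCounts(partition)
  if (format == "json") {
    jsonlite::write_json(as.list(counts), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(data.frame(pair = names(counts), count = counts),
                     path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Write an entropy table to CSV or JSON
#'
#' CSV output rounds entropy columns to `digits` decimals (the published
#' display precision); JSON keeps full double precision for programmatic
#' reuse.
#'
#' @param table data.frame as returned by [familyEntropyTable()] or
#'   [referenceEntropyTable()].
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @param digits decimals for CSV display (default 4).
#' @export
writeEntropyTable <- function(table, path, format = c("csv", "json"),
                              digits = 4) {
  format <- match.arg(format)
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("table must be a non-empty data.frame")
  if (format == "csv") {
    out <- table
    num <- setdiff(names(out)[vapply(out, is.numeric, logical(1))], "n")
    out[num] <- lapply(out[num], function(x)
      formatC(round(x, digits), format = "f", digits = digits))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}
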