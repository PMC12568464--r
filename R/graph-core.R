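#' Validate a molecular graph
#'
#' Molecular graphs are hydrogen-suppressed heavy-atom skeletons: simple
#' undirected `igraph` objects.  Self-loops and duplicate (parallel) edges
#' are rejected outright rather than coerced, naming an offending edge;
#' directed graphs are rejected.  Isolated vertices are permitted (with a
#' warning) but play no role in any edge-based computation.
#'
#' @param graph an `igraph` object.
#' @return The validated graph, invisibly unchanged.
#' @export
asMolecularGraph <- function(graph) {
  if (!igraph::is_igraph(graph))
    stop("expected an igraph object")
  if (igraph::is_directed(graph))
    stop("molecular graphs must be undirected")
  loops <- which(igraph::which_loop(graph))
  if (length(loops)) {
    e <- igraph::ends(graph, igraph::E(graph)[loops[1L]])
    stop("self-loop at vertex '", e[1L], "' is not allowed")
  }
  dup <- which(igraph::which_multiple(graph))
  if (length(dup)) {
    e <- igraph::ends(graph, igraph::E(graph)[dup[1L]])
    stop("duplicate edge {", e[1L], ", ", e[2L], "} is not allowed")
  }
  if (any(igraph::degree(graph) == 0))
    warning("graph has isolated vertices; they are ignored by all edge-based computations")
  graph
}

#' Vertex degrees of a molecular graph
#'
#' @param graph an undirected simple `igraph`.
#' @return Named integer vector mapping every vertex to its degree; the sum
#'   of degrees equals twice the number of edges.
#' @examples
#' vertexDegrees(igraph::make_ring(6))  # all 2
#' @export
vertexDegrees <- function(graph) {
  graph <- asMolecularGraph(graph)
  igraph::degree(graph)
}

#' Degree-pair edge partition of a graph
#'
#' Classifies every edge by the unordered pair of its endpoint degrees.
#'
#' @param graph an undirected simple `igraph` with at least one edge.
#' @return An [EdgePartition-class]; counts sum to the number of edges.
#' @examples
#' edgePartition(igraph::make_ring(6))  # {(2,2): 6}
#' @export
edgePartition <- function(graph) {
  graph <- asMolecularGraph(graph)
  if (igraph::ecount(graph) == 0L)
    stop("graph has no edges; partition undefined")
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  deg <- igraph::degree(graph)
  a <- deg[ends[, 1L]]
  b <- deg[ends[, 2L]]
  key <- paste(pmin(a, b), pmax(a, b), sep = ",")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), ",", fixed = TRUE))
  EdgePartition(as.integer(parts[, 1L]), as.integer(parts[, 2L]),
                as.numeric(tab))
}

#' Realizability of an edge partition
#'
#' A simple graph realizing a degree-pair partition must contain, for every
#' degree `d`, exactly `stubs(d) / d` vertices of degree `d`, where
#' `stubs(d)` counts the endpoints of degree `d` over all classes.  This
#' divisibility is a necessary condition; the forced vertex counts are
#' reported when it holds.
#'
#' @param partition an [EdgePartition-class].
#' @return A list with elements `feasible` (logical), `verticesPerDegree`
#'   (named vector, only when feasible), `nVertices`, `nEdges`, and, when
#'   infeasible, `reason` naming the violating degree.
#' @examples
#' partitionRealizability(EdgePartition(2, 2, 6))  # C6: 6 vertices, 6 edges
#' @export
partitionRealizability <- function(partition) {
  stopifnot(is(partition, "EdgePartition"))
  validObject(partition)
  degs <- sort(unique(c(partition@dLo, partition@dHi)))
  stubs <- vapply(degs, function(d) {
    sum(partition@count * ((partition@dLo == d) + (partition@dHi == d)))
  }, numeric(1))
  names(stubs) <- degs
  bad <- which(stubs %% degs != 0)
  if (length(bad)) {
    return(list(feasible = FALSE,
                reason = sprintf(
                  "stub count %g for degree %d is not divisible by %d",
                  stubs[bad[1L]], degs[bad[1L]], degs[bad[1L]]),
                nEdges = sum(partition@count)))
  }
  v <- stubs / degs
  list(feasible = TRUE,
       verticesPerDegree = setNames(v, degs),
       nVertices = sum(v),
       nEdges = sum(partition@count))
}
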