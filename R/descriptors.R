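#' Product and sum edge weights of a degree pair
#'
#' For an edge `e = pq` with endpoint degrees `d_p`, `d_q`, the two basic
#' edge weights are the degree product `w* = d_p * d_q` and the degree sum
#' `w+ = d_p + d_q`.  Every supported index is a function of these two
#' numbers.
#'
#' @param dP,dQ positive integer endpoint degrees (vectorised).
#' @return A list with numeric components `wStar` and `wPlus`.
#' @examples
#' edgeWeights(2, 3)  # wStar 6, wPlus 5
#' @export
edgeWeights <- function(dP, dQ) {
  if (any(dP < 1) || any(dQ < 1) || any(dP != round(dP)) || any(dQ != round(dQ)))
    stop("degrees must be positive integers")
  list(wStar = as.numeric(dP) * as.numeric(dQ),
       wPlus = as.numeric(dP) + as.numeric(dQ))
}

#' Per-edge contribution of a descriptor
#'
#' Returns `j_e`, the single-edge summand of the named index for an edge
#' whose endpoints have degrees `dP` and `dQ`:
#' \describe{
#'   \item{M1}{`w+`}
#'   \item{M2}{`w*`}
#'   \item{Ralpha}{`(w*)^alpha`}
#'   \item{R}{`(w*)^(-1/2)`}
#'   \item{HM}{`(w+)^2`}
#'   \item{SCI}{`(w+)^(-1/2)`}
#'   \item{CHIalpha}{`(w+)^alpha`}
#'   \item{GA}{`2 sqrt(w*) / w+`}
#'   \item{ABC}{`sqrt((w+ - 2) / w*)`}
#'   \item{H}{`2 / w+`}
#' }
#' The ABC contribution of a `(1,1)` edge is 0; this is permitted in index
#' sums but rejected by the entropy functions, where a zero contribution
#' would make the normalised distribution ill-posed.
#'
#' @param spec a [DescriptorSpec-class] or descriptor name.
#' @param dP,dQ positive integer endpoint degrees (vectorised).
#' @param alpha exponent when `spec` is the name of a parametric descriptor.
#' @return Numeric vector of contributions.
#' @examples
#' edgeContribution("GA", 2, 2)   # 1: arithmetic = geometric mean
#' edgeContribution("ABC", 3, 3)  # 2/3
#' @export
edgeContribution <- function(spec, dP, dQ, alpha = NULL) {
  spec <- .asSpec(spec, alpha)
  w <- edgeWeights(dP, dQ)
  switch(spec@name,
    M1 = w$wPlus,
    M2 = w$wStar,
    Ralpha = w$wStar^spec@alpha,
    R = w$wStar^(-0.5),
    HM = w$wPlus^2,
    SCI = w$wPlus^(-0.5),
    CHIalpha = w$wPlus^spec@alpha,
    GA = 2 * sqrt(w$wStar) / w$wPlus,
    ABC = sqrt((w$wPlus - 2) / w$wStar),
    H = 2 / w$wPlus)
}

#' Topological index of an edge partition
#'
#' Sums the per-edge contributions of a descriptor over a degree-pair edge
#' partition: `D = sum_classes count * j(dLo, dHi)`.  Because every
#' supported index is edge-additive and depends only on endpoint degrees,
#' this equals the index of any graph with that partition.
#'
#' @param partition an [EdgePartition-class].
#' @param spec a [DescriptorSpec-class] or descriptor name.
#' @param alpha exponent for parametric descriptors given by name.
#' @return The index value (numeric scalar).
#' @examples
#' ke1 <- kekulenePartition(1)
#' indexFromPartition(ke1, "M1")  # 312
#' @export
indexFromPartition <- function(partition, spec, alpha = NULL) {
  stopifnot(is(partition, "EdgePartition"))
  validObject(partition)
  spec <- .asSpec(spec, alpha)
  j <- edgeContribution(spec, partition@dLo, partition@dHi)
  sum(partition@count * j)
}

#' Topological index of a molecular graph
#'
#' Equivalent to `indexFromPartition(edgePartition(graph), spec)`, computed
#' by direct edge enumeration.
#'
#' @param graph an undirected simple `igraph` (see [asMolecularGraph()]).
#' @inheritParams indexFromPartition
#' @return The index value (numeric scalar).
#' @examples
#' c6 <- igraph::make_ring(6)
#' indexFromGraph(c6, "M1")  # 24
#' @export
indexFromGraph <- function(graph, spec, alpha = NULL) {
  graph <- asMolecularGraph(graph)
  spec <- .asSpec(spec, alpha)
  if (igraph::ecount(graph) == 0L)
    stop("graph has no edges; index undefined")
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  deg <- igraph::degree(graph)
  sum(edgeContribution(spec, deg[ends[, 1L]], deg[ends[, 2L]]))
}
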