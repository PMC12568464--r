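#' Shannon entropy of a probability vector
#'
#' `-sum(p * log(p))` with the convention `0 * log 0 = 0`.
#'
#' @param p numeric vector of non-negative probabilities summing to 1
#'   (within 1e-9).
#' @param base logarithm base, a real number greater than 1; defaults to
#'   `exp(1)` (nats).
#' @return The entropy in the requested base.
#' @examples
#' shannonEntropy(rep(1/4, 4), base = 2)  # 2 bits
#' shannonEntropy(rep(1/6, 6))            # log(6) nats
#' @export
shannonEntropy <- function(p, base = exp(1)) {
  if (!is.numeric(p) || length(p) == 0L)
    stop("p must be a non-empty numeric vector")
  if (any(p < 0))
    stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")")
  if (!is.numeric(base) || length(base) != 1L || base <= 1)
    stop("base must be a single number > 1")
  pz <- p[p > 0]
  -sum(pz * log(pz)) / log(base)
}

# shared core: contributions per class + counts -> EntropyValue
.entropyCore <- function(spec, dLo, dHi, count) {
  j <- edgeContribution(spec, dLo, dHi)
  if (any(j <= 0))
    stop("entropy undefined for non-positive contributions (descriptor ",
         spec@name, " on pair (", dLo[which(j <= 0)[1L]], ",",
         dHi[which(j <= 0)[1L]], "))")
  D <- sum(count * j)
  if (D <= 0)
    stop("entropy undefined for non-positive contributions (index total is ",
         D, ")")
  value <- log(D) - sum(count * j * log(j)) / D
  m <- sum(count)
  # clamp roundoff at the boundaries of [0, log |E|]
  value <- min(max(value, 0), log(m))
  new("EntropyValue", value = value, descriptor = spec,
      indexTotal = D, nEdges = m)
}

#' Index-weighted Shannon entropy of an edge partition
#'
#' Computes `ENT_D = log D - (1/D) sum_e j_e log j_e` in natural log, where
#' `j_e` is the per-edge contribution of the descriptor and `D` the index
#' total.  Treating each edge as one outcome with probability `j_e / D`,
#' this is exactly the Shannon entropy of the normalised contribution
#' distribution, so the value lies in `[0, log |E|]` with the maximum
#' attained iff all contributions are equal (edge-regular partitions).
#'
#' The natural logarithm is used throughout: it is the only base that
#' reproduces the published entropy tables of the fractal families handled
#' by [familyEntropyTable()].
#'
#' @param partition an [EdgePartition-class].
#' @param spec a [DescriptorSpec-class] or descriptor name.
#' @param alpha exponent for parametric descriptors given by name.
#' @return An [EntropyValue-class].
#' @examples
#' entropyFromPartition(kekulenePartition(1), "M1")  # 4.0876 nats
#' @export
entropyFromPartition <- function(partition, spec, alpha = NULL) {
  stopifnot(is(partition, "EdgePartition"))
  validObject(partition)
  spec <- .asSpec(spec, alpha)
  .entropyCore(spec, partition@dLo, partition@dHi, partition@count)
}

#' Index-weighted Shannon entropy of a molecular graph
#'
#' Equals `entropyFromPartition(edgePartition(graph), spec)`.
#'
#' @param graph an undirected simple `igraph` with at least one edge.
#' @inheritParams entropyFromPartition
#' @return An [EntropyValue-class].
#' @examples
#' entropyValue(entropyFromGraph(igraph::make_ring(6), "M2"))  # log(6)
#' @export
entropyFromGraph <- function(graph, spec, alpha = NULL) {
  graph <- asMolecularGraph(graph)
  spec <- .asSpec(spec, alpha)
  if (igraph::ecount(graph) == 0L)
    stop("graph has no edges; entropy undefined")
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  deg <- igraph::degree(graph)
  .entropyCore(spec, deg[ends[, 1L]], deg[ends[, 2L]],
               rep(1, nrow(ends)))
}
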