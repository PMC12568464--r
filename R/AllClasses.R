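#' @import methods
#' @importFrom stats setNames
NULL

#' Degree-pair edge partition of a molecular graph
#'
#' An `EdgePartition` records, for each unordered pair of endpoint degrees
#' `(d_lo, d_hi)`, how many edges of a simple undirected graph join a vertex
#' of degree `d_lo` to a vertex of degree `d_hi`.  Every degree-based
#' topological index, and every entropy built on one, is a function of this
#' partition alone, so it is the central data structure of the package.
#'
#' @slot dLo integer vector of smaller endpoint degrees (canonical order,
#'   `dLo <= dHi`).
#' @slot dHi integer vector of larger endpoint degrees.
#' @slot count numeric vector of non-negative integral edge counts (stored as
#'   doubles so that the exponentially growing counts of fractal families
#'   remain exact well beyond `.Machine$integer.max`).
#'
#' @seealso [edgePartition()] to extract one from a graph,
#'   [kekulenePartition()] and [sierpinskiPartition()] for the fractal family
#'   models, [partitionRealizability()] and [realizePartition()].
#' @export
setClass("EdgePartition",
  representation(dLo = "integer", dHi = "integer", count = "numeric"),
  validity = function(object) {
    msgs <- character()
    n <- length(object@dLo)
    if (length(object@dHi) != n || length(object@count) != n)
      msgs <- c(msgs, "dLo, dHi and count must have equal length")
    if (n == 0L)
      msgs <- c(msgs, "partition must contain at least one degree-pair class")
    if (n > 0L) {
      if (any(object@dLo < 1L) || any(object@dHi < 1L))
        msgs <- c(msgs, "degrees must be positive integers")
      if (any(object@dLo > object@dHi))
        msgs <- c(msgs, "degree pairs must be stored with dLo <= dHi")
      if (any(object@count < 0) || any(object@count != round(object@count)))
        msgs <- c(msgs, "counts must be non-negative integers")
      key <- paste(object@dLo, object@dHi, sep = ",")
      if (anyDuplicated(key))
        msgs <- c(msgs, "duplicate degree-pair classes")
    }
    if (length(msgs)) msgs else TRUE
  })

#' Construct an edge partition
#'
#' Degree pairs are canonicalised (so `(3,2)` and `(2,3)` are the same class)
#' and counts of coinciding classes are merged by summation.  Classes with a
#' zero count are dropped.
#'
#' @param dLo,dHi integer vectors of endpoint degrees, one entry per class.
#' @param count numeric vector of edge counts per class.
#' @return An [EdgePartition-class] object.
#' @examples
#' EdgePartition(c(2, 2, 3), c(2, 3, 3), c(6, 36, 18))  # kekulene, n = 1
#' @export
EdgePartition <- function(dLo, dHi, count) {
  if (length(dLo) != length(dHi) || length(dLo) != length(count))
    stop("dLo, dHi and count must have equal length")
  lo <- pmin(dLo, dHi)
  hi <- pmax(dLo, dHi)
  keep <- count != 0
  lo <- lo[keep]; hi <- hi[keep]; count <- count[keep]
  key <- paste(lo, hi, sep = ",")
  if (anyDuplicated(key)) {
    agg <- rowsum(count, key)
    key <- rownames(agg)
    count <- as.numeric(agg[, 1L])
    parts <- do.call(rbind, strsplit(key, ",", fixed = TRUE))
    lo <- as.numeric(parts[, 1L]); hi <- as.numeric(parts[, 2L])
  }
  o <- order(lo, hi)
  new("EdgePartition", dLo = as.integer(lo[o]), dHi = as.integer(hi[o]),
      count = as.numeric(count[o]))
}

#' @describeIn EdgePartition-class matrix of canonical degree pairs, one row
#'   per class, columns `dLo` and `dHi`.
#' @param x an `EdgePartition`.
#' @export
degreePairs <- function(x) {
  stopifnot(is(x, "EdgePartition"))
  cbind(dLo = x@dLo, dHi = x@dHi)
}

#' @describeIn EdgePartition-class named numeric vector of edge counts; names
#'   are `"dLo,dHi"` keys.
#' @export
edgeCounts <- function(x) {
  stopifnot(is(x, "EdgePartition"))
  setNames(x@count, paste(x@dLo, x@dHi, sep = ","))
}

#' @describeIn EdgePartition-class total number of edges (sum of counts).
#' @export
nEdges <- function(x) {
  stopifnot(is(x, "EdgePartition"))
  sum(x@count)
}

setMethod("show", "EdgePartition", function(object) {
  cat("EdgePartition with", length(object@dLo), "degree-pair classes,",
      format(sum(object@count), big.mark = ","), "edges\n")
  df <- data.frame(pair = paste0("(", object@dLo, ",", object@dHi, ")"),
                   count = object@count)
  print(df, row.names = FALSE)
  invisible(NULL)
})

.DESCRIPTOR_NAMES <- c("M1", "M2", "Ralpha", "R", "HM", "SCI", "CHIalpha",
                       "GA", "ABC", "H")
.PARAMETRIC <- c("Ralpha", "CHIalpha")

#' Specification of a degree-based topological index
#'
#' Identifies one of the ten supported edge-additive indices, together with
#' the exponent `alpha` for the two parametric families (general Randic
#' `Ralpha` and general sum-connectivity `CHIalpha`).  `alpha` has no
#' default: the literature uses different conventions and a silent default
#' would be misleading.
#'
#' @slot name one of `"M1"`, `"M2"`, `"Ralpha"`, `"R"`, `"HM"`, `"SCI"`,
#'   `"CHIalpha"`, `"GA"`, `"ABC"`, `"H"`.
#' @slot alpha numeric exponent; `NA` for non-parametric indices.
#' @seealso [descriptorNames()], [edgeContribution()], [indexFromPartition()]
#' @export
setClass("DescriptorSpec",
  representation(name = "character", alpha = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (length(object@name) != 1L || !(object@name %in% .DESCRIPTOR_NAMES))
      msgs <- c(msgs, paste("name must be one of:",
                            paste(.DESCRIPTOR_NAMES, collapse = ", ")))
    else if (object@name %in% .PARAMETRIC) {
      if (length(object@alpha) != 1L || !is.finite(object@alpha))
        msgs <- c(msgs, paste0("descriptor ", object@name,
                               " requires a finite alpha"))
    } else if (length(object@alpha) != 1L || !is.na(object@alpha))
      msgs <- c(msgs, paste0("descriptor ", object@name,
                             " does not take an alpha"))
    if (length(msgs)) msgs else TRUE
  })

#' Create a descriptor specification
#'
#' @param name descriptor name (case-insensitive); see
#'   [DescriptorSpec-class].
#' @param alpha exponent, required for `Ralpha` and `CHIalpha`, forbidden
#'   otherwise.
#' @return A [DescriptorSpec-class] object.
#' @examples
#' descriptorSpec("GA")
#' descriptorSpec("Ralpha", alpha = -1/2)
#' @export
descriptorSpec <- function(name, alpha = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  i <- match(tolower(name), tolower(.DESCRIPTOR_NAMES))
  if (is.na(i))
    stop("unknown descriptor '", name, "'; valid names: ",
         paste(.DESCRIPTOR_NAMES, collapse = ", "))
  canon <- .DESCRIPTOR_NAMES[i]
  if (canon %in% .PARAMETRIC) {
    if (is.null(alpha))
      stop("descriptor ", canon, " requires an explicit alpha")
    new("DescriptorSpec", name = canon, alpha = as.numeric(alpha))
  } else {
    if (!is.null(alpha))
      stop("descriptor ", canon, " does not take an alpha")
    new("DescriptorSpec", name = canon, alpha = NA_real_)
  }
}

#' Names of the supported descriptors
#'
#' @return Character vector of the ten descriptor names, in conventional
#'   table order.
#' @export
descriptorNames <- function() .DESCRIPTOR_NAMES

setMethod("show", "DescriptorSpec", function(object) {
  if (object@name %in% .PARAMETRIC)
    cat("DescriptorSpec:", object@name, "(alpha =", object@alpha, ")\n")
  else
    cat("DescriptorSpec:", object@name, "\n")
  invisible(NULL)
})

# coerce character or spec to DescriptorSpec
.asSpec <- function(spec, alpha = NULL) {
  if (is(spec, "DescriptorSpec")) {
    if (!is.null(alpha))
      stop("alpha must be given inside the DescriptorSpec, not separately")
    return(spec)
  }
  descriptorSpec(spec, alpha)
}

#' Entropy of an index's edge-contribution distribution
#'
#' Result container for the index-weighted Shannon entropy
#' `ENT_D = log D - (1/D) * sum_e j_e log j_e` (natural log), where `j_e` is
#' the per-edge contribution of the chosen descriptor and `D` their total
#' (the index value).  The value always lies in `[0, log |E|]`.
#'
#' @slot value entropy in nats.
#' @slot descriptor the [DescriptorSpec-class] used.
#' @slot indexTotal the normalising index value `D`.
#' @slot nEdges number of edges of the underlying graph or partition.
#' @seealso [entropyFromPartition()], [entropyFromGraph()]
#' @export
setClass("EntropyValue",
  representation(value = "numeric", descriptor = "DescriptorSpec",
                 indexTotal = "numeric", nEdges = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (length(object@value) != 1L || !is.finite(object@value))
      msgs <- c(msgs, "value must be a single finite number")
    else if (object@value < -1e-9 ||
             object@value > log(object@nEdges) + 1e-9)
      msgs <- c(msgs, "entropy must lie within [0, log nEdges]")
    if (length(msgs)) msgs else TRUE
  })

#' @describeIn EntropyValue-class the entropy in nats, as a plain number.
#' @param x an `EntropyValue`.
#' @export
entropyValue <- function(x) {
  stopifnot(is(x, "EntropyValue"))
  x@value
}

#' @describeIn EntropyValue-class the index total `D` used for
#'   normalisation.
#' @export
indexTotal <- function(x) {
  stopifnot(is(x, "EntropyValue"))
  x@indexTotal
}

setMethod("show", "EntropyValue", function(object) {
  nm <- object@descriptor@name
  if (nm %in% .PARAMETRIC)
    nm <- sprintf("%s(alpha=%g)", nm, object@descriptor@alpha)
  cat(sprintf("ENT_%s = %.6f nats  (index total D = %g, |E| = %g)\n",
              nm, object@value, object@indexTotal, object@nEdges))
  invisible(NULL)
})

#' Consistency report between closed forms and partition sums
#'
#' Produced by [verifyClosedForms()].  The `comparisons` slot holds one row
#' per (descriptor, n) with the closed-form value, the partition sum, their
#' difference and the provenance of the closed form; `notes` carries
#' additional recorded observations (for the Sierpinski family, the exact
#' coefficients of the hyper-Zagreb entropy numerator polynomial).
#'
#' @slot family `"KE"` or `"SE"`.
#' @slot nRange integers over which the comparison ran.
#' @slot comparisons data.frame of per-cell comparisons.
#' @slot notes list of recorded observations.
#' @export
setClass("ConsistencyReport",
  representation(family = "character", nRange = "integer",
                 comparisons = "data.frame", notes = "list"),
  validity = function(object) {
    msgs <- character()
    if (!(object@family %in% c("KE", "SE")))
      msgs <- c(msgs, "family must be 'KE' or 'SE'")
    need <- c("descriptor", "alpha", "n", "closedForm", "partitionSum",
              "relDiff", "source", "flagged")
    if (!all(need %in% names(object@comparisons)))
      msgs <- c(msgs, "comparisons is missing required columns")
    else if (anyDuplicated(object@comparisons[c("descriptor", "alpha", "n")]))
      msgs <- c(msgs, "each (descriptor, n) cell must appear exactly once")
    if (length(msgs)) msgs else TRUE
  })

#' @describeIn ConsistencyReport-class rows of the comparison table whose
#'   closed form disagrees with the partition sum.
#' @param x a `ConsistencyReport`.
#' @export
flaggedMismatches <- function(x) {
  stopifnot(is(x, "ConsistencyReport"))
  x@comparisons[x@comparisons$flagged, , drop = FALSE]
}

#' @describeIn ConsistencyReport-class the full comparison table.
#' @export
comparisonTable <- function(x) {
  stopifnot(is(x, "ConsistencyReport"))
  x@comparisons
}

#' @describeIn ConsistencyReport-class recorded observations (list).
#' @export
reportNotes <- function(x) {
  stopifnot(is(x, "ConsistencyReport"))
  x@notes
}

setMethod("show", "ConsistencyReport", function(object) {
  bad <- flaggedMismatches(object)
  cat(sprintf("ConsistencyReport for %s, n = %d..%d: %d comparisons, %d flagged\n",
              object@family, min(object@nRange), max(object@nRange),
              nrow(object@comparisons), nrow(bad)))
  if (nrow(bad)) {
    cat("Flagged (closed form vs partition sum):\n")
    print(bad[c("descriptor", "n", "closedForm", "partitionSum")],
          row.names = FALSE)
  }
  if (length(object@notes))
    cat("Notes:", paste(names(object@notes), collapse = ", "), "\n")
  invisible(NULL)
})
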