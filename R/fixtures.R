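# run expr with a private, seeded RNG stream; global state untouched
.withSeed <- function(seed, expr) {
  if (length(seed) != 1L || !is.numeric(seed) || seed != round(seed))
    stop("seed must be a single integer")
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Construct the kekulene C48 skeleton
#'
#' Builds the hydrogen-suppressed molecular graph of kekulene explicitly:
#' twelve benzene rings fused into a macrocycle, i.e. an outer rim of 30
#' carbons, an inner rim of 18 carbons, and 12 fusion bonds ("spokes")
#' between them.  Consecutive spokes cut off hexagons that alternate between
#' (1 inner + 3 outer) and (2 inner + 2 outer) rim bonds.  The result has 48
#' vertices (24 of degree 2, 24 of degree 3), 60 edges, and edge partition
#' `{(2,2): 6, (2,3): 36, (3,3): 18}` -- the stage-1 member of the kekulene
#' family model ([kekulenePartition()]).
#'
#' This graph is the package's single graph-level ground truth for the
#' family partition models: every partition-level index and entropy can be
#' checked against direct edge enumeration on it.
#'
#' @return An undirected simple `igraph` with vertex names `o1..o30`
#'   (outer rim) and `i1..i18` (inner rim).
#' @examples
#' ke <- buildKekulene()
#' igraph::vcount(ke)  # 48
#' edgeCounts(edgePartition(ke))
#' @export
buildKekulene <- function() {
  outer_v <- paste0("o", 1:30)
  inner_v <- paste0("i", 1:18)
  ring <- function(v) cbind(v, c(v[-1L], v[1L]))
  # spoke attachment points: inner gaps alternate 1,2; outer gaps 3,2
  ipos <- cumsum(c(1, rep(c(1, 2), 6)))[1:12]          # 1,2,4,5,...,17
  opos <- cumsum(c(1, rep(c(3, 2), 6)))[1:12]          # 1,4,6,9,...,29
  spokes <- cbind(inner_v[ipos], outer_v[opos])
  el <- rbind(ring(outer_v), ring(inner_v), spokes)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  asMolecularGraph(g)
}

#' Realize a simple graph from a feasible edge partition
#'
#' Constructs a simple undirected graph whose degree-pair edge partition
#' equals `partition` (a joint-degree-matrix realization).  The forced
#' number of vertices of each degree is created, stubs are paired class by
#' class, and any self-loops or parallel edges are repaired by
#' degree-preserving double-edge swaps *within the same degree-pair class*,
#' so the partition is preserved exactly.  Chemical plausibility (planarity,
#' ring sizes) is not attempted: every degree-based index and entropy
#' depends on the partition alone, so this is the minimal sufficient test
#' object.
#'
#' @param partition an [EdgePartition-class] passing
#'   [partitionRealizability()].
#' @param seed integer seed; identical seeds give identical graphs.
#' @param swapBudget maximum number of repair swaps before giving up.
#' @return A list with components `graph` (the realization), `attempts`
#'   (number of repair swaps used) and `achievedPartition` (re-extracted
#'   from the graph; always equal to the request).
#' @examples
#' r <- realizePartition(EdgePartition(2, 2, 6), seed = 1)
#' igraph::vcount(r$graph)  # 6: the 6-cycle
#' @export
realizePartition <- function(partition, seed = 1L, swapBudget = 1e5) {
  stopifnot(is(partition, "EdgePartition"))
  feas <- partitionRealizability(partition)
  if (!feas$feasible)
    stop("partition is not realizable: ", feas$reason)
  .withSeed(seed, {
    vpd <- feas$verticesPerDegree
    vert <- lapply(names(vpd), function(d)
      paste0("d", d, "_", seq_len(vpd[[d]])))
    names(vert) <- names(vpd)
    attempts <- 0L
    nRestarts <- 50L
    budget <- max(1, ceiling(swapBudget / nRestarts))
    for (restart in seq_len(nRestarts)) {
      # fresh shuffled stub pool per degree class
      pool <- lapply(names(vpd), function(d)
        sample(rep(vert[[d]], each = as.integer(d))))
      names(pool) <- names(vpd)
      take <- function(d, k) {
        d <- as.character(d)
        out <- pool[[d]][seq_len(k)]
        pool[[d]] <<- pool[[d]][-seq_len(k)]
        out
      }
      u <- character(0); v <- character(0); cls <- integer(0)
      for (i in seq_along(partition@count)) {
        m <- partition@count[i]
        if (m == 0) next
        a <- partition@dLo[i]; b <- partition@dHi[i]
        if (a == b) {
          s <- take(a, 2 * m)
          u <- c(u, s[seq(1, 2 * m, by = 2)])
          v <- c(v, s[seq(2, 2 * m, by = 2)])
        } else {
          u <- c(u, take(a, m))
          v <- c(v, take(b, m))
        }
        cls <- c(cls, rep(i, m))
      }
      violations <- function() {
        key <- paste(pmin(u, v), pmax(u, v))
        which(u == v | duplicated(key) | duplicated(key, fromLast = TRUE))
      }
      used <- 0L
      stuck <- FALSE
      repeat {
        bad <- violations()
        if (!length(bad)) {
          g <- igraph::graph_from_edgelist(cbind(u, v), directed = FALSE)
          achieved <- edgePartition(g)
          if (!identical(edgeCounts(achieved), edgeCounts(partition)))
            stop("internal error: realized partition does not match request")
          return(list(graph = g, attempts = attempts + used,
                      achievedPartition = achieved))
        }
        if (used >= budget) break
        e1 <- bad[sample.int(length(bad), 1L)]
        peers <- which(cls == cls[e1])
        peers <- peers[peers != e1]
        if (!length(peers)) { stuck <- TRUE; break }  # reshuffle from scratch
        e2 <- peers[sample.int(length(peers), 1L)]
        tmp <- v[e1]; v[e1] <- v[e2]; v[e2] <- tmp
        used <- used + 1L
      }
      attempts <- attempts + used + as.integer(stuck)
    }
    stop("realization not found within swap budget (", attempts,
         " attempts over ", nRestarts, " restarts)")
  })
}

#' Random feasible edge partition
#'
#' Generates a random degree-pair partition that is guaranteed to be
#' realizable as a simple graph, by sampling a bounded-degree random simple
#' graph and extracting its partition (so a witness realization always
#' exists).  Used for property testing.
#'
#' @param seed integer seed; identical seeds give identical partitions.
#' @param maxDegree largest vertex degree to allow.
#' @param maxClasses largest number of degree-pair classes to accept.
#' @param maxCount largest per-class edge count to accept.
#' @return An [EdgePartition-class] passing [partitionRealizability()].
#' @examples
#' p <- randomPartition(7)
#' partitionRealizability(p)$feasible  # TRUE
#' @export
randomPartition <- function(seed, maxDegree = 4L, maxClasses = 6L,
                            maxCount = 40L) {
  stopifnot(maxDegree >= 1, maxClasses >= 1, maxCount >= 1)
  .withSeed(seed, {
    for (try in 1:500) {
      nv <- sample(4:14, 1L)
      degs <- sample.int(maxDegree, nv, replace = TRUE)
      if (sum(degs) %% 2 == 1) {
        i <- which(degs < maxDegree)
        if (!length(i)) next
        degs[i[1L]] <- degs[i[1L]] + 1L
      }
      if (!igraph::is_graphical(degs)) next
      g <- tryCatch(
        igraph::sample_degseq(degs, method = "fast.heur.simple"),
        error = function(e) NULL)
      if (is.null(g)) next
      p <- edgePartition(g)
      if (length(p@count) <= maxClasses && max(p@count) <= maxCount)
        return(p)
    }
    stop("could not generate a feasible random partition within bounds")
  })
}
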