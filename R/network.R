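## Markov Clustering and permutation-based interaction enrichment on the
## weighted gene-interaction graph.

## Run expr with a locally-seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Markov Clustering of a weighted interaction graph
#'
#' Implements the Markov Cluster algorithm: the edge confidences (plus unit
#' self-loops) are column-normalised into a stochastic flow matrix, which is
#' alternately \emph{expanded} (raised to the matrix power
#' \code{expansion}, simulating longer random walks) and \emph{inflated}
#' (raised elementwise to \code{inflation} and re-normalised, strengthening
#' strong flows) until the largest column-wise change falls below
#' \code{tol} or \code{maxIter} is reached. Clusters are read off as the
#' weakly connected components of the non-zero structure of the limit
#' matrix. The procedure is fully deterministic; disjoint graph components
#' can never be merged because expansion preserves block structure.
#'
#' @param graph an \code{\link{InteractionGraph}} (non-empty).
#' @param inflation inflation exponent, > 1 (default 2.0; larger values give
#'   finer clusters).
#' @param expansion matrix-power exponent, integer >= 2 (default 2).
#' @param maxIter iteration cap (default 100).
#' @param tol convergence tolerance on the max absolute entry change
#'   (default 1e-6).
#' @return a \code{\link{ClusterPartition}}; \code{converged(x)} is FALSE
#'   when the cap was hit.
#' @examples
#' g <- InteractionGraph(data.frame(
#'   from = c("A", "B", "C", "D", "E", "F"),
#'   to   = c("B", "C", "A", "E", "F", "D"),
#'   confidence = 0.9))
#' nClusters(mcl(g))  # two disjoint triangles -> 2
#' @export
mcl <- function(graph, inflation = 2.0, expansion = 2L, maxIter = 100L,
                tol = 1e-6) {
  stopifnot(is(graph, "InteractionGraph"))
  if (inflation <= 1) stop("inflation must be > 1")
  if (expansion < 2) stop("expansion must be >= 2")
  g <- asIgraph(graph)
  nv <- igraph::vcount(g)
  if (nv == 0L) stop("graph is empty")
  nodes <- igraph::V(g)$name
  A <- matrix(0, nv, nv, dimnames = list(nodes, nodes))
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    conf <- igraph::E(g)$confidence
    A[cbind(el[, 1], el[, 2])] <- conf
    A[cbind(el[, 2], el[, 1])] <- conf
  }
  diag(A) <- 1                              # unit self-loops
  M <- sweep(A, 2, colSums(A), "/")
  iter <- 0L
  convergedFlag <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf <- sweep(Minf, 2, colSums(Minf), "/")
    change <- max(abs(Minf - M))
    M <- Minf
    if (change < tol) { convergedFlag <- TRUE; break }
  }
  ## attractor structure: non-zero entries of the limit matrix
  B <- (M > 1e-8) | t(M > 1e-8)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    B, mode = "undirected", diag = FALSE))$membership
  ## renumber clusters by first node appearance for a deterministic labelling
  relabel <- stats::setNames(seq_along(unique(comp)), unique(comp))
  membership <- as.integer(relabel[as.character(comp)])
  names(membership) <- nodes
  new("ClusterPartition", membership = membership,
      nClusters = length(unique(membership)), inflation = inflation,
      iterationsRun = iter, converged = convergedFlag)
}

#' Per-patient deleterious-gene subnetwork
#'
#' Induced subgraph on a patient's deleterious-variant genes at a given
#' confidence tier. Edges below \code{minConfidence} are dropped; genes with
#' no retained edge (including genes absent from the background network)
#' are kept as singletons.
#'
#' @param graph the background \code{\link{InteractionGraph}}.
#' @param genes character vector of the patient's deleterious-variant gene
#'   symbols (an empty set gives an empty graph).
#' @param minConfidence minimum edge confidence in [0, 1]; the conventional
#'   tiers are 0.15 (low), 0.4 (medium), 0.7 (high) and 0.9 (highest).
#' @return an \code{\link{InteractionGraph}} on exactly \code{genes}.
#' @export
patientSubnetwork <- function(graph, genes, minConfidence = 0.4) {
  stopifnot(is(graph, "InteractionGraph"))
  if (minConfidence < 0 || minConfidence > 1)
    stop("minConfidence must lie in [0, 1]")
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) return(InteractionGraph(NULL))
  et <- edgeTable(graph)
  keep <- et$from %in% genes & et$to %in% genes &
    et$confidence >= minConfidence
  InteractionGraph(et[keep, , drop = FALSE], nodes = genes)
}

## Degree-preserving null: randomise the whole graph by double-edge swaps
## (10 attempted swaps per edge), keeping every vertex degree exactly.
.degreePreservingNull <- function(g, swapsPerEdge = 10) {
  igraph::rewire(g, igraph::keeping_degseq(
    niter = max(1, swapsPerEdge * igraph::ecount(g))))
}

.edgesWithin <- function(g, idx) {
  sub <- igraph::induced_subgraph(g, idx)
  igraph::ecount(sub)
}

#' Permutation test for interaction enrichment of a gene set
#'
#' Tests whether a gene set carries more interactions among its members than
#' expected for genes of the same connectivity: the observed within-set edge
#' count is compared with its distribution over degree-preserving
#' randomisations of the whole graph (double-edge swaps, 10 attempted swaps
#' per edge per permutation). The p-value uses the add-one convention,
#' \code{p = (1 + #\{null >= observed\}) / (1 + nPermutations)}, and is
#' therefore bounded below by \code{1/(nPermutations + 1)}. Results are
#' reproducible for a fixed seed; the caller's RNG state is untouched.
#'
#' @param graph an \code{\link{InteractionGraph}}.
#' @param nodeSet character vector of at least 2 gene symbols, all present
#'   in the graph.
#' @param nPermutations number of permutations, >= 100 (default 1000).
#' @param seed integer RNG seed (mandatory, recorded in the result).
#' @return an \code{\link{EnrichmentResult}}.
#' @export
interactionEnrichment <- function(graph, nodeSet, nPermutations = 1000L,
                                  seed) {
  stopifnot(is(graph, "InteractionGraph"))
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  nodeSet <- unique(as.character(nodeSet))
  if (length(nodeSet) < 2L)
    stop("domain error: nodeSet must contain at least 2 genes")
  if (nPermutations < 100L) stop("nPermutations must be >= 100")
  g <- asIgraph(graph)
  missingNodes <- setdiff(nodeSet, igraph::V(g)$name)
  if (length(missingNodes))
    stop("nodeSet gene(s) not in graph: ",
         paste(missingNodes, collapse = ", "))
  observed <- .edgesWithin(g, nodeSet)
  nullCounts <- .withSeed(seed, {
    vapply(seq_len(nPermutations), function(b) {
      .edgesWithin(.degreePreservingNull(g), nodeSet)
    }, numeric(1))
  })
  p <- (1 + sum(nullCounts >= observed)) / (1 + nPermutations)
  new("EnrichmentResult", nodeSet = nodeSet,
      observedEdges = as.integer(observed),
      nullMean = mean(nullCounts), pValue = p,
      nPermutations = as.integer(nPermutations), seed = as.integer(seed))
}
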