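#' @rdname accessors
#' @aliases variantData,VariantTable-method
setMethod("variantData", "VariantTable", function(x) x@data)

#' @rdname accessors
setMethod("nVariants", "VariantTable", function(x) nrow(x@data))

#' @rdname accessors
setMethod("patientIds", "VariantTable",
          function(x) unique(x@data$patient_id))

#' @rdname accessors
setMethod("patientIds", "Cohort", function(x) x@patients$patient_id)

#' @rdname accessors
setMethod("nPatients", "Cohort", function(x) nrow(x@patients))

#' @rdname accessors
setMethod("autosomalAlleleNumber", "Cohort",
          function(x) 2L * nrow(x@patients))

#' @rdname accessors
setMethod("xAlleleNumber", "Cohort", function(x) {
  2L * sum(x@patients$sex == "female") + sum(x@patients$sex == "male")
})

#' @rdname accessors
setMethod("patientSexes", "Cohort", function(x) {
  stats::setNames(x@patients$sex, x@patients$patient_id)
})

#' @rdname accessors
setMethod("panelName", "GenePanel", function(x) x@name)

#' @rdname accessors
setMethod("panelGenes", "GenePanel", function(x) x@genes)

#' @rdname accessors
setMethod("asIgraph", "InteractionGraph", function(x) x@graph)

#' @rdname accessors
setMethod("graphNodes", "InteractionGraph",
          function(x) igraph::V(x@graph)$name)

#' @rdname accessors
setMethod("edgeTable", "InteractionGraph", function(x) {
  g <- x@graph
  if (igraph::ecount(g) == 0L)
    return(data.frame(from = character(), to = character(),
                      confidence = numeric(), stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(g)
  df <- data.frame(from = pmin(el[, 1], el[, 2]),
                   to = pmax(el[, 1], el[, 2]),
                   confidence = igraph::E(g)$confidence,
                   stringsAsFactors = FALSE)
  df[order(df$from, df$to), , drop = FALSE]
})

#' @rdname accessors
setMethod("clusterMembership", "ClusterPartition", function(x) x@membership)

#' @rdname accessors
setMethod("nClusters", "ClusterPartition", function(x) x@nClusters)

#' @rdname accessors
setMethod("converged", "ClusterPartition", function(x) x@converged)

#' @rdname accessors
setMethod("pValue", "EnrichmentResult", function(x) x@pValue)

#' @rdname accessors
setMethod("observedEdges", "EnrichmentResult", function(x) x@observedEdges)

#' @rdname accessors
setMethod("pointProb", "AggregationResult", function(x) x@pointProb)

#' @rdname accessors
setMethod("tailProb", "AggregationResult", function(x) x@tailProb)

#' Coerce an AggregationResult to a one-row data.frame
#'
#' @param x an \code{AggregationResult}.
#' @param row.names,optional,... ignored; present for generic consistency.
#' @return a one-row data.frame with the report columns.
#' @export
as.data.frame.AggregationResult <-
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(gene = x@gene, nt_change = x@ntChange, k = x@k, n = x@n,
               p_ref = x@pRef, freq_scope = x@freqScope,
               point_prob = x@pointProb, tail_prob = x@tailProb,
               mode_used = x@modeUsed, computable = x@computable,
               note = x@note, stringsAsFactors = FALSE)
  }

setMethod("show", "VariantTable", function(object) {
  d <- object@data
  cat("VariantTable with", nrow(d), "observation(s):",
      length(unique(d$patient_id)), "patient(s),",
      length(unique(d$gene)), "gene(s)\n")
  if (nrow(d)) {
    cat("  consequences:",
        paste(sprintf("%s=%d", names(table(d$consequence)),
                      table(d$consequence)), collapse = ", "), "\n")
    cat("  panels:",
        paste(unique(d$panel), collapse = ", "), "\n")
  }
})

setMethod("show", "Cohort", function(object) {
  s <- table(object@patients$sex)
  cat("Cohort of", nrow(object@patients), "patient(s) (",
      sum(object@patients$sex == "male"), "male,",
      sum(object@patients$sex == "female"), "female )\n")
  cat("  autosomal allele number:", autosomalAlleleNumber(object),
      "| X allele number:", xAlleleNumber(object), "\n")
})

setMethod("show", "GenePanel", function(object) {
  cat("GenePanel '", object@name, "': ", length(object@genes),
      " gene(s)\n", sep = "")
})

setMethod("show", "InteractionGraph", function(object) {
  g <- object@graph
  cat("InteractionGraph:", igraph::vcount(g), "node(s),",
      igraph::ecount(g), "edge(s)\n")
  if (igraph::ecount(g))
    cat("  confidence range: [",
        min(igraph::E(g)$confidence), ",",
        max(igraph::E(g)$confidence), "]\n")
})

setMethod("show", "ClusterPartition", function(object) {
  cat("ClusterPartition:", length(object@membership), "node(s) in",
      object@nClusters, "cluster(s); inflation", object@inflation,
      ";", object@iterationsRun, "iteration(s);",
      if (object@converged) "converged" else "NOT converged", "\n")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult:", length(object@nodeSet), "node(s),",
      object@observedEdges, "observed edge(s), null mean",
      format(object@nullMean, digits = 4), "\n")
  cat("  p =", format(object@pValue, digits = 4), "(",
      object@nPermutations, "permutations, seed", object@seed, ")\n")
})

setMethod("show", "AggregationResult", function(object) {
  cat("AggregationResult for", object@gene, object@ntChange, "\n")
  if (object@computable) {
    cat("  k =", object@k, "of n =", object@n, "alleles; p_ref =",
        object@pRef, "(", object@freqScope, ")\n")
    cat("  point probability P(X = k) =",
        format(object@pointProb, digits = 6),
        "| upper tail P(X >= k) =", format(object@tailProb, digits = 6),
        "| mode:", object@modeUsed, "\n")
  } else {
    cat("  not computable:", object@note, "\n")
  }
})
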