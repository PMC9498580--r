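#' @name accessors
#' @title Accessors for VariantTriage classes
#'
#' @description Small accessor layer over the S4 containers: slot access from
#' user code should go through these.
#'
#' @param x an object of the documented class.
#' @return see the individual accessor.
NULL

#' @describeIn accessors the underlying variant data.frame (one row per
#'   patient x variant observation).
#' @export
setGeneric("variantData", function(x) standardGeneric("variantData"))

#' @describeIn accessors number of variant observations.
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @describeIn accessors patient identifiers.
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @describeIn accessors number of patients in a cohort.
#' @export
setGeneric("nPatients", function(x) standardGeneric("nPatients"))

#' @describeIn accessors cohort allele number for autosomal variants
#'   (2 per patient).
#' @export
setGeneric("autosomalAlleleNumber",
           function(x) standardGeneric("autosomalAlleleNumber"))

#' @describeIn accessors cohort allele number for X-linked variants
#'   (2 per female + 1 per male).
#' @export
setGeneric("xAlleleNumber", function(x) standardGeneric("xAlleleNumber"))

#' @describeIn accessors named vector of patient sexes.
#' @export
setGeneric("patientSexes", function(x) standardGeneric("patientSexes"))

#' @describeIn accessors panel name.
#' @export
setGeneric("panelName", function(x) standardGeneric("panelName"))

#' @describeIn accessors gene symbols of a panel.
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' @describeIn accessors the wrapped \pkg{igraph} object.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @describeIn accessors vertex names of an interaction graph.
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @describeIn accessors edge table (from, to, confidence) of an interaction
#'   graph, in canonical (sorted) order.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @describeIn accessors named node-to-cluster assignment.
#' @export
setGeneric("clusterMembership",
           function(x) standardGeneric("clusterMembership"))

#' @describeIn accessors number of clusters in a partition.
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @describeIn accessors whether the MCL iteration converged.
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @describeIn accessors permutation p-value of an enrichment result.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @describeIn accessors observed within-set edge count.
#' @export
setGeneric("observedEdges", function(x) standardGeneric("observedEdges"))

#' @describeIn accessors binomial point probability P(X = k).
#' @export
setGeneric("pointProb", function(x) standardGeneric("pointProb"))

#' @describeIn accessors binomial upper-tail probability P(X >= k).
#' @export
setGeneric("tailProb", function(x) standardGeneric("tailProb"))
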