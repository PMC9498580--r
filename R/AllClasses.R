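## Controlled vocabularies shared by the readers, validity methods and the
## synthetic generator. Kept internal; the vocabularies themselves are part of
## the file-format contract documented in ?readVariantTable.
.vocab <- list(
  consequence      = c("missense", "nonsense", "frameshift", "splice",
                       "inframe_indel"),
  freq_scope       = c("latino", "global"),
  zygosity         = c("het", "hom", "hemi"),
  chromosome_class = c("autosomal", "X"),
  inheritance      = c("AD", "AR", "XL", "XLD", "NR", "ND"),
  panel            = c("tga_associated", "motile", "non_motile",
                       "ciliogenesis_trafficking"),
  clinical_class   = c("benign", "likely_benign", "VUS", "likely_pathogenic",
                       "pathogenic", "unclassified"),
  sift_label       = c("D", "T"),
  pp2_label        = c("B", "PD", "D"),
  ma_label         = c("N", "L", "M", "H"),
  loftool_label    = c("PD", "other"),
  sex              = c("male", "female")
)

## Column order of the variant-table dialect; also the canonical slot order.
.variantColumns <- c(
  "patient_id", "gene", "dbsnp", "nt_change", "consequence", "aa_change",
  "sift_label", "sift_score",
  "pp2_humdiv_label", "pp2_humdiv_score",
  "pp2_humvar_label", "pp2_humvar_score",
  "ma_label", "ma_score",
  "cadd_phred", "loftool_label", "loftool_score",
  "allele_freq", "freq_scope", "zygosity", "chromosome_class",
  "inheritance", "panel", "clinical_class"
)

.characterColumns <- c(
  "patient_id", "gene", "dbsnp", "nt_change", "consequence", "aa_change",
  "sift_label", "pp2_humdiv_label", "pp2_humvar_label", "ma_label",
  "loftool_label", "freq_scope", "zygosity", "chromosome_class",
  "inheritance", "panel", "clinical_class"
)
.numericColumns <- setdiff(.variantColumns, .characterColumns)

.checkVocab <- function(x, column, allowed, allowNA = TRUE) {
  v <- x[[column]]
  bad <- !(v %in% allowed) & !(allowNA & is.na(v))
  if (any(bad))
    sprintf("column '%s': invalid value(s) %s in row(s) %s", column,
            paste(unique(v[bad]), collapse = ", "),
            paste(which(bad), collapse = ", "))
  else
    NULL
}

.checkRange <- function(x, column, lo, hi) {
  v <- x[[column]]
  bad <- !is.na(v) & (v < lo | v > hi)
  if (any(bad))
    sprintf("column '%s': value(s) outside [%g, %g] in row(s) %s",
            column, lo, hi, paste(which(bad), collapse = ", "))
  else
    NULL
}

.validVariantData <- function(df) {
  msgs <- character()
  missing <- setdiff(.variantColumns, names(df))
  if (length(missing))
    return(sprintf("missing mandatory column(s): %s",
                   paste(missing, collapse = ", ")))
  for (cc in .characterColumns)
    if (!is.character(df[[cc]]))
      msgs <- c(msgs, sprintf("column '%s' must be character", cc))
  for (nc in .numericColumns)
    if (!is.numeric(df[[nc]]))
      msgs <- c(msgs, sprintf("column '%s' must be numeric", nc))
  if (length(msgs)) return(msgs)

  msgs <- c(msgs,
    .checkVocab(df, "consequence", .vocab$consequence, allowNA = FALSE),
    .checkVocab(df, "freq_scope", .vocab$freq_scope),
    .checkVocab(df, "zygosity", .vocab$zygosity, allowNA = FALSE),
    .checkVocab(df, "chromosome_class", .vocab$chromosome_class,
                allowNA = FALSE),
    .checkVocab(df, "inheritance", .vocab$inheritance),
    .checkVocab(df, "panel", .vocab$panel, allowNA = FALSE),
    .checkVocab(df, "clinical_class", .vocab$clinical_class),
    .checkVocab(df, "sift_label", .vocab$sift_label),
    .checkVocab(df, "pp2_humdiv_label", .vocab$pp2_label),
    .checkVocab(df, "pp2_humvar_label", .vocab$pp2_label),
    .checkVocab(df, "ma_label", .vocab$ma_label),
    .checkVocab(df, "loftool_label", .vocab$loftool_label),
    .checkRange(df, "sift_score", 0, 1),
    .checkRange(df, "pp2_humdiv_score", 0, 1),
    .checkRange(df, "pp2_humvar_score", 0, 1),
    .checkRange(df, "allele_freq", 0, 1),
    .checkRange(df, "cadd_phred", 0, Inf))

  ## Novel variants (dbsnp == "New") cannot carry a reference frequency.
  ## The converse is NOT required: printed tables contain rsID rows whose
  ## frequency was not found in the reference; those are carried with an
  ## absent frequency and flagged downstream.
  novelWithFreq <- df$dbsnp == "New" & !is.na(df$allele_freq)
  if (any(novelWithFreq))
    msgs <- c(msgs, sprintf(
      "novel variant(s) carry a reference frequency in row(s) %s",
      paste(which(novelWithFreq), collapse = ", ")))

  hemiAuto <- df$zygosity == "hemi" & df$chromosome_class != "X"
  if (any(hemiAuto))
    msgs <- c(msgs, sprintf(
      "hemizygous call(s) on autosomal variant(s) in row(s) %s",
      paste(which(hemiAuto), collapse = ", ")))

  mis <- df$consequence == "missense"
  hasMissensePredictor <-
    !is.na(df$sift_label) | !is.na(df$sift_score) |
    !is.na(df$pp2_humdiv_label) | !is.na(df$pp2_humdiv_score) |
    !is.na(df$pp2_humvar_label) | !is.na(df$pp2_humvar_score) |
    !is.na(df$ma_label) | !is.na(df$ma_score)
  if (any(mis & !hasMissensePredictor))
    msgs <- c(msgs, sprintf(
      "missense row(s) without any missense predictor: %s",
      paste(which(mis & !hasMissensePredictor), collapse = ", ")))

  lof <- df$consequence %in% c("nonsense", "frameshift", "splice",
                               "inframe_indel")
  hasLofPredictor <- !is.na(df$cadd_phred) | !is.na(df$loftool_label)
  if (any(lof & !hasLofPredictor))
    msgs <- c(msgs, sprintf(
      "LoF/splice row(s) without CADD or LoF-Tool annotation: %s",
      paste(which(lof & !hasLofPredictor), collapse = ", ")))

  if (length(msgs)) msgs else TRUE
}

#' VariantTable: annotated per-patient variant observations
#'
#' An S4 container holding one row per (patient, variant) observation of an
#' annotated candidate-gene variant table: gene symbol, dbSNP id (or the
#' novelty marker \code{"New"}), HGVS cDNA/protein change, consequence class,
#' the in-silico predictor profile (SIFT, PolyPhen2 HumDiv/HumVar,
#' MutationAssessor, CADD PHRED, LoF-Tool), a reference population allele
#' frequency with its scope (Latino stratum or global), zygosity, chromosome
#' class, inheritance mode, gene-panel category and clinical classification.
#'
#' Validity enforces the controlled vocabularies, score ranges, that novel
#' variants carry no reference frequency, that hemizygous calls occur only on
#' the X chromosome, that missense rows carry at least one missense predictor
#' and LoF/splice rows a CADD or LoF-Tool annotation.
#'
#' @slot data a \code{data.frame} with the canonical columns (see
#'   \code{\link{readVariantTable}} for the file dialect).
#' @seealso \code{\link{readVariantTable}}, \code{\link{classifyVariants}}
#' @export
setClass("VariantTable", representation(data = "data.frame"))

setValidity("VariantTable", function(object) .validVariantData(object@data))

#' Construct a VariantTable from a data.frame
#'
#' @param data data.frame carrying the canonical variant-table columns.
#'   Missing optional columns may be supplied as \code{NA}; column order is
#'   normalised.
#' @return a validated \code{\link{VariantTable}}.
#' @export
VariantTable <- function(data) {
  stopifnot(is.data.frame(data))
  missing <- setdiff(.variantColumns, names(data))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  data <- as.data.frame(data)[.variantColumns]
  rownames(data) <- NULL
  for (nc in .numericColumns) data[[nc]] <- as.numeric(data[[nc]])
  for (cc in .characterColumns) data[[cc]] <- as.character(data[[cc]])
  new("VariantTable", data = data)
}

#' Cohort: patients, sexes and allele denominators
#'
#' Records the patients of a sequencing cohort with their sexes and derives
#' the allele denominators used by the aggregation statistics: autosomal
#' variants are counted against \code{2 * nPatients} alleles and X-linked
#' variants against \code{2 * females + males} alleles (one X per male).
#'
#' @slot patients data.frame with columns \code{patient_id}, \code{sex}.
#' @seealso \code{\link{alleleCount}}, \code{\link{aggregateVariant}}
#' @export
setClass("Cohort", representation(patients = "data.frame"))

setValidity("Cohort", function(object) {
  p <- object@patients
  msgs <- character()
  if (!all(c("patient_id", "sex") %in% names(p)))
    return("patients must have columns patient_id and sex")
  if (nrow(p) == 0L) msgs <- c(msgs, "cohort is empty")
  if (anyDuplicated(p$patient_id))
    msgs <- c(msgs, "duplicated patient_id")
  if (!all(p$sex %in% .vocab$sex))
    msgs <- c(msgs, "sex must be 'male' or 'female'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Cohort
#'
#' @param patientIds character vector of unique patient identifiers.
#' @param sexes character vector, one of \code{"male"}/\code{"female"} per
#'   patient.
#' @return a \code{\link{Cohort}}.
#' @examples
#' co <- Cohort(c("P1", "P2", "P3"), c("male", "male", "female"))
#' autosomalAlleleNumber(co)  # 6
#' xAlleleNumber(co)          # 4
#' @export
Cohort <- function(patientIds, sexes) {
  new("Cohort", patients = data.frame(patient_id = as.character(patientIds),
                                      sex = as.character(sexes),
                                      stringsAsFactors = FALSE))
}

#' GenePanel: a named set of gene symbols
#'
#' @slot name single string naming the panel.
#' @slot genes character vector of unique, non-empty gene symbols.
#' @export
setClass("GenePanel",
         representation(name = "character", genes = "character"))

setValidity("GenePanel", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "name must be a single non-empty string")
  if (length(object@genes) == 0L)
    msgs <- c(msgs, "panel is empty")
  if (anyDuplicated(object@genes))
    msgs <- c(msgs, "duplicate gene symbols")
  if (any(!nzchar(object@genes)))
    msgs <- c(msgs, "empty gene symbol")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenePanel
#'
#' @param name panel name.
#' @param genes character vector of gene symbols; whitespace is stripped and
#'   duplicates removed.
#' @return a \code{\link{GenePanel}}.
#' @export
GenePanel <- function(name, genes) {
  genes <- unique(trimws(as.character(genes)))
  genes <- genes[nzchar(genes)]
  new("GenePanel", name = as.character(name), genes = genes)
}

#' InteractionGraph: weighted gene-interaction network
#'
#' Wraps an undirected simple \pkg{igraph} graph whose vertices are gene
#' symbols and whose edges carry a \code{confidence} attribute in [0, 1]
#' (STRING combined scores divided by 1000 when read from a STRING export).
#' Self-edges and duplicate pairs are disallowed.
#'
#' @slot graph an \pkg{igraph} object.
#' @seealso \code{\link{readEdgeList}}, \code{\link{mcl}},
#'   \code{\link{interactionEnrichment}}
#' @export
setClass("InteractionGraph", representation(graph = "ANY"))

setValidity("InteractionGraph", function(object) {
  g <- object@graph
  msgs <- character()
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  if (igraph::is_directed(g)) msgs <- c(msgs, "graph must be undirected")
  if (any(igraph::which_loop(g))) msgs <- c(msgs, "self-edges are not allowed")
  if (any(igraph::which_multiple(g)))
    msgs <- c(msgs, "duplicate edges are not allowed")
  if (igraph::ecount(g) > 0) {
    conf <- igraph::edge_attr(g, "confidence")
    if (is.null(conf))
      msgs <- c(msgs, "edges must carry a 'confidence' attribute")
    else if (any(is.na(conf)) || any(conf < 0 | conf > 1))
      msgs <- c(msgs, "edge confidences must lie in [0, 1]")
  }
  if (is.null(igraph::vertex_attr(g, "name")))
    msgs <- c(msgs, "vertices must be named")
  if (length(msgs)) msgs else TRUE
})

#' Construct an InteractionGraph from an edge data.frame
#'
#' Symmetric duplicate pairs are collapsed keeping the maximum confidence and
#' self-edges are dropped, matching the edge-list reader semantics.
#'
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{confidence}, or NULL for an edgeless graph.
#' @param nodes optional character vector of vertex names (isolated vertices
#'   are kept).
#' @return an \code{\link{InteractionGraph}}.
#' @export
InteractionGraph <- function(edges = NULL, nodes = character()) {
  if (is.null(edges) || nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(unique(nodes)),
                              name = unique(as.character(nodes)))
    g <- igraph::set_edge_attr(g, "confidence", value = numeric(0))
    return(new("InteractionGraph", graph = g))
  }
  stopifnot(all(c("from", "to", "confidence") %in% names(edges)))
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  conf <- as.numeric(edges$confidence)
  if (any(is.na(conf)) || any(conf < 0 | conf > 1))
    stop("edge confidences must lie in [0, 1]")
  keep <- from != to                       # self-edges dropped
  allNodes <- unique(c(from, to, as.character(nodes)))
  from <- from[keep]; to <- to[keep]; conf <- conf[keep]
  if (length(from) == 0L)
    return(InteractionGraph(NULL, nodes = allNodes))
  ## canonical orientation so A-B and B-A collapse
  lo <- pmin(from, to); hi <- pmax(from, to)
  key <- paste(lo, hi, sep = "\r")
  conf <- tapply(conf, key, max)
  pairs <- do.call(rbind, strsplit(names(conf), "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2],
               confidence = as.numeric(conf), stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = allNodes, stringsAsFactors = FALSE))
  new("InteractionGraph", graph = g)
}

#' ClusterPartition: result of Markov Clustering
#'
#' @slot membership named integer vector mapping each node to a cluster
#'   index (contiguous, 1-based).
#' @slot nClusters number of clusters.
#' @slot inflation inflation parameter used.
#' @slot iterationsRun iterations performed.
#' @slot converged logical; FALSE when the iteration hit its cap before the
#'   column-wise change fell below tolerance.
#' @export
setClass("ClusterPartition",
         representation(membership = "integer", nClusters = "integer",
                        inflation = "numeric", iterationsRun = "integer",
                        converged = "logical"))

setValidity("ClusterPartition", function(object) {
  m <- object@membership
  msgs <- character()
  if (is.null(names(m)) || anyDuplicated(names(m)))
    msgs <- c(msgs, "membership must be named uniquely by node")
  if (length(m)) {
    if (!setequal(unique(m), seq_len(object@nClusters)))
      msgs <- c(msgs, "cluster indices must be contiguous 1..nClusters")
    if (object@nClusters > length(m))
      msgs <- c(msgs, "more clusters than nodes")
  }
  if (length(msgs)) msgs else TRUE
})

#' EnrichmentResult: permutation interaction-enrichment outcome
#'
#' @slot nodeSet genes tested.
#' @slot observedEdges edges observed within the node set.
#' @slot nullMean mean within-set edge count over the permutation null.
#' @slot pValue add-one permutation p-value, bounded below by
#'   \code{1 / (nPermutations + 1)}.
#' @slot nPermutations number of degree-preserving rewirings.
#' @slot seed RNG seed used.
#' @export
setClass("EnrichmentResult",
         representation(nodeSet = "character", observedEdges = "integer",
                        nullMean = "numeric", pValue = "numeric",
                        nPermutations = "integer", seed = "integer"))

setValidity("EnrichmentResult", function(object) {
  msgs <- character()
  if (object@pValue < 1 / (object@nPermutations + 1) - 1e-12 ||
      object@pValue > 1)
    msgs <- c(msgs, "pValue outside (1/(B+1), 1]")
  if (object@observedEdges < 0L) msgs <- c(msgs, "negative observed edges")
  if (length(msgs)) msgs else TRUE
})

#' AggregationResult: binomial aggregation of one variant across the cohort
#'
#' Carries the observed alternate-allele count \code{k} out of the cohort
#' allele number \code{n}, the reference population frequency used, and both
#' binomial summaries: the point probability P(X = k) and the upper tail
#' P(X >= k). \code{modeUsed} records which one is the headline number; the
#' point probability is not a calibrated p-value and is always labelled as a
#' point probability in reports.
#'
#' @slot gene,ntChange variant identity.
#' @slot k,n observed allele count and cohort allele number.
#' @slot pRef reference allele frequency (NA when not computable).
#' @slot freqScope \code{"latino"} or \code{"global"}.
#' @slot pointProb,tailProb binomial point and upper-tail probabilities.
#' @slot modeUsed \code{"point"} or \code{"upper_tail"}.
#' @slot computable FALSE for novel variants without a reference frequency.
#' @slot note free-text annotation (e.g. why not computable).
#' @export
setClass("AggregationResult",
         representation(gene = "character", ntChange = "character",
                        k = "integer", n = "integer", pRef = "numeric",
                        freqScope = "character", pointProb = "numeric",
                        tailProb = "numeric", modeUsed = "character",
                        computable = "logical", note = "character"))

setValidity("AggregationResult", function(object) {
  msgs <- character()
  if (object@computable) {
    if (is.na(object@pointProb) || is.na(object@tailProb))
      msgs <- c(msgs, "computable result must carry both probabilities")
    else {
      if (object@tailProb < object@pointProb - 1e-12)
        msgs <- c(msgs, "upper tail must include the point mass")
      if (object@pointProb < 0 || object@pointProb > 1 ||
          object@tailProb < 0 || object@tailProb > 1)
        msgs <- c(msgs, "probabilities must lie in [0, 1]")
    }
  }
  if (!object@modeUsed %in% c("point", "upper_tail"))
    msgs <- c(msgs, "modeUsed must be 'point' or 'upper_tail'")
  if (length(msgs)) msgs else TRUE
})
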