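## Pipeline layer: validated run configuration, the three stage runners
## (triage -> aggregation -> clustering) writing deterministic TSV reports
## plus a provenance manifest, and a synthetic-cohort emitter. A thin
## command-line wrapper over these functions ships in
## inst/scripts/varianttriage.R.

#' Build a validated run configuration
#'
#' @param variantTable path to the annotated variant table (TSV).
#' @param cohort path to the cohort sheet (TSV: patient_id, sex).
#' @param panelDir optional directory of panel files named
#'   \code{panel_<category>.txt}; when given, panel membership is enforced
#'   during filtering.
#' @param edgeList optional path to the interaction edge list.
#' @param edgeScoreScale \code{"unit"} or \code{"string_999"}.
#' @param outputDir directory for reports (created if absent).
#' @param caddCutoff CADD PHRED deleteriousness cutoff (default 20).
#' @param siftFallback SIFT score fallback threshold (default 0.05).
#' @param inflation MCL inflation (default 2.0).
#' @param edgeConfidence minimum edge confidence for patient subnetworks
#'   (default 0.4, the medium tier).
#' @param mode headline aggregation statistic: \code{"point"} or
#'   \code{"upper_tail"}.
#' @param nPermutations permutations for enrichment (default 1000).
#' @param seed integer seed for all randomised stages.
#' @return a list of class \code{"runConfig"}.
#' @export
runConfig <- function(variantTable = NULL, cohort = NULL, panelDir = NULL,
                      edgeList = NULL,
                      edgeScoreScale = c("string_999", "unit"),
                      outputDir = tempfile("varianttriage_run_"),
                      caddCutoff = 20, siftFallback = 0.05,
                      inflation = 2.0, edgeConfidence = 0.4,
                      mode = c("point", "upper_tail"),
                      nPermutations = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  edgeScoreScale <- match.arg(edgeScoreScale)
  if (caddCutoff < 0) stop("caddCutoff must be nonnegative")
  if (siftFallback < 0 || siftFallback > 1)
    stop("siftFallback must lie in [0, 1]")
  if (inflation <= 1) stop("inflation must be > 1")
  if (edgeConfidence < 0 || edgeConfidence > 1)
    stop("edgeConfidence must lie in [0, 1]")
  structure(list(variantTable = variantTable, cohort = cohort,
                 panelDir = panelDir, edgeList = edgeList,
                 edgeScoreScale = edgeScoreScale, outputDir = outputDir,
                 caddCutoff = caddCutoff, siftFallback = siftFallback,
                 inflation = inflation, edgeConfidence = edgeConfidence,
                 mode = mode, nPermutations = as.integer(nPermutations),
                 seed = as.integer(seed)),
            class = "runConfig")
}

.formatReportNumbers <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- ifelse(is.na(df[[nm]]), "",
                         formatC(df[[nm]], digits = 6, format = "g"))
  df
}

.writeReport <- function(df, path) {
  utils::write.table(.formatReportNumbers(df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Serialise config + input checksums + versions so a run can be reproduced.
.writeManifest <- function(config, outputDir, stage) {
  inputs <- Filter(Negate(is.null),
                   config[c("variantTable", "cohort", "edgeList")])
  checksums <- lapply(inputs, function(p)
    unname(tools::md5sum(path.expand(p))))
  manifest <- list(
    stage = stage,
    config = config[setdiff(names(config), "outputDir")],
    input_md5 = checksums,
    package_version = as.character(utils::packageVersion("VariantTriage")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

.readPanels <- function(panelDir) {
  if (is.null(panelDir)) return(NULL)
  files <- dir(panelDir, pattern = "^panel_.*\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no panel_<category>.txt files in ", panelDir)
  names(files) <- sub("^panel_", "", sub("\\.txt$", "", basename(files)))
  lapply(files, function(f) readGenePanel(f))
}

#' Run the triage stage
#'
#' Reads the variant table, applies the panel filter, classifies every
#' observation and writes \code{triage_report.tsv} (one row per
#' observation, ordered by patient, gene, cDNA change),
#' \code{gene_summaries.tsv} (per patient x gene counts and compound
#' heterozygosity) and a provenance manifest to the output directory.
#' Stage-wise record counts are logged via \code{message()}.
#'
#' @param config a \code{\link{runConfig}} with \code{variantTable} set.
#' @return invisibly, a list with the filtered \code{variants}, the
#'   \code{calls}, the \code{summaries} and the \code{outputDir}.
#' @export
runTriage <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  if (is.null(config$variantTable)) stop("config$variantTable is required")
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  vt <- readVariantTable(config$variantTable)
  message("triage: read ", nVariants(vt), " observation(s)")
  panels <- .readPanels(config$panelDir)
  vt <- filterVariants(vt, panels)
  message("triage: ", nVariants(vt), " observation(s) after panel filter")
  calls <- classifyVariants(vt, caddCutoff = config$caddCutoff,
                            siftFallback = config$siftFallback)
  message("triage: ", sum(calls$deleterious), " deleterious call(s)")
  report <- cbind(calls,
                  consequence = variantData(vt)$consequence,
                  zygosity = variantData(vt)$zygosity,
                  panel = variantData(vt)$panel)
  ord <- order(report$patient_id, report$gene, report$nt_change)
  .writeReport(report[ord, , drop = FALSE],
               file.path(config$outputDir, "triage_report.tsv"))
  summaries <- geneGenotypeSummaries(vt, calls)
  .writeReport(summaries, file.path(config$outputDir, "gene_summaries.tsv"))
  .writeManifest(config, config$outputDir, "triage")
  invisible(list(variants = vt, calls = calls, summaries = summaries,
                 outputDir = config$outputDir))
}

#' Run the aggregation stage
#'
#' Aggregates every recurrent variant of the (panel-filtered) table against
#' the cohort's allele denominators and writes
#' \code{aggregation_report.tsv}: one row per recurrent variant with the
#' observed allele count, reference frequency and scope, the binomial point
#' and upper-tail probabilities, plus explicitly flagged not-computable
#' rows for frequency-less variants.
#'
#' @param config a \code{\link{runConfig}} with \code{variantTable} and
#'   \code{cohort} set.
#' @return invisibly, a list with the aggregation \code{report} data.frame
#'   and the \code{outputDir}.
#' @export
runAggregation <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  if (is.null(config$variantTable) || is.null(config$cohort))
    stop("config$variantTable and config$cohort are required")
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  vt <- filterVariants(readVariantTable(config$variantTable),
                       .readPanels(config$panelDir))
  cohort <- readCohort(config$cohort)
  report <- aggregateCohort(vt, cohort, mode = config$mode)
  message("aggregation: ", nrow(report), " variant(s) reported (",
          sum(!report$computable), " not computable)")
  .writeReport(report,
               file.path(config$outputDir, "aggregation_report.tsv"))
  .writeManifest(config, config$outputDir, "aggregation")
  invisible(list(report = report, outputDir = config$outputDir))
}

#' Run the clustering stage
#'
#' Reads the interaction edge list, partitions the whole network by Markov
#' Clustering (\code{partition.tsv}), extracts each patient's
#' deleterious-gene subnetwork at the configured confidence tier
#' (\code{patient_subnetworks.tsv}), and runs the degree-preserving
#' permutation enrichment test on each patient's gene set with at least two
#' genes present in the network (\code{enrichment.tsv}, seed recorded).
#' Outputs are deterministic for a fixed seed.
#'
#' @param config a \code{\link{runConfig}} with \code{variantTable} and
#'   \code{edgeList} set.
#' @return invisibly, a list with the \code{partition}, the per-patient
#'   \code{subnetworks}, the \code{enrichment} table and the
#'   \code{outputDir}.
#' @export
runClustering <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  if (is.null(config$variantTable) || is.null(config$edgeList))
    stop("config$variantTable and config$edgeList are required")
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  graph <- readEdgeList(config$edgeList,
                        scoreScale = config$edgeScoreScale)
  message("clustering: network with ",
          igraph::vcount(asIgraph(graph)), " node(s), ",
          igraph::ecount(asIgraph(graph)), " edge(s)")
  part <- mcl(graph, inflation = config$inflation)
  message("clustering: ", nClusters(part), " cluster(s)")
  .writeReport(data.frame(node = names(clusterMembership(part)),
                          cluster = clusterMembership(part),
                          stringsAsFactors = FALSE),
               file.path(config$outputDir, "partition.tsv"))

  vt <- filterVariants(readVariantTable(config$variantTable),
                       .readPanels(config$panelDir))
  calls <- classifyVariants(vt, caddCutoff = config$caddCutoff,
                            siftFallback = config$siftFallback)
  delGenes <- split(calls$gene[calls$deleterious],
                    calls$patient_id[calls$deleterious])
  delGenes <- lapply(delGenes, unique)

  subRows <- list()
  enrRows <- list()
  for (pid in sort(names(delGenes))) {
    sub <- patientSubnetwork(graph, delGenes[[pid]],
                             minConfidence = config$edgeConfidence)
    et <- edgeTable(sub)
    if (nrow(et))
      subRows[[pid]] <- cbind(patient_id = pid, et)
    singles <- setdiff(graphNodes(sub),
                       unique(c(et$from, et$to)))
    if (length(singles))
      subRows[[paste0(pid, ".s")]] <- data.frame(
        patient_id = pid, from = singles, to = NA_character_,
        confidence = NA_real_, stringsAsFactors = FALSE)
    inGraph <- intersect(delGenes[[pid]], graphNodes(graph))
    if (length(inGraph) >= 2L) {
      enr <- interactionEnrichment(graph, inGraph,
                                   nPermutations = config$nPermutations,
                                   seed = .deriveSeed(config$seed, pid))
      enrRows[[pid]] <- data.frame(
        patient_id = pid, n_genes = length(inGraph),
        observed_edges = enr@observedEdges, null_mean = enr@nullMean,
        p_value = enr@pValue, n_permutations = enr@nPermutations,
        seed = enr@seed, stringsAsFactors = FALSE)
    }
  }
  subnetworks <- if (length(subRows)) do.call(rbind, subRows) else
    data.frame(patient_id = character(), from = character(),
               to = character(), confidence = numeric(),
               stringsAsFactors = FALSE)
  rownames(subnetworks) <- NULL
  enrichment <- if (length(enrRows)) do.call(rbind, enrRows) else
    data.frame(patient_id = character(), n_genes = integer(),
               observed_edges = integer(), null_mean = numeric(),
               p_value = numeric(), n_permutations = integer(),
               seed = integer(), stringsAsFactors = FALSE)
  rownames(enrichment) <- NULL
  .writeReport(subnetworks,
               file.path(config$outputDir, "patient_subnetworks.tsv"))
  .writeReport(enrichment, file.path(config$outputDir, "enrichment.tsv"))
  .writeManifest(config, config$outputDir, "clustering")
  invisible(list(partition = part, subnetworks = subnetworks,
                 enrichment = enrichment, outputDir = config$outputDir))
}

#' Emit a synthetic cohort in the pipeline's file dialects
#'
#' Generates a seeded synthetic cohort (see
#' \code{\link{simulateGenotypes}}) and writes \code{variants.tsv},
#' \code{cohort.tsv} and \code{truth.tsv} to the output directory, ready to
#' be consumed by \code{\link{runTriage}} / \code{\link{runAggregation}}.
#'
#' @param config a \code{\link{runConfig}} (only \code{outputDir} and
#'   \code{seed} are used).
#' @param spec optional \code{\link{syntheticCohortSpec}}; by default an
#'   11-patient (9 male / 2 female) cohort with six autosomal and two
#'   X-linked variants spanning deleterious and benign truth.
#' @return invisibly, the output directory.
#' @export
runSimulation <- function(config, spec = NULL) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(spec)) {
    variants <- data.frame(
      gene = sprintf("GENE%d", 1:8),
      chromosome_class = c(rep("autosomal", 6), "X", "X"),
      allele_freq = c(0.05, 0.10, 0.01, 0.20, 0.05, 0.02, 0.05, 0.10),
      true_deleterious = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
                           TRUE, FALSE),
      consequence = c("missense", "missense", "splice", "missense",
                      "missense", "nonsense", "missense", "missense"),
      stringsAsFactors = FALSE)
    spec <- syntheticCohortSpec(variants = variants, seed = config$seed)
  }
  sim <- simulateGenotypes(spec)
  writeVariantTable(sim$variants, file.path(config$outputDir,
                                            "variants.tsv"))
  utils::write.table(sim$cohort@patients,
                     file.path(config$outputDir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeReport(sim$truth, file.path(config$outputDir, "truth.tsv"))
  .writeManifest(config, config$outputDir, "simulate")
  invisible(config$outputDir)
}
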