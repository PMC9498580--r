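## Composite deleteriousness triage.
##
## Missense variants are judged by consensus of three in-silico predictors:
## SIFT, PolyPhen2 (HumDiv and HumVar jointly count as ONE predictor,
## OR-combined) and MutationAssessor (medium or high impact). Two abnormal
## predictors call a variant deleterious; a single abnormality suffices for
## novel variants. Loss-of-function and splice classes are judged by CADD
## PHRED >= 20, falling back to a LoF-Tool "PD" label when CADD is absent.

.SIFT_FALLBACK_THRESHOLD <- 0.05
.CADD_DELETERIOUS_THRESHOLD <- 20

.lofConsequences <- c("nonsense", "frameshift", "splice", "inframe_indel")

#' Abnormal missense predictors of a variant
#'
#' Evaluates, per missense observation, which of the three missense
#' predictors flag the variant as damaging:
#' \itemize{
#'   \item \code{SIFT}: label \code{"D"}; when no label is present, a score
#'     below 0.05. The printed label is trusted over the numeric threshold
#'     when both exist, which reproduces published calls such as
#'     \code{"D (0.085)"}.
#'   \item \code{PP2}: PolyPhen2 HumDiv \emph{or} HumVar label in
#'     \{\code{PD}, \code{D}\}; the two sub-models count as a single
#'     predictor.
#'   \item \code{MA}: MutationAssessor label \code{M} (medium) or \code{H}
#'     (high).
#' }
#'
#' @param x a \code{\link{VariantTable}} of missense observations (rows of
#'   other consequence classes return \code{NA}).
#' @param siftFallback SIFT score cutoff used only when no SIFT label is
#'   present (default 0.05, the tool's own damaging threshold).
#' @return a list, one character vector per row, each a subset of
#'   \code{c("SIFT", "PP2", "MA")}.
#' @examples
#' vt <- readVariantTable(tgaExampleFile("table1_tga_panel.tsv"))
#' predictorAbnormalities(vt)[[4]]  # the novel KMT2D p.P183S row: "PP2"
#' @export
predictorAbnormalities <- function(x, siftFallback = .SIFT_FALLBACK_THRESHOLD) {
  stopifnot(is(x, "VariantTable"))
  d <- variantData(x)
  lapply(seq_len(nrow(d)), function(i) {
    if (d$consequence[i] != "missense") return(NA)
    .missenseAbnormalities(d[i, , drop = FALSE], siftFallback)
  })
}

## one-row worker; errors when all three predictors are absent
.missenseAbnormalities <- function(r,
                                   siftFallback = .SIFT_FALLBACK_THRESHOLD) {
  haveSift <- !is.na(r$sift_label) || !is.na(r$sift_score)
  havePp2 <- !is.na(r$pp2_humdiv_label) || !is.na(r$pp2_humvar_label) ||
    !is.na(r$pp2_humdiv_score) || !is.na(r$pp2_humvar_score)
  haveMa <- !is.na(r$ma_label) || !is.na(r$ma_score)
  if (!haveSift && !havePp2 && !haveMa)
    stop(sprintf(
      "insufficient annotation: no missense predictor for %s %s %s",
      r$patient_id, r$gene, r$nt_change), call. = FALSE)
  abn <- character()
  siftAbn <- if (!is.na(r$sift_label)) r$sift_label == "D"
             else !is.na(r$sift_score) && r$sift_score < siftFallback
  if (isTRUE(siftAbn)) abn <- c(abn, "SIFT")
  pp2Abn <- isTRUE(r$pp2_humdiv_label %in% c("PD", "D")) ||
            isTRUE(r$pp2_humvar_label %in% c("PD", "D"))
  if (pp2Abn) abn <- c(abn, "PP2")
  if (isTRUE(r$ma_label %in% c("M", "H"))) abn <- c(abn, "MA")
  abn
}

#' Classify variants as deleterious or not
#'
#' Applies the composite deleteriousness rules per observation:
#' \describe{
#'   \item{missense}{deleterious iff at least two of
#'     \{SIFT, PolyPhen2, MutationAssessor\} are abnormal
#'     (\code{rule_fired = "missense_two_of_three"}), or at least one when
#'     the variant is novel (\code{dbsnp == "New"};
#'     \code{rule_fired = "missense_novel_one"}).}
#'   \item{nonsense / frameshift / splice / inframe indel}{deleterious iff
#'     CADD PHRED >= 20 (the conventional top-1\%-damaging cutoff;
#'     \code{rule_fired = "lof_cadd"}); when CADD is absent, a LoF-Tool
#'     \code{"PD"} label calls the variant deleterious
#'     (\code{rule_fired = "lof_tool"}).}
#' }
#'
#' Adding an abnormal predictor can never flip a deleterious call to
#' non-deleterious (the rules are monotone in the abnormality set).
#'
#' @param x a \code{\link{VariantTable}}.
#' @param caddCutoff CADD PHRED threshold for LoF/splice classes (default
#'   20, the conventional top-1\%-damaging value).
#' @param siftFallback see \code{\link{predictorAbnormalities}}.
#' @return a data.frame with one row per observation: \code{patient_id},
#'   \code{gene}, \code{nt_change}, \code{deleterious} (logical),
#'   \code{abnormal_predictors} (comma-separated), \code{rule_fired},
#'   \code{notes}.
#' @examples
#' vt <- readVariantTable(tgaExampleFile("table1_tga_panel.tsv"))
#' table(classifyVariants(vt)$deleterious)  # 9 TRUE, 5 FALSE
#' @export
classifyVariants <- function(x, caddCutoff = .CADD_DELETERIOUS_THRESHOLD,
                             siftFallback = .SIFT_FALLBACK_THRESHOLD) {
  stopifnot(is(x, "VariantTable"))
  d <- variantData(x)
  n <- nrow(d)
  out <- data.frame(
    patient_id = d$patient_id, gene = d$gene, nt_change = d$nt_change,
    deleterious = logical(n), abnormal_predictors = character(n),
    rule_fired = rep("none", n), notes = character(n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    r <- d[i, , drop = FALSE]
    if (r$consequence == "missense") {
      abn <- .missenseAbnormalities(r, siftFallback)
      out$abnormal_predictors[i] <- paste(abn, collapse = ",")
      if (length(abn) >= 2L) {
        out$deleterious[i] <- TRUE
        out$rule_fired[i] <- "missense_two_of_three"
      } else if (length(abn) >= 1L && r$dbsnp == "New") {
        out$deleterious[i] <- TRUE
        out$rule_fired[i] <- "missense_novel_one"
        out$notes[i] <- "novel variant: one abnormality suffices"
      }
    } else if (r$consequence %in% .lofConsequences) {
      if (!is.na(r$cadd_phred)) {
        if (r$cadd_phred >= caddCutoff) {
          out$deleterious[i] <- TRUE
          out$rule_fired[i] <- "lof_cadd"
          out$abnormal_predictors[i] <- "CADD"
        }
        out$notes[i] <- sprintf("CADD PHRED %g vs cutoff %g",
                                r$cadd_phred, caddCutoff)
      } else if (isTRUE(r$loftool_label == "PD")) {
        out$deleterious[i] <- TRUE
        out$rule_fired[i] <- "lof_tool"
        out$abnormal_predictors[i] <- "LoFTool"
      }
    }
  }
  out
}

#' Apply the panel-dependent variant filter
#'
#' The TGA-associated panel retains every non-synonymous observation
#' regardless of clinical classification; the three cilia panels (motile,
#' non-motile, ciliogenesis/trafficking) retain only observations classified
#' VUS, likely pathogenic or pathogenic. Input order is preserved.
#'
#' @param x a \code{\link{VariantTable}}; every row must carry a panel
#'   category.
#' @param panels optional named list of \code{\link{GenePanel}} objects
#'   (names = panel categories). When supplied, each observation's gene must
#'   belong to its declared panel; violations are a validation error.
#' @return the filtered \code{\link{VariantTable}}.
#' @export
filterVariants <- function(x, panels = NULL) {
  stopifnot(is(x, "VariantTable"))
  d <- variantData(x)
  if (nrow(d) == 0L) return(x)
  if (!is.null(panels)) {
    for (i in seq_len(nrow(d))) {
      p <- panels[[d$panel[i]]]
      if (is.null(p))
        stop("validation error: no panel definition for category '",
             d$panel[i], "' (row ", i, ")")
      if (!d$gene[i] %in% panelGenes(p))
        stop(sprintf(
          "validation error: row %d gene %s not in its declared panel '%s'",
          i, d$gene[i], d$panel[i]))
    }
  }
  keep <- d$panel == "tga_associated" |
    (!is.na(d$clinical_class) &
       d$clinical_class %in% c("VUS", "likely_pathogenic", "pathogenic"))
  VariantTable(d[keep, , drop = FALSE])
}

#' Per-patient, per-gene genotype summary
#'
#' Counts deleterious calls by zygosity for one (patient, gene) pair and
#' detects compound heterozygosity: two or more \emph{distinct} (by cDNA
#' change) deleterious heterozygous variants of the same gene in one
#' patient.
#'
#' @param x a \code{\link{VariantTable}} whose rows all share one
#'   \code{patient_id} and one \code{gene} (anything else is a precondition
#'   error).
#' @param calls the output of \code{\link{classifyVariants}} for \code{x};
#'   computed when omitted.
#' @return a one-row data.frame: \code{patient_id}, \code{gene},
#'   \code{n_deleterious_het}, \code{n_deleterious_hom},
#'   \code{n_deleterious_hemi}, \code{compound_het}.
#' @export
summarizeGeneGenotype <- function(x, calls = classifyVariants(x)) {
  stopifnot(is(x, "VariantTable"))
  d <- variantData(x)
  if (nrow(d) == 0L) stop("no records supplied")
  if (length(unique(d$patient_id)) != 1L || length(unique(d$gene)) != 1L)
    stop("precondition error: records must share one patient and one gene")
  del <- calls$deleterious
  hetChanges <- unique(d$nt_change[del & d$zygosity == "het"])
  data.frame(
    patient_id = d$patient_id[1], gene = d$gene[1],
    n_deleterious_het = sum(del & d$zygosity == "het"),
    n_deleterious_hom = sum(del & d$zygosity == "hom"),
    n_deleterious_hemi = sum(del & d$zygosity == "hemi"),
    compound_het = length(hetChanges) >= 2L,
    stringsAsFactors = FALSE)
}

#' Genotype summaries for every (patient, gene) pair
#'
#' Convenience wrapper applying \code{\link{summarizeGeneGenotype}} to every
#' (patient, gene) group of a table. Cross-panel repeats of the same
#' observation (identical patient, cDNA change and zygosity) are collapsed
#' first so a variant listed under two panels is not double-counted.
#'
#' @param x a \code{\link{VariantTable}}.
#' @param calls classification calls for \code{x}; computed when omitted.
#' @return a data.frame, one row per (patient, gene), sorted by patient then
#'   gene.
#' @examples
#' vt <- tgaStudyVariants()
#' gs <- geneGenotypeSummaries(vt)
#' gs[gs$compound_het, ]  # DNAH9 in proband T180401
#' @export
geneGenotypeSummaries <- function(x, calls = classifyVariants(x)) {
  stopifnot(is(x, "VariantTable"))
  d <- variantData(x)
  if (nrow(d) == 0L)
    return(data.frame(patient_id = character(), gene = character(),
                      n_deleterious_het = integer(),
                      n_deleterious_hom = integer(),
                      n_deleterious_hemi = integer(),
                      compound_het = logical(), stringsAsFactors = FALSE))
  dup <- duplicated(d[c("patient_id", "gene", "nt_change", "zygosity")])
  d <- d[!dup, , drop = FALSE]
  calls <- calls[!dup, , drop = FALSE]
  groups <- split(seq_len(nrow(d)),
                  list(d$patient_id, d$gene), drop = TRUE)
  rows <- lapply(groups, function(idx)
    summarizeGeneGenotype(VariantTable(d[idx, , drop = FALSE]),
                          calls[idx, , drop = FALSE]))
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Observed allele count of one variant across the cohort
#'
#' Sums per-carrier allele doses (heterozygous 1, homozygous 2, hemizygous
#' 1) for a single variant and returns the cohort allele denominator:
#' \code{2 * nPatients} for autosomal variants, \code{2 * females + males}
#' for X-linked variants.
#'
#' All records must share one gene and cDNA change. Identical cross-panel
#' repeats (same patient, same zygosity) are collapsed; the same patient
#' reported with two \emph{different} zygosities for one variant is a
#' validation error.
#'
#' @param x a \code{\link{VariantTable}} of observations of one variant.
#' @param cohort a \code{\link{Cohort}}; every carrier must be a member.
#' @return a list with elements \code{k} (observed alternate alleles) and
#'   \code{n} (cohort allele number).
#' @examples
#' vt <- tgaStudyVariants()
#' d <- variantData(vt)
#' dnah9 <- VariantTable(d[d$gene == "DNAH9" & d$nt_change == "c.3050A>G", ])
#' alleleCount(dnah9, tgaStudyCohort())  # k = 2, n = 22
#' @export
alleleCount <- function(x, cohort) {
  stopifnot(is(x, "VariantTable"), is(cohort, "Cohort"))
  d <- variantData(x)
  if (nrow(d) == 0L) stop("no records supplied")
  if (length(unique(d$gene)) != 1L || length(unique(d$nt_change)) != 1L)
    stop("precondition error: records must share one gene and nt_change")
  d <- d[!duplicated(d[c("patient_id", "zygosity")]), , drop = FALSE]
  if (anyDuplicated(d$patient_id))
    stop("validation error: conflicting duplicate observations for ",
         "patient(s) ",
         paste(unique(d$patient_id[duplicated(d$patient_id)]),
               collapse = ", "))
  if (!all(d$patient_id %in% patientIds(cohort)))
    stop("carrier(s) not in cohort: ",
         paste(setdiff(d$patient_id, patientIds(cohort)), collapse = ", "))
  dose <- c(het = 1L, hom = 2L, hemi = 1L)[d$zygosity]
  chrClass <- unique(d$chromosome_class)
  if (length(chrClass) != 1L)
    stop("validation error: mixed chromosome classes for one variant")
  n <- if (chrClass == "X") xAlleleNumber(cohort)
       else autosomalAlleleNumber(cohort)
  k <- as.integer(sum(dose))
  if (k > n)
    stop("observed allele count exceeds the cohort allele number")
  list(k = k, n = as.integer(n))
}
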