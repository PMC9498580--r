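## Seeded synthetic-data generators: cohorts with Hardy-Weinberg genotypes
## (X-linked dosage included), predictor profiles conditional on a
## ground-truth deleterious label, and planted-partition interaction graphs.
## A single root seed derives independent per-stream sub-seeds so each stage
## can be regenerated in isolation.

## Deterministic sub-seed derivation; kept strictly below 2^31.
.deriveSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Specify a synthetic cohort
#'
#' Bundles the parameters of a synthetic whole-exome cohort: size, sex
#' composition, and a set of variants with known reference allele
#' frequencies and ground-truth deleteriousness. The defaults mirror an
#' 11-proband cohort with 9 males and 2 females, so the natural allele
#' denominators (22 autosomal, 13 X) arise in downstream tests.
#'
#' @param nPatients cohort size (default 11).
#' @param sexRatio fraction of males in [0, 1] (default 9/11); male counts
#'   are rounded to the nearest integer.
#' @param variants data.frame with columns \code{gene},
#'   \code{chromosome_class} (\code{"autosomal"}/\code{"X"}),
#'   \code{allele_freq} in [0, 1], \code{true_deleterious} (logical),
#'   \code{consequence}.
#' @param seed mandatory integer root seed.
#' @return a list of class \code{"SyntheticCohortSpec"}.
#' @export
syntheticCohortSpec <- function(nPatients = 11L, sexRatio = 9 / 11,
                                variants, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(is.data.frame(variants),
            all(c("gene", "chromosome_class", "allele_freq",
                  "true_deleterious", "consequence") %in% names(variants)))
  if (any(variants$allele_freq < 0 | variants$allele_freq > 1))
    stop("allele frequencies must lie in [0, 1]")
  if (sexRatio < 0 || sexRatio > 1) stop("sexRatio must lie in [0, 1]")
  if (!all(variants$chromosome_class %in% .vocab$chromosome_class))
    stop("invalid chromosome_class")
  if (!all(variants$consequence %in% .vocab$consequence))
    stop("invalid consequence")
  structure(list(nPatients = as.integer(nPatients), sexRatio = sexRatio,
                 variants = as.data.frame(variants),
                 seed = as.integer(seed)),
            class = "SyntheticCohortSpec")
}

## Patients and sexes of a spec (deterministic: first nMale are male).
.specCohort <- function(spec) {
  nMale <- round(spec$nPatients * spec$sexRatio)
  Cohort(sprintf("S%03d", seq_len(spec$nPatients)),
         c(rep("male", nMale), rep("female", spec$nPatients - nMale)))
}

#' Simulate genotypes for a synthetic cohort
#'
#' Draws Hardy-Weinberg genotypes per patient and variant: autosomal
#' genotypes are Binomial(2, AF); on the X chromosome females draw
#' Binomial(2, AF) while males draw Bernoulli(AF) and are recorded as
#' hemizygous. Only carrier observations are emitted (dose >= 1), matching
#' the shape of an annotated variant table. Each variant's predictor
#' profile is generated once (via \code{\link{simulatePredictors}}) and
#' shared by its carriers. Identical seeds give byte-identical output.
#'
#' @param spec a \code{\link{syntheticCohortSpec}}.
#' @param discordance per-variant probability that one predictor disagrees
#'   with the ground truth (default 0.1).
#' @return a list: \code{variants} (a \code{\link{VariantTable}} of carrier
#'   observations), \code{cohort} (the \code{\link{Cohort}}), and
#'   \code{truth} (the spec's variant data.frame with an \code{nt_change}
#'   key column added).
#' @export
simulateGenotypes <- function(spec, discordance = 0.1) {
  stopifnot(inherits(spec, "SyntheticCohortSpec"))
  cohort <- .specCohort(spec)
  sexes <- patientSexes(cohort)
  ids <- patientIds(cohort)
  vs <- spec$variants
  vs$nt_change <- sprintf("c.%dA>G", 1000L + seq_len(nrow(vs)))
  rows <- list()
  for (i in seq_len(nrow(vs))) {
    af <- vs$allele_freq[i]
    isX <- vs$chromosome_class[i] == "X"
    doses <- .withSeed(.deriveSeed(spec$seed, paste0("genotypes", i)), {
      vapply(seq_along(ids), function(j) {
        if (isX && sexes[j] == "male") stats::rbinom(1, 1, af)
        else stats::rbinom(1, 2, af)
      }, numeric(1))
    })
    prof <- simulatePredictors(vs$true_deleterious[i], vs$consequence[i],
                               seed = .deriveSeed(spec$seed,
                                                  paste0("predictors", i)),
                               discordance = discordance)
    carriers <- which(doses >= 1)
    for (j in carriers) {
      zyg <- if (isX && sexes[j] == "male") "hemi"
             else if (doses[j] == 2) "hom" else "het"
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = ids[j], gene = vs$gene[i],
        dbsnp = sprintf("rsSIM%05d", i), nt_change = vs$nt_change[i],
        consequence = vs$consequence[i],
        aa_change = sprintf("p.A%dV", i),
        sift_label = prof$sift_label, sift_score = prof$sift_score,
        pp2_humdiv_label = prof$pp2_humdiv_label,
        pp2_humdiv_score = prof$pp2_humdiv_score,
        pp2_humvar_label = prof$pp2_humvar_label,
        pp2_humvar_score = prof$pp2_humvar_score,
        ma_label = prof$ma_label, ma_score = prof$ma_score,
        cadd_phred = prof$cadd_phred,
        loftool_label = prof$loftool_label,
        loftool_score = prof$loftool_score,
        allele_freq = af, freq_scope = "latino",
        zygosity = zyg,
        chromosome_class = vs$chromosome_class[i],
        inheritance = "NR", panel = "motile", clinical_class = "VUS",
        stringsAsFactors = FALSE)
    }
  }
  d <- if (length(rows)) do.call(rbind, rows) else .emptyVariantData()
  list(variants = VariantTable(d), cohort = cohort, truth = vs)
}

#' Simulate a predictor profile conditional on ground truth
#'
#' Draws an in-silico predictor profile for a variant of known
#' deleteriousness. Deleterious missense truth draws SIFT scores U(0, 0.05)
#' with label \code{D}, PolyPhen2 scores U(0.9, 1) with label \code{PD} and
#' a MutationAssessor label \code{M}/\code{H}; benign truth draws SIFT
#' U(0.2, 1) with label \code{T}, PolyPhen2 U(0, 0.3) with label \code{B}
#' and MutationAssessor \code{N}/\code{L}. LoF/splice classes draw CADD
#' PHRED U(25, 45) (deleterious) vs U(5, 15) (benign). With probability
#' \code{discordance} exactly one missense predictor (or the CADD range for
#' LoF classes) is drawn from the opposite condition, exercising the
#' 2-of-3 consensus logic.
#'
#' @param trueDeleterious logical ground truth.
#' @param consequence consequence class.
#' @param seed integer seed (mandatory).
#' @param discordance probability of one discordant predictor (default 0.1).
#' @return a one-row list of the predictor fields.
#' @export
simulatePredictors <- function(trueDeleterious, consequence, seed,
                               discordance = 0.1) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(consequence %in% .vocab$consequence)
  .withSeed(seed, {
    prof <- list(sift_label = NA_character_, sift_score = NA_real_,
                 pp2_humdiv_label = NA_character_,
                 pp2_humdiv_score = NA_real_,
                 pp2_humvar_label = NA_character_,
                 pp2_humvar_score = NA_real_,
                 ma_label = NA_character_, ma_score = NA_real_,
                 cadd_phred = NA_real_,
                 loftool_label = NA_character_, loftool_score = NA_real_)
    flip <- stats::runif(1) < discordance
    if (consequence == "missense") {
      conds <- rep(trueDeleterious, 3)
      if (flip) {
        which.flip <- sample.int(3, 1)
        conds[which.flip] <- !conds[which.flip]
      }
      prof[c("sift_label", "sift_score")] <- .drawSift(conds[1])
      pp2 <- .drawPp2(conds[2])
      prof[c("pp2_humdiv_label", "pp2_humdiv_score",
             "pp2_humvar_label", "pp2_humvar_score")] <- pp2
      prof[c("ma_label", "ma_score")] <- .drawMa(conds[3])
    } else {
      cond <- if (flip) !trueDeleterious else trueDeleterious
      prof$cadd_phred <- if (cond) stats::runif(1, 25, 45)
                         else stats::runif(1, 5, 15)
    }
    prof
  })
}

.drawSift <- function(deleterious) {
  if (deleterious) list("D", stats::runif(1, 0, 0.05))
  else list("T", stats::runif(1, 0.2, 1))
}

.drawPp2 <- function(deleterious) {
  if (deleterious)
    list("PD", stats::runif(1, 0.9, 1), "PD", stats::runif(1, 0.9, 1))
  else
    list("B", stats::runif(1, 0, 0.3), "B", stats::runif(1, 0, 0.3))
}

.drawMa <- function(deleterious) {
  if (deleterious)
    list(sample(c("M", "H"), 1), stats::runif(1, 2, 4.5))
  else
    list(sample(c("N", "L"), 1), stats::runif(1, -2, 1.9))
}

#' Simulate a planted-partition interaction graph
#'
#' Stochastic block model: \code{nBlocks} blocks of \code{blockSize} nodes;
#' each within-block pair is an edge with probability \code{pWithin}, each
#' between-block pair with probability \code{pBetween}. Present edges carry
#' confidences U(0.4, 0.95). The ground-truth block labels are returned for
#' clustering-recovery tests.
#'
#' @param nBlocks,blockSize number and size of planted blocks.
#' @param pWithin,pBetween edge probabilities in [0, 1].
#' @param seed integer seed (mandatory).
#' @return a list: \code{graph} (an \code{\link{InteractionGraph}}) and
#'   \code{truth} (named integer block labels).
#' @examples
#' sg <- simulateGraph(3, 10, 0.9, 0.05, seed = 7)
#' nClusters(mcl(sg$graph))
#' @export
simulateGraph <- function(nBlocks, blockSize, pWithin, pBetween, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(pWithin >= 0, pWithin <= 1, pBetween >= 0, pBetween <= 1)
  n <- nBlocks * blockSize
  nodes <- sprintf("G%03d", seq_len(n))
  truth <- rep(seq_len(nBlocks), each = blockSize)
  names(truth) <- nodes
  .withSeed(.deriveSeed(seed, "graph"), {
    pairs <- utils::combn(n, 2)
    sameBlock <- truth[pairs[1, ]] == truth[pairs[2, ]]
    pEdge <- ifelse(sameBlock, pWithin, pBetween)
    present <- stats::runif(ncol(pairs)) < pEdge
    conf <- stats::runif(sum(present), 0.4, 0.95)
    edges <- data.frame(from = nodes[pairs[1, present]],
                        to = nodes[pairs[2, present]],
                        confidence = conf, stringsAsFactors = FALSE)
    list(graph = InteractionGraph(edges, nodes = nodes), truth = truth)
  })
}
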