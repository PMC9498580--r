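## Cohort-level aggregation statistics: binomial probability of the observed
## alternate-allele count given a reference population frequency, and an
## exact two-sided 2x2 test for sex differences in allele frequency.

#' Binomial point probability
#'
#' P(X = k) for X ~ Binomial(n, p), evaluated in log space
#' (\code{lchoose(n, k) + k log p + (n - k) log(1 - p)}) for numerical
#' stability at small p and moderate n.
#'
#' This is the headline aggregation statistic for a recurrent variant: the
#' probability of drawing exactly \code{k} alternate alleles among the
#' cohort's \code{n} alleles when the reference population frequency is
#' \code{p}. It is a point mass, \emph{not} a calibrated tail p-value; see
#' \code{\link{binomialUpperTail}} for the "k or more" probability.
#'
#' @param k observed count(s), \code{0 <= k <= n}.
#' @param n number of trials (cohort allele number).
#' @param p success probability (reference allele frequency) in [0, 1].
#' @return numeric vector of probabilities.
#' @examples
#' binomialPointProb(2, 22, 0.0530)   # ~0.2184
#' binomialPointProb(5, 22, 0.1021)   # < 0.05
#' @export
binomialPointProb <- function(k, n, p) {
  .checkBinomialArgs(k, n, p)
  logTerm <- function(kk) {
    lp <- lchoose(n, kk)
    if (kk > 0) lp <- lp + kk * log(p)
    if (n - kk > 0) lp <- lp + (n - kk) * log1p(-p)
    lp
  }
  ## handle p = 0 / p = 1 degenerately (0 * log 0 := 0)
  vapply(k, function(kk) {
    if (p == 0) return(as.numeric(kk == 0))
    if (p == 1) return(as.numeric(kk == n))
    exp(logTerm(kk))
  }, numeric(1))
}

#' Binomial upper-tail probability
#'
#' P(X >= k) for X ~ Binomial(n, p): the sum of the point masses from
#' \code{k} to \code{n}. This is the calibrated "k or more alternate
#' alleles" probability.
#'
#' @inheritParams binomialPointProb
#' @return numeric vector of tail probabilities.
#' @examples
#' binomialUpperTail(0, 22, 0.053)  # exactly 1
#' binomialUpperTail(2, 22, 0.053)  # ~0.327
#' @export
binomialUpperTail <- function(k, n, p) {
  .checkBinomialArgs(k, n, p)
  vapply(k, function(kk) {
    if (kk == 0) return(1)
    sum(binomialPointProb(kk:n, n, p))
  }, numeric(1))
}

.checkBinomialArgs <- function(k, n, p) {
  if (length(n) != 1L || length(p) != 1L)
    stop("n and p must be scalars")
  if (any(k != floor(k)) || n != floor(n))
    stop("domain error: k and n must be integers")
  if (any(k < 0) || any(k > n))
    stop("domain error: k must satisfy 0 <= k <= n")
  if (is.na(p) || p < 0 || p > 1)
    stop("domain error: p must lie in [0, 1]")
  invisible(TRUE)
}

#' Aggregate one variant across the cohort
#'
#' Combines \code{\link{alleleCount}} with the binomial point and upper-tail
#' probabilities at the variant's reference population frequency. Novel
#' variants (no reference frequency) yield an explicit not-computable
#' result, never a silent skip.
#'
#' @param x a \code{\link{VariantTable}} of observations of one variant.
#' @param cohort a \code{\link{Cohort}}.
#' @param pRef reference allele frequency; defaults to the (unique) value
#'   carried by the records.
#' @param mode which probability is the headline number: \code{"point"}
#'   (default, the conventional report statistic) or \code{"upper_tail"}
#'   (the calibrated "k or more" probability). Both are always computed.
#' @return an \code{\link{AggregationResult}}.
#' @examples
#' vt <- tgaStudyVariants()
#' d <- variantData(vt)
#' dnah9 <- VariantTable(d[d$gene == "DNAH9" & d$nt_change == "c.3050A>G", ])
#' aggregateVariant(dnah9, tgaStudyCohort())
#' @export
aggregateVariant <- function(x, cohort, pRef = NULL,
                             mode = c("point", "upper_tail")) {
  mode <- match.arg(mode)
  stopifnot(is(x, "VariantTable"))
  d <- variantData(x)
  ac <- alleleCount(x, cohort)
  scope <- unique(d$freq_scope[!is.na(d$freq_scope)])
  if (is.null(pRef)) {
    freqs <- unique(d$allele_freq[!is.na(d$allele_freq)])
    if (length(freqs) > 1L)
      stop("validation error: records carry conflicting reference ",
           "frequencies: ", paste(freqs, collapse = ", "))
    pRef <- if (length(freqs)) freqs else NA_real_
  }
  if (is.na(pRef)) {
    return(new("AggregationResult",
               gene = d$gene[1], ntChange = d$nt_change[1],
               k = ac$k, n = ac$n, pRef = NA_real_,
               freqScope = NA_character_,
               pointProb = NA_real_, tailProb = NA_real_,
               modeUsed = mode, computable = FALSE,
               note = "no reference allele frequency (novel variant)"))
  }
  new("AggregationResult",
      gene = d$gene[1], ntChange = d$nt_change[1],
      k = ac$k, n = ac$n, pRef = pRef,
      freqScope = if (length(scope)) scope[1] else "latino",
      pointProb = binomialPointProb(ac$k, ac$n, pRef),
      tailProb = binomialUpperTail(ac$k, ac$n, pRef),
      modeUsed = mode, computable = TRUE, note = "")
}

#' Aggregate every variant of a table across the cohort
#'
#' Groups a variant table by (gene, cDNA change), collapses cross-panel
#' repeats, and aggregates each variant. By default only recurrent variants
#' (observed allele count >= \code{minK}) are reported, plus every
#' frequency-less variant flagged not-computable.
#'
#' @param x a \code{\link{VariantTable}}.
#' @param cohort a \code{\link{Cohort}}.
#' @param mode headline statistic, as in \code{\link{aggregateVariant}}.
#' @param minK minimum observed allele count for a computable variant to be
#'   reported (default 2, i.e. recurrent variants).
#' @return a data.frame with one row per reported variant (the
#'   \code{\link{AggregationResult}} fields), sorted by gene then cDNA
#'   change.
#' @export
aggregateCohort <- function(x, cohort, mode = c("point", "upper_tail"),
                            minK = 2L) {
  mode <- match.arg(mode)
  stopifnot(is(x, "VariantTable"))
  d <- variantData(x)
  groups <- split(seq_len(nrow(d)), paste(d$gene, d$nt_change, sep = "\r"))
  rows <- lapply(groups, function(idx) {
    sub <- VariantTable(d[idx, , drop = FALSE])
    freqs <- unique(d$allele_freq[idx][!is.na(d$allele_freq[idx])])
    if (length(freqs) > 1L) {
      ## published tables occasionally disagree on a variant's frequency
      ## across panels; surface this as a flagged row, never pick silently
      res <- aggregateVariant(sub, cohort, pRef = NA_real_, mode = mode)
      res@note <- paste0("conflicting reference frequencies: ",
                         paste(freqs, collapse = " vs "))
      return(as.data.frame(res))
    }
    res <- aggregateVariant(sub, cohort, mode = mode)
    if (res@computable && res@k < minK) NULL else as.data.frame(res)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene = character(), nt_change = character(),
                      k = integer(), n = integer(), p_ref = numeric(),
                      freq_scope = character(), point_prob = numeric(),
                      tail_prob = numeric(), mode_used = character(),
                      computable = logical(), note = character(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$gene, out$nt_change), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value under the probability-ordering convention: with
#' margins fixed, the hypergeometric probabilities of all tables no more
#' probable than the observed one (within relative tolerance 1e-7) are
#' summed. Tables with a zero row or column margin give p = 1 exactly.
#'
#' @param tab a 2x2 matrix of nonnegative integer counts (e.g. alternate /
#'   reference alleles by male / female).
#' @return the two-sided p-value in (0, 1].
#' @examples
#' fisherExact2x2(matrix(c(5, 0, 0, 5), 2))  # 2/252
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("domain error: table must be 2x2")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != floor(tab)))
    stop("domain error: counts must be nonnegative integers")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  pObs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Compare allele frequency between sexes
#'
#' Builds the 2x2 contingency table of alternate vs reference alleles by sex
#' and applies \code{\link{fisherExact2x2}}.
#'
#' @param kMale,nMale alternate-allele count and total allele number in
#'   males.
#' @param kFemale,nFemale the same in females.
#' @return a list with the 2x2 \code{table} (rows alt/ref, columns
#'   male/female) and the two-sided \code{p_value}.
#' @export
sexFrequencyTest <- function(kMale, nMale, kFemale, nFemale) {
  if (kMale > nMale || kFemale > nFemale)
    stop("domain error: counts exceed totals")
  tab <- matrix(c(kMale, nMale - kMale, kFemale, nFemale - kFemale), 2, 2,
                dimnames = list(c("alt", "ref"), c("male", "female")))
  list(table = tab, p_value = fisherExact2x2(tab))
}
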