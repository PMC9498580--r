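# Builders for in-code fixtures: a one-row variant observation with sensible
# defaults, overridable per test.

variantRow <- function(patient_id = "P1", gene = "GENE1", dbsnp = "rs1",
                       nt_change = "c.100A>G", consequence = "missense",
                       aa_change = "p.K34R",
                       sift_label = "D", sift_score = 0.01,
                       pp2_humdiv_label = "PD", pp2_humdiv_score = 0.99,
                       pp2_humvar_label = "PD", pp2_humvar_score = 0.95,
                       ma_label = "M", ma_score = 2.5,
                       cadd_phred = NA_real_,
                       loftool_label = NA_character_,
                       loftool_score = NA_real_,
                       allele_freq = 0.01, freq_scope = "latino",
                       zygosity = "het", chromosome_class = "autosomal",
                       inheritance = "AR", panel = "motile",
                       clinical_class = "VUS") {
  data.frame(patient_id = patient_id, gene = gene, dbsnp = dbsnp,
             nt_change = nt_change, consequence = consequence,
             aa_change = aa_change,
             sift_label = sift_label, sift_score = sift_score,
             pp2_humdiv_label = pp2_humdiv_label,
             pp2_humdiv_score = pp2_humdiv_score,
             pp2_humvar_label = pp2_humvar_label,
             pp2_humvar_score = pp2_humvar_score,
             ma_label = ma_label, ma_score = ma_score,
             cadd_phred = cadd_phred, loftool_label = loftool_label,
             loftool_score = loftool_score,
             allele_freq = allele_freq, freq_scope = freq_scope,
             zygosity = zygosity, chromosome_class = chromosome_class,
             inheritance = inheritance, panel = panel,
             clinical_class = clinical_class, stringsAsFactors = FALSE)
}

lofRow <- function(..., consequence = "splice", cadd_phred = 25,
                   sift_label = NA_character_, sift_score = NA_real_,
                   pp2_humdiv_label = NA_character_,
                   pp2_humdiv_score = NA_real_,
                   pp2_humvar_label = NA_character_,
                   pp2_humvar_score = NA_real_,
                   ma_label = NA_character_, ma_score = NA_real_,
                   aa_change = NA_character_) {
  variantRow(..., consequence = consequence, cadd_phred = cadd_phred,
             sift_label = sift_label, sift_score = sift_score,
             pp2_humdiv_label = pp2_humdiv_label,
             pp2_humdiv_score = pp2_humdiv_score,
             pp2_humvar_label = pp2_humvar_label,
             pp2_humvar_score = pp2_humvar_score,
             ma_label = ma_label, ma_score = ma_score,
             aa_change = aa_change)
}

studyCohort <- function() tgaStudyCohort()

# Independent Fisher oracle: enumerate all 2x2 tables with the observed
# margins, computing each table's conditional probability from factorials
# (no dhyper), and sum those <= the observed probability.
fisherEnumerationOracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  c2 <- sum(tab[, 2]); n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  tabProb <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    if (b < 0 || cc < 0 || d < 0) return(NA_real_)
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
          lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(cc) -
          lfactorial(d))
  }
  support <- 0:min(r1, c1)
  probs <- vapply(support, tabProb, numeric(1))
  probs <- probs[!is.na(probs)]
  pObs <- tabProb(tab[1, 1])
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Independent binomial oracle: arrangement counting by explicit enumeration
# of success-position subsets (combn), no lchoose/dbinom.
binomialEnumerationOracle <- function(k, n, p) {
  arrangements <- if (k == 0 || k == n) 1 else ncol(utils::combn(n, k))
  arrangements * p^k * (1 - p)^(n - k)
}
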