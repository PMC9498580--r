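table1 <- function() suppressMessages(
  readVariantTable(tgaExampleFile("table1_tga_panel.tsv")))

test_that("missense predictor abnormalities follow the label-first rules", {
  vt <- table1()
  d <- variantData(vt)
  abn <- predictorAbnormalities(vt)
  ## novel KMT2D p.P183S: T/PD/PD/N -> only PolyPhen2 abnormal
  expect_identical(abn[[which(d$nt_change == "c.547C>T")]], "PP2")
  ## KDM6A p.R78C: T/B/B/L -> nothing abnormal
  expect_identical(abn[[which(d$gene == "KDM6A")]], character(0))
  ## all three abnormal
  allAbn <- VariantTable(variantRow(sift_label = "D", pp2_humdiv_label = "PD",
                                    pp2_humvar_label = "PD", ma_label = "H"))
  expect_setequal(predictorAbnormalities(allAbn)[[1]],
                  c("SIFT", "PP2", "MA"))
  ## the SIFT label is trusted over the numeric score (printed "D (0.085)")
  megf8 <- VariantTable(variantRow(sift_label = "D", sift_score = 0.085,
                                   pp2_humdiv_label = "B",
                                   pp2_humdiv_score = 0.1,
                                   pp2_humvar_label = "B",
                                   pp2_humvar_score = 0.1,
                                   ma_label = "N", ma_score = 0.3))
  expect_identical(predictorAbnormalities(megf8)[[1]], "SIFT")
  ## fallback threshold applies only when the label is absent
  noLabel <- VariantTable(variantRow(sift_label = NA, sift_score = 0.04,
                                     ma_label = "N"))
  expect_true("SIFT" %in% predictorAbnormalities(noLabel)[[1]])
  ## non-missense rows yield NA
  expect_true(is.na(predictorAbnormalities(VariantTable(lofRow()))[[1]]))
})

test_that("composite classification reproduces the TGA-panel fixture calls", {
  vt <- table1()
  d <- variantData(vt)
  calls <- classifyVariants(vt)
  expected <- c("c.232C>T" = FALSE, "c.187G>A" = FALSE, "c.404C>T" = FALSE,
                "c.547C>T" = TRUE, "c.1315C>T" = TRUE, "c.15686G>A" = TRUE,
                "c.2344C>T" = TRUE, "c.203G>A" = TRUE, "c.1852C>G" = TRUE,
                "c.470+3A>G" = FALSE, "c.2561C>T" = TRUE, "c.170C>T" = TRUE,
                "c.2089-2A>G" = TRUE, "c.1110T>G" = FALSE)
  expect_identical(stats::setNames(calls$deleterious, d$nt_change),
                   expected)
  expect_identical(calls$rule_fired[d$nt_change == "c.547C>T"],
                   "missense_novel_one")
  expect_identical(calls$rule_fired[d$nt_change == "c.2089-2A>G"],
                   "lof_cadd")
})

test_that("the printed cilia-panel rows all classify deleterious", {
  for (f in c("table2_motile.tsv", "table3_nonmotile.tsv",
              "table4_ciliogenesis.tsv")) {
    vt <- suppressMessages(readVariantTable(tgaExampleFile(f)))
    calls <- classifyVariants(vt)
    mismatches <- calls[!calls$deleterious, ]
    expect_identical(nrow(mismatches), 0L,
                     info = paste(f, paste(mismatches$nt_change,
                                           collapse = ", ")))
  }
})

test_that("LoF rules: CADD threshold is inclusive, LoF-Tool is the fallback", {
  expect_true(classifyVariants(VariantTable(lofRow(cadd_phred = 20)))$deleterious)
  expect_false(classifyVariants(VariantTable(lofRow(cadd_phred = 19.99)))$deleterious)
  expect_false(classifyVariants(VariantTable(lofRow(cadd_phred = 16.55)))$deleterious)
  expect_true(classifyVariants(VariantTable(lofRow(cadd_phred = 33)))$deleterious)
  lt <- classifyVariants(VariantTable(lofRow(
    cadd_phred = NA, loftool_label = "PD", loftool_score = 0.514,
    consequence = "frameshift")))
  expect_true(lt$deleterious)
  expect_identical(lt$rule_fired, "lof_tool")
  ## CADD, when present, decides even if LoF-Tool says PD
  both <- classifyVariants(VariantTable(lofRow(
    cadd_phred = 10, loftool_label = "PD", loftool_score = 0.5)))
  expect_false(both$deleterious)
  ## the novel-variant one-abnormality rule is missense-only
  novelLof <- classifyVariants(VariantTable(lofRow(dbsnp = "New",
                                                   allele_freq = NA,
                                                   cadd_phred = 15)))
  expect_false(novelLof$deleterious)
})

test_that("deleterious calls are monotone in the abnormality set", {
  base <- list(sift_label = "T", pp2_humdiv_label = "B",
               pp2_humvar_label = "B", ma_label = "N")
  upgrades <- list(SIFT = c(sift_label = "D"),
                   PP2 = c(pp2_humvar_label = "PD"),
                   MA = c(ma_label = "M"))
  for (novel in c(FALSE, TRUE)) {
    for (subset in 0:7) {
      on <- as.logical(bitwAnd(subset, c(1L, 2L, 4L)))
      args <- base
      for (i in which(on)) args[names(upgrades[[i]])] <- upgrades[[i]]
      args$dbsnp <- if (novel) "New" else "rs1"
      args$allele_freq <- if (novel) NA_real_ else 0.01
      vt <- VariantTable(do.call(variantRow, args))
      del <- classifyVariants(vt)$deleterious
      ## flipping any remaining predictor to abnormal must not revoke a call
      for (i in which(!on)) {
        args2 <- args
        args2[names(upgrades[[i]])] <- upgrades[[i]]
        del2 <- classifyVariants(VariantTable(do.call(variantRow,
                                                      args2)))$deleterious
        expect_true(del2 >= del)
      }
    }
  }
})

test_that("panel filter keeps all TGA-panel rows but only VUS+ cilia rows", {
  rows <- rbind(
    variantRow(panel = "tga_associated", clinical_class = "benign",
               nt_change = "c.1A>G"),
    variantRow(panel = "motile", clinical_class = "benign",
               nt_change = "c.2A>G"),
    variantRow(panel = "motile", clinical_class = "VUS",
               nt_change = "c.3A>G"),
    variantRow(panel = "non_motile", clinical_class = "likely_pathogenic",
               nt_change = "c.4A>G"),
    variantRow(panel = "ciliogenesis_trafficking",
               clinical_class = "likely_benign", nt_change = "c.5A>G"))
  kept <- variantData(filterVariants(VariantTable(rows)))
  expect_identical(kept$nt_change, c("c.1A>G", "c.3A>G", "c.4A>G"))
  ## empty input passes through
  empty <- VariantTable(rows[0, ])
  expect_identical(nVariants(filterVariants(empty)), 0L)
  ## panel membership is enforced when panel definitions are supplied
  panels <- list(tga_associated = GenePanel("tga_associated", "OTHER"),
                 motile = GenePanel("motile", "GENE1"),
                 non_motile = GenePanel("non_motile", "GENE1"),
                 ciliogenesis_trafficking =
                   GenePanel("ciliogenesis_trafficking", "GENE1"))
  expect_error(filterVariants(VariantTable(rows), panels),
               "not in its declared panel")
})

test_that("compound heterozygosity needs two distinct deleterious het variants", {
  two <- rbind(
    variantRow(patient_id = "T180401", gene = "DNAH9",
               nt_change = "c.3050A>G", allele_freq = 0.053),
    lofRow(patient_id = "T180401", gene = "DNAH9",
           nt_change = "c.5151+1G>A", cadd_phred = 34,
           allele_freq = 1.1e-4))
  s <- summarizeGeneGenotype(VariantTable(two))
  expect_true(s$compound_het)
  expect_identical(s$n_deleterious_het, 2L)

  one <- VariantTable(two[1, ])
  expect_false(summarizeGeneGenotype(one)$compound_het)

  ## two het variants, only one deleterious
  mixed <- rbind(two[1, ],
                 variantRow(patient_id = "T180401", gene = "DNAH9",
                            nt_change = "c.9999A>G", sift_label = "T",
                            pp2_humdiv_label = "B", pp2_humvar_label = "B",
                            ma_label = "N"))
  expect_false(summarizeGeneGenotype(VariantTable(mixed))$compound_het)

  ## mixed patients or genes are a precondition error
  bad <- rbind(two[1, ], variantRow(patient_id = "T999", gene = "DNAH9",
                                    nt_change = "c.1X>Y"))
  expect_error(summarizeGeneGenotype(VariantTable(bad)),
               "one patient and one gene")
})

test_that("whole-study genotype summaries find exactly one compound heterozygote", {
  vt <- tgaStudyVariants()
  gs <- geneGenotypeSummaries(vt)
  ch <- gs[gs$compound_het, ]
  expect_identical(nrow(ch), 1L)
  expect_identical(ch$patient_id, "T180401")
  expect_identical(ch$gene, "DNAH9")
})

test_that("allele counting sums doses against the right denominator", {
  co <- studyCohort()
  vt <- tgaStudyVariants()
  d <- variantData(vt)

  dnah9 <- d[d$gene == "DNAH9" & d$nt_change == "c.3050A>G", ]
  expect_identical(alleleCount(VariantTable(dnah9), co), list(k = 2L, n = 22L))
  ## record order is irrelevant
  expect_identical(alleleCount(VariantTable(dnah9[2:1, ]), co),
                   list(k = 2L, n = 22L))

  ## two homozygotes + one heterozygote -> 5 alleles (the study's text
  ## scenario for PIBF1)
  pibf1 <- rbind(
    variantRow(patient_id = "T180801", gene = "PIBF1",
               nt_change = "c.1214G>A", zygosity = "hom",
               allele_freq = 0.1021),
    variantRow(patient_id = "T181201", gene = "PIBF1",
               nt_change = "c.1214G>A", zygosity = "hom",
               allele_freq = 0.1021),
    variantRow(patient_id = "T180201", gene = "PIBF1",
               nt_change = "c.1214G>A", zygosity = "het",
               allele_freq = 0.1021))
  expect_identical(alleleCount(VariantTable(pibf1), co),
                   list(k = 5L, n = 22L))

  ## X-linked: one hemizygous male against 2*2 + 9 = 13 alleles
  xv <- variantRow(patient_id = "T180801", gene = "OFD1",
                   nt_change = "c.2482T>G", zygosity = "hemi",
                   chromosome_class = "X", allele_freq = 5.17e-5)
  expect_identical(alleleCount(VariantTable(xv), co), list(k = 1L, n = 13L))

  ## identical cross-panel repeats collapse; conflicting zygosity errors
  expect_identical(alleleCount(VariantTable(rbind(pibf1, pibf1[1, ])), co),
                   list(k = 5L, n = 22L))
  conflict <- rbind(pibf1, transform(pibf1[1, ], zygosity = "het"))
  expect_error(alleleCount(VariantTable(conflict), co),
               "conflicting duplicate")
})
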