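test_that("packaged study tables read with the printed row counts and pass validity", {
  counts <- c(table1_tga_panel.tsv = 14L, table2_motile.tsv = 31L,
              table3_nonmotile.tsv = 13L, table4_ciliogenesis.tsv = 19L)
  for (f in names(counts)) {
    vt <- suppressMessages(readVariantTable(tgaExampleFile(f)))
    expect_s4_class(vt, "VariantTable")
    expect_true(validObject(vt))
    expect_identical(nVariants(vt), counts[[f]])
  }
})

test_that("frequency dialect: asterisk marks global scope, 'New' means absent", {
  vt <- suppressMessages(
    readVariantTable(tgaExampleFile("table1_tga_panel.tsv")))
  d <- variantData(vt)
  kdm6a <- d[d$gene == "KDM6A", ]
  expect_equal(kdm6a$allele_freq, 3.95e-4)
  expect_identical(kdm6a$freq_scope, "global")
  kmt2d <- d[d$gene == "KMT2D" & d$nt_change == "c.547C>T", ]
  expect_identical(kmt2d$dbsnp, "New")
  expect_true(is.na(kmt2d$allele_freq))
  ## plain cells default to the Latino stratum
  megf8 <- d[d$nt_change == "c.1315C>T", ]
  expect_identical(megf8$freq_scope, "latino")
})

test_that("scientific-notation forms parse equivalently", {
  expect_equal(VariantTriage:::.parseScientific(
    c("3.95 x 10^-4", "3.95e-4", "2.897 x10^-5", "0.1021",
      "5.30 × 10−2")),
    c(3.95e-4, 3.95e-4, 2.897e-5, 0.1021, 5.30e-2))
})

test_that("header-only file yields an empty table; malformed input errors name the problem", {
  tmp <- tempfile(fileext = ".tsv")
  vt0 <- suppressMessages(
    readVariantTable(tgaExampleFile("table1_tga_panel.tsv")))
  writeVariantTable(VariantTable(variantData(vt0)[0, ]), tmp)
  expect_identical(nVariants(readVariantTable(tmp)), 0L)

  ## missing mandatory column
  d <- utils::read.delim(tgaExampleFile("table1_tga_panel.tsv"),
                         colClasses = "character")
  utils::write.table(d[-2], tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(readVariantTable(tmp), "missing mandatory column")

  ## consequence outside the vocabulary names the row
  d2 <- utils::read.delim(tgaExampleFile("table1_tga_panel.tsv"),
                          colClasses = "character", check.names = FALSE)
  d2$consequence[3] <- "synonymous"
  utils::write.table(d2, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readVariantTable(tmp), "consequence.*3")

  ## malformed numeric cell is reported with its row
  d3 <- utils::read.delim(tgaExampleFile("table1_tga_panel.tsv"),
                          colClasses = "character", check.names = FALSE)
  d3$sift_score[2] <- "abc"
  utils::write.table(d3, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readVariantTable(tmp), "malformed numeric.*row\\(s\\) 2")
})

test_that("variant tables round-trip through write/read unchanged", {
  vt <- tgaStudyVariants()
  tmp <- tempfile(fileext = ".tsv")
  writeVariantTable(vt, tmp)
  back <- suppressMessages(readVariantTable(tmp))
  expect_equal(variantData(back), variantData(vt))
})

test_that("variant-table validity rejects inconsistent records", {
  expect_error(VariantTable(variantRow(dbsnp = "New", allele_freq = 0.01)),
               "novel")
  expect_error(VariantTable(variantRow(zygosity = "hemi",
                                       chromosome_class = "autosomal")),
               "hemizygous")
  expect_error(VariantTable(variantRow(sift_score = 1.5)), "sift_score")
  ## missense row with no predictor at all
  expect_error(VariantTable(variantRow(
    sift_label = NA, sift_score = NA, pp2_humdiv_label = NA,
    pp2_humdiv_score = NA, pp2_humvar_label = NA, pp2_humvar_score = NA,
    ma_label = NA, ma_score = NA)), "without any missense predictor")
  ## LoF row with neither CADD nor LoF-Tool
  expect_error(VariantTable(lofRow(cadd_phred = NA)), "without CADD")
})

test_that("rsID rows with absent frequency are kept and surfaced as notes", {
  vt <- suppressMessages(readVariantTable(tgaExampleFile("table2_motile.tsv")))
  notes <- annotationNotes(vt)
  expect_true(any(grepl("MNS1", notes)))
  ## the printed female hemizygous call is surfaced once the cohort is known
  notes2 <- annotationNotes(vt, studyCohort())
  expect_true(any(grepl("T181001 OFD1", notes2)))
})

test_that("gene panels read with dedup, comments and whitespace handling", {
  tmp <- tempfile(fileext = ".txt")
  writeLines(c("# motile cilia", "DNAH9", " DNAH11 ", "ODAD4", "DNAH9"), tmp)
  p <- readGenePanel(tmp, "motile")
  expect_setequal(panelGenes(p), c("DNAH9", "DNAH11", "ODAD4"))
  expect_length(panelGenes(p), 3L)

  writeLines(c("# only", "# comments"), tmp)
  expect_error(readGenePanel(tmp), "no gene symbols")
})

test_that("edge lists: STRING scaling, symmetric collapse, self-edge drop, shuffle invariance", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines("DNAH9\tHYDIN\t900", tmp)
  g <- readEdgeList(tmp, scoreScale = "string_999")
  expect_equal(edgeTable(g)$confidence, 0.9)

  writeLines(c("A\tB\t500", "B\tA\t500"), tmp)
  g <- readEdgeList(tmp, scoreScale = "string_999")
  expect_equal(nrow(edgeTable(g)), 1L)

  writeLines(c("A\tB\t500", "B\tA\t700"), tmp)
  expect_equal(edgeTable(readEdgeList(tmp, "string_999"))$confidence, 0.7)

  writeLines("A\tA\t500", tmp)
  g <- readEdgeList(tmp, scoreScale = "string_999")
  expect_identical(graphNodes(g), "A")
  expect_equal(nrow(edgeTable(g)), 0L)

  lines <- c("A\tB\t900", "B\tC\t400", "C\tD\t150", "A\tD\t700")
  writeLines(lines, tmp)
  et1 <- edgeTable(readEdgeList(tmp, "string_999"))
  writeLines(rev(lines), tmp)
  et2 <- edgeTable(readEdgeList(tmp, "string_999"))
  expect_equal(et1, et2)

  writeLines("A\tB\t1500", tmp)
  expect_error(readEdgeList(tmp, "string_999"), "outside \\[0, 1\\]")
})
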