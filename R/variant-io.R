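## Parse decimal numbers that may use spreadsheet scientific notation
## ("3.95 x 10^-4", with or without spaces, ASCII or Unicode multiplication
## sign and minus) in addition to plain "3.95e-4" forms. Returns NA for
## unparseable cells; callers decide whether that is an error.
.parseScientific <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("×", "x", x)        # multiplication sign
  x <- gsub("−", "-", x)        # Unicode minus
  out <- suppressWarnings(as.numeric(x))
  needs <- is.na(out) & nzchar(x)
  if (any(needs)) {
    m <- regmatches(x[needs],
      regexec("^([0-9]*\\.?[0-9]+)\\s*[xX]\\s*10\\^?\\(?([+-]?[0-9]+)\\)?$",
              x[needs]))
    out[needs] <- vapply(m, function(g) {
      if (length(g) == 3L) as.numeric(g[2]) * 10^as.numeric(g[3]) else
        NA_real_
    }, numeric(1))
  }
  out
}

## Frequency cells additionally understand the table dialect: a trailing "*"
## marks a global (rather than Latino-stratum) frequency, and "New"/"NF"/empty
## mean the frequency is absent.
.parseFrequencyCells <- function(cells) {
  cells <- trimws(as.character(cells))
  global <- grepl("\\*\\s*$", cells)
  stripped <- trimws(sub("\\*\\s*$", "", cells))
  absent <- is.na(stripped) | stripped %in% c("", "New", "NF", "NA", ".")
  values <- rep(NA_real_, length(cells))
  values[!absent] <- .parseScientific(stripped[!absent])
  list(values = values, global = global,
       malformed = which(!absent & is.na(values)))
}

.blankToNA <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "NF", ".")] <- NA_character_
  x
}

.numericOrStop <- function(cells, column) {
  cells <- .blankToNA(cells)
  out <- .parseScientific(cells)
  bad <- which(!is.na(cells) & is.na(out))
  if (length(bad))
    stop(sprintf("malformed numeric cell(s) in column '%s', row(s) %s",
                 column, paste(bad, collapse = ", ")), call. = FALSE)
  out
}

#' Read an annotated variant table
#'
#' Reads the tab-separated annotated variant dialect: one row per
#' (patient, variant) observation, a mandatory header naming the canonical
#' columns (see \code{\link{VariantTable}}). Numeric cells accept plain and
#' scientific notation, including the spreadsheet form \code{"3.95 x 10^-4"}.
#' Two dialect quirks of published candidate-gene tables are handled:
#' \itemize{
#'   \item a trailing asterisk on the \code{allele_freq} cell marks a
#'     \emph{global} reference frequency (the default scope being the Latino
#'     population stratum); the asterisk overrides any \code{freq_scope}
#'     column value;
#'   \item the literal \code{"New"} in the \code{dbsnp} column marks a novel
#'     variant, which must have an absent reference frequency; \code{"NF"}
#'     (not found) frequency cells are carried as absent and flagged in the
#'     annotation notes.
#' }
#'
#' @param path path to a UTF-8 TSV file.
#' @return a validated \code{\link{VariantTable}}. Rows whose annotation is
#'   internally inconsistent in ways the study tables themselves exhibit
#'   (an rsID with an absent frequency; a hemizygous call in a female once a
#'   cohort is known) are kept and surfaced via
#'   \code{\link{annotationNotes}}, not silently corrected.
#' @examples
#' vt <- readVariantTable(tgaExampleFile("table1_tga_panel.tsv"))
#' nVariants(vt)
#' @export
readVariantTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL,
                           fileEncoding = "UTF-8")
  missing <- setdiff(.variantColumns, names(raw))
  if (length(missing))
    stop("format error: missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  raw <- raw[.variantColumns]
  if (nrow(raw) == 0L)
    return(VariantTable(.emptyVariantData()))

  freq <- .parseFrequencyCells(raw$allele_freq)
  if (length(freq$malformed))
    stop(sprintf("malformed frequency cell(s) in row(s) %s",
                 paste(freq$malformed, collapse = ", ")), call. = FALSE)

  df <- raw
  for (cc in .characterColumns) df[[cc]] <- .blankToNA(raw[[cc]])
  for (nc in setdiff(.numericColumns, "allele_freq"))
    df[[nc]] <- .numericOrStop(raw[[nc]], nc)
  df$allele_freq <- freq$values
  scope <- df$freq_scope
  scope[is.na(scope)] <- "latino"
  scope[freq$global] <- "global"
  scope[is.na(df$allele_freq)] <- NA_character_
  df$freq_scope <- scope

  vt <- VariantTable(df)
  notes <- annotationNotes(vt)
  if (length(notes))
    message("readVariantTable: ", length(notes),
            " annotation inconsistency/ies noted; see annotationNotes()")
  vt
}

.emptyVariantData <- function() {
  df <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(.variantColumns)),
                    .variantColumns), stringsAsFactors = FALSE)
  for (nc in .numericColumns) df[[nc]] <- numeric(0)
  df
}

#' Surface annotation inconsistencies in a variant table
#'
#' Published candidate-gene tables occasionally carry internally inconsistent
#' annotations. These are preserved on reading and enumerated here rather
#' than silently corrected: an rsID whose reference frequency was not found,
#' and (when a cohort with sexes is supplied) a hemizygous call recorded for
#' a female patient.
#'
#' @param x a \code{\link{VariantTable}}.
#' @param cohort optional \code{\link{Cohort}} enabling sex-aware checks.
#' @return character vector of human-readable notes (empty when clean).
#' @export
annotationNotes <- function(x, cohort = NULL) {
  stopifnot(is(x, "VariantTable"))
  d <- variantData(x)
  notes <- character()
  odd <- which(d$dbsnp != "New" & is.na(d$allele_freq))
  for (i in odd)
    notes <- c(notes, sprintf(
      "row %d (%s %s %s): known rsID but reference frequency not found",
      i, d$patient_id[i], d$gene[i], d$nt_change[i]))
  if (!is.null(cohort)) {
    sexes <- patientSexes(cohort)
    femaleHemi <- which(d$zygosity == "hemi" &
                          sexes[d$patient_id] == "female")
    for (i in femaleHemi)
      notes <- c(notes, sprintf(
        "row %d (%s %s %s): hemizygous call recorded for a female patient",
        i, d$patient_id[i], d$gene[i], d$nt_change[i]))
  }
  notes
}

#' Write an annotated variant table
#'
#' Writes the canonical TSV dialect consumed by \code{\link{readVariantTable}}
#' (plain numeric cells, explicit \code{freq_scope} column). Reading the
#' written file back yields a field-by-field identical table.
#'
#' @param x a \code{\link{VariantTable}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVariantTable <- function(x, path) {
  stopifnot(is(x, "VariantTable"))
  d <- variantData(x)
  out <- d
  for (nc in .numericColumns)
    out[[nc]] <- ifelse(is.na(d[[nc]]), "",
                        format(d[[nc]], digits = 15, scientific = TRUE,
                               trim = TRUE))
  for (cc in .characterColumns)
    out[[cc]] <- ifelse(is.na(d[[cc]]), "", d[[cc]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene panel
#'
#' Plain text, one gene symbol per line; \code{#} starts a comment, blank
#' lines are ignored, whitespace is stripped, duplicates removed.
#'
#' @param path path to the panel file.
#' @param name panel name; defaults to the file name without extension.
#' @return a \code{\link{GenePanel}}.
#' @export
readGenePanel <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  genes <- trimws(lines)
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L)
    stop("validation error: panel file contains no gene symbols: ", path)
  GenePanel(name, genes)
}

#' Read a weighted interaction edge list
#'
#' Reads tab- or space-separated \code{node node score} triples, as exported
#' by protein-interaction databases. With
#' \code{scoreScale = "string_999"} integer combined scores on the 0-999
#' scale are divided by 1000; with \code{"unit"} scores are taken as given.
#' A header line is skipped automatically when its third field is not
#' numeric. Symmetric duplicates are collapsed keeping the maximum
#' confidence; self-edges are dropped (their node is retained).
#'
#' @param path path to the edge-list file.
#' @param scoreScale \code{"unit"} or \code{"string_999"}.
#' @return an \code{\link{InteractionGraph}}.
#' @export
readEdgeList <- function(path, scoreScale = c("unit", "string_999")) {
  scoreScale <- match.arg(scoreScale)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(InteractionGraph(NULL))
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stop(sprintf("edge list line(s) without 3 fields: %s",
                 paste(bad, collapse = ", ")))
  m <- do.call(rbind, fields)
  ## tolerate a header row
  if (is.na(suppressWarnings(as.numeric(m[1, 3])))) m <- m[-1, , drop = FALSE]
  if (nrow(m) == 0L) return(InteractionGraph(NULL))
  score <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(score))
    stop("malformed score cell(s) in edge list row(s) ",
         paste(which(is.na(score)), collapse = ", "))
  conf <- if (scoreScale == "string_999") score / 1000 else score
  if (any(conf < 0 | conf > 1))
    stop("validation error: confidence outside [0, 1] after scaling in ",
         "row(s) ", paste(which(conf < 0 | conf > 1), collapse = ", "))
  InteractionGraph(data.frame(from = m[, 1], to = m[, 2], confidence = conf,
                              stringsAsFactors = FALSE))
}

#' Write an interaction graph as a unit-scale edge list
#'
#' @param x an \code{\link{InteractionGraph}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(x, path) {
  stopifnot(is(x, "InteractionGraph"))
  et <- edgeTable(x)
  utils::write.table(et, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cohort file
#'
#' TSV with columns \code{patient_id} and \code{sex}
#' (\code{male}/\code{female}).
#'
#' @param path path to the cohort file.
#' @return a \code{\link{Cohort}}.
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (!all(c("patient_id", "sex") %in% names(d)))
    stop("format error: cohort file needs columns patient_id, sex")
  Cohort(d$patient_id, trimws(tolower(d$sex)))
}

#' Path to a packaged example file
#'
#' Convenience wrapper around \code{system.file} for the packaged
#' case-study fixtures under \code{extdata/}: the four annotated variant
#' tables of an 11-proband TGA exome cohort, its gene panels, cohort sheet,
#' and a synthetic interaction edge list.
#'
#' @param file file name under \code{extdata/}; with no argument, lists the
#'   available files.
#' @return a file path, or a character vector of file names.
#' @export
tgaExampleFile <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "VariantTriage")))
  p <- system.file("extdata", file, package = "VariantTriage")
  if (!nzchar(p)) stop("no packaged example file named ", file)
  p
}

#' Packaged TGA case-study objects
#'
#' Loaders for the packaged case study: an 11-proband (9 male, 2 female)
#' whole-exome TGA cohort with annotated candidate-gene variants across four
#' panels (TGA-associated, motile cilia, non-motile cilia,
#' ciliogenesis/trafficking).
#'
#' \code{tgaStudyVariants()} reads the four panel tables into one
#' \code{\link{VariantTable}} (77 observations). \code{tgaStudyCohort()}
#' returns the cohort (autosomal allele number 22, X allele number 13).
#' \code{tgaStudyPanels()} returns the four \code{\link{GenePanel}}s.
#' \code{tgaStudyNetwork()} reads the packaged \emph{synthetic}
#' interaction edge list (a stand-in for a database export, for examples
#' and tests).
#'
#' @return see above.
#' @name tgaStudy
NULL

#' @rdname tgaStudy
#' @export
tgaStudyVariants <- function() {
  files <- c("table1_tga_panel.tsv", "table2_motile.tsv",
             "table3_nonmotile.tsv", "table4_ciliogenesis.tsv")
  parts <- lapply(files, function(f)
    variantData(suppressMessages(readVariantTable(tgaExampleFile(f)))))
  VariantTable(do.call(rbind, parts))
}

#' @rdname tgaStudy
#' @export
tgaStudyCohort <- function() readCohort(tgaExampleFile("cohort.tsv"))

#' @rdname tgaStudy
#' @export
tgaStudyPanels <- function() {
  files <- c(tga_associated = "panel_tga_associated.txt",
             motile = "panel_motile.txt",
             non_motile = "panel_non_motile.txt",
             ciliogenesis_trafficking = "panel_ciliogenesis_trafficking.txt")
  lapply(stats::setNames(names(files), names(files)), function(n)
    readGenePanel(tgaExampleFile(files[[n]]), name = n))
}

#' @rdname tgaStudy
#' @export
tgaStudyNetwork <- function() {
  readEdgeList(tgaExampleFile("string_edges_synthetic.tsv"),
               scoreScale = "string_999")
}
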