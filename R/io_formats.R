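#' Read a peptide-level IP-MS intensity table
#'
#' The table is the pipeline's primary input: one row per observed peptide per
#' immunoprecipitation run. Missing observations are encoded by the absence of
#' a row, never by a zero or sentinel intensity, so every stored intensity must
#' be strictly positive.
#'
#' @param path Path to a UTF-8, tab-separated file with header columns
#'   `run_id`, `cell_line`, `condition` (`bait` or `control`), `replicate`,
#'   `protein_accession`, `gene_symbol`, `peptide_sequence`, `intensity`.
#' @return A `data.frame` of class `peptide_table` with validated columns.
#' @export
read_peptide_table <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  as_peptide_table(df)
}

PEPTIDE_COLUMNS <- c("run_id", "cell_line", "condition", "replicate",
                     "protein_accession", "gene_symbol", "peptide_sequence",
                     "intensity")

#' Validate a data frame as a peptide table
#'
#' @param df A data frame with the eight peptide-table columns.
#' @return The validated `peptide_table`.
#' @export
as_peptide_table <- function(df) {
  missing_cols <- setdiff(PEPTIDE_COLUMNS, names(df))
  if (length(missing_cols))
    stop_fmt("peptide table format error: missing column(s) %s",
             paste(missing_cols, collapse = ", "))
  df <- df[PEPTIDE_COLUMNS]
  df$intensity <- suppressWarnings(as.numeric(df$intensity))
  bad <- !is.finite(df$intensity) | df$intensity <= 0
  if (any(bad))
    stop_fmt(paste0("peptide table format error: %d row(s) with non-positive ",
                    "or non-numeric intensity (first offender: row %d); ",
                    "missingness must be encoded by row absence"),
             sum(bad), which(bad)[1])
  df$replicate <- suppressWarnings(as.integer(df$replicate))
  assert_that(all(is.finite(df$replicate) & df$replicate >= 1),
              "peptide table format error: replicate must be a positive integer")
  assert_that(all(df$condition %in% c("bait", "control")),
              "peptide table format error: condition must be 'bait' or 'control'")
  ok_seq <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", df$peptide_sequence)
  if (!all(ok_seq))
    stop_fmt("peptide table format error: invalid peptide sequence '%s'",
             df$peptide_sequence[!ok_seq][1])
  key <- paste(df$run_id, df$protein_accession, df$peptide_sequence, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop_fmt("duplicate (run, accession, peptide) row: run=%s accession=%s peptide=%s",
             df$run_id[i], df$protein_accession[i], df$peptide_sequence[i])
  }
  rownames(df) <- NULL
  class(df) <- c("peptide_table", "data.frame")
  df
}

#' Write a peptide table as TSV
#'
#' @param x A `peptide_table`.
#' @param path Output path.
#' @export
write_peptide_table <- function(x, path) {
  write_tsv(as.data.frame(x)[PEPTIDE_COLUMNS], path)
}

# Canonical TSV dialect: UTF-8, tab separator, '.' decimal, no quoting.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a protein FASTA file
#'
#' Headers follow the `>accession|gene_symbol description` convention; when no
#' `|gene` field is present the gene symbol falls back to the accession.
#' Sequences are uppercased and trailing `*` stop characters stripped.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A `protein_db`: data frame with columns `protein_accession`,
#'   `gene_symbol`, `sequence`.
#' @export
read_fasta <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  aa <- Biostrings::readBStringSet(path)
  headers <- names(aa)
  first_tok <- sub("\\s.*$", "", headers)
  accession <- sub("\\|.*$", "", first_tok)
  gene <- ifelse(grepl("\\|", first_tok),
                 sub("^[^|]*\\|", "", first_tok), accession)
  seqs <- toupper(gsub("\\*", "", as.character(aa)))
  protein_db(accession, gene, seqs)
}

#' Construct a protein database
#'
#' @param protein_accession,gene_symbol,sequence Parallel character vectors.
#' @return A `protein_db` data frame.
#' @export
protein_db <- function(protein_accession, gene_symbol, sequence) {
  if (anyDuplicated(protein_accession))
    stop_fmt("duplicate accession: %s",
             protein_accession[duplicated(protein_accession)][1])
  assert_that(all(nchar(sequence) > 0), "empty sequence for accession %s",
              protein_accession[nchar(sequence) == 0][1])
  for (i in seq_along(sequence)) validate_aa(sequence[i], protein_accession[i])
  db <- data.frame(protein_accession = unname(protein_accession),
                   gene_symbol = unname(gene_symbol),
                   sequence = unname(sequence), stringsAsFactors = FALSE)
  rownames(db) <- NULL
  class(db) <- c("protein_db", "data.frame")
  db
}

#' Write a protein database as FASTA
#'
#' @param db A `protein_db`.
#' @param path Output path.
#' @export
write_fasta <- function(db, path) {
  lines <- character(2L * nrow(db))
  lines[c(TRUE, FALSE)] <- sprintf(">%s|%s", db$protein_accession, db$gene_symbol)
  lines[c(FALSE, TRUE)] <- db$sequence
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene set collection in GMT format
#'
#' Broad dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a `.gmt` file.
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3))
    stop_fmt("GMT format error at line %d: fewer than 3 tab-separated fields",
             which(n < 3)[1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  gene_set_collection(sets, vapply(fields, `[`, "", 2L))
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors (unique names, non-empty sets).
#' @param descriptions Optional character vector of per-set descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = rep("", length(sets))) {
  assert_that(!is.null(names(sets)) && all(nzchar(names(sets))),
              "gene sets must be named")
  if (anyDuplicated(names(sets)))
    stop_fmt("duplicate gene set name: %s", names(sets)[duplicated(names(sets))][1])
  assert_that(all(lengths(sets) > 0), "empty gene set: %s",
              names(sets)[lengths(sets) == 0][1])
  structure(sets, descriptions = setNames(descriptions, names(sets)),
            class = "gene_set_collection")
}

#' Write a gene set collection in GMT format
#'
#' @param sets A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression cohort with survival annotations
#'
#' The expression TSV has a first column `gene` and one column per sample
#' (log2 scale); the survival CSV has columns `sample_id`, `time_days`,
#' `event`. Samples are inner-joined on sample id and the number of dropped
#' samples is reported via `message()`.
#'
#' @param expr_path Path to the gene x sample expression TSV.
#' @param surv_path Path to the survival CSV.
#' @param id Cohort identifier.
#' @return A `cohort` object: list with `cohort_id`, `expression` (gene x
#'   sample matrix) and `survival` (data frame `sample_id`, `time_days`,
#'   `event`).
#' @export
read_cohort <- function(expr_path, surv_path, id) {
  assert_that(file.exists(expr_path), "file not found: %s", expr_path)
  assert_that(file.exists(surv_path), "file not found: %s", surv_path)
  edf <- read.delim(expr_path, check.names = FALSE)
  assert_that(names(edf)[1] == "gene",
              "expression table must have 'gene' as its first column")
  expr <- as.matrix(edf[, -1, drop = FALSE])
  rownames(expr) <- edf$gene
  surv <- utils::read.csv(surv_path, check.names = FALSE)
  need <- c("sample_id", "time_days", "event")
  missing_cols <- setdiff(need, names(surv))
  if (length(missing_cols))
    stop_fmt("survival table missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  cohort(id, expr, surv)
}

#' Construct a cohort object
#'
#' @param cohort_id Cohort identifier.
#' @param expression Gene x sample numeric matrix (log2 scale).
#' @param survival Data frame with `sample_id`, `time_days`, `event`.
#' @return A `cohort`.
#' @export
cohort <- function(cohort_id, expression, survival) {
  shared <- intersect(colnames(expression), survival$sample_id)
  if (length(shared) == 0)
    stop_fmt("cohort %s: zero overlapping samples between expression and survival",
             cohort_id)
  dropped <- (ncol(expression) - length(shared)) +
    (nrow(survival) - length(shared))
  if (dropped > 0)
    message(sprintf("cohort %s: dropped %d sample(s) absent from one table",
                    cohort_id, dropped))
  expression <- expression[, shared, drop = FALSE]
  survival <- survival[match(shared, survival$sample_id), , drop = FALSE]
  rownames(survival) <- NULL
  assert_that(!anyNA(survival$time_days) && !anyNA(survival$event),
              "cohort %s: missing survival entries", cohort_id)
  assert_that(all(survival$time_days >= 0), "cohort %s: negative survival time",
              cohort_id)
  assert_that(all(survival$event %in% c(0, 1)),
              "cohort %s: event must be 0 or 1", cohort_id)
  structure(list(cohort_id = cohort_id, expression = expression,
                 survival = survival), class = "cohort")
}

#' Write the ranked interactor table
#'
#' Column order mirrors the published layout: rank, identifiers, one
#' bait/control ratio column per cell line, then detection metadata and the
#' three criterion flags.
#'
#' @param records Interactor records from [select_interactors()].
#' @param path Output path.
#' @export
write_interactor_table <- function(records, path) {
  ratio_cols <- grep("^ratio_", names(records), value = TRUE)
  cols <- c("rank", "protein_accession", "gene_symbol", ratio_cols,
            "n_detected_bait_runs", "max_unique_peptides",
            "pass_i", "pass_ii", "pass_iii", "selected")
  write_tsv(as.data.frame(records)[intersect(cols, names(records))], path)
}

#' Write an enrichment (ORA or GSEA) report as TSV
#'
#' @param results Data frame of enrichment results.
#' @param path Output path.
#' @export
write_enrichment_report <- function(results, path) {
  write_tsv(as.data.frame(results), path)
}

#' Write the per-gene, per-cohort Cox forest table
#'
#' Stable column order: gene, cohort_id, beta, se, hr, ci95 bounds, z, p,
#' reproducible flag.
#'
#' @param fits Data frame of Cox fits (one row per gene x cohort), as returned
#'   by [cox_screen()] with the concordance flag merged in.
#' @param path Output path.
#' @export
write_forest_table <- function(fits, path) {
  cols <- c("gene", "cohort_id", "beta", "se", "hr", "ci95_low", "ci95_high",
            "z", "p", "reproducible")
  write_tsv(as.data.frame(fits)[intersect(cols, names(fits))], path)
}

#' Load the packaged ranked-interactor reference fixture
#'
#' 49 prioritized bait interactors with per-cell-line bait/control iBAQ
#' ratios (NB4 and U937) and the published rank.
#'
#' @return Data frame with columns `rank`, `protein_accession`,
#'   `gene_symbol`, `ratio_NB4`, `ratio_U937`.
#' @export
load_interactor_reference <- function() {
  path <- system.file("extdata", "table1_interactors.tsv", package = "ipmsig",
                      mustWork = TRUE)
  read.delim(path, comment.char = "#")
}

#' Load the packaged HSC-versus-AML expression reference fixture
#'
#' Per-gene published log2 medians in healthy HSCs and AML blasts with the
#' published two-sided p-value (significance at p < 0.05).
#'
#' @return Data frame with columns `gene_symbol`, `hsc_median`, `aml_median`,
#'   `p_value`.
#' @export
load_expression_reference <- function() {
  path <- system.file("extdata", "table2_expression.tsv", package = "ipmsig",
                      mustWork = TRUE)
  read.delim(path, comment.char = "#")
}
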