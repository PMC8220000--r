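#' In-silico tryptic digestion
#'
#' Standard trypsin specificity: cleave C-terminal to lysine (K) or arginine
#' (R) except when the next residue is proline (P). With `missed_cleavages =
#' m`, all concatenations of up to `m + 1` adjacent fully-cleaved fragments
#' are also returned, in N-to-C order.
#'
#' @param sequence Amino-acid string (20-letter alphabet).
#' @param missed_cleavages Non-negative integer number of allowed missed
#'   cleavage sites.
#' @return Character vector of peptides in N-to-C order (fully cleaved
#'   fragments first, then 2-fragment concatenations, and so on).
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0L) {
  assert_that(is_count(missed_cleavages), "missed_cleavages must be a count")
  validate_aa(sequence)
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  # cleavage after position i when res[i] is K/R and res[i+1] is not P
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  frags <- substring(sequence, starts, ends)
  out <- frags
  if (missed_cleavages > 0 && length(frags) > 1) {
    for (m in seq_len(min(missed_cleavages, length(frags) - 1L))) {
      i <- seq_len(length(frags) - m)
      out <- c(out, substring(sequence, starts[i], ends[i + m]))
    }
  }
  out
}

#' Quantification configuration
#'
#' @param background_intensity Fixed iBAQ value imputed for proteins not
#'   detected in a run (default 1000 intensity units).
#' @param observable_min_len,observable_max_len Length window (residues) for a
#'   tryptic peptide to count as observable in the iBAQ denominator
#'   (conventional window 7--30).
#' @param missed_cleavages Missed cleavages allowed when counting theoretical
#'   peptides (default 0).
#' @return A `quant_config` list.
#' @export
quant_config <- function(background_intensity = 1000,
                         observable_min_len = 7L, observable_max_len = 30L,
                         missed_cleavages = 0L) {
  assert_that(is_number(background_intensity) && background_intensity > 0,
              "background_intensity must be a positive number")
  assert_that(is_count(observable_min_len) && observable_min_len > 0 &&
                is_count(observable_max_len) &&
                observable_min_len <= observable_max_len,
              "need 0 < observable_min_len <= observable_max_len")
  assert_that(is_count(missed_cleavages), "missed_cleavages must be a count")
  structure(list(background_intensity = background_intensity,
                 observable_min_len = as.integer(observable_min_len),
                 observable_max_len = as.integer(observable_max_len),
                 missed_cleavages = as.integer(missed_cleavages)),
            class = "quant_config")
}

#' Count theoretically observable tryptic peptides
#'
#' The iBAQ denominator: the number of digest peptides whose length falls in
#' the observable window. Clamped below at 1 so the denominator is never zero.
#'
#' @param sequence Amino-acid string.
#' @param cfg A [quant_config()].
#' @return Positive integer count.
#' @export
count_theoretical_peptides <- function(sequence, cfg = quant_config()) {
  peps <- tryptic_digest(sequence, cfg$missed_cleavages)
  len <- nchar(peps)
  max(sum(len >= cfg$observable_min_len & len <= cfg$observable_max_len), 1L)
}

#' Compute per-protein, per-run iBAQ values
#'
#' For every (protein, run) pair with at least one observed peptide, iBAQ is
#' the sum of that protein's peptide intensities in that run divided by its
#' theoretical observable-peptide count. The output grid is complete over
#' every protein (all accessions observed in the table, or the whole database
#' when `full_grid = TRUE`) crossed with every run present in the table;
#' undetected pairs are imputed at the fixed background intensity.
#'
#' @param peptides A `peptide_table`.
#' @param db A `protein_db` covering every accession in `peptides`.
#' @param cfg A [quant_config()].
#' @param full_grid If `TRUE`, the grid covers every protein in `db`;
#'   otherwise only accessions observed at least once.
#' @return An `ibaq_grid` data frame with columns `protein_accession`,
#'   `gene_symbol`, `run_id`, `cell_line`, `condition`, `replicate`, `ibaq`,
#'   `n_unique_peptides`, `detected`, `imputed`.
#' @export
compute_ibaq <- function(peptides, db, cfg = quant_config(),
                         full_grid = FALSE) {
  missing_acc <- setdiff(peptides$protein_accession, db$protein_accession)
  if (length(missing_acc))
    stop_fmt("accession absent from protein database: %s", missing_acc[1])
  accs <- if (full_grid) db$protein_accession else
    db$protein_accession[db$protein_accession %in% peptides$protein_accession]
  runs <- unique(as.data.frame(peptides)[c("run_id", "cell_line", "condition",
                                           "replicate")])
  runs <- runs[order(runs$run_id), , drop = FALSE]
  n_theor <- vapply(db$sequence[match(accs, db$protein_accession)],
                    count_theoretical_peptides, 1L, cfg = cfg,
                    USE.NAMES = FALSE)

  pep_df <- peptides
  class(pep_df) <- "data.frame"
  dt <- data.table::as.data.table(pep_df)
  obs <- dt[, list(total_intensity = sum(intensity),
                   n_unique_peptides = data.table::uniqueN(peptide_sequence)),
            by = c("protein_accession", "run_id")]

  grid <- expand.grid(protein_accession = accs, run_id = runs$run_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(paste(grid$protein_accession, grid$run_id, sep = "\r"),
             paste(obs$protein_accession, obs$run_id, sep = "\r"))
  grid$gene_symbol <- db$gene_symbol[match(grid$protein_accession,
                                           db$protein_accession)]
  j <- match(grid$run_id, runs$run_id)
  grid$cell_line <- runs$cell_line[j]
  grid$condition <- runs$condition[j]
  grid$replicate <- runs$replicate[j]
  grid$n_unique_peptides <- ifelse(is.na(i), 0L, obs$n_unique_peptides[i])
  grid$detected <- !is.na(i)
  grid$imputed <- !grid$detected
  denom <- n_theor[match(grid$protein_accession, accs)]
  grid$ibaq <- ifelse(grid$detected, obs$total_intensity[i] / denom,
                      cfg$background_intensity)
  cols <- c("protein_accession", "gene_symbol", "run_id", "cell_line",
            "condition", "replicate", "ibaq", "n_unique_peptides",
            "detected", "imputed")
  grid <- grid[order(grid$protein_accession, grid$run_id), cols]
  rownames(grid) <- NULL
  class(grid) <- c("ibaq_grid", "data.frame")
  grid
}
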