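#' Interactor selection criteria
#'
#' The three-criterion rule applied to the imputed iBAQ grid: (i) at least
#' `min_unique_peptides` unique peptides for the protein; (ii) detection in at
#' least `min_detected_bait_runs` of the `total_bait_runs` bait IP runs (both
#' cell lines pooled; control runs do not count); (iii) bait/control iBAQ
#' ratio strictly greater than `min_ratio` in every cell line.
#'
#' @param min_unique_peptides Minimum unique peptides (default 2).
#' @param min_detected_bait_runs Minimum bait runs with detection (default 4).
#' @param total_bait_runs Total number of bait IP runs in the design
#'   (default 6 = 3 replicates x 2 cell lines).
#' @param min_ratio Strict lower bound on the per-cell-line bait/control
#'   ratio (default 30).
#' @param require_ratio_in_all_cell_lines If `TRUE` (default) criterion (iii)
#'   must hold in every cell line; otherwise in at least one.
#' @param unique_peptide_scope `"experiment"` (default): criterion (i) uses
#'   the maximum unique-peptide count over all runs; `"run"`: at least one
#'   single run must reach the threshold on its own (identical for a max
#'   statistic, but kept distinct for summed-per-run variants).
#' @param aggregate Replicate aggregation for the condition summary iBAQ:
#'   arithmetic `"mean"` (default) or `"geometric"` mean.
#' @return A `selection_criteria` list.
#' @export
selection_criteria <- function(min_unique_peptides = 2L,
                               min_detected_bait_runs = 4L,
                               total_bait_runs = 6L,
                               min_ratio = 30,
                               require_ratio_in_all_cell_lines = TRUE,
                               unique_peptide_scope = c("experiment", "run"),
                               aggregate = c("mean", "geometric")) {
  assert_that(is_count(min_unique_peptides) && min_unique_peptides >= 1,
              "min_unique_peptides must be a positive count")
  assert_that(is_count(min_detected_bait_runs) && is_count(total_bait_runs) &&
                min_detected_bait_runs <= total_bait_runs,
              "need min_detected_bait_runs <= total_bait_runs")
  assert_that(is_number(min_ratio) && min_ratio > 0, "min_ratio must be > 0")
  structure(list(min_unique_peptides = as.integer(min_unique_peptides),
                 min_detected_bait_runs = as.integer(min_detected_bait_runs),
                 total_bait_runs = as.integer(total_bait_runs),
                 min_ratio = min_ratio,
                 require_ratio_in_all_cell_lines =
                   isTRUE(require_ratio_in_all_cell_lines),
                 unique_peptide_scope = match.arg(unique_peptide_scope),
                 aggregate = match.arg(aggregate)),
            class = "selection_criteria")
}

#' Summarize a condition's replicate iBAQ values per protein
#'
#' Arithmetic (default) or geometric mean across the imputed-complete
#' replicate iBAQ values of one (cell line, condition).
#'
#' @param quants An `ibaq_grid`.
#' @param cell_line,condition The (cell line, condition) to summarize.
#' @param aggregate `"mean"` or `"geometric"`.
#' @return Named numeric vector of summary iBAQ per protein accession.
#' @export
summarize_condition <- function(quants, cell_line, condition,
                                aggregate = c("mean", "geometric")) {
  aggregate <- match.arg(aggregate)
  assert_that(cell_line %in% quants$cell_line, "unknown cell line: %s",
              cell_line)
  sub <- quants[quants$cell_line == cell_line & quants$condition == condition, ]
  assert_that(nrow(sub) > 0, "no runs for (%s, %s)", cell_line, condition)
  v <- if (aggregate == "mean") sub$ibaq else log(sub$ibaq)
  s <- vapply(split(v, sub$protein_accession), mean, 0)
  if (aggregate == "geometric") s <- exp(s)
  s
}

#' Per-protein, per-cell-line bait/control iBAQ ratios
#'
#' Ratio = summary(bait) / summary(control); strictly positive because both
#' summaries are bounded below by the imputation background.
#'
#' @param quants An `ibaq_grid`.
#' @param cell_lines Cell lines to use, in ranking priority order
#'   (default: order of appearance in the grid).
#' @param aggregate Passed to [summarize_condition()].
#' @return Data frame with `protein_accession`, `gene_symbol`, and one
#'   `ratio_<cell_line>` column per cell line.
#' @export
compute_ratios <- function(quants, cell_lines = unique(quants$cell_line),
                           aggregate = "mean") {
  accs <- unique(quants$protein_accession)
  out <- data.frame(protein_accession = accs,
                    gene_symbol = quants$gene_symbol[
                      match(accs, quants$protein_accession)],
                    stringsAsFactors = FALSE)
  for (cl in cell_lines) {
    bait <- summarize_condition(quants, cl, "bait", aggregate)
    ctrl <- summarize_condition(quants, cl, "control", aggregate)
    out[[paste0("ratio_", cl)]] <- unname(bait[accs] / ctrl[accs])
  }
  out
}

#' Apply the three-criterion interactor selection rule
#'
#' Accepts either an `ibaq_grid` (detection and unique-peptide metadata are
#' derived from the grid) or a precomputed ratio table (a data frame with
#' `protein_accession` and `ratio_*` columns, optionally
#' `n_detected_bait_runs` and `max_unique_peptides`; absent metadata columns
#' are treated as passing, which supports published post-filter ratio tables).
#' Selected records are ranked by the first cell line's ratio descending,
#' ties broken by the following cell lines' ratios, then accession.
#'
#' @param x An `ibaq_grid` or a precomputed ratio data frame.
#' @param criteria A [selection_criteria()].
#' @param cell_lines Ranking priority order of cell lines (grid input only).
#' @return An `interactor_records` data frame with per-protein ratios,
#'   criterion flags `pass_i`/`pass_ii`/`pass_iii`, `selected`, and `rank`
#'   (NA for unselected records).
#' @export
select_interactors <- function(x, criteria = selection_criteria(),
                               cell_lines = NULL) {
  if (inherits(x, "ibaq_grid")) {
    cell_lines <- cell_lines %||% unique(x$cell_line)
    bait <- x[x$condition == "bait", ]
    n_bait_runs <- length(unique(bait$run_id))
    assert_that(criteria$total_bait_runs <= n_bait_runs,
                "criteria reference %d bait runs but only %d exist",
                criteria$total_bait_runs, n_bait_runs)
    tab <- compute_ratios(x, cell_lines, criteria$aggregate)
    det <- vapply(split(bait$detected, bait$protein_accession), sum, 0L)
    upep <- vapply(split(x$n_unique_peptides, x$protein_accession),
                   max, 0L)
    tab$n_detected_bait_runs <- unname(det[tab$protein_accession])
    tab$max_unique_peptides <- unname(upep[tab$protein_accession])
  } else {
    tab <- as.data.frame(x)
    assert_that("protein_accession" %in% names(tab) &&
                  any(grepl("^ratio_", names(tab))),
                "ratio table needs protein_accession and ratio_* columns")
  }
  ratio_cols <- grep("^ratio_", names(tab), value = TRUE)

  tab$pass_i <- if ("max_unique_peptides" %in% names(tab))
    tab$max_unique_peptides >= criteria$min_unique_peptides else TRUE
  tab$pass_ii <- if ("n_detected_bait_runs" %in% names(tab))
    tab$n_detected_bait_runs >= criteria$min_detected_bait_runs else TRUE
  ratio_pass <- as.matrix(tab[ratio_cols]) > criteria$min_ratio  # strict
  tab$pass_iii <- if (criteria$require_ratio_in_all_cell_lines)
    apply(ratio_pass, 1, all) else apply(ratio_pass, 1, any)
  tab$selected <- tab$pass_i & tab$pass_ii & tab$pass_iii

  ord <- do.call(order, c(lapply(tab[ratio_cols], function(r) -r),
                          list(tab$protein_accession)))
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- NA_integer_
  tab$rank[tab$selected] <- seq_len(sum(tab$selected))
  rownames(tab) <- NULL
  class(tab) <- c("interactor_records", "data.frame")
  tab
}

#' Score a selection against simulation ground truth
#'
#' Precision/recall/F1 of the selected set against the truth labels from
#' [simulate_ipms()]. Convention for degenerate cases: an empty selection has
#' precision 1 (no false claims) and recall 0 when true interactors exist;
#' F1 is 0 when precision + recall = 0.
#'
#' @param records An `interactor_records` data frame.
#' @param truth Named character vector mapping accession to
#'   `"true_interactor"` or `"background"`.
#' @return List with `precision`, `recall`, `f1`, `n_selected`, `n_true`.
#' @export
evaluate_against_truth <- function(records, truth) {
  unlabeled <- setdiff(records$protein_accession, names(truth))
  if (length(unlabeled))
    stop_fmt("unlabeled protein in records: %s", unlabeled[1])
  sel <- records$protein_accession[records$selected]
  pos <- names(truth)[truth == "true_interactor"]
  tp <- length(intersect(sel, pos))
  precision <- if (length(sel) == 0) 1 else tp / length(sel)
  recall <- if (length(pos) == 0) 1 else tp / length(pos)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_selected = length(sel), n_true = length(pos))
}
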