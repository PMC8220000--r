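make_grid <- function(df) {
  # complete (protein x run) grid from a compact spec data frame
  class(df) <- c("ibaq_grid", "data.frame")
  df
}

# two cell lines x (bait, control) x 3 replicates, fully imputed except
# where overridden; a minimal hand-buildable grid
grid_template <- function(proteins) {
  runs <- expand.grid(replicate = 1:3, condition = c("bait", "control"),
                      cell_line = c("NB4", "U937"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  runs$run_id <- paste(runs$cell_line, runs$condition, runs$replicate, sep = "_")
  g <- merge(data.frame(protein_accession = proteins,
                        gene_symbol = proteins, stringsAsFactors = FALSE),
             runs)
  g$ibaq <- 1000; g$n_unique_peptides <- 0L
  g$detected <- FALSE; g$imputed <- TRUE
  make_grid(g)
}

set_cells <- function(g, protein, cell_line, condition, ibaq, npep) {
  i <- g$protein_accession == protein & g$cell_line == cell_line &
    g$condition == condition
  g$ibaq[i] <- ibaq
  g$n_unique_peptides[i] <- npep
  g$detected[i] <- TRUE
  g$imputed[i] <- FALSE
  g
}

test_that("condition summaries average imputed-complete replicates", {
  g <- grid_template("P1")
  g$ibaq[g$protein_accession == "P1" & g$cell_line == "NB4" &
           g$condition == "bait"] <- c(2000, 4000, 6000)
  expect_equal(unname(summarize_condition(g, "NB4", "bait")["P1"]), 4000)
  # all replicates undetected: mean of the background
  expect_equal(unname(summarize_condition(g, "NB4", "control")["P1"]), 1000)
  expect_error(summarize_condition(g, "HL60", "bait"), "unknown cell line")
})

test_that("ratios follow summary(bait)/summary(control)", {
  g <- grid_template("P1")
  g <- set_cells(g, "P1", "NB4", "bait", 3e6, 3L)
  r <- compute_ratios(g)
  expect_equal(r$ratio_NB4[r$protein_accession == "P1"], 3e6 / 1000)
  expect_equal(r$ratio_U937[r$protein_accession == "P1"], 1)  # bait = control
})

test_that("the three criteria apply with the documented boundaries", {
  g <- grid_template(c("PA", "PB", "PC"))
  # PA: clean interactor (6/6 bait runs, 5 peptides, huge ratios)
  g <- set_cells(g, "PA", "NB4", "bait", 3e6, 5L)
  g <- set_cells(g, "PA", "U937", "bait", 2e6, 5L)
  # PB: ratio exactly 30x in NB4 -> criterion (iii) strict, fails
  g <- set_cells(g, "PB", "NB4", "bait", 30000, 5L)
  g <- set_cells(g, "PB", "U937", "bait", 2e6, 5L)
  # PC: detected in only 3 of 6 bait runs (one cell line) -> fails (ii)
  g <- set_cells(g, "PC", "NB4", "bait", 3e6, 5L)
  rec <- select_interactors(g)
  rec <- rec[match(c("PA", "PB", "PC"), rec$protein_accession), ]
  expect_equal(rec$selected, c(TRUE, FALSE, FALSE))
  expect_false(rec$pass_iii[2])  # 30.0 is not > 30
  expect_true(rec$pass_i[2] && rec$pass_ii[2])
  expect_false(rec$pass_ii[3])
  expect_equal(rec$n_detected_bait_runs, c(6L, 6L, 3L))
  # ranks only on selected records, 1..k
  expect_equal(rec$rank, c(1L, NA_integer_, NA_integer_))
})

test_that("unique-peptide criterion uses the experiment-wide maximum", {
  g <- grid_template("PA")
  g <- set_cells(g, "PA", "NB4", "bait", 3e6, 1L)
  g <- set_cells(g, "PA", "U937", "bait", 3e6, 1L)
  expect_false(select_interactors(g)$selected)  # max 1 unique peptide
  g$n_unique_peptides[g$detected][1] <- 2L
  expect_true(select_interactors(g)$selected)   # one run with 2 suffices
})

test_that("selection is monotone in its thresholds", {
  sim <- simulate_ipms(ipms_sim_config(n_proteins = 60,
                                       n_true_interactors = 10,
                                       log2_enrichment = 5, seed = 9))
  grid <- compute_ibaq(sim$peptides, sim$db, full_grid = TRUE)
  prev <- Inf
  for (thr in c(2, 10, 30, 100, 1000)) {
    n_sel <- sum(select_interactors(
      grid, selection_criteria(min_ratio = thr))$selected)
    expect_lte(n_sel, prev)
    prev <- n_sel
  }
  prev <- Inf
  for (k in 1:6) {
    n_sel <- sum(select_interactors(
      grid, selection_criteria(min_detected_bait_runs = k))$selected)
    expect_lte(n_sel, prev)
    prev <- n_sel
  }
})

test_that("selection equals the brute-force oracle on small instances", {
  for (s in 1:5) {
    sim <- simulate_ipms(ipms_sim_config(n_proteins = 12,
                                         n_true_interactors = 3,
                                         log2_enrichment = 6, seed = s))
    grid <- compute_ibaq(sim$peptides, sim$db, full_grid = TRUE)
    rec <- select_interactors(grid)
    expect_equal(sort(rec$protein_accession[rec$selected]),
                 oracle_select(grid), info = sprintf("seed %d", s))
  }
})

test_that("precomputed-ratio mode applies criterion (iii) alone", {
  t1 <- load_interactor_reference()
  rec <- select_interactors(t1, selection_criteria(min_ratio = 30))
  expect_true(all(rec$selected))
  expect_true(all(is.na(rec$pass_i) | rec$pass_i))  # no metadata: treated pass
})

test_that("truth evaluation uses the documented conventions", {
  rec <- data.frame(protein_accession = c("A", "B"),
                    selected = c(TRUE, FALSE))
  truth <- c(A = "true_interactor", B = "background")
  ev <- evaluate_against_truth(rec, truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  # empty selection: precision 1 by convention, recall 0
  rec$selected <- FALSE
  ev2 <- evaluate_against_truth(rec, truth)
  expect_equal(ev2$precision, 1)
  expect_equal(ev2$recall, 0)
  expect_equal(ev2$f1, 0)
  expect_error(evaluate_against_truth(rec, truth["A"]), "unlabeled")
})
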