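#' Configuration for the IP-MS experiment simulator
#'
#' The defaults emulate the design the pipeline targets: two cell lines,
#' three bait and three isotype-control IP replicates each, log-normal
#' peptide intensities with intensity-dependent (logistic) dropout, and a
#' contaminant class that is abundant in bait and control alike (the ratio
#' criterion must reject it).
#'
#' @param n_proteins Total simulated proteins.
#' @param n_true_interactors Number of proteins enriched in bait IPs.
#' @param n_replicates Replicates per condition per cell line (default 3).
#' @param cell_lines Cell line names (default `c("NB4", "U937")`).
#' @param log2_enrichment Mean bait-over-control log2 fold change for true
#'   interactors (default 8, a strong but not saturating pulldown).
#' @param background_log_intensity_mean,background_log_intensity_sd Natural-log
#'   mean and sd of the per-peptide base intensity (defaults log(2e6), 1.5).
#' @param dropout_midpoint Natural-log intensity at which an observation is
#'   dropped with probability 1/2 (default log(5e4); set to `-Inf` to disable
#'   dropout).
#' @param dropout_slope Steepness of the logistic missingness curve
#'   (default 1; dropout probability decreases in log intensity).
#' @param peptides_per_protein Integer range (length-2) of observable
#'   peptides sampled per protein (default 3--8, capped by availability).
#' @param contaminant_fraction Fraction of background proteins simulated as
#'   high-abundance contaminants (default 0.1).
#' @param replicate_sd Natural-log sd of per-run replicate noise (default 0.3).
#' @param seed Integer seed; identical configs and seeds give identical output.
#' @return An `ipms_sim_config` list.
#' @export
ipms_sim_config <- function(n_proteins = 200L, n_true_interactors = 20L,
                            n_replicates = 3L,
                            cell_lines = c("NB4", "U937"),
                            log2_enrichment = 8,
                            background_log_intensity_mean = log(2e6),
                            background_log_intensity_sd = 1.5,
                            dropout_midpoint = log(5e4), dropout_slope = 1,
                            peptides_per_protein = c(3L, 8L),
                            contaminant_fraction = 0.1,
                            replicate_sd = 0.3, seed = 1L) {
  assert_that(is_count(n_proteins) && n_proteins >= 1, "n_proteins must be >= 1")
  assert_that(is_count(n_true_interactors) &&
                n_true_interactors <= n_proteins,
              "need n_true_interactors <= n_proteins")
  assert_that(is_count(n_replicates) && n_replicates >= 1,
              "n_replicates must be >= 1")
  assert_that(length(cell_lines) >= 1 && !anyDuplicated(cell_lines),
              "cell_lines must be distinct names")
  assert_that(is_number(background_log_intensity_sd) &&
                background_log_intensity_sd > 0, "intensity sd must be > 0")
  assert_that(is_number(replicate_sd) && replicate_sd > 0,
              "replicate_sd must be > 0")
  assert_that(is_number(dropout_slope) && dropout_slope >= 0,
              "dropout_slope must be >= 0")
  assert_that(length(peptides_per_protein) == 2 &&
                peptides_per_protein[1] >= 1 &&
                peptides_per_protein[1] <= peptides_per_protein[2],
              "peptides_per_protein must be an increasing positive range")
  assert_that(is_number(contaminant_fraction) && contaminant_fraction >= 0 &&
                contaminant_fraction <= 1,
              "contaminant_fraction must be in [0,1]")
  structure(list(n_proteins = as.integer(n_proteins),
                 n_true_interactors = as.integer(n_true_interactors),
                 n_replicates = as.integer(n_replicates),
                 cell_lines = cell_lines,
                 log2_enrichment = log2_enrichment,
                 background_log_intensity_mean = background_log_intensity_mean,
                 background_log_intensity_sd = background_log_intensity_sd,
                 dropout_midpoint = dropout_midpoint,
                 dropout_slope = dropout_slope,
                 peptides_per_protein = as.integer(peptides_per_protein),
                 contaminant_fraction = contaminant_fraction,
                 replicate_sd = replicate_sd, seed = as.integer(seed)),
            class = "ipms_sim_config")
}

# Random amino-acid sequence with realistic K+R density (~11%) so tryptic
# digestion yields peptides of observable length.
random_protein_sequence <- function(length) {
  freq <- c(A = 8.3, C = 1.4, D = 5.5, E = 6.7, F = 3.9, G = 7.1, H = 2.3,
            I = 6.0, K = 5.8, L = 9.7, M = 2.4, N = 4.1, P = 4.7, Q = 4.0,
            R = 5.6, S = 6.6, T = 5.4, V = 6.9, W = 1.1, Y = 2.9)
  paste(sample(names(freq), length, replace = TRUE, prob = freq),
        collapse = "")
}

#' Simulate an IP-MS experiment with known interactor truth
#'
#' Proteins get random amino-acid sequences (length 80--600); per-protein
#' observable tryptic peptides are sampled and assigned log-normal base
#' intensities. True interactors receive a `+log2_enrichment * ln 2` shift on
#' the natural-log scale in the bait runs of every cell line; background
#' proteins are exchangeable between bait and control (a contaminant subset
#' is abundant in both). Each peptide observation is independently dropped
#' with logistic probability decreasing in its log intensity.
#'
#' @param cfg An [ipms_sim_config()].
#' @return List with `peptides` (a `peptide_table`), `db` (a `protein_db`),
#'   and `truth` (named vector: accession -> `"true_interactor"` or
#'   `"background"`).
#' @export
simulate_ipms <- function(cfg = ipms_sim_config()) {
  assert_that(inherits(cfg, "ipms_sim_config"), "cfg must be an ipms_sim_config")
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  accs <- sprintf("SIM%04d", seq_len(n))
  genes <- sprintf("GENE%04d", seq_len(n))
  seqs <- vapply(round(runif(n, 80, 600)), random_protein_sequence, "")
  db <- protein_db(accs, genes, seqs)
  truth <- setNames(rep("background", n), accs)
  truth[sample.int(n, cfg$n_true_interactors)] <- "true_interactor"
  n_bg <- sum(truth == "background")
  contaminant <- setNames(rep(FALSE, n), accs)
  if (n_bg > 0 && cfg$contaminant_fraction > 0)
    contaminant[sample(names(truth)[truth == "background"],
                       round(cfg$contaminant_fraction * n_bg))] <- TRUE

  runs <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      condition = c("bait", "control"),
                      cell_line = cfg$cell_lines,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  runs$run_id <- paste(runs$cell_line, runs$condition, runs$replicate,
                       sep = "_")
  enrich_ln <- cfg$log2_enrichment * log(2)

  rows <- vector("list", n)
  for (p in seq_len(n)) {
    cand <- tryptic_digest(seqs[p])
    cand <- unique(cand[nchar(cand) >= 7 & nchar(cand) <= 30])
    if (!length(cand)) next
    rng <- cfg$peptides_per_protein
    k <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
    peps <- sample(cand, min(k, length(cand)))
    base <- rnorm(length(peps), cfg$background_log_intensity_mean,
                  cfg$background_log_intensity_sd)
    if (contaminant[p]) base <- base + 2  # high in bait AND control
    m <- length(peps) * nrow(runs)
    logi <- rep(base, times = nrow(runs)) +
      rnorm(m, 0, cfg$replicate_sd)
    run_idx <- rep(seq_len(nrow(runs)), each = length(peps))
    if (truth[p] == "true_interactor")
      logi <- logi + enrich_ln * (runs$condition[run_idx] == "bait")
    p_drop <- if (is.infinite(cfg$dropout_midpoint) && cfg$dropout_midpoint < 0)
      rep(0, m)
    else
      1 / (1 + exp(cfg$dropout_slope * (logi - cfg$dropout_midpoint)))
    keep <- runif(m) >= p_drop
    if (!any(keep)) next
    rows[[p]] <- data.frame(
      run_id = runs$run_id[run_idx][keep],
      cell_line = runs$cell_line[run_idx][keep],
      condition = runs$condition[run_idx][keep],
      replicate = runs$replicate[run_idx][keep],
      protein_accession = accs[p], gene_symbol = genes[p],
      peptide_sequence = rep(peps, times = nrow(runs))[keep],
      intensity = exp(logi[keep]), stringsAsFactors = FALSE)
  }
  peptides <- as_peptide_table(do.call(rbind, rows[!vapply(rows, is.null, TRUE)]))
  list(peptides = peptides, db = db, truth = truth)
}

#' Configuration for the survival-cohort simulator
#'
#' Expression follows a one-latent-factor Gaussian model on the log2 scale:
#' signature genes load on a shared per-sample factor with
#' `latent_factor_loading`; all other genes are independent noise. Survival
#' is exponential with hazard `baseline_hazard * exp(lp)` where the linear
#' predictor is `beta` times the mean centered expression of the prognostic
#' genes; censoring is an independent exponential whose rate is calibrated
#' numerically so the expected censored fraction equals `censor_rate`.
#'
#' @param n_genes,n_signature_genes,n_prognostic_genes Gene counts
#'   (prognostic genes are a subset of signature genes; defaults 500/49/12
#'   mirror a 49-gene interactor signature with 12 outcome-associated genes).
#' @param n_samples Samples per cohort (default 200, a typical AML
#'   transcriptomic study size).
#' @param n_cohorts Number of independent cohorts (default 3).
#' @param latent_factor_loading Correlation of signature genes with the
#'   shared factor (default 0.6).
#' @param beta Log-hazard per unit of the prognostic linear predictor
#'   (default 0.5; positive = higher expression, worse outcome, shared sign
#'   across cohorts).
#' @param baseline_hazard Baseline event rate per day (default 1/500,
#'   median survival around 1 year at lp = 0).
#' @param censor_rate Target censored fraction in (0,1) (default 0.3).
#' @param mean_log2_expression Gene-level mean on the log2 scale (default 8).
#' @param seed Integer seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_genes = 500L, n_signature_genes = 49L,
                              n_prognostic_genes = 12L, n_samples = 200L,
                              n_cohorts = 3L, latent_factor_loading = 0.6,
                              beta = 0.5, baseline_hazard = 1 / 500,
                              censor_rate = 0.3, mean_log2_expression = 8,
                              seed = 1L) {
  assert_that(is_count(n_genes) && is_count(n_signature_genes) &&
                is_count(n_prognostic_genes) &&
                n_prognostic_genes <= n_signature_genes &&
                n_signature_genes <= n_genes,
              "need n_prognostic_genes <= n_signature_genes <= n_genes")
  assert_that(is_count(n_samples) && n_samples >= 2, "n_samples must be >= 2")
  assert_that(is_count(n_cohorts) && n_cohorts >= 1, "n_cohorts must be >= 1")
  assert_that(is_number(latent_factor_loading) &&
                abs(latent_factor_loading) <= 1,
              "latent_factor_loading must be in [-1,1]")
  assert_that(is_number(beta), "beta must be a number")
  assert_that(is_number(baseline_hazard) && baseline_hazard > 0,
              "baseline_hazard must be > 0")
  assert_that(is_number(censor_rate) && censor_rate > 0 && censor_rate < 1,
              "censor_rate must be in (0,1)")
  structure(list(n_genes = as.integer(n_genes),
                 n_signature_genes = as.integer(n_signature_genes),
                 n_prognostic_genes = as.integer(n_prognostic_genes),
                 n_samples = as.integer(n_samples),
                 n_cohorts = as.integer(n_cohorts),
                 latent_factor_loading = latent_factor_loading, beta = beta,
                 baseline_hazard = baseline_hazard, censor_rate = censor_rate,
                 mean_log2_expression = mean_log2_expression,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# Censoring-rate calibration: for exponential event times with per-subject
# hazard lambda_i and independent exponential censoring at rate c, subject i
# is censored with probability c / (c + lambda_i). Solve the average for c.
calibrate_censor_rate <- function(lambda, target) {
  f <- function(logc) mean(exp(logc) / (exp(logc) + lambda)) - target
  exp(uniroot(f, lower = log(min(lambda)) - 20, upper = log(max(lambda)) + 20,
              tol = 1e-10)$root)
}

#' Simulate expression cohorts with planted prognostic genes
#'
#' @param cfg A [cohort_sim_config()].
#' @return List with `cohorts` (list of `cohort` objects), `signature_genes`,
#'   `prognostic_genes`, and `beta` (the planted log-hazard coefficient,
#'   same sign in every cohort).
#' @export
simulate_cohorts <- function(cfg = cohort_sim_config()) {
  assert_that(inherits(cfg, "cohort_sim_config"),
              "cfg must be a cohort_sim_config")
  set.seed(cfg$seed)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  sig <- genes[seq_len(cfg$n_signature_genes)]
  prog <- sig[seq_len(cfg$n_prognostic_genes)]
  lam <- cfg$latent_factor_loading
  cohorts <- vector("list", cfg$n_cohorts)
  for (ci in seq_len(cfg$n_cohorts)) {
    ns <- cfg$n_samples
    f <- rnorm(ns)
    expr <- matrix(rnorm(cfg$n_genes * ns), cfg$n_genes, ns,
                   dimnames = list(genes,
                                   sprintf("C%d_S%03d", ci, seq_len(ns))))
    expr[sig, ] <- lam * rep(f, each = length(sig)) +
      sqrt(1 - lam^2) * expr[sig, ]
    lp <- if (length(prog)) cfg$beta * colMeans(expr[prog, , drop = FALSE])
          else rep(0, ns)
    lambda <- cfg$baseline_hazard * exp(lp)
    t_event <- rexp(ns, lambda)
    c_rate <- calibrate_censor_rate(lambda, cfg$censor_rate)
    t_cens <- rexp(ns, c_rate)
    surv <- data.frame(sample_id = colnames(expr),
                       time_days = pmin(t_event, t_cens),
                       event = as.integer(t_event <= t_cens))
    cohorts[[ci]] <- cohort(sprintf("cohort%d", ci),
                            expr + cfg$mean_log2_expression, surv)
  }
  list(cohorts = cohorts, signature_genes = sig, prognostic_genes = prog,
       beta = cfg$beta)
}

#' Simulate gene set collections with one planted set
#'
#' The planted set is drawn from the signature (high-loading) genes; decoy
#' sets are drawn uniformly from the whole gene universe.
#'
#' @param universe Character vector of all gene symbols.
#' @param signature_genes Genes correlated with the signature factor (the
#'   planted set is a subset of these).
#' @param set_size Genes per set.
#' @param n_decoys Number of uniformly drawn decoy sets.
#' @param seed Integer seed.
#' @return A `gene_set_collection` whose first set is named `"planted"`.
#' @export
simulate_gene_sets <- function(universe, signature_genes, set_size = 20L,
                               n_decoys = 10L, seed = 1L) {
  assert_that(set_size <= length(universe),
              "requested set size exceeds the gene universe")
  assert_that(all(signature_genes %in% universe),
              "signature genes must be part of the universe")
  set.seed(seed)
  sets <- c(list(planted = sample(signature_genes,
                                  min(set_size, length(signature_genes)))),
            setNames(lapply(seq_len(n_decoys),
                            function(i) sample(universe, set_size)),
                     sprintf("decoy%02d", seq_len(n_decoys))))
  gene_set_collection(sets)
}
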