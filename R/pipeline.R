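#' Pipeline configuration
#'
#' One configuration object drives [run_all()]: either paths to real inputs
#' (peptide TSV + FASTA) or a simulation request, plus the stage parameters
#' and a single global seed from which per-stage seeds are derived
#' deterministically (stage-name hashing), so stages are reproducible in
#' isolation.
#'
#' @param out_dir Output directory (created if absent).
#' @param peptides_path,fasta_path Paths to a peptide TSV and protein FASTA;
#'   leave `NULL` to simulate inputs with [simulate_ipms()].
#' @param ipms_sim An [ipms_sim_config()] used when simulating.
#' @param cohort_sim A [cohort_sim_config()] for the survival stage.
#' @param quant A [quant_config()].
#' @param criteria A [selection_criteria()].
#' @param gene_sets_path Optional GMT path; when `NULL`, gene sets are
#'   simulated with [simulate_gene_sets()].
#' @param ora_alpha ORA significance level (default 0.05).
#' @param n_perm,weight_exponent GSEA parameters (defaults 1000, 1).
#' @param cox_alpha,k_min Concordance-rule parameters (defaults 0.05, 2).
#' @param seed Global seed (default 1).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            peptides_path = NULL, fasta_path = NULL,
                            ipms_sim = ipms_sim_config(),
                            cohort_sim = cohort_sim_config(),
                            quant = quant_config(),
                            criteria = selection_criteria(),
                            gene_sets_path = NULL,
                            ora_alpha = 0.05, n_perm = 1000L,
                            weight_exponent = 1, cox_alpha = 0.05,
                            k_min = 2L, seed = 1L) {
  if (!is.null(peptides_path))
    assert_that(file.exists(peptides_path), "file not found: %s", peptides_path)
  if (!is.null(peptides_path))
    assert_that(!is.null(fasta_path) && file.exists(fasta_path),
                "file not found: %s", fasta_path %||% "<missing fasta_path>")
  if (!is.null(gene_sets_path))
    assert_that(file.exists(gene_sets_path), "file not found: %s",
                gene_sets_path)
  structure(list(out_dir = out_dir, peptides_path = peptides_path,
                 fasta_path = fasta_path, ipms_sim = ipms_sim,
                 cohort_sim = cohort_sim, quant = quant, criteria = criteria,
                 gene_sets_path = gene_sets_path, ora_alpha = ora_alpha,
                 n_perm = as.integer(n_perm),
                 weight_exponent = weight_exponent, cox_alpha = cox_alpha,
                 k_min = as.integer(k_min), seed = as.integer(seed)),
            class = "pipeline_config")
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full pipeline
#'
#' Executes quantify -> select -> ORA/GSEA -> survival/differential
#' expression, writing every artifact as TSV under `cfg$out_dir` plus a
#' manifest (`manifest.tsv`) listing each artifact with its MD5 checksum.
#' Identical configuration and seed give identical checksums. Stage failures
#' abort with a stage-named error.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the manifest data frame (`artifact`, `md5`).
#' @export
run_all <- function(cfg) {
  assert_that(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(obj, name, writer = write_tsv) {
    p <- file.path(cfg$out_dir, name)
    writer(obj, p)
    paths <<- c(paths, p)
    p
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop_fmt("stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  # --- inputs ---------------------------------------------------------------
  truth <- NULL
  if (is.null(cfg$peptides_path)) {
    sim_cfg <- cfg$ipms_sim
    sim_cfg$seed <- derive_seed(cfg$seed, "simulate-ipms")
    sim <- run_stage("simulate-ipms", simulate_ipms(sim_cfg))
    peptides <- sim$peptides; db <- sim$db; truth <- sim$truth
    emit(data.frame(protein_accession = names(truth), label = unname(truth)),
         "truth.tsv")
    emit(peptides, "peptides.tsv", write_peptide_table)
    emit(db, "proteins.fasta", write_fasta)
    log_stage("simulate-ipms", "%d proteins, %d peptide observations",
              nrow(db), nrow(peptides))
  } else {
    peptides <- run_stage("read-inputs", read_peptide_table(cfg$peptides_path))
    db <- run_stage("read-inputs", read_fasta(cfg$fasta_path))
  }

  # --- quantify -------------------------------------------------------------
  grid <- run_stage("quantify", compute_ibaq(peptides, db, cfg$quant,
                                             full_grid = TRUE))
  emit(as.data.frame(grid), "ibaq.tsv")
  log_stage("quantify", "%d protein x run cells (%d imputed)",
            nrow(grid), sum(grid$imputed))

  # --- select ---------------------------------------------------------------
  records <- run_stage("select", select_interactors(grid, cfg$criteria))
  emit(records, "interactors.tsv", write_interactor_table)
  log_stage("select", "%d of %d proteins selected", sum(records$selected),
            nrow(records))

  # --- cohorts + signature --------------------------------------------------
  co_cfg <- cfg$cohort_sim
  co_cfg$seed <- derive_seed(cfg$seed, "simulate-cohorts")
  cosim <- run_stage("simulate-cohorts", simulate_cohorts(co_cfg))
  sig_genes <- cosim$signature_genes
  first <- cosim$cohorts[[1]]

  # --- enrichment -----------------------------------------------------------
  sets <- if (is.null(cfg$gene_sets_path))
    simulate_gene_sets(rownames(first$expression), sig_genes,
                       seed = derive_seed(cfg$seed, "gene-sets"))
  else read_gmt(cfg$gene_sets_path)
  ora <- run_stage("ora", over_representation(sig_genes,
                                              rownames(first$expression),
                                              sets, cfg$ora_alpha))
  emit(ora, "ora.tsv", write_enrichment_report)

  score <- run_stage("score", signature_score(first, sig_genes))
  emit(data.frame(sample_id = names(score), score = unname(score),
                  group = dichotomize_median(score)), "scores.tsv")
  ranking <- run_stage("gsea", rank_genes(first$expression,
                                          reference_score = score))
  gsea <- run_stage("gsea", gsea_preranked(ranking, sets,
                                           weight_exponent = cfg$weight_exponent,
                                           n_perm = cfg$n_perm,
                                           seed = derive_seed(cfg$seed, "gsea")))
  emit(gsea, "gsea.tsv", write_enrichment_report)
  log_stage("gsea", "%d set(s) significant at q < 0.25", sum(gsea$significant))

  # --- survival -------------------------------------------------------------
  fits <- run_stage("survival", cox_screen(cosim$cohorts, sig_genes))
  calls <- run_stage("survival", concordance_call(fits, cfg$cox_alpha,
                                                  cfg$k_min))
  fits$reproducible <- calls$reproducible[match(fits$gene, calls$gene)]
  emit(fits, "forest.tsv", write_forest_table)
  emit(calls, "concordance.tsv")
  log_stage("survival", "%d of %d genes reproducibly prognostic",
            sum(calls$reproducible), nrow(calls))

  # --- differential expression ---------------------------------------------
  grp <- dichotomize_median(score)
  de <- run_stage("diffexp",
                  diff_expression(first$expression[, grp == "low", drop = FALSE],
                                  first$expression[, grp == "high", drop = FALSE]))
  emit(de, "diffexp.tsv")

  manifest <- data.frame(artifact = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  log_stage("run-all", "wrote %d artifacts + manifest to %s",
            nrow(manifest), cfg$out_dir)
  invisible(manifest)
}

#' Command-line interface
#'
#' Subcommands: `simulate-ipms`, `simulate-cohorts`, `quantify`, `select`,
#' `ora`, `gsea`, `score`, `survival`, `diffexp`, `run-all`, plus `--version`.
#' Flags are `--key value` pairs (see the package README). Designed to be
#' driven by `Rscript -e 'ipmsig::ipmsig_cli()'` or the installed
#' `inst/cli/ipmsig` launcher.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Invisibly, the subcommand's result; called for its side effects.
#' @export
ipmsig_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("--help", "-h")) {
    message("usage: ipmsig <subcommand> [--key value ...]\n",
            "subcommands: simulate-ipms simulate-cohorts quantify select ",
            "ora gsea score survival diffexp run-all")
    return(invisible(NULL))
  }
  if (args[1] == "--version") {
    message("ipmsig ", as.character(utils::packageVersion("ipmsig")))
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- parse_cli_flags(args[-1])
  seed <- as.integer(opts$seed %||% 1)
  out <- opts$out %||% "."

  switch(cmd,
    "run-all" = {
      cfg <- pipeline_config(out_dir = out,
                             peptides_path = opts$peptides,
                             fasta_path = opts$fasta,
                             gene_sets_path = opts$sets, seed = seed)
      run_all(cfg)
    },
    "simulate-ipms" = {
      sim <- simulate_ipms(ipms_sim_config(seed = seed))
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_peptide_table(sim$peptides, file.path(out, "peptides.tsv"))
      write_fasta(sim$db, file.path(out, "proteins.fasta"))
      write_tsv(data.frame(protein_accession = names(sim$truth),
                           label = unname(sim$truth)),
                file.path(out, "truth.tsv"))
      invisible(sim)
    },
    "simulate-cohorts" = {
      cosim <- simulate_cohorts(cohort_sim_config(seed = seed))
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      for (co in cosim$cohorts) {
        edf <- data.frame(gene = rownames(co$expression), co$expression,
                          check.names = FALSE)
        write_tsv(edf, file.path(out, paste0(co$cohort_id, "_expr.tsv")))
        utils::write.csv(co$survival,
                         file.path(out, paste0(co$cohort_id, "_surv.csv")),
                         row.names = FALSE, quote = FALSE)
      }
      write_tsv(data.frame(gene = cosim$prognostic_genes),
                file.path(out, "prognostic_genes.tsv"))
      invisible(cosim)
    },
    "quantify" = {
      peptides <- read_peptide_table(req_opt(opts, "peptides"))
      db <- read_fasta(req_opt(opts, "fasta"))
      cfg <- quant_config(
        background_intensity = as.numeric(opts$background %||% 1000),
        observable_min_len = as.integer(opts[["min-len"]] %||% 7),
        observable_max_len = as.integer(opts[["max-len"]] %||% 30))
      grid <- compute_ibaq(peptides, db, cfg, full_grid = TRUE)
      write_tsv(as.data.frame(grid), req_opt(opts, "out"))
      invisible(grid)
    },
    "select" = {
      crit <- selection_criteria(
        min_unique_peptides = as.integer(opts[["min-unique-peptides"]] %||% 2),
        min_detected_bait_runs = as.integer(opts[["min-detect"]] %||% 4),
        total_bait_runs = as.integer(opts[["total-bait-runs"]] %||% 6),
        min_ratio = as.numeric(opts[["min-ratio"]] %||% 30))
      x <- if (!is.null(opts$ibaq)) {
        grid <- read.delim(opts$ibaq)
        class(grid) <- c("ibaq_grid", "data.frame")
        grid
      } else read.delim(req_opt(opts, "ratios"), comment.char = "#")
      records <- select_interactors(x, crit)
      write_interactor_table(records, req_opt(opts, "out"))
      invisible(records)
    },
    "ora" = {
      res <- over_representation(readLines(req_opt(opts, "query")),
                                 readLines(req_opt(opts, "universe")),
                                 read_gmt(req_opt(opts, "sets")),
                                 alpha = as.numeric(opts$alpha %||% 0.05))
      write_enrichment_report(res, req_opt(opts, "out"))
      invisible(res)
    },
    "gsea" = {
      rnk <- read.delim(req_opt(opts, "ranking"), header = FALSE,
                        col.names = c("gene", "score"))
      res <- gsea_preranked(rnk, read_gmt(req_opt(opts, "sets")),
                            weight_exponent = as.numeric(opts$weight %||% 1),
                            n_perm = as.integer(opts$perms %||% 1000),
                            seed = seed)
      write_enrichment_report(res, req_opt(opts, "out"))
      invisible(res)
    },
    "score" = {
      co <- read_cohort(req_opt(opts, "expr"), req_opt(opts, "surv"),
                        opts$id %||% "cohort")
      s <- signature_score(co, readLines(req_opt(opts, "genes")))
      write_tsv(data.frame(sample_id = names(s), score = unname(s),
                           group = dichotomize_median(s)),
                req_opt(opts, "out"))
      invisible(s)
    },
    "survival" = {
      expr_paths <- strsplit(req_opt(opts, "expr"), ",")[[1]]
      surv_paths <- strsplit(req_opt(opts, "surv"), ",")[[1]]
      cohorts <- mapply(read_cohort, expr_paths, surv_paths,
                        sprintf("cohort%d", seq_along(expr_paths)),
                        SIMPLIFY = FALSE)
      fits <- cox_screen(cohorts, readLines(req_opt(opts, "genes")))
      calls <- concordance_call(fits,
                                alpha = as.numeric(opts$alpha %||% 0.05),
                                k_min = as.integer(opts$kmin %||% 2))
      fits$reproducible <- calls$reproducible[match(fits$gene, calls$gene)]
      write_forest_table(fits, req_opt(opts, "out"))
      invisible(calls)
    },
    "diffexp" = {
      a <- as.matrix(read.delim(req_opt(opts, "group-a"), row.names = 1))
      b <- as.matrix(read.delim(req_opt(opts, "group-b"), row.names = 1))
      de <- diff_expression(a, b)
      write_tsv(de, req_opt(opts, "out"))
      invisible(de)
    },
    stop_fmt("unknown subcommand: %s", cmd)
  )
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    assert_that(startsWith(args[i], "--"), "expected --flag, got '%s'", args[i])
    key <- sub("^--", "", args[i])
    assert_that(i + 1 <= length(args), "flag --%s needs a value", key)
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

req_opt <- function(opts, key) {
  assert_that(!is.null(opts[[key]]), "missing required flag --%s", key)
  opts[[key]]
}
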