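# ipmsig

**Bait interactome prioritization from IP-MS data, and prognostic evaluation
of the interactor gene signature.**

`ipmsig` is an R package for the computational chain that turns peptide-level
immunoprecipitation mass-spectrometry (IP-MS / AP-MS) data into a prioritized
list of bait interactors, and then asks whether the genes encoding those
interactors carry clinical signal in expression cohorts with survival
follow-up. It was built around a concrete use case — the NTAL (LAT2) adaptor
protein pulled down in two AML cell lines (NB4, U937) against isotype
controls — but every stage is generic and fully configurable.

## Who it is for

Proteomics / systems-biology groups who have identified-peptide tables from
an IP-MS experiment (bait vs isotype control, replicated, possibly in several
cell lines) and want a tested, reproducible route to:

1. **iBAQ quantification** — per protein and run, summed peptide precursor
   intensities divided by the number of theoretically observable tryptic
   peptides (in-silico digest, 7–30 residue window), with undetected
   (protein, run) cells imputed at a fixed background intensity of 1000;
2. **three-criterion interactor selection** — keep a protein iff
   (i) ≥ 2 unique peptides, (ii) detected in ≥ 4 of the 6 bait IP runs, and
   (iii) bait/control iBAQ ratio **strictly** > 30 in *every* cell line;
   selected proteins are ranked by the first cell line's ratio;
3. **enrichment** — hypergeometric over-representation with
   Benjamini–Hochberg correction (α = 0.05), and preranked GSEA (weighted
   Kolmogorov–Smirnov running sum, gene-label permutation NES/FDR,
   significance at FDR q < 0.25);
4. **survival** — per-gene univariate Cox proportional-hazards screening
   (Efron ties, Newton ascent on the partial likelihood) across multiple
   cohorts, with a *concordance rule*: a gene is reproducibly prognostic iff
   it reaches p < α with a consistent coefficient sign in ≥ 2 independent
   cohorts; plus median-dichotomized signature scores, log-rank tests, and
   exact Mann–Whitney differential expression.

A synthetic-data module simulates IP-MS experiments (log-normal intensities,
intensity-dependent logistic dropout, contaminant class, known truth labels)
and survival cohorts (latent-factor expression, exponential hazards with a
planted log-linear effect, calibrated censoring), so the whole pipeline is
testable without any external download.

## The statistics in brief

For protein *p* in run *r* with observed peptide intensities
*I₁ … I_k* and *N_p* theoretical observable tryptic peptides:

    iBAQ(p, r) = (I₁ + … + I_k) / N_p        (background 1000 if k = 0)

Per cell line *c*, the selection ratio is
`mean over bait replicates of iBAQ / mean over control replicates`, and
criterion (iii) requires `ratio_c > 30` for all *c* (strict inequality — a
protein at exactly 30-fold fails).

The Cox stage fits `h(t | x) = h₀(t) · exp(βx)` per gene and cohort with *x*
the continuous log2 expression; `HR = exp(β)`, 95% CI `exp(β ± 1.96·se)`.
GSEA uses hit increments `|s_i|^w / Σ|s_j|^w` (w = 1 by default, w = 0 for
the classic KS statistic) and miss increments `1/(N − m)`; ES is the signed
maximum running-sum deviation, NES divides by the mean same-sign null ES.

## Worked example

```r
library(ipmsig)

sim     <- simulate_ipms(ipms_sim_config(n_proteins = 60,
                                         n_true_interactors = 8, seed = 42))
grid    <- compute_ibaq(sim$peptides, sim$db)
records <- select_interactors(grid)
head(records[records$selected, c("rank", "gene_symbol", "ratio_NB4",
                                 "ratio_U937", "n_detected_bait_runs")], 5)
#>   rank gene_symbol ratio_NB4 ratio_U937 n_detected_bait_runs
#> 1    1    GENE0037     289.1      251.8                    6
#> 2    2    GENE0051     272.7      200.8                    6
#> 3    3    GENE0038     269.2      247.8                    6
#> 4    4    GENE0026     262.0      180.7                    6
#> 5    5    GENE0010     250.7      304.8                    6

unlist(evaluate_against_truth(records, sim$truth))
#>  precision     recall         f1 n_selected     n_true
#>          1          1          1          8          8
```

All eight planted interactors are recovered with no false positives: the
default simulated enrichment (2⁸-fold) sits far above the 30-fold rule while
contaminants, abundant in bait *and* control, are rejected by the ratio.

```r
cs    <- simulate_cohorts(cohort_sim_config(seed = 42))  # 3 cohorts, n = 200
fits  <- cox_screen(cs$cohorts, cs$signature_genes)
calls <- concordance_call(fits, alpha = 0.05, k_min = 2)
table(planted = calls$gene %in% cs$prognostic_genes,
      called  = calls$reproducible)
#>        called
#> planted FALSE TRUE
#>   FALSE    17   20
#>   TRUE      2   10
```

10 of the 12 planted prognostic genes are flagged at n = 200 per cohort
(power, not correctness, limits the other two), and 20 *non*-prognostic
signature genes are flagged too — they share the latent expression factor
with the planted genes, so their association with survival is real
confounding, not a false positive of the rule. Decoy genes outside the
signature are essentially never flagged (see the acceptance suite, which
measures a ≤ 10% decoy rate with truly null decoys).

## Published-anchor fixtures

`load_interactor_reference()` ships the 49-protein NTAL interactor reference
(per-cell-line NTAL/CT iBAQ ratios; rank 1 CD59 at NB4 = 11003.31 down to
rank 49 FLOT2 at NB4 = 30.45) and `load_expression_reference()` the 50-gene
HSC-vs-AML log2-median table (29 genes at p < 0.05, 22 of them higher in
AML). Applying criterion (iii) at > 30-fold to the reference keeps all 49
records; raising the threshold to 31 drops the boundary rows — both are
asserted in `tests/testthat/test-acceptance.R`.

## Command line

```sh
inst/cli/ipmsig run-all --out out/ --seed 7
inst/cli/ipmsig quantify --peptides peptides.tsv --fasta proteins.fasta --out ibaq.tsv
inst/cli/ipmsig select --ibaq ibaq.tsv --min-ratio 30 --min-detect 4 --out interactors.tsv
inst/cli/ipmsig gsea --ranking ranking.rnk --sets sets.gmt --perms 1000 --seed 7 --out gsea.tsv
```

`run-all` writes every stage artifact plus `manifest.tsv` with MD5 checksums;
the same config and seed reproduce identical checksums.

## Vignette

`vignettes/ipmsig-methods.Rmd` documents the model assumptions, the default
parameters and why they were chosen, what the simulators do and do not
emulate, and the numerical conventions (tie handling, rounding, degenerate
inputs).
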