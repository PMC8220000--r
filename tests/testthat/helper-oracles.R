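# Independent brute-force oracles. These deliberately use a different
# strategy than the package implementation (substring enumeration, triple
# loops over data frames) so agreement is evidence, not tautology.

# All substrings that are valid tryptic peptides with <= m missed cleavages.
# A substring [s, e] is valid iff both boundaries are termini or cleavage
# sites, and it spans at most m internal cleavage sites.
oracle_digest <- function(sequence, m = 0L) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  is_site <- function(i) i >= 1 && i < n && res[i] %in% c("K", "R") &&
    res[i + 1] != "P"
  site_after <- vapply(seq_len(n), function(i) i == n || is_site(i), TRUE)
  out <- character(0)
  for (s in seq_len(n)) {
    if (!(s == 1 || site_after[s - 1])) next
    for (e in s:n) {
      if (!site_after[e]) next
      internal <- if (e > s) sum(vapply(s:(e - 1), is_site, TRUE)) else 0
      if (internal <= m)
        out <- c(out, paste(res[s:e], collapse = ""))
    }
  }
  out
}

oracle_theoretical_count <- function(sequence, min_len = 7, max_len = 30) {
  peps <- oracle_digest(sequence, 0L)
  max(sum(nchar(peps) >= min_len & nchar(peps) <= max_len), 1L)
}

# Brute-force iBAQ: nested loops over every (protein, run) cell.
oracle_ibaq <- function(peptides, db, background = 1000,
                        min_len = 7, max_len = 30) {
  pep <- as.data.frame(peptides)
  accs <- sort(unique(pep$protein_accession))
  runs <- sort(unique(pep$run_id))
  out <- NULL
  for (a in accs) {
    seqs <- db$sequence[db$protein_accession == a]
    denom <- oracle_theoretical_count(seqs, min_len, max_len)
    for (r in runs) {
      rows <- pep[pep$protein_accession == a & pep$run_id == r, ]
      ib <- if (nrow(rows) == 0) background else sum(rows$intensity) / denom
      out <- rbind(out, data.frame(
        protein_accession = a, run_id = r, ibaq = ib,
        n_unique_peptides = length(unique(rows$peptide_sequence)),
        imputed = nrow(rows) == 0, stringsAsFactors = FALSE))
    }
  }
  out
}

# Brute-force three-criterion filter, written directly from the rule: (i) at
# least two unique peptides; (ii) detection in >= 4 of the 6 bait IP runs;
# (iii) bait/control mean-iBAQ ratio > 30 in every cell line.
oracle_select <- function(grid, min_unique = 2, min_detect = 4,
                          min_ratio = 30) {
  g <- as.data.frame(grid)
  sel <- character(0)
  for (a in unique(g$protein_accession)) {
    d <- g[g$protein_accession == a, ]
    upep <- max(d$n_unique_peptides)
    ndet <- sum(d$detected[d$condition == "bait"])
    ok_ratio <- TRUE
    for (cl in unique(g$cell_line)) {
      bait <- mean(d$ibaq[d$cell_line == cl & d$condition == "bait"])
      ctrl <- mean(d$ibaq[d$cell_line == cl & d$condition == "control"])
      if (!(bait / ctrl > min_ratio)) ok_ratio <- FALSE
    }
    if (upep >= min_unique && ndet >= min_detect && ok_ratio)
      sel <- c(sel, a)
  }
  sort(sel)
}

# Small deterministic peptide table for I/O and quantification tests.
toy_peptides <- function() {
  as_peptide_table(data.frame(
    run_id = c("NB4_bait_1", "NB4_bait_1", "NB4_control_1", "U937_bait_1"),
    cell_line = c("NB4", "NB4", "NB4", "U937"),
    condition = c("bait", "bait", "control", "bait"),
    replicate = c(1L, 1L, 1L, 1L),
    protein_accession = c("P1", "P1", "P2", "P1"),
    gene_symbol = c("G1", "G1", "G2", "G1"),
    peptide_sequence = c("AAAAAAAK", "CCCCCCCCCR", "DDDDDDDK", "AAAAAAAK"),
    intensity = c(1.2e6, 0.8e6, 5e5, 2e6),
    stringsAsFactors = FALSE))
}

toy_db <- function() {
  protein_db(c("P1", "P2"), c("G1", "G2"),
             c("AAAAAAAKCCCCCCCCCR", "DDDDDDDKEEEEEEER"))
}
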