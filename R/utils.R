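#' @importFrom stats median pchisq pnorm qnorm rbinom rexp rnorm runif sd
#'   setNames uniroot var complete.cases
#' @importFrom utils read.delim write.table head combn
NULL

# Valid amino-acid alphabet for peptide/protein sequences (20 standard residues)
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

# data.table is used via :: only; declare awareness so [.data.table dispatches
.datatable.aware <- TRUE

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(ok, ...) if (!isTRUE(ok)) stop_fmt(...)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == as.integer(x) && x >= 0

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

validate_aa <- function(sequence, what = "sequence") {
  bad <- setdiff(strsplit(sequence, "")[[1]], AA_ALPHABET)
  if (length(bad))
    stop_fmt("invalid residue character(s) in %s: %s", what,
             paste(unique(bad), collapse = ", "))
  invisible(sequence)
}

# Deterministic 32-bit sub-seed from a parent seed and a stage label, so that
# pipeline stages are individually reproducible from one global seed.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 1103515245 + h) %% 2147483647)
}
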