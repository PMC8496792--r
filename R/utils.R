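# Internal helpers: sequence handling, rounding, structured error conditions.

#' @importFrom methods as is
#' @importFrom stats rbinom runif setNames
#' @importFrom utils read.csv write.csv write.table head tail
NULL

abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ribodesign_validation", "ribodesign_error")))
}

abort_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ribodesign_io", "ribodesign_error")))
}

abort_parse <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ribodesign_parse", "ribodesign_error")))
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character DNA (IUPAC codes
#' accepted, case preserved as upper).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Half-away-from-zero decimal rounding (base round() is banker's rounding).
round_half_away <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_acgt <- function(x) {
  grepl("^[ACGT]+$", x)
}

check_dna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTNRYSWKMBDHV]", toupper(x))
  if (any(bad)) {
    abort_validation("%s contains non-IUPAC characters: %s", what,
                     paste(head(unique(unlist(strsplit(
                       gsub("[ACGTNRYSWKMBDHV]", "", toupper(x[bad])), ""))), 5),
                       collapse = ", "))
  }
  invisible(TRUE)
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_validation("seed must be a single number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Random DNA string(s) at a given GC content; integer RNG only.
random_dna <- function(n_bases, gc = 0.5) {
  stopifnot(n_bases >= 0)
  if (n_bases == 0L) return("")
  pick <- sample.int(2L, n_bases, replace = TRUE, prob = c(gc, 1 - gc))
  gcb <- sample(c("G", "C"), n_bases, replace = TRUE)
  atb <- sample(c("A", "T"), n_bases, replace = TRUE)
  paste(ifelse(pick == 1L, gcb, atb), collapse = "")
}

substr_vec <- function(seq, starts, ends) {
  substring(seq, starts, ends)
}
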