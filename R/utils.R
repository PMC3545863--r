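# Shared low-level helpers: sequence arithmetic and rounding.

BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over its argument. `N` is its own complement; any other
#' letter is an error.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, upper case).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAC"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(paste0("non-ACGTN letters in sequence(s): ", paste(head(which(bad), 3), collapse = ", ")))
  }
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Round half away from zero
#'
#' Conventional half-up rounding at a fixed number of decimals, used for
#' every reported percentage and density so printed figures match the
#' familiar arithmetic (89.7, 2798, ...) rather than banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# uppercases and maps non-ACGTN IUPAC letters to N; attaches the count of
# replaced letters as an attribute so callers can log it
clean_sequence <- function(seq) {
  seq <- toupper(seq)
  n_amb <- sum(vapply(
    gregexpr("[^ACGTN]", seq),
    function(m) if (m[1] == -1L) 0L else length(m), integer(1)
  ))
  if (n_amb > 0) seq <- gsub("[^ACGTN]", "N", seq)
  attr(seq, "n_ambiguous") <- n_amb
  seq
}

# split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# TRUE if motif is a tandem repetition of a shorter unit (non-primitive)
is_reducible_motif <- function(motif) {
  u <- nchar(motif)
  for (d in seq_len(u - 1)) {
    if (u %% d == 0 && strrep(substr(motif, 1, d), u / d) == motif) return(TRUE)
  }
  FALSE
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483000L
}
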