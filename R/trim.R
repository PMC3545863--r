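# Read trimming: the two policies used before assembly. The normal policy
# strips low-quality terminal bases (per-base Q20 end rule) and keeps reads
# of 40-85 nt; the stringent policy additionally removes a fixed 10 nt from
# the 5' end and 5 nt from the 3' end and keeps 25-70 nt.

#' Trimming policy
#'
#' @param qual_threshold terminal bases with Phred below this are stripped.
#' @param min_len,max_len retained length bounds after trimming (nt).
#' @param head_trim,tail_trim fixed counts removed from the 5'/3' ends
#'   (used by the stringent policy, applied after quality trimming).
#' @return a `capsi_trim_policy` list.
#' @export
trim_policy <- function(qual_threshold = 20, min_len = 40, max_len = 85,
                        head_trim = 0, tail_trim = 0) {
  if (min_len > max_len) abort("min_len must be <= max_len")
  if (head_trim < 0 || tail_trim < 0) abort("fixed trims must be >= 0")
  structure(
    list(qual_threshold = qual_threshold, min_len = min_len, max_len = max_len,
         head_trim = as.integer(head_trim), tail_trim = as.integer(tail_trim)),
    class = "capsi_trim_policy"
  )
}

#' @rdname trim_policy
#' @export
stringent_policy <- function() {
  trim_policy(qual_threshold = 20, min_len = 25, max_len = 70,
              head_trim = 10, tail_trim = 5)
}

#' Quality-trim reads from both ends
#'
#' Bases are stripped from each end while the terminal base's Phred score
#' is below the threshold (interior low-quality bases are retained); the
#' read is kept only if the trimmed length is within
#' `[min_len, max_len]`. Rejection is a tallied outcome, not an error.
#'
#' @param reads tibble with columns `seq` and `quals` (list of integer
#'   Phred scores per base); extra columns are carried through.
#' @param policy a [trim_policy()].
#' @return the input tibble with `seq`/`quals` replaced by their trimmed
#'   versions, plus a logical `kept` column; rejected reads keep their
#'   original sequence. Use [trim_report()] for summary counts.
#' @export
quality_trim <- function(reads, policy = trim_policy()) {
  thr <- policy$qual_threshold
  bounds <- t(vapply(reads$quals, function(q) {
    ok <- which(q >= thr)
    if (length(ok) == 0) c(0L, -1L) else c(ok[1], ok[length(ok)])
  }, integer(2)))
  newlen <- bounds[, 2] - bounds[, 1] + 1L
  kept <- newlen >= policy$min_len & newlen <= policy$max_len
  out <- reads
  out$seq[kept] <- substring(reads$seq[kept], bounds[kept, 1], bounds[kept, 2])
  out$quals[kept] <- lapply(which(kept), function(i) {
    reads$quals[[i]][bounds[i, 1]:bounds[i, 2]]
  })
  out$kept <- kept
  out
}

#' Stringently trim reads by fixed head/tail removal
#'
#' Applies the fixed `head_trim`/`tail_trim` removal of the stringent
#' policy to reads that already passed [quality_trim()] (40-85 nt), then
#' keeps reads within `[min_len, max_len]` (default 25-70 nt).
#'
#' @inheritParams quality_trim
#' @return as [quality_trim()].
#' @export
stringent_trim <- function(reads, policy = stringent_policy()) {
  len <- nchar(reads$seq)
  newlen <- len - policy$head_trim - policy$tail_trim
  kept <- newlen >= policy$min_len & newlen <= policy$max_len
  out <- reads
  out$seq[kept] <- substring(reads$seq[kept], policy$head_trim + 1L,
                             len[kept] - policy$tail_trim)
  out$quals[kept] <- lapply(which(kept), function(i) {
    q <- reads$quals[[i]]
    q[(policy$head_trim + 1L):(length(q) - policy$tail_trim)]
  })
  out$kept <- kept
  out
}

#' Summarise a trimming run
#'
#' @param trimmed output of [quality_trim()] or [stringent_trim()].
#' @return a list with `n_input`, `n_retained`, and a `length_histogram`
#'   tibble (`length`, `n`) over retained reads.
#' @export
trim_report <- function(trimmed) {
  keptlen <- nchar(trimmed$seq[trimmed$kept])
  hist <- dplyr::count(tibble::tibble(length = keptlen), .data$length, name = "n")
  list(
    n_input = nrow(trimmed),
    n_retained = sum(trimmed$kept),
    length_histogram = hist
  )
}
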