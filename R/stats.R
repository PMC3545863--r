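# Assembly and marker summary statistics: contig-set descriptives (N50,
# GC%, size bins), marker density, and half-up percentage arithmetic.

#' Summary statistics of a contig assembly
#'
#' N50 is the length L such that contigs of length >= L contain at least
#' half of the assembled bases (sort descending, accumulate). GC% is
#' (G+C)/(A+C+G+T) * 100 with `N` excluded from the denominator. Size
#' bins follow the conventional report layout (<1 KB, 1-2, ..., 10-20 KB,
#' plus an overflow bin for anything larger); bin counts always sum to
#' the number of contigs.
#'
#' @param contigs contig tibble (`id`, `seq`) with at least one contig.
#' @return one-row tibble of class `capsi_assembly_stats`: `n_contigs`,
#'   `total_nt`, `gc_pct` (1 decimal), `longest`, `mean_len` (1 decimal),
#'   `median_len`, `n50`, and bin counts `n_lt_1kb` .. `n_ge_20kb`.
#' @export
assembly_stats <- function(contigs) {
  if (nrow(contigs) == 0) abort("assembly statistics require at least one contig")
  len <- nchar(contigs$seq)
  total <- sum(len)
  gc <- sum(stringr::str_count(contigs$seq, "[GC]"))
  acgt <- sum(stringr::str_count(contigs$seq, "[ACGT]"))
  sorted <- sort(len, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= total / 2)[1]]
  breaks <- c(0, 1e3, 2e3, 3e3, 4e3, 5e3, 1e4, 2e4, Inf)
  bins <- table(cut(len, breaks = breaks, right = FALSE))
  out <- tibble::tibble(
    n_contigs = nrow(contigs),
    total_nt = total,
    gc_pct = round_half_up(100 * gc / acgt, 1),
    longest = max(len),
    mean_len = round_half_up(mean(len), 1),
    median_len = median(len),
    n50 = n50,
    n_lt_1kb = as.integer(bins[1]), n_1_2kb = as.integer(bins[2]),
    n_2_3kb = as.integer(bins[3]), n_3_4kb = as.integer(bins[4]),
    n_4_5kb = as.integer(bins[5]), n_5_10kb = as.integer(bins[6]),
    n_10_20kb = as.integer(bins[7]), n_ge_20kb = as.integer(bins[8])
  )
  class(out) <- c("capsi_assembly_stats", class(out))
  out
}

#' Marker density of an assembly
#'
#' @param total_bases bases examined.
#' @param n_markers markers found in them.
#' @param n_contigs optional contig count for the per-contig rate.
#' @return one-row tibble `total_bases`, `n_markers`, `bases_per_marker`
#'   (nearest integer), `markers_per_contig` (one decimal; NA without
#'   `n_contigs`). With `n_markers = 0` the rates are NA.
#' @export
snp_density <- function(total_bases, n_markers, n_contigs = NULL) {
  tibble::tibble(
    total_bases = total_bases,
    n_markers = n_markers,
    bases_per_marker = if (n_markers >= 1) round_half_up(total_bases / n_markers) else NA_real_,
    markers_per_contig = if (!is.null(n_contigs) && n_contigs >= 1) {
      round_half_up(n_markers / n_contigs, 1)
    } else NA_real_
  )
}

#' Percentage with half-up rounding
#'
#' @param numerator,denominator the ratio to report (`denominator >= 1`).
#' @param decimals decimal places (default 1).
#' @return `100 * numerator / denominator`, rounded half-up.
#' @export
rate_pct <- function(numerator, denominator, decimals = 1) {
  if (any(denominator < 1)) abort("denominator must be >= 1")
  round_half_up(100 * numerator / denominator, decimals)
}
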