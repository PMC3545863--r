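# Cross-assembly SNP comparison: a 101-nt fragment centred on each SNP is
# aligned reciprocally against the other assembly's SNP fragments; a valid
# hit has at least 80 matching bases, and a SNP is common when it forms a
# reciprocal best pair. The BLASTN step of the original protocol is
# replaced by exact Smith-Waterman local alignment with fixed scoring,
# which removes database-size-dependent E-values and makes the comparison
# bit-reproducible; both orientations are searched.

align_submat <- function(match = 1, mismatch = -2) {
  letters5 <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(m) <- match
  m["N", "N"] <- mismatch # N never counts as informative agreement
  m
}

#' Extract the 101-nt window centred on a SNP
#'
#' @param contigs contig tibble (`id`, `seq`).
#' @param snps tibble with `contig_id`, `pos` (filtered SNPs are
#'   guaranteed 50 bases of flank; positions closer to a contig end are an
#'   error).
#' @param flank flank size each side (default 50, window = 2*flank + 1).
#' @return tibble `snp_id` (`contig:pos`), `contig_id`, `pos`, `seq`
#'   (window, SNP base at offset `flank + 1`).
#' @export
extract_snp_windows <- function(contigs, snps, flank = 50) {
  seqs <- setNames(contigs$seq, contigs$id)
  lens <- setNames(nchar(contigs$seq), contigs$id)
  if (any(is.na(lens[snps$contig_id]))) {
    abort("SNP references a contig absent from `contigs`")
  }
  bad <- snps$pos - flank < 1 | snps$pos + flank > lens[snps$contig_id]
  if (any(bad)) {
    abort(paste0(
      "SNP at ", snps$contig_id[bad][1], ":", snps$pos[bad][1],
      " is within ", flank, " bases of a contig end; windows require ",
      flank, " bases of flank (filter SNPs first)"
    ))
  }
  tibble::tibble(
    snp_id = paste0(snps$contig_id, ":", snps$pos),
    contig_id = snps$contig_id, pos = snps$pos,
    seq = unname(substr(seqs[snps$contig_id], snps$pos - flank, snps$pos + flank))
  )
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment under simple scoring (defaults: match
#' +1, mismatch -2, gap of length L costs `gap_open + L * gap_ext` =
#' 5 + 2L). Returns the match statistics of the optimal alignment (the
#' alignment engine's deterministic traceback resolves score ties).
#'
#' @param a,b sequences (A/C/G/T/N).
#' @param match,mismatch,gap_open,gap_ext scoring parameters (costs given
#'   as positive numbers for the gap terms).
#' @return one-row tibble `n_matches`, `n_aligned` (alignment columns),
#'   `identity`, `score`.
#' @export
local_align <- function(a, b, match = 1, mismatch = -2, gap_open = 5, gap_ext = 2) {
  al <- Biostrings::pairwiseAlignment(
    a, b, type = "local",
    substitutionMatrix = align_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_ext
  )
  n_aligned <- Biostrings::nchar(al)
  nm <- Biostrings::nmatch(al)
  tibble::tibble(
    n_matches = nm, n_aligned = n_aligned,
    identity = ifelse(n_aligned > 0, nm / n_aligned, 0),
    score = Biostrings::score(al)
  )
}

# vectorised: align many patterns against one subject; returns matrix with
# rows n_matches, n_aligned, score
align_many <- function(patterns, subject, match = 1, mismatch = -2,
                       gap_open = 5, gap_ext = 2) {
  al <- Biostrings::pairwiseAlignment(
    patterns, subject, type = "local",
    substitutionMatrix = align_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_ext
  )
  rbind(
    n_matches = Biostrings::nmatch(al),
    n_aligned = Biostrings::nchar(al),
    score = Biostrings::score(al)
  )
}

# best match count over both orientations for a single pair
best_match_count <- function(a, b) {
  f <- align_many(a, b)
  r <- align_many(a, revcomp(b))
  as.integer(max(f["n_matches", 1], r["n_matches", 1]))
}

#' Reciprocal comparison of two SNP window sets
#'
#' Every window of set A is aligned locally against every window of set B
#' in both orientations; a valid hit has at least `min_matches` matching
#' bases. A SNP pair is common when each member is the other's best valid
#' hit (reciprocal best hit, ties broken toward the smaller index);
#' remaining SNPs are unique to their assembly. The partition is exact:
#' `n_common + n_unique` equals the set size on each side.
#'
#' @param windows_a,windows_b window tibbles from [extract_snp_windows()].
#' @param min_matches minimum matching bases for a valid hit (default 80).
#' @return object of class `snp_comparison`: list with `pairs` (tibble
#'   `snp_a`, `snp_b`, `n_matches`), `n_common`, `n_unique_a`,
#'   `n_unique_b`, `n_a`, `n_b`, `min_matches`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
compare_snp_sets <- function(windows_a, windows_b, min_matches = 80) {
  na <- nrow(windows_a); nb <- nrow(windows_b)
  M <- matrix(0L, na, nb)
  if (na > 0 && nb > 0) {
    for (j in seq_len(nb)) {
      f <- align_many(windows_a$seq, windows_b$seq[j])
      r <- align_many(windows_a$seq, revcomp(windows_b$seq[j]))
      M[, j] <- as.integer(pmax(f["n_matches", ], r["n_matches", ]))
    }
  }
  valid <- M >= min_matches
  best_b_of_a <- apply(M, 1, function(r) if (any(r > 0)) which.max(r) else NA_integer_)
  best_a_of_b <- apply(M, 2, function(c) if (any(c > 0)) which.max(c) else NA_integer_)
  common_a <- which(
    !is.na(best_b_of_a) &
      valid[cbind(seq_len(na), ifelse(is.na(best_b_of_a), 1L, best_b_of_a))] &
      best_a_of_b[ifelse(is.na(best_b_of_a), 1L, best_b_of_a)] == seq_len(na)
  )
  pairs <- tibble::tibble(
    snp_a = windows_a$snp_id[common_a],
    snp_b = windows_b$snp_id[best_b_of_a[common_a]],
    n_matches = M[cbind(common_a, best_b_of_a[common_a])]
  )
  structure(
    list(
      pairs = pairs,
      n_common = nrow(pairs),
      n_unique_a = na - nrow(pairs),
      n_unique_b = nb - nrow(pairs),
      n_a = na, n_b = nb, min_matches = min_matches
    ),
    class = "snp_comparison"
  )
}

#' @export
print.snp_comparison <- function(x, ...) {
  cat("<snp_comparison> ", x$n_common, " common, ",
      x$n_unique_a, " unique to A (of ", x$n_a, "), ",
      x$n_unique_b, " unique to B (of ", x$n_b, ")\n", sep = "")
  invisible(x)
}

#' Look up a SNP window in another assembly (KASPar-window rule)
#'
#' Finds the best local alignment of a 101-nt SNP window against every
#' contig of an assembly (both orientations) and declares a hit when the
#' identity is at least `min_identity` over at least `min_aligned` aligned
#' bases -- a deterministic surrogate for a BLASTN E-value cut at fixed
#' window length.
#'
#' @param window a window sequence (string) or one-row tibble from
#'   [extract_snp_windows()].
#' @param contigs contig tibble (`id`, `seq`) of the target assembly.
#' @param min_identity minimum identity of the best hit (default 0.95).
#' @param min_aligned minimum aligned bases (default 80).
#' @return one-row tibble `contig_id`, `n_matches`, `n_aligned`,
#'   `identity`, `score` for a hit; zero-row tibble otherwise.
#' @export
kaspar_window_lookup <- function(window, contigs, min_identity = 0.95,
                                 min_aligned = 80) {
  if (is.data.frame(window)) window <- window$seq[[1]]
  stats <- lapply(contigs$seq, function(ctg) {
    f <- align_many(window, ctg)
    r <- align_many(window, revcomp(ctg))
    if (f["score", 1] >= r["score", 1]) f[, 1] else r[, 1]
  })
  sc <- vapply(stats, `[[`, numeric(1), "score")
  best <- which.max(sc)
  s <- stats[[best]]
  identity <- if (s[["n_aligned"]] > 0) s[["n_matches"]] / s[["n_aligned"]] else 0
  hit <- identity >= min_identity && s[["n_aligned"]] >= min_aligned
  out <- tibble::tibble(
    contig_id = contigs$id[best],
    n_matches = as.integer(s[["n_matches"]]),
    n_aligned = as.integer(s[["n_aligned"]]),
    identity = identity, score = s[["score"]]
  )
  if (hit) out else out[0, ]
}
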