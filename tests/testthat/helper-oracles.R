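# Independent oracles used by the property tests. These deliberately take
# the slow, definitional route (regex scans, quadratic DP, exhaustive
# position scans) and share no code with the implementation they check.

# --- SSR scanner oracle: leftmost greedy regex over every unit size -------
oracle_ssrs <- function(seq, thresholds = ssr_thresholds()) {
  rows <- list()
  for (u in as.integer(names(thresholds))) {
    thr <- thresholds[[as.character(u)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, thr - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    lens <- attr(m, "match.length")
    for (i in seq_along(m)) {
      s <- m[i]
      motif <- substr(seq, s, s + u - 1L)
      # reducible motifs belong to a smaller unit size
      reducible <- FALSE
      for (d in seq_len(u - 1)) {
        if (u %% d == 0 && strrep(substr(motif, 1, d), u / d) == motif) {
          reducible <- TRUE
          break
        }
      }
      if (reducible) next
      k <- lens[i] %/% u
      rows[[length(rows) + 1]] <- data.frame(
        start = s, unit_size = u, repeat_count = k, motif = motif,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), unit_size = integer(),
                      repeat_count = integer(), motif = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$unit_size), , drop = FALSE]
}

# --- local alignment oracle: quadratic Gotoh DP, gap length L costs
#     open + L * ext, local (scores floored at 0); returns the best score
oracle_local_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = 5, gap_ext = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1) # gap in A (consume B)
  F <- matrix(NEG, n + 1, m + 1) # gap in B (consume A)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_ext, E[i + 1, j] - gap_ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_ext, F[i, j + 1] - gap_ext)
      s <- if (A[i] == B[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
      if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
    }
  }
  best
}

# --- read placement oracle: exhaustive Hamming scan over all positions ----
oracle_best_placement <- function(read, contigs) {
  rl <- nchar(read)
  best <- NULL; best_mm <- Inf; ties <- 0L
  for (ci in seq_len(nrow(contigs))) {
    sq <- contigs$seq[ci]
    L <- nchar(sq)
    if (L < rl) next
    for (p in 1:(L - rl + 1)) {
      mm <- sum(charToRaw(substr(sq, p, p + rl - 1)) != charToRaw(read))
      if (mm < best_mm) {
        best_mm <- mm; best <- c(contigs$id[ci], p); ties <- 1L
      } else if (mm == best_mm) {
        ties <- ties + 1L
      }
    }
  }
  list(contig = best[1], pos = as.integer(best[2]), mismatches = best_mm,
       unique = ties == 1L)
}

# --- small fixture builders ----------------------------------------------
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

make_reads <- function(seqs, quals = NULL, ids = NULL) {
  n <- length(seqs)
  tibble::tibble(
    id = ids %||% paste0("r", seq_len(n)),
    seq = seqs,
    quals = quals %||% lapply(nchar(seqs), function(L) rep(30L, L))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
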