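# Microsatellite (SSR) discovery: MISA-style scanning for perfect tandem
# repeats of unit size 2-6 at thresholds (2/6) (3/5) (4/5) (5/5) (6/5),
# compound merging with a <= 100 bp spacer, canonical motif classes
# (rotation + reverse-complement equivalence), cross-assembly SSR matching
# and Primer3 task generation.

#' Default SSR repeat-count thresholds
#'
#' Minimum number of repeats required per unit size:
#' di 6, tri 5, tetra 5, penta 5, hexa 5. Mononucleotide runs are not
#' scanned.
#'
#' @return named integer vector, names = unit sizes `"2"`..`"6"`.
#' @export
ssr_thresholds <- function() {
  c(`2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)
}

# scan one sequence; returns tibble(start, end, motif, unit_size, repeat_count)
find_perfect_ssrs_seq <- function(seq, thresholds = ssr_thresholds()) {
  n <- nchar(seq)
  x <- utf8ToInt(seq)
  valid <- BASE_CODE[x] %in% 1:4
  rows <- list()
  for (u in as.integer(names(thresholds))) {
    thr <- thresholds[[as.character(u)]]
    if (n < u * thr) next
    eq <- x[1:(n - u)] == x[(u + 1):n] & valid[1:(n - u)] & valid[(u + 1):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run_i <- which(r$values)
    for (ri in run_i) {
      s <- starts[ri]
      reg_len <- r$lengths[ri] + u
      k <- reg_len %/% u
      if (k < thr) next
      motif <- substr(seq, s, s + u - 1L)
      if (is_reducible_motif(motif)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        start = s, end = s + k * u - 1L, motif = motif,
        unit_size = u, repeat_count = k
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      start = integer(), end = integer(), motif = character(),
      unit_size = integer(), repeat_count = integer()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$start, .data$unit_size)
}

#' Find perfect SSRs in a set of contigs
#'
#' Reports maximal perfect tandem runs of unit size 2-6 meeting the
#' repeat-count thresholds. A run is reported at the leftmost base of its
#' maximal repeat region and truncated to complete repeats; runs whose
#' motif is itself a tandem of a smaller unit (e.g. `ATAT` at unit size 4)
#' are reported only at the smaller unit size; `N` breaks any run.
#' Overlapping runs of different, non-reducible unit sizes are all
#' reported.
#'
#' @param contigs contig tibble (`id`, `seq`), or a character vector of
#'   sequences.
#' @param thresholds named vector, unit size -> minimum repeats.
#' @return tibble `contig_id`, `start`, `end` (1-based inclusive),
#'   `motif` (as observed), `unit_size`, `repeat_count`,
#'   `canonical_class`.
#' @export
find_ssrs <- function(contigs, thresholds = ssr_thresholds()) {
  if (is.character(contigs)) {
    ids <- names(contigs) %||% paste0("seq", seq_along(contigs))
    contigs <- tibble::tibble(id = ids, seq = unname(contigs))
  }
  out <- purrr::map2_dfr(contigs$id, contigs$seq, function(id, sq) {
    res <- find_perfect_ssrs_seq(sq, thresholds)
    if (nrow(res)) res$contig_id <- id
    res
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(
      contig_id = character(), start = integer(), end = integer(),
      motif = character(), unit_size = integer(), repeat_count = integer(),
      canonical_class = character()
    ))
  }
  out$canonical_class <- canonical_motif(out$motif)
  dplyr::arrange(
    out[, c("contig_id", "start", "end", "motif", "unit_size", "repeat_count", "canonical_class")],
    .data$contig_id, .data$start
  )
}

rotations <- function(m) {
  u <- nchar(m)
  vapply(seq_len(u), function(i) {
    paste0(substr(m, i, u), substr(m, 1, i - 1))
  }, character(1))
}

#' Canonical motif class of an SSR motif
#'
#' All rotations of the motif and all rotations of its reverse complement
#' form one equivalence class; the lexicographically smallest member is
#' the class representative. The printed label is
#' `"rep/rep2"` where `rep2` is the smallest rotation of the reverse
#' complement of the representative that differs from it (so `CT` ->
#' `AG/CT`, `GTT` -> `AAC/GTT`, and the self-complementary `TA` ->
#' `AT/TA`).
#'
#' @param motif character vector of motifs over A/C/G/T, length 2-6.
#' @return character vector of class labels.
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    if (grepl("[^ACGT]", m) || nchar(m) < 2 || nchar(m) > 6) {
      abort(paste0("motif must be 2-6 bases over ACGT, got '", m, "'"))
    }
    all_rot <- c(rotations(m), rotations(revcomp(m)))
    rep1 <- min(all_rot)
    rc_rot <- rotations(revcomp(rep1))
    others <- setdiff(rc_rot, rep1)
    rep2 <- if (length(others)) min(others) else rep1
    paste0(rep1, "/", rep2)
  }, character(1), USE.NAMES = FALSE)
}

#' Merge nearby SSRs into compound records
#'
#' Consecutive SSRs on a contig separated by at most `max_spacer`
#' intervening bases are chained into one compound record; every input SSR
#' belongs to exactly one output record. Compound records are formatted in
#' MISA's display style, `(AC)6tt(AG)7`, with the spacer sequence in lower
#' case; overlapping members (possible for different unit sizes) are
#' joined with `*`.
#'
#' @param ssrs tibble from [find_ssrs()].
#' @param contigs contig tibble (`id`, `seq`); needed to render spacer
#'   sequences (optional: without it spacers render as `n` runs).
#' @param max_spacer maximum spacer length in bp (default 100).
#' @return tibble with one row per output record: `contig_id`, `kind`
#'   (`"perfect"`/`"compound"`), `start`, `end`, `size`, `n_members`,
#'   `ssr` (formatted text), `motif`, `unit_size`, `repeat_count`,
#'   `canonical_class` (NA for compound records).
#' @export
merge_compound <- function(ssrs, contigs = NULL, max_spacer = 100) {
  if (nrow(ssrs) == 0) {
    return(tibble::tibble(
      contig_id = character(), kind = character(), start = integer(),
      end = integer(), size = integer(), n_members = integer(),
      ssr = character(), motif = character(), unit_size = integer(),
      repeat_count = integer(), canonical_class = character()
    ))
  }
  seqs <- if (!is.null(contigs)) setNames(contigs$seq, contigs$id) else NULL
  ssrs |>
    dplyr::arrange(.data$contig_id, .data$start) |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::group_modify(function(df, key) {
      gap <- c(Inf, df$start[-1] - df$end[-nrow(df)] - 1L)
      grp <- cumsum(gap > max_spacer)
      df$.grp <- grp
      cid <- key$contig_id[[1]]
      df |>
        dplyr::group_by(.data$.grp) |>
        dplyr::group_modify(function(g, k2) {
          if (nrow(g) == 1) {
            return(tibble::tibble(
              kind = "perfect", start = g$start, end = g$end,
              size = g$end - g$start + 1L, n_members = 1L,
              ssr = sprintf("(%s)%d", g$motif, g$repeat_count),
              motif = g$motif, unit_size = g$unit_size,
              repeat_count = g$repeat_count, canonical_class = g$canonical_class
            ))
          }
          parts <- sprintf("(%s)%d", g$motif, g$repeat_count)
          joined <- parts[1]
          for (i in 2:nrow(g)) {
            sp <- g$start[i] - g$end[i - 1] - 1L
            sep <- if (sp < 0) "*"
              else if (sp == 0) ""
              else if (!is.null(seqs)) tolower(substr(seqs[[cid]], g$end[i - 1] + 1L, g$start[i] - 1L))
              else strrep("n", sp)
            joined <- paste0(joined, sep, parts[i])
          }
          tibble::tibble(
            kind = "compound", start = min(g$start), end = max(g$end),
            size = max(g$end) - min(g$start) + 1L, n_members = nrow(g),
            ssr = joined, motif = paste(g$motif, collapse = "+"),
            unit_size = NA_integer_, repeat_count = NA_integer_,
            canonical_class = NA_character_
          )
        }) |>
        dplyr::ungroup() |>
        dplyr::select(-".grp")
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$contig_id, .data$start)
}

#' Match SSRs between two assemblies
#'
#' An SSR pair is declared common when canonical class and repeat count
#' are identical and the flanking windows (SSR span extended by `flank`
#' bases each side) align locally with at least `min_matches` matching
#' bases (both orientations tried). Each SSR is matched at most once,
#' assigned greedily by descending match count.
#'
#' @param ssrs_a,ssrs_b perfect-SSR tibbles from [find_ssrs()].
#' @param contigs_a,contigs_b the corresponding contig tibbles.
#' @param flank flanking window size (default 50).
#' @param min_matches minimum matching bases in the window alignment.
#' @return tibble of matched pairs: `contig_a`, `start_a`, `contig_b`,
#'   `start_b`, `canonical_class`, `repeat_count`, `n_matches`.
#' @export
match_ssrs_across_assemblies <- function(ssrs_a, contigs_a, ssrs_b, contigs_b,
                                         flank = 50, min_matches = 80) {
  empty <- tibble::tibble(
    contig_a = character(), start_a = integer(), contig_b = character(),
    start_b = integer(), canonical_class = character(),
    repeat_count = integer(), n_matches = integer()
  )
  if (nrow(ssrs_a) == 0 || nrow(ssrs_b) == 0) return(empty)
  wa <- ssr_windows(ssrs_a, contigs_a, flank)
  wb <- ssr_windows(ssrs_b, contigs_b, flank)
  cand <- dplyr::inner_join(
    dplyr::mutate(wa, .ia = dplyr::row_number()),
    dplyr::mutate(wb, .ib = dplyr::row_number()),
    by = c("canonical_class", "repeat_count"), suffix = c("_a", "_b"),
    relationship = "many-to-many"
  )
  if (nrow(cand) == 0) return(empty)
  cand$n_matches <- vapply(seq_len(nrow(cand)), function(i) {
    best_match_count(cand$window_a[i], cand$window_b[i])
  }, integer(1))
  cand <- cand[cand$n_matches >= min_matches, ]
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(-cand$n_matches, cand$.ia, cand$.ib), ]
  used_a <- logical(max(cand$.ia)); used_b <- logical(max(cand$.ib))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!used_a[cand$.ia[i]] && !used_b[cand$.ib[i]]) {
      keep[i] <- TRUE
      used_a[cand$.ia[i]] <- TRUE
      used_b[cand$.ib[i]] <- TRUE
    }
  }
  res <- cand[keep, ]
  tibble::tibble(
    contig_a = res$contig_id_a, start_a = res$start_a,
    contig_b = res$contig_id_b, start_b = res$start_b,
    canonical_class = res$canonical_class, repeat_count = res$repeat_count,
    n_matches = res$n_matches
  )
}

ssr_windows <- function(ssrs, contigs, flank) {
  seqs <- setNames(contigs$seq, contigs$id)
  lens <- setNames(nchar(contigs$seq), contigs$id)
  dplyr::mutate(
    ssrs,
    window = substr(
      seqs[.data$contig_id],
      pmax(1L, .data$start - flank),
      pmin(lens[.data$contig_id], .data$end + flank)
    )
  )
}

# ---------------------------------------------------------------------------
# Primer3 task generation and output parsing

#' Generate Primer3 boulder-IO input records for SSRs
#'
#' One record per SSR, targeting the SSR span, with the assay design
#' policy used for these markers: amplicon 100-300 bp, optimal annealing
#' temperature 60 degrees C, optimal primer length 20 nt.
#' `SEQUENCE_TARGET` uses Primer3's own 0-based start convention. SSRs
#' flush against a contig end are still emitted but flagged (primer design
#' cannot be guaranteed).
#'
#' @param ssrs tibble from [find_ssrs()] (or the perfect rows of
#'   [merge_compound()]).
#' @param contigs contig tibble (`id`, `seq`).
#' @param product_size_range length-2 amplicon size range (bp).
#' @param opt_tm optimal primer melting temperature (degrees C).
#' @param opt_size optimal primer length (nt).
#' @return tibble `seq_id`, `record` (boulder text incl. terminating `=`),
#'   `warn_flank` (TRUE when the SSR touches a contig end). Concatenate
#'   `record` with newlines to obtain the Primer3 input file.
#' @export
make_primer3_input <- function(ssrs, contigs, product_size_range = c(100, 300),
                               opt_tm = 60, opt_size = 20) {
  seqs <- setNames(contigs$seq, contigs$id)
  lens <- setNames(nchar(contigs$seq), contigs$id)
  n <- nrow(ssrs)
  seq_id <- sprintf("%s_ssr%d", ssrs$contig_id, seq_len(n))
  warn <- ssrs$start <= 1L | ssrs$end >= lens[ssrs$contig_id]
  rec <- vapply(seq_len(n), function(i) {
    paste(
      c(
        paste0("SEQUENCE_ID=", seq_id[i]),
        paste0("SEQUENCE_TEMPLATE=", seqs[[ssrs$contig_id[i]]]),
        paste0("SEQUENCE_TARGET=", ssrs$start[i] - 1L, ",", ssrs$end[i] - ssrs$start[i] + 1L),
        paste0("PRIMER_PRODUCT_SIZE_RANGE=", product_size_range[1], "-", product_size_range[2]),
        sprintf("PRIMER_OPT_TM=%.1f", opt_tm),
        paste0("PRIMER_OPT_SIZE=", opt_size),
        "="
      ),
      collapse = "\n"
    )
  }, character(1))
  tibble::tibble(seq_id = seq_id, record = rec, warn_flank = unname(warn))
}

#' Parse Primer3 boulder-IO output into a primer-pair table
#'
#' @param lines character vector of Primer3 output lines (or a single
#'   string with embedded newlines).
#' @return tibble with one row per returned primer pair: `seq_id`,
#'   `pair_index`, `left_seq`, `right_seq`, `left_tm`, `right_tm`,
#'   `product_size` (NA where Primer3 omitted a tag).
#' @export
parse_primer3_output <- function(lines) {
  if (length(lines) == 1 && grepl("\n", lines)) {
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  }
  recs <- split(lines, cumsum(dplyr::lag(lines == "=", default = FALSE)))
  out <- purrr::map_dfr(recs, function(rl) {
    rl <- rl[rl != "=" & nzchar(rl)]
    if (length(rl) == 0) return(NULL)
    kv <- strsplit(rl, "=", fixed = TRUE)
    keys <- vapply(kv, `[[`, character(1), 1)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
    tags <- setNames(vals, keys)
    sid <- tags[["SEQUENCE_ID"]] %||% tags[["PRIMER_SEQUENCE_ID"]] %||% NA_character_
    idx <- unique(as.integer(sub(
      "^PRIMER_LEFT_([0-9]+)_SEQUENCE$", "\\1",
      grep("^PRIMER_LEFT_[0-9]+_SEQUENCE$", keys, value = TRUE)
    )))
    if (length(idx) == 0) return(NULL)
    purrr::map_dfr(sort(idx), function(i) {
      tg <- function(k) if (k %in% names(tags)) tags[[k]] else NA_character_
      tibble::tibble(
        seq_id = sid, pair_index = i,
        left_seq = tg(sprintf("PRIMER_LEFT_%d_SEQUENCE", i)),
        right_seq = tg(sprintf("PRIMER_RIGHT_%d_SEQUENCE", i)),
        left_tm = as.numeric(tg(sprintf("PRIMER_LEFT_%d_TM", i))),
        right_tm = as.numeric(tg(sprintf("PRIMER_RIGHT_%d_TM", i))),
        product_size = as.integer(tg(sprintf("PRIMER_PAIR_%d_PRODUCT_SIZE", i)))
      )
    })
  })
  out
}
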