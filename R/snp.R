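# SNP discovery. Two callers share this file:
#  * the three-genotype pileup caller: per-line allele calls at minimum
#    depth 10, a putative SNP where two lines share a homozygous allele and
#    the third is homozygous for a different one, heterozygous positions
#    tracked separately; filters require >= 50 bp distance from splice
#    junctions, other candidate SNPs and heterozygote positions, and a
#    summed depth of >= 20 reads across the lines;
#  * the EST consensus-alignment caller: a position is polymorphic when two
#    alleles each reach depth 2 in the pileup of member sequences; filters
#    remove positions within 50 bp of contig ends and, of two candidates
#    closer than 50 bp, keep only the higher-coverage one.

BASE_CODE <- local({
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L
  code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L
  code[utf8ToInt("T")] <- 4L
  code[utf8ToInt("N")] <- 5L
  code
})

#' Build a per-genotype pileup from alignments
#'
#' CIGAR-aware: `M` consumes read and reference, `I` consumes only the
#' read, `D` only the reference (reference positions under a deletion
#' receive no base count), `S` is ignored. Alignments that would overrun
#' their contig are skipped and counted. `N` bases are tallied in `other`
#' and excluded from depth.
#'
#' @param alignments alignment tibble (`genotype`, `contig_id`, `pos`,
#'   `cigar`, `seq`), e.g. from [naive_map()] or [read_sam()].
#' @param contigs contig tibble (`id`, `length`).
#' @return tibble with one row per (contig, position, genotype):
#'   `contig_id`, `pos`, `genotype`, `A`, `C`, `G`, `T`, `other`, `depth`
#'   (sum of A/C/G/T). Attribute `n_skipped` counts overrunning records.
#' @export
build_pileup <- function(alignments, contigs) {
  gts <- sort(unique(alignments$genotype))
  ngen <- length(gts)
  clen <- setNames(as.integer(contigs$length), contigs$id)
  offset <- setNames(c(0L, cumsum(as.integer(contigs$length))[-nrow(contigs)]), contigs$id)
  total_len <- sum(clen)
  tab <- integer(total_len * ngen * 5L)

  unknown <- !(alignments$contig_id %in% contigs$id)
  if (any(unknown)) {
    abort(paste0("alignment references unknown contig: ", alignments$contig_id[unknown][1]))
  }
  simple <- alignments$cigar == paste0(nchar(alignments$seq), "M")
  n_skipped <- 0L

  add_counts <- function(gpos, base_code, gen_idx) {
    keep <- base_code > 0L
    idx <- (gpos[keep] - 1L) * (ngen * 5L) + (gen_idx[keep] - 1L) * 5L + base_code[keep]
    add <- tabulate(idx, nbins = total_len * ngen * 5L)
    tab <<- tab + add
  }

  if (any(simple)) {
    a <- alignments[simple, ]
    lens <- nchar(a$seq)
    fits <- a$pos >= 1L & a$pos + lens - 1L <= clen[a$contig_id]
    n_skipped <- n_skipped + sum(!fits)
    a <- a[fits, ]
    lens <- lens[fits]
    if (nrow(a)) {
      gstart <- offset[a$contig_id] + a$pos
      gpos <- sequence(lens, from = gstart)
      base_code <- BASE_CODE[utf8ToInt(paste(a$seq, collapse = ""))]
      gen_idx <- rep(match(a$genotype, gts), lens)
      add_counts(gpos, base_code, gen_idx)
    }
  }
  if (any(!simple)) {
    a <- alignments[!simple, ]
    gp_all <- integer(0); bc_all <- integer(0); gi_all <- integer(0)
    for (i in seq_len(nrow(a))) {
      ops <- cigar_ops(a$cigar[i])
      rpos <- a$pos[i]; qpos <- 1L
      gp <- integer(0); bc <- integer(0)
      overrun <- FALSE
      for (j in seq_along(ops$op)) {
        len <- ops$len[j]
        switch(ops$op[j],
          M = {
            if (rpos + len - 1L > clen[a$contig_id[i]] || rpos < 1L) { overrun <- TRUE; break }
            gp <- c(gp, offset[a$contig_id[i]] + rpos:(rpos + len - 1L))
            bc <- c(bc, BASE_CODE[utf8ToInt(substr(a$seq[i], qpos, qpos + len - 1L))])
            rpos <- rpos + len; qpos <- qpos + len
          },
          I = { qpos <- qpos + len },
          D = { rpos <- rpos + len },
          S = { qpos <- qpos + len }
        )
      }
      if (overrun) { n_skipped <- n_skipped + 1L; next }
      gp_all <- c(gp_all, gp)
      bc_all <- c(bc_all, bc)
      gi_all <- c(gi_all, rep(match(a$genotype[i], gts), length(gp)))
    }
    if (length(gp_all)) add_counts(gp_all, bc_all, gi_all)
  }

  arr <- array(tab, dim = c(5L, ngen, total_len))
  contig_rep <- rep(contigs$id, clen)
  pos_rep <- sequence(clen)
  rows <- lapply(seq_len(ngen), function(g) {
    m <- t(arr[, g, , drop = TRUE])
    tibble::tibble(
      contig_id = contig_rep, pos = pos_rep, genotype = gts[g],
      A = m[, 1], C = m[, 2], G = m[, 3], T = m[, 4], other = m[, 5],
      depth = m[, 1] + m[, 2] + m[, 3] + m[, 4]
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$contig_id, .data$pos, .data$genotype)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Genotype a single line's base counts at one position
#'
#' A line is called homozygous for base `b` when depth >= `min_line_depth`
#' and `b` carries at least `hom_fraction` of the depth; heterozygous when
#' depth suffices, no base reaches `hom_fraction`, and the second allele
#' has at least `het_min_count` reads; `low_depth` otherwise.
#'
#' @param counts named numeric vector of A/C/G/T counts.
#' @param min_line_depth minimum reads to call the line (default 10).
#' @param hom_fraction majority fraction required for a homozygous call.
#' @param het_min_count minimum reads on the second allele for a het call.
#' @return list with `status` (`"hom"`, `"het"`, `"low_depth"`), `allele`
#'   (base for hom calls, else NA), `depth`, `major_fraction`.
#' @export
call_line <- function(counts, min_line_depth = 10, hom_fraction = 0.9,
                      het_min_count = 2) {
  cnt <- setNames(numeric(4), BASES)
  cnt[names(counts)] <- counts
  depth <- sum(cnt)
  if (depth == 0) {
    return(list(status = "low_depth", allele = NA_character_, depth = 0, major_fraction = NA_real_))
  }
  major <- names(cnt)[which.max(cnt)]
  frac <- max(cnt) / depth
  second <- sort(cnt, decreasing = TRUE)[2]
  status <- if (depth >= min_line_depth && frac >= hom_fraction) "hom"
    else if (depth >= min_line_depth && second >= het_min_count) "het"
    else "low_depth"
  list(
    status = status,
    allele = if (status == "hom") major else NA_character_,
    depth = depth, major_fraction = frac
  )
}

#' Genotype every line at every pileup position
#'
#' Vectorised version of [call_line()] over a [build_pileup()] tibble.
#'
#' @param pileup tibble from [build_pileup()].
#' @inheritParams call_line
#' @return the pileup tibble with added columns `status`, `allele`,
#'   `major_fraction`.
#' @export
call_lines <- function(pileup, min_line_depth = 10, hom_fraction = 0.9,
                       het_min_count = 2) {
  m <- cbind(pileup$A, pileup$C, pileup$G, pileup$T)
  depth <- pileup$depth
  mx <- pmax(pileup$A, pileup$C, pileup$G, pileup$T)
  major <- BASES[max.col(m, ties.method = "first")]
  second <- apply_second_largest(m)
  frac <- ifelse(depth > 0, mx / depth, NA_real_)
  status <- ifelse(
    depth >= min_line_depth & frac >= hom_fraction, "hom",
    ifelse(depth >= min_line_depth & second >= het_min_count, "het", "low_depth")
  )
  out <- pileup
  out$status <- status
  out$allele <- ifelse(status == "hom", major, NA_character_)
  out$major_fraction <- frac
  out
}

# second-largest value in each row of a 4-column count matrix
apply_second_largest <- function(m) {
  mx_i <- max.col(m, ties.method = "first")
  m[cbind(seq_len(nrow(m)), mx_i)] <- -1L
  pmax(m[, 1], m[, 2], m[, 3], m[, 4])
}

#' Call putative SNPs with the two-out-of-three homozygote rule
#'
#' A position yields a putative SNP when all three lines are called
#' homozygous, two share the same allele and the third differs. Positions
#' where any line is heterozygous are recorded on a separate track used by
#' the adjacency filter. Tri-allelic positions (all three lines homozygous
#' for different bases) are not emitted.
#'
#' @param line_calls tibble from [call_lines()] with exactly three
#'   genotypes per position.
#' @return list with `snps` (tibble `contig_id`, `pos`, `ref` = shared
#'   majority allele, `alt` = minority allele, `allele_<genotype>`,
#'   `depth_<genotype>`, `total_depth`, `source`, `flags`) and
#'   `het_positions` (tibble `contig_id`, `pos`).
#' @export
call_iga_snps <- function(line_calls) {
  gts <- sort(unique(line_calls$genotype))
  if (length(gts) != 3) {
    abort("the two-out-of-three rule requires exactly 3 genotypes")
  }
  lc <- dplyr::arrange(line_calls, .data$contig_id, .data$pos, .data$genotype)
  n <- nrow(lc) / 3L
  if (n != floor(n)) abort("line_calls must cover every genotype at every position")
  sm <- matrix(lc$status, ncol = 3, byrow = TRUE)
  am <- matrix(lc$allele, ncol = 3, byrow = TRUE)
  dm <- matrix(lc$depth, ncol = 3, byrow = TRUE)
  pos <- lc$pos[seq(1, nrow(lc), by = 3)]
  ctg <- lc$contig_id[seq(1, nrow(lc), by = 3)]

  any_het <- rowSums(sm == "het") > 0
  all_hom <- rowSums(sm == "hom") == 3
  ndiff <- (am[, 1] != am[, 2]) + (am[, 1] != am[, 3]) + (am[, 2] != am[, 3])
  is_snp <- all_hom & !is.na(ndiff) & ndiff == 2

  het_positions <- tibble::tibble(contig_id = ctg[any_het], pos = pos[any_het])

  i <- which(is_snp)
  ref <- ifelse(am[i, 1] == am[i, 2] | am[i, 1] == am[i, 3], am[i, 1], am[i, 2])
  alt <- ifelse(am[i, 1] != ref, am[i, 1], ifelse(am[i, 2] != ref, am[i, 2], am[i, 3]))
  snps <- tibble::tibble(
    contig_id = ctg[i], pos = pos[i], ref = ref, alt = alt
  )
  for (g in seq_along(gts)) {
    snps[[paste0("allele_", gts[g])]] <- am[i, g]
    snps[[paste0("depth_", gts[g])]] <- dm[i, g]
  }
  snps$total_depth <- rowSums(dm[i, , drop = FALSE])
  snps$source <- rep("iga", length(i))
  snps$flags <- rep("", length(i))
  list(snps = snps, het_positions = het_positions)
}

# distance from each position to the nearest element of a sorted vector
nearest_distance <- function(pos, targets) {
  if (length(targets) == 0) return(rep(Inf, length(pos)))
  targets <- sort(targets)
  i <- findInterval(pos, targets)
  lo <- ifelse(i >= 1, targets[pmax(i, 1)], -Inf)
  hi <- ifelse(i < length(targets), targets[pmin(i + 1, length(targets))], Inf)
  pmin(abs(pos - lo), abs(hi - pos))
}

#' Filter putative SNPs by distance and depth rules
#'
#' A SNP is kept iff it lies at least `window` bp from every splice
#' junction, every other candidate SNP and every heterozygote position
#' ("at least 50 bp" reads as distance >= 50: a 49 bp gap fails), and its
#' summed depth across the genotypes is at least `total_min_depth`.
#' Rejected SNPs carry the specific flag(s) in `flags`.
#'
#' @param snps candidate tibble from [call_iga_snps()].
#' @param het_positions heterozygote-position tibble from the same call.
#' @param junctions junction tibble (`contig_id`, `pos`), or NULL for none.
#' @param window minimum distance in bp (default 50).
#' @param total_min_depth minimum summed depth across genotypes (default 20).
#' @return the SNP tibble with `flags` (semicolon-joined rule names, `""`
#'   when clean) and logical `kept` columns.
#' @export
filter_iga_snps <- function(snps, het_positions, junctions = NULL,
                            window = 50, total_min_depth = 20) {
  if (nrow(snps) == 0) {
    snps$kept <- logical(0)
    return(snps)
  }
  jx_by <- if (!is.null(junctions) && nrow(junctions)) split(junctions$pos, junctions$contig_id) else list()
  het_by <- if (nrow(het_positions)) split(het_positions$pos, het_positions$contig_id) else list()

  out <- snps |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::group_modify(function(df, key) {
      cid <- key$contig_id[[1]]
      df <- dplyr::arrange(df, .data$pos)
      d_snp <- if (nrow(df) > 1) {
        gaps <- diff(df$pos)
        pmin(c(Inf, gaps), c(gaps, Inf))
      } else Inf
      d_jx <- nearest_distance(df$pos, jx_by[[cid]] %||% integer(0))
      d_het <- nearest_distance(df$pos, het_by[[cid]] %||% integer(0))
      flags <- mapply(function(fj, fs, fh, fd) {
        paste(c(
          if (fj) "near_junction", if (fs) "adjacent_snp",
          if (fh) "adjacent_het", if (fd) "low_depth_total"
        ), collapse = ";")
      }, d_jx < window, d_snp < window, d_het < window,
         df$total_depth < total_min_depth)
      df$flags <- unname(flags)
      df$kept <- !nzchar(df$flags)
      df
    }) |>
    dplyr::ungroup()
  dplyr::arrange(out, .data$contig_id, .data$pos)
}

# ---------------------------------------------------------------------------
# EST consensus-alignment caller

#' Pile up EST member sequences on their consensus
#'
#' Members are ungapped placements of each EST on the contig consensus;
#' `-` characters (alignment gaps) and `N` carry no information and are
#' not counted. Contigs with fewer than two members are excluded
#' (singleton unigenes cannot be examined for polymorphism).
#'
#' @param members tibble with columns `contig_id`, `member_id`, `start`
#'   (1-based offset of the member on the consensus) and `seq` (may
#'   contain `-`).
#' @param contigs contig tibble (`id`, `length`).
#' @return tibble `contig_id`, `pos`, `A`, `C`, `G`, `T`, `depth`.
#' @export
est_pileup <- function(members, contigs) {
  n_members <- dplyr::count(members, .data$contig_id)
  multi <- n_members$contig_id[n_members$n >= 2]
  members <- members[members$contig_id %in% multi, ]
  contigs <- contigs[contigs$id %in% multi, , drop = FALSE]
  if (nrow(members) == 0) {
    return(tibble::tibble(
      contig_id = character(), pos = integer(),
      A = integer(), C = integer(), G = integer(), T = integer(), depth = integer()
    ))
  }
  clen <- setNames(as.integer(contigs$length), contigs$id)
  offset <- setNames(c(0L, cumsum(as.integer(contigs$length))[-nrow(contigs)]), contigs$id)
  total_len <- sum(clen)
  lens <- nchar(members$seq)
  fits <- members$start >= 1L & members$start + lens - 1L <= clen[members$contig_id]
  if (any(!fits)) {
    abort(paste0("member overruns its contig: ", members$member_id[!fits][1]))
  }
  gpos <- sequence(lens, from = offset[members$contig_id] + members$start)
  base_code <- BASE_CODE[utf8ToInt(paste(toupper(members$seq), collapse = ""))]
  keep <- base_code %in% 1:4
  idx <- (gpos[keep] - 1L) * 4L + base_code[keep]
  tab <- tabulate(idx, nbins = total_len * 4L)
  m <- matrix(tab, ncol = 4L, byrow = TRUE)
  tibble::tibble(
    contig_id = rep(contigs$id, clen), pos = sequence(clen),
    A = m[, 1], C = m[, 2], G = m[, 3], T = m[, 4],
    depth = rowSums(m)
  )
}

#' Call SNPs in an EST consensus pileup
#'
#' A position is emitted when at least two distinct bases each reach
#' `min_allele_depth` reads. When three or more bases qualify the two
#' highest-count alleles are reported (count ties broken alphabetically)
#' and the record carries a `tri_allelic` flag; downstream filtering drops
#' flagged records by default.
#'
#' @param columns tibble from [est_pileup()].
#' @param min_allele_depth minimum reads per allele (default 2).
#' @return tibble `contig_id`, `pos`, `allele1`, `allele2`, `depth1`,
#'   `depth2`, `total_depth`, `source = "est"`, `flags`.
#' @export
call_est_snps <- function(columns, min_allele_depth = 2) {
  m <- cbind(columns$A, columns$C, columns$G, columns$T)
  qual <- m >= min_allele_depth
  n_alleles <- rowSums(qual)
  i <- which(n_alleles >= 2)
  if (length(i) == 0) {
    return(tibble::tibble(
      contig_id = character(), pos = integer(), allele1 = character(),
      allele2 = character(), depth1 = integer(), depth2 = integer(),
      total_depth = integer(), source = character(), flags = character()
    ))
  }
  picks <- t(vapply(i, function(r) {
    ord <- order(-m[r, ], BASES) # count desc, base asc on ties
    ord[1:2]
  }, integer(2)))
  tibble::tibble(
    contig_id = columns$contig_id[i], pos = columns$pos[i],
    allele1 = BASES[picks[, 1]], allele2 = BASES[picks[, 2]],
    depth1 = m[cbind(seq_along(i), picks[, 1])],
    depth2 = m[cbind(seq_along(i), picks[, 2])],
    total_depth = columns$depth[i],
    source = "est",
    flags = ifelse(n_alleles[i] >= 3, "tri_allelic", "")
  )
}

#' Filter EST-derived SNPs by contig-end and adjacency rules
#'
#' Drops SNPs within `end_window` bp of either contig end (positions 1-50
#' and the last 50 positions), then makes a greedy left-to-right pass: of
#' any two surviving candidates closer than `adjacency_window` bp, only
#' the one with higher total coverage is kept (ties keep the leftmost),
#' re-evaluating each candidate against the kept survivor.
#'
#' @param snps tibble from [call_est_snps()].
#' @param contigs contig tibble (`id`, `length`).
#' @param end_window,adjacency_window distances in bp (default 50).
#' @param drop_triallelic drop records flagged `tri_allelic` (default TRUE).
#' @return the SNP tibble with `flags` updated and a logical `kept` column.
#' @export
filter_est_snps <- function(snps, contigs, end_window = 50,
                            adjacency_window = 50, drop_triallelic = TRUE) {
  if (nrow(snps) == 0) {
    snps$kept <- logical(0)
    return(snps)
  }
  clen <- setNames(as.integer(contigs$length), contigs$id)
  out <- snps |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::group_modify(function(df, key) {
      L <- clen[[key$contig_id[[1]]]]
      df <- dplyr::arrange(df, .data$pos)
      near_end <- df$pos <= end_window | df$pos > L - end_window
      df$flags <- ifelse(
        near_end,
        ifelse(nzchar(df$flags), paste(df$flags, "near_end", sep = ";"), "near_end"),
        df$flags
      )
      tri <- drop_triallelic & grepl("tri_allelic", df$flags)
      eligible <- which(!near_end & !tri)
      kept_idx <- integer(0)
      for (r in eligible) {
        if (length(kept_idx) == 0) { kept_idx <- r; next }
        last <- kept_idx[length(kept_idx)]
        if (df$pos[r] - df$pos[last] >= adjacency_window) {
          kept_idx <- c(kept_idx, r)
        } else if (df$total_depth[r] > df$total_depth[last]) {
          kept_idx[length(kept_idx)] <- r # replace the survivor
          df$flags[last] <- flag_add(df$flags[last], "adjacent_snp")
        } else {
          df$flags[r] <- flag_add(df$flags[r], "adjacent_snp")
        }
      }
      df$kept <- seq_len(nrow(df)) %in% kept_idx
      df
    }) |>
    dplyr::ungroup()
  dplyr::arrange(out, .data$contig_id, .data$pos)
}

flag_add <- function(flags, flag) {
  ifelse(nzchar(flags), paste(flags, flag, sep = ";"), flag)
}
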