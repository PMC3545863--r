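# Synthetic-data module: transcript contigs for three near-isogenic
# homozygous genotypes with planted SNPs, heterozygous positions, SSR
# tracts and exon-exon junction coordinates, plus an error-bearing short
# read simulator and a naive seed-and-extend mapper. Every downstream
# stage of the pipeline is testable against this planted ground truth.

# primitive repeat motifs used for SSR planting, by unit size
MOTIF_POOL <- list(
  `2` = c("AC", "AG", "AT", "CT", "GA", "GT"),
  `3` = c("AAC", "AAG", "AAT", "ACC", "AGG", "ATC", "CTT"),
  `4` = c("AAAC", "AAAG", "AAAT", "ACAT", "AGAT"),
  `5` = c("AAAAC", "AAAAG", "AATAC"),
  `6` = c("AAAAAC", "AACACC", "AAGAGG")
)

#' Simulation configuration
#'
#' Defaults emulate the study design the package targets: three
#' near-isogenic homozygous pepper lines (CM334, Maor, Early Jalapeno)
#' sequenced at 85 nt per read, transcript contigs of roughly 2 kb, a SNP
#' density of about one SNP per 2.5 kb, and a small rate of residual
#' heterozygous positions that the caller must reject.
#'
#' @param n_genes number of transcript contigs to simulate.
#' @param transcript_len min/max transcript length (nt).
#' @param n_exons min/max exons per gene; junctions fall at cumulative
#'   exon-length boundaries.
#' @param genotype_names names of the (>= 3) homozygous lines.
#' @param snp_rate planted inter-genotype SNPs per kb.
#' @param het_rate planted heterozygous positions per kb.
#' @param ssr_plant_rate expected planted SSR tracts per transcript.
#' @param viol_junction_rate,viol_adjacent_rate,viol_het_rate per-transcript
#'   probability of planting a SNP that deliberately violates the 50-bp
#'   junction / adjacent-SNP / heterozygote distance filter, to exercise
#'   filter flagging (only active when `snp_rate > 0`).
#' @param read_len read length in nt.
#' @param depth_per_line mean per-base coverage per genotype.
#' @param error_rate per-base substitution error rate.
#' @param qual_model list with `mean`, `sd` and per-position `decay` of the
#'   simulated Phred scores.
#' @param seed RNG seed; all sampling derives from it.
#' @return a list of class `capsi_sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       transcript_len = c(1200, 2800),
                       n_exons = c(2, 6),
                       genotype_names = c("CM334", "Maor", "EJ"),
                       snp_rate = 0.4,
                       het_rate = 0.2,
                       ssr_plant_rate = 0.1,
                       viol_junction_rate = 0.1,
                       viol_adjacent_rate = 0.1,
                       viol_het_rate = 0.1,
                       read_len = 85,
                       depth_per_line = 20,
                       error_rate = 0.005,
                       qual_model = list(mean = 35, sd = 3, decay = 0.05),
                       seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes), transcript_len = as.integer(transcript_len),
    n_exons = as.integer(n_exons), genotype_names = genotype_names,
    snp_rate = snp_rate, het_rate = het_rate, ssr_plant_rate = ssr_plant_rate,
    viol_junction_rate = viol_junction_rate,
    viol_adjacent_rate = viol_adjacent_rate, viol_het_rate = viol_het_rate,
    read_len = as.integer(read_len), depth_per_line = depth_per_line,
    error_rate = error_rate, qual_model = qual_model, seed = as.integer(seed)
  )
  rates <- c(cfg$snp_rate, cfg$het_rate, cfg$ssr_plant_rate, cfg$error_rate,
             cfg$depth_per_line, cfg$viol_junction_rate, cfg$viol_adjacent_rate,
             cfg$viol_het_rate)
  if (any(rates < 0)) abort("all rates must be >= 0")
  if (cfg$read_len < 25) abort("read_len must be >= 25")
  if (length(cfg$genotype_names) < 3) abort("at least 3 genotype names are required")
  if (cfg$transcript_len[1] > cfg$transcript_len[2]) abort("transcript_len must be min <= max")
  if (cfg$ssr_plant_rate > 0 && cfg$transcript_len[1] < 6 * 8 + 240) {
    abort("transcripts too short to host a planted SSR with clean flanks")
  }
  if (cfg$transcript_len[1] < 2 * cfg$read_len) {
    abort("transcripts must be at least two read lengths long")
  }
  structure(cfg, class = "capsi_sim_config")
}

# rejection-sample a position satisfying `ok(pos)`; NA when no luck
try_place <- function(lo, hi, ok, tries = 60) {
  if (hi < lo) return(NA_integer_)
  for (i in seq_len(tries)) {
    p <- sample(lo:hi, 1)
    if (ok(p)) return(p)
  }
  NA_integer_
}

#' Simulate a planted-truth marker data set
#'
#' Generates transcript contigs (the reference consensus), exon-exon
#' junction coordinates, planted biallelic SNPs (each carried homozygously
#' by one genotype), occasional heterozygous positions, and perfect SSR
#' tracts with clean flanking breaker bases. A configurable share of
#' planted SNPs deliberately violates the 50-bp distance filters (near a
#' junction, in an adjacent pair, or near a heterozygous site) so that the
#' filter flags can be verified. Deterministic for a fixed seed.
#'
#' Compliant SNPs are placed at least 100 nt from contig ends (so coverage
#' is full), at least 50 nt from junctions, and at least 50 nt from every
#' other planted site.
#'
#' @param config a [sim_config()].
#' @return an object of class `capsi_truth`: a list with tibbles `contigs`
#'   (`id`, `seq`, `length`), `junctions` (`contig_id`, `pos`), `variants`
#'   (`contig_id`, `pos`, `ref`, `alt`, `alt_genotype`, `is_het`,
#'   `category`), `ssrs` (`contig_id`, `start`, `end`, `motif`,
#'   `repeat_count`), and the `config`.
#' @export
simulate_truth <- function(config = sim_config()) {
  stopifnot(inherits(config, "capsi_sim_config"))
  set.seed(config$seed)
  gts <- config$genotype_names
  thr <- ssr_thresholds()
  contigs <- vector("list", config$n_genes)
  junctions <- vector("list", config$n_genes)
  variants <- vector("list", config$n_genes)
  ssrs <- vector("list", config$n_genes)

  for (g in seq_len(config$n_genes)) {
    id <- sprintf("ctg%04d", g)
    L <- sample(config$transcript_len[1]:config$transcript_len[2], 1)
    n_ex <- sample(config$n_exons[1]:config$n_exons[2], 1)
    ex_len <- as.vector(stats::rmultinom(1, L - 60L * n_ex, rep(1, n_ex))) + 60L
    jx <- if (n_ex > 1) cumsum(ex_len)[-n_ex] else integer(0)
    sq <- chars(paste(sample(BASES, L, replace = TRUE), collapse = ""))

    # --- SSR tracts (planted before variants; variants avoid their spans)
    ssr_rows <- list()
    n_ssr <- rpois(1, config$ssr_plant_rate)
    occupied_ssr <- integer(0) # flattened exclusion positions
    for (s in seq_len(n_ssr)) {
      u <- sample(2:6, 1, prob = c(.4, .3, .15, .1, .05))
      motif <- sample(MOTIF_POOL[[as.character(u)]], 1)
      count <- unname(thr[as.character(u)]) + sample(0:3, 1)
      span <- u * count
      st <- try_place(120L, L - 120L - span, function(p) {
        !any(seq(p - 200L, p + span + 200L) %in% occupied_ssr)
      })
      if (is.na(st)) next
      en <- st + span - 1L
      sq[st:en] <- chars(strrep(motif, count))
      mb <- chars(motif)
      # breaker bases so the tract cannot extend into the flanks
      sq[st - 1L] <- sample(setdiff(BASES, mb[u]), 1)
      sq[en + 1L] <- sample(setdiff(BASES, mb[1]), 1)
      occupied_ssr <- c(occupied_ssr, st:en)
      ssr_rows[[length(ssr_rows) + 1]] <- tibble::tibble(
        contig_id = id, start = st, end = en, motif = motif, repeat_count = count
      )
    }
    # --- site placement -------------------------------------------------
    sites <- integer(0) # all placed variant positions
    site_ok <- function(p, min_dist_sites = 50L, min_dist_jx = 50L) {
      p >= 101L && p <= L - 100L &&
        (length(sites) == 0 || min(abs(sites - p)) >= min_dist_sites) &&
        (length(jx) == 0 || min(abs(jx - p)) >= min_dist_jx || min_dist_jx == 0L) &&
        !any(abs(occupied_ssr - p) <= 10L)
    }
    var_rows <- list()
    add_variant <- function(pos, is_het, category) {
      ref <- sq[pos]
      alt <- sample(setdiff(BASES, ref), 1)
      carrier <- sample(gts, 1)
      var_rows[[length(var_rows) + 1]] <<- tibble::tibble(
        contig_id = id, pos = pos, ref = ref, alt = alt,
        alt_genotype = carrier, is_het = is_het, category = category
      )
      sites <<- c(sites, pos)
    }

    # heterozygous positions
    n_het <- rpois(1, L / 1000 * config$het_rate)
    for (i in seq_len(n_het)) {
      p <- try_place(101L, L - 100L, function(p) site_ok(p, 50L, 0L))
      if (!is.na(p)) add_variant(p, TRUE, "het_site")
    }

    if (config$snp_rate > 0) {
      # compliant SNPs
      n_snp <- rpois(1, L / 1000 * config$snp_rate)
      for (i in seq_len(n_snp)) {
        p <- try_place(101L, L - 100L, site_ok)
        if (!is.na(p)) add_variant(p, FALSE, "compliant")
      }
      # junction-violating SNP
      if (length(jx) && runif(1) < config$viol_junction_rate) {
        j <- jx[sample.int(length(jx), 1)]
        p <- try_place(max(101L, j - 49L), min(L - 100L, j + 49L), function(p) {
          site_ok(p, 50L, 0L) && abs(p - j) >= 5L
        })
        if (!is.na(p)) add_variant(p, FALSE, "near_junction")
      }
      # adjacent SNP pair
      if (runif(1) < config$viol_adjacent_rate) {
        a <- try_place(101L, L - 150L, site_ok)
        if (!is.na(a)) {
          b <- try_place(a + 10L, a + 49L, function(p) {
            p <= L - 100L &&
              min(abs(setdiff(sites, a) - p), Inf) >= 50L &&
              (length(jx) == 0 || min(abs(jx - p)) >= 50L) &&
              !any(abs(occupied_ssr - p) <= 10L)
          })
          if (!is.na(b)) {
            add_variant(a, FALSE, "adjacent_pair")
            add_variant(b, FALSE, "adjacent_pair")
          }
        }
      }
      # SNP near a (new) heterozygous site
      if (runif(1) < config$viol_het_rate) {
        h <- try_place(151L, L - 150L, function(p) site_ok(p, 50L, 50L))
        if (!is.na(h)) {
          p <- try_place(h + 10L, h + 49L, function(p) {
            p <= L - 100L &&
              min(abs(setdiff(sites, h) - p), Inf) >= 50L &&
              (length(jx) == 0 || min(abs(jx - p)) >= 50L) &&
              !any(abs(occupied_ssr - p) <= 10L)
          })
          if (!is.na(p)) {
            add_variant(h, TRUE, "het_site")
            add_variant(p, FALSE, "near_het")
          }
        }
      }
    }

    contigs[[g]] <- tibble::tibble(id = id, seq = paste(sq, collapse = ""), length = L)
    junctions[[g]] <- if (length(jx)) tibble::tibble(contig_id = id, pos = jx) else NULL
    variants[[g]] <- if (length(var_rows)) dplyr::bind_rows(var_rows) else NULL
    ssrs[[g]] <- if (length(ssr_rows)) dplyr::bind_rows(ssr_rows) else NULL
  }

  out <- list(
    contigs = dplyr::bind_rows(contigs),
    junctions = dplyr::bind_rows(junctions) %||% tibble::tibble(contig_id = character(), pos = integer()),
    variants = dplyr::bind_rows(variants) %||% empty_variants(),
    ssrs = dplyr::bind_rows(ssrs) %||% empty_ssr_truth(),
    config = config
  )
  if (nrow(out$variants) == 0) out$variants <- empty_variants()
  if (nrow(out$ssrs) == 0) out$ssrs <- empty_ssr_truth()
  if (nrow(out$junctions) == 0) {
    out$junctions <- tibble::tibble(contig_id = character(), pos = integer())
  }
  out$variants <- dplyr::arrange(out$variants, .data$contig_id, .data$pos)
  out$ssrs <- dplyr::arrange(out$ssrs, .data$contig_id, .data$start)
  structure(out, class = "capsi_truth")
}

empty_variants <- function() {
  tibble::tibble(
    contig_id = character(), pos = integer(), ref = character(),
    alt = character(), alt_genotype = character(), is_het = logical(),
    category = character()
  )
}

empty_ssr_truth <- function() {
  tibble::tibble(
    contig_id = character(), start = integer(), end = integer(),
    motif = character(), repeat_count = integer()
  )
}

#' @export
print.capsi_truth <- function(x, ...) {
  cat("<capsi_truth>", nrow(x$contigs), "contigs,",
      sum(!x$variants$is_het), "planted SNPs,",
      sum(x$variants$is_het), "het sites,",
      nrow(x$ssrs), "SSR tracts\n")
  invisible(x)
}

# per-genotype haplotype sequences (homozygous substitutions applied;
# het sites stay at the reference allele and are resolved per read)
haplotype_seqs <- function(truth, genotype) {
  seqs <- setNames(truth$contigs$seq, truth$contigs$id)
  v <- truth$variants[!truth$variants$is_het & truth$variants$alt_genotype == genotype, ]
  if (nrow(v)) {
    for (i in seq_len(nrow(v))) {
      substr(seqs[[v$contig_id[i]]], v$pos[i], v$pos[i]) <- v$alt[i]
    }
  }
  seqs
}

#' Simulate error-bearing short reads for every genotype
#'
#' Read start positions are drawn by systematic sampling with a small
#' random jitter (near-even spacing along each transcript), which pins
#' realised per-base coverage to the target depth away from contig ends;
#' marginally the start positions are still close to uniform. Heterozygous
#' positions emit the two alleles in strict alternation across overlapping
#' reads, so each het site shows an essentially 50/50 allele balance.
#' Substitution errors occur at `error_rate` per base; Phred scores follow
#' the configured positional decay model.
#'
#' @param truth a `capsi_truth` from [simulate_truth()].
#' @param config simulation config; defaults to the one inside `truth`.
#' @return tibble with columns `id`, `genotype`, `contig_id`, `true_start`,
#'   `seq`, `quals` (list of integer Phred scores).
#' @export
simulate_reads <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "capsi_truth"))
  set.seed(derive_seed(config$seed, 1L))
  rl <- config$read_len
  out <- list()
  for (gt in config$genotype_names) {
    haps <- haplotype_seqs(truth, gt)
    hets <- truth$variants[truth$variants$is_het & truth$variants$alt_genotype == gt, ]
    for (ci in seq_len(nrow(truth$contigs))) {
      cid <- truth$contigs$id[ci]
      L <- truth$contigs$length[ci]
      if (L < rl) next
      n_reads <- round(config$depth_per_line * L / rl)
      if (n_reads < 1) next
      starts <- floor(seq(1, L - rl + 1, length.out = n_reads)) +
        sample(-3:3, n_reads, replace = TRUE)
      starts <- pmin(pmax(starts, 1L), L - rl + 1L)
      seqs <- substring(haps[[cid]], starts, starts + rl - 1L)
      # alternate het alleles across the reads overlapping each het site
      ch <- hets[hets$contig_id == cid, ]
      if (nrow(ch)) {
        for (i in seq_len(nrow(ch))) {
          ov <- which(starts <= ch$pos[i] & starts + rl - 1L >= ch$pos[i])
          alt_reads <- ov[seq_along(ov) %% 2L == 0L]
          off <- ch$pos[i] - starts[alt_reads] + 1L
          for (j in seq_along(alt_reads)) {
            substr(seqs[alt_reads[j]], off[j], off[j]) <- ch$alt[i]
          }
        }
      }
      # substitution errors
      if (config$error_rate > 0) {
        n_err <- rbinom(n_reads, rl, config$error_rate)
        for (i in which(n_err > 0)) {
          ep <- sample.int(rl, n_err[i])
          s <- chars(seqs[i])
          s[ep] <- vapply(s[ep], function(b) sample(setdiff(BASES, b), 1), character(1))
          seqs[i] <- paste(s, collapse = "")
        }
      }
      qm <- config$qual_model
      mu <- qm$mean - qm$decay * (seq_len(rl) - 1)
      qmat <- matrix(
        pmin(41L, pmax(2L, as.integer(round(rnorm(rl * n_reads, mean = mu, sd = qm$sd))))),
        nrow = rl
      )
      out[[length(out) + 1]] <- tibble::tibble(
        id = sprintf("%s_%s_%d_%d", gt, cid, starts, seq_len(n_reads)),
        genotype = gt, contig_id = cid, true_start = as.integer(starts),
        seq = seqs,
        quals = lapply(seq_len(n_reads), function(j) qmat[, j])
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Map reads to contigs with a naive seed-and-extend strategy
#'
#' Contigs are indexed by exact k-mers; each read is seeded at offsets
#' 0, k, 2k, ... until a candidate set of ungapped end-to-end placements is
#' found, candidates are ranked by Hamming distance, and the read is placed
#' only when a unique best placement exists. Reads with no candidate or
#' with tied best placements are discarded and counted. No indels are
#' modelled: placements are ungapped (`<len>M` CIGAR).
#'
#' @param reads tibble with columns `id`, `seq` (and optionally `genotype`).
#' @param contigs tibble with columns `id`, `seq`.
#' @param k seed length (default 21).
#' @return alignment tibble (`read_id`, `genotype`, `contig_id`, `pos`,
#'   `cigar`, `seq`) with attribute `counts` = c(mapped, unmapped,
#'   ambiguous).
#' @export
naive_map <- function(reads, contigs, k = 21) {
  k <- as.integer(k)
  stopifnot(k >= 8)
  clen <- setNames(nchar(contigs$seq), contigs$id)
  # --- k-mer index
  idx <- lapply(seq_len(nrow(contigs)), function(i) {
    L <- clen[[i]]
    if (L < k) return(NULL)
    tibble::tibble(
      kmer = substring(contigs$seq[i], 1:(L - k + 1), k:L),
      contig = contigs$id[i], kpos = 1:(L - k + 1)
    )
  })
  idx <- dplyr::bind_rows(idx)
  dup <- duplicated(idx$kmer) | duplicated(idx$kmer, fromLast = TRUE)
  uniq_tbl <- idx[!dup, ]
  dup_tbl <- idx[dup, ]
  dup_map <- if (nrow(dup_tbl)) {
    split(seq_len(nrow(dup_tbl)), dup_tbl$kmer)
  } else list()
  cseq <- setNames(contigs$seq, contigs$id)

  n <- nrow(reads)
  rlen <- nchar(reads$seq)
  res_contig <- rep(NA_character_, n)
  res_pos <- rep(NA_integer_, n)
  ambiguous <- rep(FALSE, n)

  # fast path: unique offset-0 seed with an exact end-to-end match
  k0 <- substr(reads$seq, 1, k)
  m0 <- match(k0, uniq_tbl$kmer)
  cand_ok <- !is.na(m0)
  if (any(cand_ok)) {
    i <- which(cand_ok)
    ctg <- uniq_tbl$contig[m0[i]]
    pos <- uniq_tbl$kpos[m0[i]]
    fits <- pos + rlen[i] - 1L <= clen[ctg]
    ref <- rep(NA_character_, length(i))
    ref[fits] <- substring(cseq[ctg[fits]], pos[fits], pos[fits] + rlen[i][fits] - 1L)
    exact <- fits & !is.na(ref) & ref == reads$seq[i]
    res_contig[i[exact]] <- ctg[exact]
    res_pos[i[exact]] <- pos[exact]
  }

  # slow path: errors, duplicated seeds, or no offset-0 hit
  todo <- which(is.na(res_pos))
  if (length(todo)) {
    umap <- split(seq_len(nrow(uniq_tbl)), uniq_tbl$kmer)
    for (i in todo) {
      rl_i <- rlen[i]
      offs <- seq(0L, rl_i - k, by = k)
      cand <- character(0) # "contig\tpos"
      for (off in offs) {
        km <- substr(reads$seq[i], off + 1L, off + k)
        hit <- umap[[km]]
        rows <- NULL
        if (!is.null(hit)) rows <- uniq_tbl[hit, ]
        dh <- dup_map[[km]]
        if (!is.null(dh)) rows <- dplyr::bind_rows(rows, dup_tbl[dh, ])
        if (!is.null(rows) && nrow(rows)) {
          p <- rows$kpos - off
          keep <- p >= 1L & p + rl_i - 1L <= clen[rows$contig]
          cand <- c(cand, paste(rows$contig[keep], p[keep], sep = "\t"))
        }
      }
      cand <- unique(cand)
      if (!length(cand)) next
      parts <- strsplit(cand, "\t", fixed = TRUE)
      ctgs <- vapply(parts, `[[`, character(1), 1)
      poss <- as.integer(vapply(parts, `[[`, character(1), 2))
      refs <- substring(cseq[ctgs], poss, poss + rl_i - 1L)
      mm <- vapply(refs, function(r) sum(charToRaw(r) != charToRaw(reads$seq[i])),
                   integer(1), USE.NAMES = FALSE)
      best <- which(mm == min(mm))
      if (length(best) > 1L) {
        ambiguous[i] <- TRUE
      } else {
        res_contig[i] <- ctgs[best]
        res_pos[i] <- poss[best]
      }
    }
  }

  placed <- !is.na(res_pos)
  out <- tibble::tibble(
    read_id = reads$id[placed],
    genotype = if ("genotype" %in% names(reads)) reads$genotype[placed] else NA_character_,
    contig_id = res_contig[placed],
    pos = res_pos[placed],
    cigar = paste0(rlen[placed], "M"),
    seq = reads$seq[placed]
  )
  attr(out, "counts") <- c(
    mapped = sum(placed),
    unmapped = sum(!placed & !ambiguous),
    ambiguous = sum(ambiguous)
  )
  out
}

#' Write / read a planted-truth set as plain-text files
#'
#' Writes `contigs.fa`, `junctions.tsv`, `variants.tsv` and `ssrs.tsv`
#' under `dir`. `read_truth()` restores the tibbles (the config is not
#' serialized).
#'
#' @param truth a `capsi_truth`.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly; for `read_truth()`, a `capsi_truth` without
#'   config.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(truth$contigs, file.path(dir, "contigs.fa"))
  write_junctions(truth$junctions, file.path(dir, "junctions.tsv"))
  readr::write_tsv(truth$variants, file.path(dir, "variants.tsv"))
  readr::write_tsv(truth$ssrs, file.path(dir, "ssrs.tsv"))
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  contigs <- read_fasta(file.path(dir, "contigs.fa"))[, c("id", "seq", "length")]
  junctions <- read_junctions(file.path(dir, "junctions.tsv"), contigs)
  variants <- readr::read_tsv(
    file.path(dir, "variants.tsv"),
    col_types = readr::cols(
      contig_id = "c", pos = "i", ref = "c", alt = "c",
      alt_genotype = "c", is_het = "l", category = "c"
    ), progress = FALSE
  )
  ssrs <- readr::read_tsv(
    file.path(dir, "ssrs.tsv"),
    col_types = readr::cols(
      contig_id = "c", start = "i", end = "i", motif = "c", repeat_count = "i"
    ), progress = FALSE
  )
  structure(
    list(contigs = contigs, junctions = junctions, variants = variants,
         ssrs = ssrs, config = NULL),
    class = "capsi_truth"
  )
}
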