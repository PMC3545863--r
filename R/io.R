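# Readers and writers for the standard formats the pipeline touches:
# FASTA, FASTQ (Phred+33), a SAM subset, 2-column junction TSV and VCF output.
# Internally all coordinates are handled 1-based inclusive, matching the
# serialized conventions of these formats.

#' Read a FASTA file into a tibble
#'
#' Sequences are uppercased and any IUPAC ambiguity letter other than
#' A/C/G/T/N is mapped to `N` (the downstream callers treat non-ACGT bases
#' as carrying no information); a warning reports how many letters were
#' replaced. Empty sequences are an error.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id` (first whitespace-delimited token of
#'   the header), `desc` (remainder of the header, possibly `""`), `seq`
#'   and `length`, in file order.
#' @export
read_fasta <- function(path) {
  xs <- Biostrings::readBStringSet(path)
  if (length(xs) == 0) abort(paste0("no records in FASTA file: ", path))
  full <- names(xs)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seqs <- as.character(xs)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(paste0("empty sequence body for record '", id[which(empty)[1]], "' in ", path))
  }
  n_amb <- 0L
  seqs <- vapply(seqs, function(s) {
    s <- clean_sequence(s)
    n_amb <<- n_amb + attr(s, "n_ambiguous")
    as.character(s)
  }, character(1), USE.NAMES = FALSE)
  if (n_amb > 0) {
    warn(paste0(n_amb, " ambiguity letter(s) mapped to N while reading ", path))
  }
  tibble::tibble(id = id, desc = desc, seq = seqs, length = nchar(seqs))
}

#' Write contigs to a FASTA file
#'
#' @param contigs tibble with columns `id`, `seq` (and optionally `desc`).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 70) {
  hdr <- contigs$id
  if ("desc" %in% names(contigs)) {
    hdr <- ifelse(nzchar(contigs$desc), paste(hdr, contigs$desc), hdr)
  }
  xs <- Biostrings::BStringSet(setNames(contigs$seq, hdr))
  Biostrings::writeXStringSet(xs, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (Phred+33) into a tibble
#'
#' Only Sanger/Illumina-1.8 Phred+33 quality encoding is supported;
#' Phred+64 input is not auto-detected. Sequence/quality length mismatches
#' are an error naming the offending read.
#'
#' @param path path to a 4-line-per-record FASTQ file.
#' @return tibble with columns `id`, `seq`, and `quals` (list column of
#'   integer Phred scores, one per base).
#' @export
read_fastq <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0) {
    return(tibble::tibble(id = character(), seq = character(), quals = list()))
  }
  if (length(lines) %% 4 != 0) {
    abort(paste0("truncated FASTQ (", length(lines), " lines, not a multiple of 4): ", path))
  }
  i <- seq(1, length(lines), by = 4)
  if (!all(startsWith(lines[i], "@"))) {
    abort(paste0("malformed FASTQ header at line ", i[!startsWith(lines[i], "@")][1], " of ", path))
  }
  id <- sub("\\s.*$", "", sub("^@", "", lines[i]))
  seqs <- toupper(lines[i + 1])
  qstr <- lines[i + 3]
  bad <- nchar(seqs) != nchar(qstr)
  if (any(bad)) {
    abort(paste0("sequence/quality length mismatch for read '", id[which(bad)[1]], "'"))
  }
  quals <- lapply(qstr, function(q) utf8ToInt(q) - 33L)
  rng <- range(unlist(lapply(quals, range), use.names = FALSE))
  if (rng[1] < 0 || rng[2] > 93) {
    abort("Phred scores outside 0..93; only Phred+33 encoding is supported")
  }
  tibble::tibble(id = id, seq = seqs, quals = quals)
}

#' Write reads to a FASTQ file (Phred+33)
#'
#' @param reads tibble with columns `id`, `seq`, `quals` (list of integers).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qstr <- vapply(reads$quals, function(q) intToUtf8(q + 33L), character(1))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qstr))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a SAM file (subset) into an alignment tibble
#'
#' Accepts plain-text SAM with CIGAR operations M, I, D and S only; spliced
#' (`N`) or other operations are an error, since alignments are expected to
#' be against transcript contigs where introns are absent. Unmapped
#' (flag 0x4) and secondary/supplementary (0x100/0x800) records are skipped
#' and counted.
#'
#' @param path path to a SAM file.
#' @param genotype_of function mapping `(read_id, rg)` to a genotype tag;
#'   by default the RG tag value is used as-is (NA when absent).
#' @return tibble with columns `read_id`, `genotype`, `contig_id`, `pos`
#'   (1-based leftmost), `cigar`, `seq`; attribute `skipped` holds counts
#'   of skipped records.
#' @export
read_sam <- function(path, genotype_of = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  skipped <- c(unmapped = 0L, secondary = 0L)
  if (length(lines) == 0) {
    out <- empty_alignments()
    attr(out, "skipped") <- skipped
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11)) {
    abort(paste0("SAM record with fewer than 11 fields at data line ", which(nf < 11)[1]))
  }
  flag <- as.integer(vapply(fields, `[[`, character(1), 2))
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L
  skipped <- c(unmapped = sum(unmapped), secondary = sum(secondary & !unmapped))
  keep <- !unmapped & !secondary
  fields <- fields[keep]
  cigar <- vapply(fields, `[[`, character(1), 6)
  badop <- grepl("[0-9]+[^0-9MIDS]", cigar)
  if (any(badop)) {
    abort(paste0(
      "unsupported CIGAR operation in '", cigar[badop][1],
      "': only M/I/D/S are handled; spliced (N) alignments are not ",
      "expected against transcript contigs"
    ))
  }
  read_id <- vapply(fields, `[[`, character(1), 1)
  rg <- vapply(fields, function(f) {
    hit <- grep("^RG:Z:", f[-(1:11)], value = TRUE)
    if (length(hit)) sub("^RG:Z:", "", hit[1]) else NA_character_
  }, character(1))
  genotype <- if (is.null(genotype_of)) rg else {
    mapply(genotype_of, read_id, rg, USE.NAMES = FALSE)
  }
  out <- tibble::tibble(
    read_id = read_id,
    genotype = genotype,
    contig_id = vapply(fields, `[[`, character(1), 3),
    pos = as.integer(vapply(fields, `[[`, character(1), 4)),
    cigar = cigar,
    seq = toupper(vapply(fields, `[[`, character(1), 10))
  )
  qlen <- cigar_query_length(out$cigar)
  bad <- qlen != nchar(out$seq)
  if (any(bad)) {
    abort(paste0(
      "CIGAR/read length mismatch for read '", out$read_id[bad][1],
      "': cigar consumes ", qlen[bad][1], ", sequence has ", nchar(out$seq)[bad][1]
    ))
  }
  attr(out, "skipped") <- skipped
  out
}

empty_alignments <- function() {
  tibble::tibble(
    read_id = character(), genotype = character(), contig_id = character(),
    pos = integer(), cigar = character(), seq = character()
  )
}

# read-consuming length of each CIGAR string (M, I, S consume the read)
cigar_query_length <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- cigar_ops(cg)
    sum(ops$len[ops$op %in% c("M", "I", "S")])
  }, integer(1), USE.NAMES = FALSE)
}

cigar_ops <- function(cg) {
  len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
  op <- regmatches(cg, gregexpr("[A-Z]", cg))[[1]]
  if (length(len) != length(op) || length(op) == 0) {
    abort(paste0("malformed CIGAR string: '", cg, "'"))
  }
  list(len = len, op = op)
}

#' Read splice-junction coordinates from a 2-column TSV
#'
#' The file holds `contig_id <TAB> pos`, one junction per line, where `pos`
#' is the 1-based coordinate of the last base of the upstream exon.
#'
#' @param path path to the TSV (no header).
#' @param contigs optional contig tibble for bounds validation.
#' @return tibble `contig_id`, `pos`, sorted and unique.
#' @export
read_junctions <- function(path, contigs = NULL) {
  jx <- readr::read_tsv(path,
    col_names = c("contig_id", "pos"),
    col_types = readr::cols(contig_id = "c", pos = "i"), progress = FALSE
  )
  jx <- dplyr::arrange(dplyr::distinct(jx), .data$contig_id, .data$pos)
  if (any(jx$pos < 1)) abort("junction coordinates must be >= 1")
  if (!is.null(contigs)) {
    len <- setNames(contigs$length, contigs$id)
    bad <- is.na(len[jx$contig_id]) | jx$pos >= len[jx$contig_id]
    if (any(bad)) {
      abort(paste0(
        "junction outside its contig: ", jx$contig_id[bad][1], ":", jx$pos[bad][1]
      ))
    }
  }
  jx
}

#' @rdname read_junctions
#' @param junctions tibble `contig_id`, `pos`.
#' @export
write_junctions <- function(junctions, path) {
  readr::write_tsv(junctions[, c("contig_id", "pos")], path, col_names = FALSE)
  invisible(path)
}

#' Write candidate SNPs as VCF 4.2 text
#'
#' REF is the allele shared by the majority of genotypes, ALT the minority
#' allele. Genotype columns carry `GT:DP` with homozygous calls. By default
#' only kept SNPs are written with `FILTER=PASS`; with `all_records = TRUE`
#' rejected SNPs are written too, FILTER listing the failing rule names.
#'
#' @param snps candidate SNP tibble as produced by [call_iga_snps()] /
#'   [filter_iga_snps()] (columns `contig_id`, `pos`, `ref`, `alt`,
#'   `allele_*`, `depth_*`, `total_depth`, `flags`, optionally `kept`).
#' @param contigs contig tibble (`id`, `length`) for the VCF header.
#' @param path output path.
#' @param all_records write flagged records as well as kept ones.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, contigs, path, all_records = FALSE) {
  len <- setNames(contigs$length, contigs$id)
  if (nrow(snps)) {
    bad <- is.na(len[snps$contig_id]) | snps$pos > len[snps$contig_id] | snps$pos < 1
    if (any(bad)) {
      abort(paste0("SNP outside its contig: ", snps$contig_id[bad][1], ":", snps$pos[bad][1]))
    }
  }
  gnames <- sub("^allele_", "", grep("^allele_", names(snps), value = TRUE))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=capsimark",
    paste0("##contig=<ID=", contigs$id, ",length=", contigs$length, ">"),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Summed depth across genotypes\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FILTER=<ID=", c("near_end", "near_junction", "adjacent_snp", "adjacent_het", "low_depth_total"),
           ",Description=\"Failed the ", c("contig-end", "splice-junction", "adjacent-SNP", "adjacent-heterozygote", "total-depth"),
           " distance/depth rule\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", gnames), collapse = "\t")
  )
  if (!all_records && "kept" %in% names(snps)) snps <- snps[snps$kept, , drop = FALSE]
  body <- character(0)
  if (nrow(snps)) {
    filt <- if ("flags" %in% names(snps)) ifelse(nzchar(snps$flags), snps$flags, "PASS") else "PASS"
    gcols <- vapply(seq_len(nrow(snps)), function(i) {
      paste(vapply(gnames, function(g) {
        al <- snps[[paste0("allele_", g)]][i]
        gt <- if (al == snps$ref[i]) "0/0" else "1/1"
        paste0(gt, ":", snps[[paste0("depth_", g)]][i])
      }, character(1)), collapse = "\t")
    }, character(1))
    body <- paste(
      snps$contig_id, snps$pos, ".", snps$ref, snps$alt, ".",
      filt, paste0("DP=", snps$total_depth), "GT:DP", gcols,
      sep = "\t"
    )
  }
  readr::write_lines(c(header, body), path)
  invisible(path)
}
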