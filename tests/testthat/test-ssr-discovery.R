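# SSR scanning, canonical classes, compound merging, cross-assembly
# matching and Primer3 task IO

test_that("perfect-SSR thresholds are (2/6) (3/5) (4/5) (5/5) (6/5)", {
  hit <- find_ssrs(c(s = strrep("AC", 6)))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$motif, "AC")
  expect_equal(hit$repeat_count, 6L)
  expect_equal(hit$start, 1L)
  expect_equal(hit$end, 12L)
  expect_equal(nrow(find_ssrs(c(s = strrep("AC", 5)))), 0L) # below 2/6
  expect_equal(nrow(find_ssrs(c(s = strrep("AAG", 5)))), 1L)
  expect_equal(nrow(find_ssrs(c(s = strrep("AAG", 4)))), 0L)
})

test_that("a framed tri-repeat is reported once, leftmost, with class AAG/CTT", {
  hit <- find_ssrs(c(s = "GGAAGAAGAAGAAGAAGCC"))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$unit_size, 3L)
  expect_equal(hit$repeat_count, 5L)
  expect_equal(hit$canonical_class, "AAG/CTT")
  # the leftmost frame of the maximal repeat region starts at base 2 (GAA)
  expect_equal(hit$start, 2L)
  expect_equal(hit$end - hit$start + 1L, 15L)
})

test_that("reducible motifs are reported only at the smallest unit size and N breaks runs", {
  hit <- find_ssrs(c(s = strrep("AT", 8))) # could masquerade as (ATAT)4
  expect_equal(hit$unit_size, 2L)
  expect_equal(nrow(find_ssrs(c(s = paste0(strrep("AC", 4), "N", strrep("AC", 4))))), 0L)
})

test_that("the scanner matches the regex oracle on random sequences", {
  set.seed(2026)
  for (i in 1:150) {
    sq <- rand_seq(2000)
    got <- find_ssrs(c(s = sq))
    exp <- oracle_ssrs(sq)
    expect_equal(
      got[, c("start", "unit_size", "repeat_count", "motif")],
      tibble::as_tibble(exp),
      ignore_attr = TRUE
    )
  }
})

test_that("every planted SSR is recovered with exact span and count", {
  tr <- simulate_truth(sim_config(n_genes = 40, ssr_plant_rate = 1, seed = 77))
  expect_gt(nrow(tr$ssrs), 10)
  found <- find_ssrs(tr$contigs)
  key_found <- paste(found$contig_id, found$start, found$end, found$repeat_count)
  key_truth <- paste(tr$ssrs$contig_id, tr$ssrs$start, tr$ssrs$end, tr$ssrs$repeat_count)
  expect_true(all(key_truth %in% key_found))
})

test_that("canonical motif classes collapse rotation and reverse complement", {
  expect_equal(canonical_motif("CT"), "AG/CT")
  expect_equal(canonical_motif("GTT"), "AAC/GTT")
  expect_equal(canonical_motif("TA"), "AT/TA")
  expect_error(canonical_motif("AXT"), "ACGT")
  # invariance: any rotation or reverse complement maps to the same class
  set.seed(5)
  for (i in 1:50) {
    u <- sample(2:6, 1)
    m <- rand_seq(u)
    cls <- canonical_motif(m)
    rot <- paste0(substr(m, 2, u), substr(m, 1, 1))
    expect_equal(canonical_motif(rot), cls)
    expect_equal(canonical_motif(revcomp(m)), cls)
    rep1 <- sub("/.*", "", cls)
    expect_equal(canonical_motif(rep1), cls) # idempotent on the representative
  }
})

test_that("compound merging chains SSRs within the 100 bp spacer bound", {
  mk <- function(gap) {
    sq <- paste0("GG", strrep("AC", 6), strrep("T", gap), strrep("AG", 6), "GG")
    tibble::tibble(id = "c1", seq = sq)
  }
  ctg <- mk(2)
  recs <- merge_compound(find_ssrs(ctg), ctg)
  expect_equal(recs$kind, "compound")
  expect_equal(recs$ssr, "(AC)6tt(AG)6")
  expect_equal(recs$n_members, 2L)

  ctg101 <- mk(101)
  recs101 <- merge_compound(find_ssrs(ctg101), ctg101)
  expect_equal(recs101$kind, c("perfect", "perfect"))

  ctg100 <- mk(100)
  expect_equal(merge_compound(find_ssrs(ctg100), ctg100)$kind, "compound")

  # three members with 10 nt gaps chain into one compound record
  sq3 <- paste0("GG", strrep("AC", 6), strrep("T", 10), strrep("AG", 6),
                strrep("C", 10), strrep("AAG", 5), "GG")
  ctg3 <- tibble::tibble(id = "c1", seq = sq3)
  recs3 <- merge_compound(find_ssrs(ctg3), ctg3)
  expect_equal(recs3$n_members, 3L)
  # every input SSR lands in exactly one output record
  expect_equal(sum(recs3$n_members), nrow(find_ssrs(ctg3)))
})

test_that("cross-assembly SSR matching needs class, size and context to agree", {
  set.seed(12)
  shared <- paste0(rand_seq(200), strrep("AC", 7), rand_seq(200))
  ctg_a <- tibble::tibble(id = "a1", seq = shared)
  ctg_b <- tibble::tibble(id = "b1", seq = shared)
  m <- match_ssrs_across_assemblies(find_ssrs(ctg_a), ctg_a, find_ssrs(ctg_b), ctg_b)
  expect_equal(nrow(m), 1L)
  expect_equal(m$canonical_class, "AC/GT")

  # same motif and count but unrelated flanks: no match
  ctg_c <- tibble::tibble(id = "c1", seq = paste0(rand_seq(200), strrep("AC", 7), rand_seq(200)))
  expect_equal(
    nrow(match_ssrs_across_assemblies(find_ssrs(ctg_a), ctg_a, find_ssrs(ctg_c), ctg_c)),
    0L
  )

  # same context but different repeat count: no match
  longer <- paste0(substr(shared, 1, 200), strrep("AC", 8), substr(shared, 215, 414))
  ctg_d <- tibble::tibble(id = "d1", seq = longer)
  expect_equal(
    nrow(match_ssrs_across_assemblies(find_ssrs(ctg_a), ctg_a, find_ssrs(ctg_d), ctg_d)),
    0L
  )
})

test_that("Primer3 tasks carry the SSR target and the assay design policy", {
  ctg <- tibble::tibble(id = "c1", seq = paste0(rand_seq(119), strrep("AC", 6), rand_seq(269)))
  ssrs <- find_ssrs(ctg)
  expect_equal(ssrs$start, 120L)
  task <- make_primer3_input(ssrs, ctg)
  expect_false(task$warn_flank)
  lines <- strsplit(task$record, "\n")[[1]]
  expect_true("SEQUENCE_TARGET=119,12" %in% lines) # 0-based start, length 12
  expect_true("PRIMER_PRODUCT_SIZE_RANGE=100-300" %in% lines)
  expect_true("PRIMER_OPT_TM=60.0" %in% lines)
  expect_true("PRIMER_OPT_SIZE=20" %in% lines)
  expect_equal(lines[length(lines)], "=")

  # SSR flush against the contig start is flagged
  ctg2 <- tibble::tibble(id = "c2", seq = paste0(strrep("AC", 6), rand_seq(100)))
  task2 <- make_primer3_input(find_ssrs(ctg2), ctg2)
  expect_true(task2$warn_flank)
})

test_that("Primer3 boulder output parses into a primer-pair table", {
  out_text <- c(
    "SEQUENCE_ID=c1_ssr1",
    "PRIMER_PAIR_NUM_RETURNED=1",
    "PRIMER_LEFT_0_SEQUENCE=ACGTACGTACGTACGTACGT",
    "PRIMER_RIGHT_0_SEQUENCE=TTTTGGGGCCCCAAAATTTT",
    "PRIMER_LEFT_0_TM=59.8",
    "PRIMER_RIGHT_0_TM=60.2",
    "PRIMER_PAIR_0_PRODUCT_SIZE=180",
    "=",
    "SEQUENCE_ID=c2_ssr2",
    "PRIMER_PAIR_NUM_RETURNED=0",
    "="
  )
  pp <- parse_primer3_output(out_text)
  expect_equal(nrow(pp), 1L)
  expect_equal(pp$seq_id, "c1_ssr1")
  expect_equal(pp$left_tm, 59.8)
  expect_equal(pp$product_size, 180L)
})
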