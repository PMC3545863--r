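# 101-nt SNP windows, local alignment, reciprocal comparison and the
# KASPar-window lookup

test_that("extract_snp_windows centres the SNP with 50 nt of flank", {
  ctg <- tibble::tibble(id = "c1", seq = rand_seq(300))
  w <- extract_snp_windows(ctg, tibble::tibble(contig_id = "c1", pos = 151L))
  expect_equal(nchar(w$seq), 101L)
  expect_equal(w$seq, substr(ctg$seq, 101, 201))
  expect_equal(substr(w$seq, 51, 51), substr(ctg$seq, 151, 151))

  # boundary: pos 51 spans 1..101
  w2 <- extract_snp_windows(ctg, tibble::tibble(contig_id = "c1", pos = 51L))
  expect_equal(w2$seq, substr(ctg$seq, 1, 101))
  # pos 50 lacks flank
  expect_error(
    extract_snp_windows(ctg, tibble::tibble(contig_id = "c1", pos = 50L)),
    "within 50"
  )
})

mutate_at_positions <- function(seq, positions) {
  s <- strsplit(seq, "")[[1]]
  s[positions] <- vapply(s[positions], function(b) {
    setdiff(c("A", "C", "G", "T"), b)[1]
  }, "")
  paste(s, collapse = "")
}

test_that("local_align counts matches of the optimal alignment", {
  set.seed(41)
  a <- rand_seq(101)
  expect_equal(local_align(a, a)$n_matches, 101L)
  # 25 interior mismatches spread so that every prefix/suffix trim strictly
  # loses score: the end-to-end alignment is the unique optimum
  gaps <- c(4, rep(3, 10), rep(2, 4), rep(3, 10), 4) # 26 match runs, sum 76
  b <- mutate_at_positions(a, cumsum(gaps[1:25] + 1))
  res <- local_align(a, b)
  expect_equal(res$n_matches, 76L)
  expect_lt(res$n_matches, 80) # an invalid hit under the 80-base rule
  # unrelated sequences score far below the 80-match bar
  res2 <- local_align(rand_seq(101), rand_seq(101))
  expect_lt(res2$n_matches, 80)
})

test_that("local alignment scores equal the quadratic DP oracle", {
  set.seed(99)
  for (i in 1:120) {
    a <- rand_seq(sample(5:30, 1))
    b <- if (runif(1) < 0.3) {
      mutate_at_positions(a, sample(nchar(a), min(3, nchar(a))))
    } else {
      rand_seq(sample(5:30, 1))
    }
    expect_equal(local_align(a, b)$score, oracle_local_score(a, b))
  }
})

make_windows <- function(seqs, prefix) {
  tibble::tibble(
    snp_id = paste0(prefix, seq_along(seqs)),
    contig_id = paste0(prefix, seq_along(seqs)),
    pos = 51L, seq = seqs
  )
}

test_that("reciprocal comparison partitions SNPs into common and unique", {
  set.seed(6)
  seqs <- vapply(rep(101, 5), rand_seq, "")
  wa <- make_windows(seqs, "a")
  wb <- make_windows(seqs, "b")
  res <- compare_snp_sets(wa, wb)
  expect_equal(res$n_common, 5L)
  expect_equal(res$n_unique_a, 0L)
  expect_equal(res$n_unique_b, 0L)

  # disjoint sequence universes: nothing in common
  wc <- make_windows(vapply(rep(101, 4), rand_seq, ""), "c")
  res2 <- compare_snp_sets(wa, wc)
  expect_equal(res2$n_common, 0L)
  expect_equal(res2$n_unique_a + res2$n_common, res2$n_a) # exact partition
  expect_equal(res2$n_unique_b, 4L)
})

test_that("a one-sided hit without reciprocity stays unique", {
  set.seed(7)
  base <- rand_seq(101)
  a1 <- mutate_at_positions(base, seq(5, 49, by = 5)) # 9 mismatches from base
  a2 <- base
  b1 <- base
  wa <- make_windows(c(a1, a2), "a")
  wb <- make_windows(b1, "b")
  res <- compare_snp_sets(wa, wb)
  # b1's best hit is a2 (identical), so a1's valid hit is not reciprocated
  expect_equal(res$pairs$snp_a, "a2")
  expect_equal(res$n_common, 1L)
  expect_equal(res$n_unique_a, 1L)
})

test_that("reverse-complement orientation is searched", {
  set.seed(17)
  s <- rand_seq(101)
  wa <- make_windows(s, "a")
  wb <- make_windows(revcomp(s), "b")
  res <- compare_snp_sets(wa, wb)
  expect_equal(res$n_common, 1L)
})

test_that("the comparison is symmetric on paired assemblies", {
  set.seed(23)
  shared <- vapply(rep(101, 8), rand_seq, "")
  only_a <- vapply(rep(101, 3), rand_seq, "")
  only_b <- vapply(rep(101, 4), rand_seq, "")
  wa <- make_windows(c(shared, only_a), "a")
  wb <- make_windows(c(shared, only_b), "b")
  ab <- compare_snp_sets(wa, wb)
  ba <- compare_snp_sets(wb, wa)
  expect_equal(ab$n_common, ba$n_common)
  expect_equal(ab$n_unique_a, ba$n_unique_b)
  expect_equal(ab$n_common, 8L)
})

test_that("KASPar window lookup applies the 95% identity rule", {
  set.seed(10)
  ctg <- tibble::tibble(id = c("c1", "c2"), seq = c(rand_seq(600), rand_seq(600)))
  win <- substr(ctg$seq[1], 200, 300)
  hit <- kaspar_window_lookup(win, ctg)
  expect_equal(hit$contig_id, "c1")
  expect_equal(hit$identity, 1)

  # 4 mismatches over 101: identity ~ 0.96, still a hit
  win4 <- mutate_at_positions(win, c(20, 40, 60, 80))
  expect_equal(nrow(kaspar_window_lookup(win4, ctg)), 1L)

  # 10 mismatches: identity ~ 0.90, no hit
  win10 <- mutate_at_positions(win, seq(10, 100, by = 10))
  expect_equal(nrow(kaspar_window_lookup(win10, ctg)), 0L)
})

test_that("tidy and glance expose comparison results as tibbles", {
  set.seed(3)
  seqs <- vapply(rep(101, 3), rand_seq, "")
  res <- compare_snp_sets(make_windows(seqs, "a"), make_windows(seqs, "b"))
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(tidy(res)), 3L)
  g <- glance(res)
  expect_equal(g$n_common, 3L)
  expect_equal(g$n_a, 3L)
})
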