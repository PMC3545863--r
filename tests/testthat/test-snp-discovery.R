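# pileup construction, per-line genotype calls, the two-out-of-three SNP
# rule, the distance/depth filters, and the EST consensus caller

aln_row <- function(id, gt, ctg, pos, cigar, seq) {
  tibble::tibble(read_id = id, genotype = gt, contig_id = ctg,
                 pos = pos, cigar = cigar, seq = seq)
}

test_that("build_pileup counts per position and per genotype", {
  contigs <- tibble::tibble(id = "c1", seq = strrep("A", 200), length = 200L)
  al <- dplyr::bind_rows(
    aln_row("r1", "CM334", "c1", 1L, "85M", strrep("G", 85)),
    aln_row("r2", "EJ", "c1", 1L, "85M", strrep("C", 85))
  )
  pile <- build_pileup(al, contigs)
  p1 <- pile[pile$pos <= 85, ]
  expect_equal(sum(p1$G[p1$genotype == "CM334"]), 85L)
  expect_equal(sum(p1$C[p1$genotype == "EJ"]), 85L)
  expect_equal(sum(p1$G[p1$genotype == "EJ"]), 0L) # counts kept separate
  expect_true(all(pile$depth[pile$pos > 85] == 0))
})

test_that("build_pileup honours CIGAR semantics for I, D and S", {
  contigs <- tibble::tibble(id = "c1", seq = strrep("A", 100), length = 100L)
  # 10M 2D 10M: positions 11-12 are deleted -> no base count there
  al <- aln_row("r1", "CM334", "c1", 1L, "10M2D10M", strrep("G", 20))
  pile <- build_pileup(al, contigs)
  covered <- pile$pos[pile$depth > 0]
  expect_equal(covered, c(1:10, 13:22))
  # 2S 10M 3I 5M consumes 20 read bases but only 15 reference positions
  al2 <- aln_row("r2", "CM334", "c1", 5L, "2S10M3I5M", strrep("T", 20))
  pile2 <- build_pileup(al2, contigs)
  expect_equal(pile2$pos[pile2$depth > 0], 5:19)
  # overrunning alignment is skipped and counted
  al3 <- aln_row("r3", "CM334", "c1", 95L, "10M", strrep("G", 10))
  pile3 <- build_pileup(al3, contigs)
  expect_equal(attr(pile3, "n_skipped"), 1L)
  expect_true(all(pile3$depth == 0))
})

test_that("call_line applies the depth-10 / 90% homozygote rule", {
  expect_equal(call_line(c(G = 15))$status, "hom")
  expect_equal(call_line(c(G = 15))$allele, "G")
  expect_equal(call_line(c(G = 9))$status, "low_depth") # depth-10 boundary
  expect_equal(call_line(c(G = 8, C = 6))$status, "het") # no base reaches 90%
  expect_equal(call_line(c(G = 9, C = 1))$status, "hom") # exactly 90%
  expect_equal(call_line(c(G = 9, C = 1, A = 1))$status, "low_depth") # 2nd allele 1 < 2
})

# build a line-calls tibble directly for the caller tests
lc_row <- function(pos, gt, status, allele, depth = 15L) {
  tibble::tibble(contig_id = "c1", pos = pos, genotype = gt,
                 status = status, allele = allele, depth = depth)
}
lc_position <- function(pos, statuses, alleles, depths = c(15L, 15L, 15L)) {
  dplyr::bind_rows(purrr::pmap(
    list(c("CM334", "EJ", "Maor"), statuses, alleles, depths),
    function(g, s, a, d) lc_row(pos, g, s, a, d)
  ))
}

test_that("the two-out-of-three homozygote rule calls SNPs and tracks hets", {
  lc <- dplyr::bind_rows(
    lc_position(100L, c("hom", "hom", "hom"), c("G", "C", "G")), # SNP G/G/C
    lc_position(200L, c("hom", "hom", "hom"), c("G", "G", "G")), # no SNP
    lc_position(300L, c("hom", "het", "hom"), c("G", NA, "C")),  # het position
    lc_position(400L, c("hom", "hom", "hom"), c("A", "C", "G")), # tri-allelic
    lc_position(500L, c("hom", "hom", "low_depth"), c("G", "C", NA))
  )
  res <- call_iga_snps(lc)
  expect_equal(res$snps$pos, 100L)
  expect_equal(res$snps$ref, "G") # majority allele
  expect_equal(res$snps$alt, "C")
  expect_equal(res$snps$allele_EJ, "C")
  expect_equal(res$snps$total_depth, 45)
  expect_equal(res$het_positions$pos, 300L)
})

mk_cand <- function(pos, depth = 36) {
  n <- length(pos)
  tibble::tibble(
    contig_id = "c1", pos = as.integer(pos), ref = "G", alt = "C",
    allele_CM334 = "G", allele_EJ = "C", allele_Maor = "G",
    depth_CM334 = depth / 3, depth_EJ = depth / 3, depth_Maor = depth / 3,
    total_depth = rep(depth, length.out = n), source = "iga", flags = ""
  )
}
no_hets <- tibble::tibble(contig_id = character(), pos = integer())

test_that("filter_iga_snps flags junction, adjacency, het and depth failures", {
  jx <- tibble::tibble(contig_id = "c1", pos = 150L)
  # 30 bp from a junction
  out <- filter_iga_snps(mk_cand(120), no_hets, jx)
  expect_false(out$kept)
  expect_equal(out$flags, "near_junction")
  # a pair 49 bp apart: both flagged
  out2 <- filter_iga_snps(mk_cand(c(300, 349)), no_hets, jx)
  expect_equal(out2$flags, c("adjacent_snp", "adjacent_snp"))
  # 50 bp apart passes
  out2b <- filter_iga_snps(mk_cand(c(300, 350)), no_hets, jx)
  expect_true(all(out2b$kept))
  # isolated, junction 100 bp away, depth 36: kept
  out3 <- filter_iga_snps(mk_cand(500), no_hets, jx)
  expect_true(out3$kept)
  # heterozygote 20 bp away
  hets <- tibble::tibble(contig_id = "c1", pos = 520L)
  out4 <- filter_iga_snps(mk_cand(500), hets, jx)
  expect_equal(out4$flags, "adjacent_het")
  # summed depth below 20
  out5 <- filter_iga_snps(mk_cand(500, depth = 18), no_hets, jx)
  expect_equal(out5$flags, "low_depth_total")
})

test_that("raising min_line_depth never enlarges the kept SNP set", {
  cfg <- sim_config(n_genes = 8, seed = 21, error_rate = 0, depth_per_line = 14)
  tr <- simulate_truth(cfg)
  rd <- simulate_reads(tr)
  al <- naive_map(rd, tr$contigs)
  pile <- build_pileup(al, tr$contigs)
  kept_sets <- lapply(c(5, 10, 13), function(d) {
    cc <- call_iga_snps(call_lines(pile, min_line_depth = d))
    fl <- filter_iga_snps(cc$snps, cc$het_positions, tr$junctions)
    paste0(fl$contig_id, ":", fl$pos)[fl$kept]
  })
  expect_true(all(kept_sets[[2]] %in% kept_sets[[1]]))
  expect_true(all(kept_sets[[3]] %in% kept_sets[[2]]))
})

test_that("kept SNPs respect the 50 bp spacing invariants end to end", {
  cfg <- sim_config(n_genes = 15, seed = 13, error_rate = 0)
  tr <- simulate_truth(cfg)
  rd <- simulate_reads(tr)
  al <- naive_map(rd, tr$contigs)
  cc <- call_iga_snps(call_lines(build_pileup(al, tr$contigs)))
  fl <- filter_iga_snps(cc$snps, cc$het_positions, tr$junctions)
  kept <- fl[fl$kept, ]
  for (cid in unique(kept$contig_id)) {
    pos <- sort(kept$pos[kept$contig_id == cid])
    if (length(pos) > 1) expect_true(all(diff(pos) >= 50))
    jx <- tr$junctions$pos[tr$junctions$contig_id == cid]
    if (length(jx)) {
      expect_true(all(vapply(pos, function(p) min(abs(jx - p)), 0) >= 50))
    }
  }
})

# --- EST consensus caller -------------------------------------------------

test_that("est_pileup counts member bases, skipping gaps and singletons", {
  contigs <- tibble::tibble(id = c("u1", "u2"), seq = c(strrep("A", 30), strrep("A", 30)),
                            length = c(30L, 30L))
  members <- tibble::tibble(
    contig_id = c("u1", "u1", "u2"),
    member_id = c("e1", "e2", "e3"),
    start = c(1L, 5L, 1L),
    seq = c("ACGTACGTAC", "AC-TA", "AAAAA")
  )
  cols <- est_pileup(members, contigs)
  expect_false(any(cols$contig_id == "u2")) # singleton contig excluded
  p7 <- cols[cols$pos == 7, ]
  expect_equal(p7$depth, 1L) # gap in e2 at consensus pos 7 carries no information
})

est_col <- function(pos, A = 0, C = 0, G = 0, T = 0) {
  tibble::tibble(contig_id = "u1", pos = as.integer(pos),
                 A = A, C = C, G = G, T = T, depth = A + C + G + T)
}

test_that("call_est_snps requires depth 2 on two distinct alleles", {
  expect_equal(call_est_snps(est_col(10, A = 3, G = 2))$allele2, "G")
  expect_equal(nrow(call_est_snps(est_col(10, A = 5, G = 1))), 0L)
  tri <- call_est_snps(est_col(10, A = 2, G = 2, T = 2))
  expect_equal(tri$flags, "tri_allelic")
  expect_equal(c(tri$allele1, tri$allele2), c("A", "G")) # count tie -> alphabetical
})

est_snp <- function(pos, depth) {
  tibble::tibble(
    contig_id = "u1", pos = as.integer(pos), allele1 = "A", allele2 = "G",
    depth1 = depth - 2L, depth2 = 2L, total_depth = as.integer(depth),
    source = "est", flags = ""
  )
}

test_that("filter_est_snps applies the end rule and coverage-greedy adjacency", {
  contigs <- tibble::tibble(id = "u1", length = 500L)
  # within 50 bp of the start
  out <- filter_est_snps(est_snp(40, 10), contigs)
  expect_false(out$kept)
  expect_match(out$flags, "near_end")
  # of two SNPs 30 bp apart, the higher-coverage one survives
  out2 <- filter_est_snps(dplyr::bind_rows(est_snp(100, 10), est_snp(130, 6)), contigs)
  expect_equal(out2$kept, c(TRUE, FALSE))
  # coverage tie keeps the leftmost
  out3 <- filter_est_snps(dplyr::bind_rows(est_snp(100, 8), est_snp(130, 8)), contigs)
  expect_equal(out3$kept, c(TRUE, FALSE))
  # greedy pass re-evaluates against the survivor
  out4 <- filter_est_snps(
    dplyr::bind_rows(est_snp(100, 5), est_snp(130, 9), est_snp(160, 6)), contigs
  )
  expect_equal(out4$kept, c(FALSE, TRUE, FALSE))
  # last-50 rule: position > length - 50
  out5 <- filter_est_snps(est_snp(460, 10), contigs)
  expect_false(out5$kept)
})
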