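# gene models, RPKM rules, gene-set ratios, codon-34 allele classification

toy_gene_models <- function() {
  gene_models(methods::as(list(
    gA = GenomicRanges::GRanges("chrT", IRanges::IRanges(
      start = c(101, 1501), end = c(1100, 2500)), strand = "+"),   # 2 kb
    gB = GenomicRanges::GRanges("chrT", IRanges::IRanges(
      start = 5001, end = 6000), strand = "-"),                    # 1 kb
    gC = GenomicRanges::GRanges("chrT", IRanges::IRanges(
      start = 8001, end = 8400), strand = "+")), "GRangesList"))
}

# reverse-protocol read whose 5' start sits at 1-based position `pos`
rev_read <- function(pos, gene_strand = "+", len = 50L) {
  if (gene_strand == "+")
    GenomicRanges::GRanges("chrT", IRanges::IRanges(pos - len + 1L, pos),
                           strand = "-")
  else
    GenomicRanges::GRanges("chrT", IRanges::IRanges(pos, pos + len - 1L),
                           strand = "+")
}

test_that("gene_models merges isoforms into union exons", {
  gl <- methods::as(list(
    g1 = GenomicRanges::GRanges("chrT", IRanges::IRanges(
      start = c(1, 51, 26), end = c(50, 150, 75)), strand = "+")),
    "GRangesList")
  gm <- gene_models(gl)
  expect_equal(unname(gm$union_exon_length["g1"]), 150L)
  expect_equal(length(gm$exons[["g1"]]), 1L)  # overlapping exons reduced

  # plain GRanges with gene_id: single-exon models
  gr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 100),
                               strand = "+", gene_id = "x")
  expect_equal(unname(gene_models(gr)$union_exon_length["x"]), 100L)
})

test_that("quantify_rpkm applies assignment, strandedness and exclusion
           rules", {
  gm <- toy_gene_models()
  reads <- c(rev_read(200), rev_read(1600), rev_read(5500, "-"))
  tab <- quantify_rpkm(list(s1 = reads), gm)
  expect_equal(sort(tab$gene_id), c("gA", "gB"))
  expect_equal(tab$count_s1[tab$gene_id == "gA"], 2L)
  tot <- attr(tab, "total_assigned")[["s1"]]
  expect_equal(tot, 3L)
  expect_equal(tab$rpkm_s1[tab$gene_id == "gA"], 2 * 1e9 / (2000 * 3))
  # gC has zero counts in every sample and is excluded
  expect_false("gC" %in% tab$gene_id)

  # sense-strand read on a + gene under the reverse protocol: unassigned
  sense <- GenomicRanges::GRanges("chrT", IRanges::IRanges(200, 249),
                                  strand = "+")
  tab <- quantify_rpkm(list(s1 = c(rev_read(5500, "-"), sense)), gm)
  expect_false("gA" %in% tab$gene_id)
  tab <- quantify_rpkm(list(s1 = sense), gm, strandedness = "forward")
  expect_equal(tab$gene_id, "gA")

  # a read whose 5' start is outside union exons is not assigned
  intronic <- rev_read(1200)
  tab <- quantify_rpkm(list(s1 = c(rev_read(5500, "-"), intronic)), gm)
  expect_false("gA" %in% tab$gene_id)

  # a read hitting exons of two genes is unassigned and tallied
  gm2 <- gene_models(methods::as(list(
    g1 = GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 1000),
                                strand = "+"),
    g2 = GenomicRanges::GRanges("chrT", IRanges::IRanges(500, 1500),
                                strand = "+")), "GRangesList"))
  tab <- quantify_rpkm(list(s1 = c(rev_read(700), rev_read(100))), gm2)
  expect_equal(attr(tab, "n_multi_gene")[["s1"]], 1L)
  expect_equal(attr(tab, "total_assigned")[["s1"]], 1L)
})

test_that("rpkm closed form and scale invariance", {
  expect_identical(rpkm(100, 2000, 1e7), 5)
  expect_equal(rpkm(7, 1000, 1e6), 7000 / 1000)
  expect_equal(rpkm(2 * 100, 2000, 2 * 1e7), rpkm(100, 2000, 1e7))
  set.seed(9)
  cnt <- rpois(20, 50); len <- sample(500:5000, 20); tot <- 1e6
  expect_equal(rpkm(3 * cnt, len, 3 * tot), rpkm(cnt, len, tot))
})

test_that("gene_set_log_ratio sorts ascending and controls are seeded", {
  tab <- data.frame(gene_id = paste0("g", 1:40),
                    rpkm_WT = c(4, 2, rep(8, 38)),
                    rpkm_MUT = c(1, 2, rep(8, 38)))
  out <- gene_set_log_ratio(tab, c("g1", "g2"), c("WT", "MUT"), seed = 1)
  expect_equal(out$set$log2_ratio, c(-2, 0))  # ascending
  expect_equal(nrow(out$control), 2L)
  out2 <- gene_set_log_ratio(tab, c("g1", "g2"), c("WT", "MUT"), seed = 1)
  expect_identical(out$control$gene_id, out2$control$gene_id)
  out3 <- gene_set_log_ratio(tab, c("g1", "g2"), c("WT", "MUT"), seed = 2)
  expect_false(identical(out$control$gene_id, out3$control$gene_id))

  # identical columns: all ratios zero
  tab$rpkm_MUT <- tab$rpkm_WT
  out <- gene_set_log_ratio(tab, c("g1", "g2"), c("WT", "MUT"), seed = 1)
  expect_true(all(out$set$log2_ratio == 0))
  expect_true(all(out$control$log2_ratio == 0))

  # zero-RPKM genes are excluded without pseudocounts, and reported
  tab$rpkm_MUT[1] <- 0
  out <- gene_set_log_ratio(tab, c("g1", "g2"), c("WT", "MUT"), seed = 1)
  expect_equal(out$set$gene_id, "g2")
  expect_equal(out$zero_excluded$set, "g1")

  expect_warning(
    gene_set_log_ratio(tab, c("g2", "nope"), c("WT", "MUT"), seed = 1),
    "absent")
  expect_error(
    gene_set_log_ratio(tab, c("zzz"), c("WT", "MUT"), seed = 1),
    "missing")
  expect_error(gene_set_log_ratio(tab, "g1", c("WT", "MUT")), "seed")
})

# a deterministic miniature allele trio: codon 34 at position 100
make_lib <- function() {
  set.seed(42)
  base <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  base[99:108] <- c("T", "G", "G", "A", "C", "A", "T", "G", "G", "C")
  a <- base
  tg <- base; tg[100] <- "A"                     # G34R substitution
  gb <- base; gb[99] <- "C"; gb[108] <- "T"      # synonymous, near codon
  sq <- vapply(list(tg, a, gb), paste, character(1), collapse = "")
  list(lib = allele_library(setNames(sq, c("G34R", "geneA", "geneB")), 100),
       chars = list(G34R = tg, geneA = a, geneB = gb))
}

test_that("allele_library finds diagnostic positions and validates", {
  ml <- make_lib()
  expect_equal(ml$lib$diagnostic_positions, c(99L, 100L, 108L))
  # identical within the window -> error
  s <- as.character(ml$lib$sequences)
  expect_error(allele_library(setNames(s[c(1, 1, 2)], names(s)), 100),
               "distinct")
  expect_error(allele_library(unname(s)[1:3], 100), "named")
  expect_error(allele_library(setNames(s, names(s)), 299), "codon 34")
})

test_that("classify_codon_reads assigns, dedups and rejects correctly", {
  ml <- make_lib()
  sub50 <- function(chars, start) paste(chars[start:(start + 49)],
                                        collapse = "")
  r_g34r <- sub50(ml$chars$G34R, 70)   # covers 99..108 and the codon
  r_a <- sub50(ml$chars$geneA, 62)
  r_b <- sub50(ml$chars$geneB, 95)
  r_up <- sub50(ml$chars$geneA, 1)     # entirely upstream of codon 34
  res <- classify_codon_reads(c(r_g34r, r_a, r_b, r_up), ml$lib)
  expect_equal(unname(res$counts[c("G34R", "geneA", "geneB",
                                   "uninformative")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(res$n_duplicates_removed, 0L)

  # byte-identical duplicates are collapsed before counting
  res <- classify_codon_reads(c(r_g34r, r_g34r, r_g34r, r_a), ml$lib)
  expect_equal(unname(res$counts["G34R"]), 1L)
  expect_equal(res$n_duplicates_removed, 2L)

  # reverse-complement reads are recognized
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(r_b)))
  res <- classify_codon_reads(rc, ml$lib)
  expect_equal(unname(res$counts["geneB"]), 1L)

  # a read partially covering the diagnostic span is uninformative
  r_part <- sub50(ml$chars$geneA, 100)  # misses position 99
  res <- classify_codon_reads(r_part, ml$lib)
  expect_equal(unname(res$counts["uninformative"]), 1L)

  # a mismatch at a diagnostic position prevents assignment
  broken <- strsplit(r_a, "")[[1]]
  broken[100 - 62 + 1] <- "C"  # neither G (WT) nor A (G34R)
  res <- classify_codon_reads(paste(broken, collapse = ""), ml$lib)
  expect_equal(unname(res$counts["uninformative"]), 1L)

  # up to max_mismatch errors outside diagnostic positions are tolerated
  noisy <- strsplit(r_a, "")[[1]]
  noisy[2] <- setdiff(c("A", "C", "G", "T"), noisy[2])[1]
  res <- classify_codon_reads(paste(noisy, collapse = ""), ml$lib)
  expect_equal(unname(res$counts["geneA"]), 1L)

  # read-order permutation invariance
  reads <- c(r_g34r, r_a, r_b, r_up, rc)
  res1 <- classify_codon_reads(reads, ml$lib)
  res2 <- classify_codon_reads(rev(reads), ml$lib)
  expect_equal(res1$counts, res2$counts)
})
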