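# seeded generators: determinism, truth completeness, null behaviour

small_chip <- function(...) sim_chipseq_config(
  chrom_sizes = c(chrS1 = 4e5, chrS2 = 4e5), n_genes = 16L,
  gene_length_range = c(8000, 30000), n_blocks = 30L, n_blacklist = 4L,
  ...)

small_rna <- function(...) sim_rnaseq_config(
  n_genes = 60L, n_set_genes = 8L, n_allele_reads = 120L,
  n_duplicates = 7L, ...)

test_that("generators are deterministic in (config, seed)", {
  a <- simulate_chipseq(small_chip(), seed = 11)
  b <- simulate_chipseq(small_chip(), seed = 11)
  expect_identical(a$reads_wt, b$reads_wt)
  expect_identical(a$reads_mut, b$reads_mut)
  expect_identical(a$truth$blocks, b$truth$blocks)
  c <- simulate_chipseq(small_chip(), seed = 12)
  expect_false(identical(a$reads_wt, c$reads_wt))

  r1 <- simulate_rnaseq_alleles(small_rna(), seed = 4)
  r2 <- simulate_rnaseq_alleles(small_rna(), seed = 4)
  expect_identical(r1$allele_reads, r2$allele_reads)
  expect_identical(r1$alignments$WT, r2$alignments$WT)

  s1 <- simulate_spectrum(sim_spectrum_config(), seed = 9)
  s2 <- simulate_spectrum(sim_spectrum_config(), seed = 9)
  expect_identical(s1$spectrum, s2$spectrum)
  expect_false(identical(
    s1$spectrum,
    simulate_spectrum(sim_spectrum_config(), seed = 10)$spectrum))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulate_chipseq(small_chip(), seed = 1))
  expect_identical(runif(3), before)
})

test_that("chip read depth scales with depth_per_bin", {
  lo <- simulate_chipseq(small_chip(depth_per_bin = 10), seed = 2)
  hi <- simulate_chipseq(small_chip(depth_per_bin = 20), seed = 2)
  ratio <- length(hi$reads_wt) / length(lo$reads_wt)
  expect_gt(ratio, 1.9)
  expect_lt(ratio, 2.1)
})

test_that("chip truth is complete and internally consistent", {
  sim <- simulate_chipseq(small_chip(), seed = 5)
  blocks <- sim$truth$blocks
  expect_equal(length(blocks), 30L)
  # every planted domain lies inside a gene and on whole bins
  expect_true(all(IRanges::overlapsAny(blocks, sim$genes,
                                       type = "within",
                                       ignore.strand = TRUE)))
  expect_true(all((GenomicRanges::start(blocks) - 1L) %% 200 == 0))
  expect_true(all(GenomicRanges::width(blocks) %in% c(200L, 400L)))
  expect_identical(sim$truth$factor_sites,
                   blocks[blocks$factor_site])
  expect_identical(sim$truth$seed, 5)

  # the factor-gain structure is visible in raw counts: factor-site domains
  # have higher mutant/wt signal than non-factor domains
  t_wt <- count_reads(sim$reads_wt, sim$grid, FALSE)
  t_mut <- count_reads(sim$reads_mut, sim$grid, FALSE)
  s_wt <- region_scores(blocks, t_wt)
  s_mut <- region_scores(blocks, t_mut)
  gain <- s_mut / s_wt
  expect_gt(median(gain[blocks$factor_site]),
            median(gain[!blocks$factor_site]))
})

test_that("a gain factor of 1 makes WT and mutant exchangeable", {
  pvals <- vapply(1:5, function(s) {
    sim <- simulate_chipseq(small_chip(gain_factor = 1), seed = 100 + s)
    wt <- count_reads(sim$reads_wt, sim$grid, FALSE)$values
    mut <- count_reads(sim$reads_mut, sim$grid, FALSE)$values
    suppressWarnings(stats::ks.test(wt, mut)$p.value)
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 4L)
})

test_that("rnaseq truth covers reads, set membership and duplicates", {
  sim <- simulate_rnaseq_alleles(small_rna(), seed = 8)
  tr <- sim$truth$reads
  expect_equal(nrow(tr), 120L + 7L)
  expect_equal(sum(tr$is_planted_duplicate), 7L)
  expect_setequal(unique(tr$allele), names(sim$truth$allele_proportions))
  expect_true(all(sim$gene_set %in% names(sim$truth$expression)))
  # planted duplicates are the only repeated sequences (distinct placements)
  expect_equal(sim$truth$n_planted_duplicates, 7L)
  expect_equal(sum(duplicated(tr$read)), 7L)

  # noiseless reads classify with perfect fidelity
  res <- classify_codon_reads(sim$allele_reads, sim$allele_library)
  expect_equal(res$n_duplicates_removed, 7L)
  uniq <- tr[!duplicated(tr$read), ]
  got <- res$assignments$class[match(uniq$read, res$assignments$read)]
  expect_true(all(got[uniq$informative] == uniq$allele[uniq$informative]))
  expect_true(all(got[!uniq$informative] == "uninformative"))
})

test_that("allele class frequencies track the configured proportions", {
  cfg <- sim_rnaseq_config(n_genes = 60L, n_set_genes = 8L,
                           n_allele_reads = 500L, n_duplicates = 0L,
                           allele_proportions = c(G34R = 0.25,
                                                  geneA_WT = 0.25,
                                                  geneB_WT = 0.50))
  sim <- simulate_rnaseq_alleles(cfg, seed = 21)
  res <- classify_codon_reads(sim$allele_reads, sim$allele_library)
  inf <- sum(res$counts[c("G34R", "geneA_WT", "geneB_WT")])
  for (nm in c("G34R", "geneA_WT", "geneB_WT")) {
    p <- cfg$allele_proportions[[nm]]
    se <- sqrt(p * (1 - p) / inf)
    expect_lt(abs(res$counts[[nm]] / inf - p), 3 * se + 0.02)
  }
})

test_that("spectrum generator honours its stated world", {
  cfg <- sim_spectrum_config(abundances = c(me0 = 0, me1 = 1, me2 = 0,
                                            me3 = 0), noise_sd = 0)
  sim <- simulate_spectrum(cfg, seed = 1)
  p <- assign_methyl_states(sim$spectrum, sim$series)
  expect_equal(unname(p$abundance), c(0, 1, 0, 0))
  expect_error(sim_spectrum_config(abundances = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
})

test_that("score cohort generator plants the requested gain fraction", {
  d <- simulate_score_cohort(n_regions = 500, gain_fraction = 0.2,
                             sigma = 0, seed = 6)
  expect_equal(sum(d$true_gained), 100L)
  expect_true(all(abs(d$ko[d$true_gained] / d$wt[d$true_gained] - 2)
                  < 1e-12))
  expect_identical(d, simulate_score_cohort(n_regions = 500,
                                            gain_fraction = 0.2,
                                            sigma = 0, seed = 6))
})
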