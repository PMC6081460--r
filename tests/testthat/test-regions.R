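# enrichment-bin selection, merge/filter, factor stratification, overlaps,
# scaled profiles, percentile conventions

test_that("nearest-rank percentile and quantile summary conventions", {
  expect_equal(percentile_nearest_rank(1:100, 95), 95)
  expect_equal(percentile_nearest_rank(1:100, 25), 25)
  expect_equal(percentile_nearest_rank(c(3, 1, 2), 50), 2)
  expect_error(percentile_nearest_rank(numeric(0), 50), "empty")
  expect_error(percentile_nearest_rank(1:10, 100), "0, 100")

  expect_equal(unname(quantile_summary(1:100)),
               c(10.9, 25.75, 50.5, 75.25, 90.1))
  expect_equal(unname(quantile_summary(42)), rep(42, 5))
  expect_equal(unname(quantile_summary(rep(3.5, 9))), rep(3.5, 5))
  expect_error(quantile_summary(numeric(0)), "empty")
})

test_that("enrichment_config validates its thresholds", {
  expect_silent(enrichment_config())
  expect_error(enrichment_config(select_percentile = 0))
  expect_error(enrichment_config(extreme_top_fraction = 0))
  expect_error(enrichment_config(factor_enriched_percentile = 20,
                                 factor_depleted_percentile = 25),
               "depleted")
})

test_that("genic bins above the per-track 95th percentile are selected", {
  g <- toy_grid(100)
  genes <- gene_spanning(g)
  set.seed(5)
  wt_vals <- sample(1:100)
  wt <- toy_track(wt_vals, g, state = "matched")
  mut <- toy_track(rep(0, 100), g, state = "matched")
  sel <- select_enriched_genic_bins(wt, mut, genes)
  expect_equal(length(sel), 5L)
  expect_setequal(sel$wt, 96:100)
  expect_equal(attr(sel, "threshold_wt"), 95)
  expect_true(all(sel$source_condition == "WT"))

  # either-condition rule: a bin above threshold only in the mutant counts
  mut_vals <- rep(0, 100)
  mut_vals[7] <- 50
  sel <- select_enriched_genic_bins(wt, toy_track(mut_vals, g,
                                                  state = "matched"),
                                    genes)
  expect_true(1200 %in% (GenomicRanges::start(sel) - 1L))  # bin 7

  # genic restriction: high bins outside genes are never selected
  genes_half <- gene_spanning(g, to0 = 10000)  # bins 1..50 genic
  vals <- rep(1, 100)
  vals[80] <- 1000                             # non-genic spike
  vals[3] <- 500
  sel <- select_enriched_genic_bins(toy_track(vals, g, state = "matched"),
                                    toy_track(rep(0, 100), g,
                                              state = "matched"),
                                    genes_half)
  expect_equal(GenomicRanges::start(sel) - 1L, 400)

  expect_warning(
    sel0 <- select_enriched_genic_bins(
      wt, mut, GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 100))),
    "no genic bins")
  expect_equal(length(sel0), 0L)
})

test_that("merge_and_filter merges within distance and applies exclusions", {
  mk <- function(start0, end0, score = 1)
    GenomicRanges::GRanges("chrA",
                           IRanges::IRanges(start0 + 1L, end0),
                           score = score)
  cfg <- enrichment_config()

  # gap of exactly 100 merges; merged length 500 is retained
  r <- merge_and_filter(c(mk(0, 200, 2), mk(300, 500, 4)), cfg)
  expect_equal(length(r), 1L)
  expect_equal(GenomicRanges::start(r) - 1L, 0)
  expect_equal(GenomicRanges::end(r), 500)
  expect_equal(r$score, 3)
  expect_equal(r$n_bins, 2L)

  # gap of 101 does not merge
  r <- merge_and_filter(c(mk(0, 200), mk(301, 501)), cfg)
  expect_equal(length(r), 2L)

  # three adjacent bins merge to 600 bp and are excluded as too long
  r <- merge_and_filter(c(mk(0, 200), mk(200, 400), mk(400, 600)), cfg)
  expect_equal(length(r), 0L)
  expect_equal(unname(attr(r, "log")[["excluded_length"]]), 1L)
  expect_equal(attr(r, "excluded")$reason, "length_gt_max")

  # top-0.01% exclusion removes exactly floor(n * fraction) regions
  n <- 10000L
  bins <- GenomicRanges::GRanges("chrA",
                                 IRanges::IRanges(seq_len(n) * 1000 + 1,
                                                  width = 200),
                                 score = seq_len(n))
  r <- merge_and_filter(bins, cfg)
  expect_equal(length(r), n - 1L)
  expect_false(n %in% r$score)  # the single top-scoring region is gone
  expect_equal(unname(attr(r, "log")[["excluded_extreme"]]), 1L)

  # empty in, empty out
  r <- merge_and_filter(mk(0, 0)[0], cfg)
  expect_equal(length(r), 0L)
})

test_that("merging is idempotent and matches the O(n^2) oracle", {
  set.seed(23)
  cfg <- enrichment_config()
  for (rep in 1:30) {
    n <- sample(2:40, 1)
    start0 <- sort(sample(seq(0, 8000, 200), n))
    bins <- GenomicRanges::GRanges("chrA",
                                   IRanges::IRanges(start0 + 1L,
                                                    start0 + 200L),
                                   score = round(runif(n, 0, 50), 3))
    r <- merge_and_filter(bins, cfg)
    o <- oracle_merge(data.frame(chrom = "chrA", start0 = start0,
                                 end0 = start0 + 200, score = bins$score),
                      cfg$merge_distance, cfg$max_region_length,
                      cfg$extreme_top_fraction)
    expect_equal(GenomicRanges::start(r) - 1L, o$start0)
    expect_equal(GenomicRanges::end(r), o$end0)
    expect_equal(r$score, o$score, tolerance = 1e-12)
    # idempotence: feeding retained regions back reproduces them
    r2 <- merge_and_filter(r, cfg)
    expect_equal(GenomicRanges::start(r2), GenomicRanges::start(r))
    expect_equal(r2$score, r$score)
  }
})

test_that("classify_by_factor uses strict nearest-rank thresholds", {
  g <- toy_grid(100)
  regions <- g$bins
  fac <- toy_track(1:100, g)
  lab <- classify_by_factor(regions, fac)
  expect_equal(sum(lab == "enriched"), 25L)  # scores 76..100
  expect_equal(sum(lab == "depleted"), 24L)  # scores 1..24
  expect_equal(sum(lab == "neither"), 51L)
  expect_equal(attr(lab, "threshold_enriched"), 75)

  # 90th-percentile variant for variant-histone tracks
  lab90 <- classify_by_factor(regions, fac,
                              enrichment_config(
                                factor_enriched_percentile = 90))
  expect_equal(sum(lab90 == "enriched"), 10L)

  # constant factor track: nothing strictly above/below -> all neither
  lab <- classify_by_factor(regions, toy_track(rep(7, 100), g))
  expect_true(all(lab == "neither"))

  # zero-coverage regions are depleted when the 25th percentile is positive
  vals <- c(rep(0, 10), 1:90)
  lab <- classify_by_factor(regions, toy_track(vals, g))
  expect_true(all(lab[1:10] == "depleted"))

  expect_error(classify_by_factor(regions[1:3], fac), "at least 4")

  # order permutation invariance
  set.seed(31)
  perm <- sample(100)
  lab_p <- classify_by_factor(regions[perm], fac)
  expect_equal(as.character(lab_p), as.character(lab)[perm])
})

test_that("overlap_classes counts exclusive combinations with depletion
           exclusion", {
  labs <- function(x) factor(x, levels = c("enriched", "depleted",
                                           "neither"))
  cls <- list(A = labs(c("enriched", "enriched", "neither", "depleted")),
              B = labs(c("enriched", "depleted", "enriched", "neither")),
              C = labs(c("enriched", "neither", "neither", "neither")))
  out <- overlap_classes(cls)
  expect_equal(unname(out[["A&B&C"]]), 1L)  # region 1
  # region 2: enriched A, depleted B -> counts only in the A cell
  expect_equal(unname(out[["A"]]), 1L)
  expect_equal(unname(out[["A&B"]]), 0L)
  expect_equal(unname(out[["B"]]), 1L)      # region 3
  expect_equal(unname(out[["C"]]), 0L)

  empty <- list(A = labs(character(0)), B = labs(character(0)))
  expect_true(all(overlap_classes(empty) == 0L))

  expect_error(overlap_classes(list(A = labs("enriched"),
                                    B = labs(c("enriched", "neither")))),
               "different region sets")
})

test_that("scaled_region_matrix rescales bodies and excludes blacklist", {
  g <- toy_grid(30)
  const <- toy_track(rep(4, 30), g)
  # regions with both 1 kb flanks inside the chromosome
  regions <- GenomicRanges::GRanges("chrA", IRanges::IRanges(
    start = c(1201, 2601), end = c(1600, 3000)))
  m <- scaled_region_matrix(regions, const)
  expect_true(all(m == 4))
  expect_equal(nrow(m), 2L)
  expect_equal(ncol(m), 5L + 3L + 5L)  # 1kb flanks + ceil(500/200) body

  # region inside a blacklist interval is absent
  bl <- GenomicRanges::GRanges("chrA", IRanges::IRanges(2601, 3000))
  m <- scaled_region_matrix(regions, const, blacklist = bl)
  expect_equal(nrow(m), 1L)
  expect_equal(attr(m, "n_blacklisted"), 1L)

  # 400-bp region over bins valued 2 and 6: hand-computed linear re-gridding
  vals <- rep(0, 30)
  vals[3:4] <- c(2, 6)  # bins [400,600) and [600,800)
  tr <- toy_track(vals, g)
  reg <- GenomicRanges::GRanges("chrA", IRanges::IRanges(401, 800))
  m <- scaled_region_matrix(reg, tr, flank = 0)
  # body columns sample rel. positions 1/6, 1/2, 5/6 of [bin centers .25,.75]
  expect_equal(unname(m[1, ]), c(2, 4, 6))

  # flank positions beyond the chromosome end contribute zero
  reg <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 400))
  m <- scaled_region_matrix(reg, const)
  expect_true(all(m[1, 1:5] == 0))
})
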