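# Percentile-based calling of mark-enriched genic regions, merge/filter rules,
# factor-occupancy stratification, class overlaps, and scaled-region profiles.

#' Nearest-rank percentile
#'
#' The thresholding convention used throughout region calling: the Pth
#' percentile of `x` is the value at rank `ceiling(P/100 * n)` of the sorted
#' vector, and "exceeds the Pth percentile" means strictly greater than that
#' value. Reproducible on integer-valued counts (no interpolation).
#'
#' @param x Numeric vector (non-empty).
#' @param p Percentile in (0, 100).
#' @return The nearest-rank percentile value.
#' @export
percentile_nearest_rank <- function(x, p) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  if (!is.numeric(p) || p <= 0 || p >= 100)
    stop("p must be in (0, 100)", call. = FALSE)
  sort(x)[ceiling(p / 100 * length(x))]
}

#' Descriptive five-number percentile summary
#'
#' 10th, 25th, 50th, 75th and 90th percentiles under the linear-interpolation
#' convention (`stats::quantile`, type 7) — the box-and-whisker convention
#' (boxes 25/50/75, whiskers 10/90).
#'
#' @param values Numeric vector with at least one value.
#' @return Named numeric vector `p10, p25, p50, p75, p90`.
#' @export
quantile_summary <- function(values) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  setNames(as.numeric(quantile(values, c(.10, .25, .50, .75, .90),
                               type = 7, names = FALSE)),
           c("p10", "p25", "p50", "p75", "p90"))
}

#' Region-calling configuration
#'
#' Holds every threshold of the enrichment-region pipeline: bins above the
#' `select_percentile` (over genic bins, per track) in either condition are
#' selected; selected bins within `merge_distance` bp are merged; merged
#' regions longer than `max_region_length` bp and the top
#' `extreme_top_fraction` of regions by score are excluded. Factor
#' stratification uses `factor_enriched_percentile` (75 for demethylase
#' tracks, 90 for variant-histone tracks) and `factor_depleted_percentile`.
#'
#' @param select_percentile Genic-bin selection percentile (default 95).
#' @param merge_distance Maximum gap merged, bp (default 100).
#' @param max_region_length Maximum retained region length, bp (default 500).
#' @param extreme_top_fraction Fraction of top-scoring regions excluded
#'   (default 1e-4, i.e. the top 0.01 percent).
#' @param factor_enriched_percentile Factor-enrichment percentile (default 75).
#' @param factor_depleted_percentile Factor-depletion percentile (default 25).
#' @return An `EnrichmentConfig` list.
#' @export
enrichment_config <- function(select_percentile = 95,
                              merge_distance = 100,
                              max_region_length = 500,
                              extreme_top_fraction = 1e-4,
                              factor_enriched_percentile = 75,
                              factor_depleted_percentile = 25) {
  stopifnot(select_percentile > 0, select_percentile < 100,
            merge_distance >= 0, max_region_length > 0,
            extreme_top_fraction > 0, extreme_top_fraction < 1)
  if (!(factor_depleted_percentile > 0 &&
        factor_depleted_percentile < factor_enriched_percentile &&
        factor_enriched_percentile < 100))
    stop("need 0 < depleted percentile < enriched percentile < 100",
         call. = FALSE)
  structure(list(select_percentile = select_percentile,
                 merge_distance = merge_distance,
                 max_region_length = max_region_length,
                 extreme_top_fraction = extreme_top_fraction,
                 factor_enriched_percentile = factor_enriched_percentile,
                 factor_depleted_percentile = factor_depleted_percentile),
            class = "EnrichmentConfig")
}

#' Select mark-enriched genic bins from a condition pair
#'
#' Restricts to bins overlapping (>= 1 bp) any annotated gene, computes the
#' per-track nearest-rank `select_percentile` threshold over those genic bins,
#' and returns the genic bins whose value strictly exceeds the threshold in
#' either condition.
#'
#' @param track_wt,track_mut Matched-normalized `CoverageTrack`s on one grid.
#' @param genes A [GenomicRanges::GRanges] of gene bodies (or anything
#'   coercible via [gene_models()]; gene spans are used).
#' @param config An [enrichment_config()].
#' @return A [GenomicRanges::GRanges] of selected bins with metadata columns
#'   `wt`, `mut` (the two track values), `score` (their mean) and
#'   `source_condition` (`"WT"`, `"mutant"` or `"either"`), plus the two
#'   thresholds as attributes `threshold_wt` / `threshold_mut`.
#' @export
select_enriched_genic_bins <- function(track_wt, track_mut, genes,
                                       config = enrichment_config()) {
  stopifnot(inherits(track_wt, "CoverageTrack"),
            inherits(track_mut, "CoverageTrack"))
  if (!same_grid(track_wt$grid, track_mut$grid))
    stop("tracks are on different grids", call. = FALSE)
  if (inherits(genes, "GeneModels")) genes <- genes$genes
  if (length(genes) == 0L) stop("gene models are empty", call. = FALSE)
  bins <- track_wt$grid$bins
  # annotation may carry chromosomes absent from the grid; that is fine
  genic <- suppressWarnings(
    IRanges::overlapsAny(bins, genes, ignore.strand = TRUE))
  if (!any(genic)) {
    warning("no genic bins on this grid; empty selection", call. = FALSE)
    out <- bins[0]
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      wt = numeric(0), mut = numeric(0), score = numeric(0),
      source_condition = character(0))
    return(out)
  }
  wt <- track_wt$values
  mut <- track_mut$values
  thr_wt <- percentile_nearest_rank(wt[genic], config$select_percentile)
  thr_mut <- percentile_nearest_rank(mut[genic], config$select_percentile)
  hit_wt <- genic & wt > thr_wt
  hit_mut <- genic & mut > thr_mut
  sel <- hit_wt | hit_mut
  out <- bins[sel]
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    wt = wt[sel], mut = mut[sel], score = (wt[sel] + mut[sel]) / 2,
    source_condition = ifelse(hit_wt[sel] & hit_mut[sel], "either",
                              ifelse(hit_wt[sel], "WT", "mutant")))
  attr(out, "threshold_wt") <- thr_wt
  attr(out, "threshold_mut") <- thr_mut
  out
}

#' Merge selected bins into regions and apply exclusion rules
#'
#' Bins separated by at most `merge_distance` bp are merged into one region
#' whose score is the mean of its member-bin scores (MergeBed
#' `-d <dist> -o mean` semantics). Merged regions longer than
#' `max_region_length` bp are then excluded, and finally the top
#' `floor(n * extreme_top_fraction)` regions by score are excluded as
#' extreme. Exclusions are kept, with reasons, in the `excluded` attribute.
#'
#' @param bins A [GenomicRanges::GRanges] of selected bins carrying a numeric
#'   `score` metadata column (as produced by [select_enriched_genic_bins()]).
#' @param config An [enrichment_config()].
#' @return A `RegionSet`: [GenomicRanges::GRanges] with metadata columns
#'   `score`, `n_bins`, `source_condition`; attributes `excluded` (GRanges
#'   with a `reason` column) and `log` (named counts by fate).
#' @export
merge_and_filter <- function(bins, config = enrichment_config()) {
  if (length(bins) == 0L) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      score = numeric(0), n_bins = integer(0),
      source_condition = character(0))
    attr(out, "excluded") <- out
    attr(out, "log") <- c(merged = 0L, excluded_length = 0L,
                          excluded_extreme = 0L, retained = 0L)
    return(out)
  }
  if (is.null(bins$score)) stop("bins need a 'score' metadata column",
                                call. = FALSE)
  bins <- sort(GenomicRanges::granges(bins, use.mcols = TRUE),
               ignore.strand = TRUE)
  merged <- GenomicRanges::reduce(bins, ignore.strand = TRUE,
                                  min.gapwidth = config$merge_distance + 1L)
  hits <- GenomicRanges::findOverlaps(bins, merged, ignore.strand = TRUE)
  grp <- S4Vectors::subjectHits(hits)
  score <- as.numeric(tapply(bins$score[S4Vectors::queryHits(hits)],
                             grp, mean))
  n_bins <- as.integer(tapply(grp, grp, length))
  src <- if (!is.null(bins$source_condition)) {
    vapply(split(bins$source_condition[S4Vectors::queryHits(hits)], grp),
           function(s) if (length(unique(s)) == 1L) s[[1]] else "either",
           character(1))
  } else rep("either", length(merged))
  S4Vectors::mcols(merged) <- S4Vectors::DataFrame(
    score = score, n_bins = n_bins, source_condition = unname(src))
  too_long <- GenomicRanges::width(merged) > config$max_region_length
  kept <- merged[!too_long]
  # floor: a set smaller than 1/fraction loses nothing (removing "the top
  # 0.01%" of a handful of regions would empty the set)
  n_extreme <- as.integer(floor(length(kept) * config$extreme_top_fraction))
  extreme_idx <- if (n_extreme > 0L)
    order(kept$score, decreasing = TRUE)[seq_len(n_extreme)]
  else integer(0)
  excluded <- c(merged[too_long], kept[extreme_idx])
  if (length(excluded) > 0L)
    excluded$reason <- c(rep("length_gt_max", sum(too_long)),
                         rep("extreme_top_fraction", n_extreme))
  out <- if (length(extreme_idx) > 0L) kept[-extreme_idx] else kept
  attr(out, "excluded") <- excluded
  attr(out, "log") <- c(merged = length(merged),
                        excluded_length = sum(too_long),
                        excluded_extreme = n_extreme,
                        retained = length(out))
  out
}

#' Mean track signal over regions, length-weighted
#'
#' The factor/mark score of a region: the mean of the overlapping bin values,
#' weighted by the number of bp each bin contributes to the region span.
#'
#' @param regions A [GenomicRanges::GRanges].
#' @param track A `CoverageTrack` on the genome the regions live on.
#' @return Numeric vector of per-region scores (0 for regions with no
#'   overlapping bins).
#' @export
region_scores <- function(regions, track) {
  stopifnot(inherits(track, "CoverageTrack"))
  scores <- numeric(length(regions))
  if (length(regions) == 0L) return(scores)
  hits <- GenomicRanges::findOverlaps(regions, track$grid$bins,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(scores)
  q <- S4Vectors::queryHits(hits)
  ov <- GenomicRanges::pintersect(regions[q],
                                  track$grid$bins[S4Vectors::subjectHits(hits)],
                                  ignore.strand = TRUE)
  w <- GenomicRanges::width(ov)
  v <- track$values[S4Vectors::subjectHits(hits)]
  num <- tapply(w * v, q, sum)
  den <- tapply(w, q, sum)
  scores[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  scores
}

#' Stratify regions by factor occupancy
#'
#' Scores each region under a factor track ([region_scores()]) and labels it
#' `enriched` if the score strictly exceeds the nearest-rank
#' `factor_enriched_percentile` of the region-score distribution, `depleted`
#' if strictly below the `factor_depleted_percentile`, else `neither`.
#' Thresholds are computed within the region set.
#'
#' @param regions A `RegionSet` (>= 4 regions).
#' @param factor_track `CoverageTrack` of factor occupancy.
#' @param config An [enrichment_config()]; set
#'   `factor_enriched_percentile = 90` for variant-histone tracks.
#' @return Factor vector of labels (`enriched`/`depleted`/`neither`) aligned
#'   to `regions`, with attributes `scores`, `threshold_enriched`,
#'   `threshold_depleted`.
#' @export
classify_by_factor <- function(regions, factor_track,
                               config = enrichment_config()) {
  if (length(regions) < 4L)
    stop("need at least 4 regions for percentile classification",
         call. = FALSE)
  s <- region_scores(regions, factor_track)
  thr_e <- percentile_nearest_rank(s, config$factor_enriched_percentile)
  thr_d <- percentile_nearest_rank(s, config$factor_depleted_percentile)
  lab <- ifelse(s > thr_e, "enriched", ifelse(s < thr_d, "depleted",
                                              "neither"))
  lab <- factor(lab, levels = c("enriched", "depleted", "neither"))
  attr(lab, "scores") <- s
  attr(lab, "threshold_enriched") <- thr_e
  attr(lab, "threshold_depleted") <- thr_d
  lab
}

#' Count exclusive enrichment overlaps between factor classifications
#'
#' Venn-style counts over one region set classified against several factors.
#' A region counts for a factor combination S when it is enriched for every
#' factor in S, enriched for no factor outside S, and depleted for no factor
#' in S (depletion is an exclusion criterion).
#'
#' @param classifications Named list of label vectors from
#'   [classify_by_factor()], all over the same region set.
#' @return Named integer vector of exclusive counts, one per non-empty factor
#'   combination (names joined with `&`).
#' @export
overlap_classes <- function(classifications) {
  k <- length(classifications)
  if (k == 0L) return(setNames(integer(0), character(0)))
  if (is.null(names(classifications)) || any(!nzchar(names(classifications))))
    stop("classifications must be a named list", call. = FALSE)
  n <- unique(vapply(classifications, length, integer(1)))
  if (length(n) != 1L)
    stop("classifications cover different region sets", call. = FALSE)
  E <- vapply(classifications, function(x) as.character(x) == "enriched",
              logical(n))
  D <- vapply(classifications, function(x) as.character(x) == "depleted",
              logical(n))
  if (n == 1L) { E <- matrix(E, nrow = 1); D <- matrix(D, nrow = 1) }
  nms <- names(classifications)
  combos <- unlist(lapply(seq_len(k), function(m)
    utils::combn(seq_len(k), m, simplify = FALSE)), recursive = FALSE)
  counts <- vapply(combos, function(S) {
    inS <- E[, S, drop = FALSE]
    outS <- E[, setdiff(seq_len(k), S), drop = FALSE]
    depS <- D[, S, drop = FALSE]
    sum(rowSums(inS) == length(S) & rowSums(outS) == 0L &
          rowSums(depS) == 0L)
  }, integer(1))
  setNames(counts, vapply(combos, function(S)
    paste(nms[S], collapse = "&"), character(1)))
}

#' Scaled-region profile matrix
#'
#' One row per region: `flank/bin` upstream columns at native resolution, the
#' region body linearly re-gridded onto `ceiling(body_length/bin)` columns,
#' then `flank/bin` downstream columns. Regions overlapping any blacklist
#' interval are removed before computation. Flank positions beyond chromosome
#' ends contribute 0. Used for cumulative profile plots (column means are
#' attached as an attribute).
#'
#' @param regions A [GenomicRanges::GRanges].
#' @param track A `CoverageTrack`.
#' @param body_length Target body length in bp (default 500).
#' @param flank Flank length in bp on each side (default 1000).
#' @param blacklist Optional [GenomicRanges::GRanges] of excluded intervals.
#' @param matrix_bin_width Column resolution in bp (default: the track's grid
#'   bin width).
#' @return Numeric matrix with attributes `colmeans`, `n_blacklisted`, and
#'   `col_type` (`"upstream"`, `"body"`, `"downstream"` per column).
#' @export
scaled_region_matrix <- function(regions, track, body_length = 500,
                                 flank = 1000, blacklist = NULL,
                                 matrix_bin_width = NULL) {
  stopifnot(inherits(track, "CoverageTrack"))
  grid <- track$grid
  w <- matrix_bin_width %||% grid$bin_width
  n_bl <- 0L
  if (!is.null(blacklist) && length(blacklist) > 0L) {
    bl <- IRanges::overlapsAny(regions, blacklist, ignore.strand = TRUE)
    n_bl <- sum(bl)
    regions <- regions[!bl]
  }
  if (length(regions) == 0L)
    stop("no regions left after blacklist exclusion", call. = FALSE)
  n_body <- max(1L, as.integer(ceiling(body_length / w)))
  n_flank <- as.integer(ceiling(flank / w))
  value_at <- function(chrom, pos0) {
    idx <- bin_index(grid, chrom, pos0)
    ifelse(is.na(idx), 0, track$values[idx])
  }
  chrom <- as.character(GenomicRanges::seqnames(regions))
  start0 <- GenomicRanges::start(regions) - 1L
  end0 <- GenomicRanges::end(regions)
  rows <- lapply(seq_along(regions), function(i) {
    up <- if (n_flank > 0L)
      value_at(rep(chrom[i], n_flank),
               start0[i] - flank + (seq_len(n_flank) - 0.5) * w)
    else numeric(0)
    dn <- if (n_flank > 0L)
      value_at(rep(chrom[i], n_flank),
               end0[i] + (seq_len(n_flank) - 0.5) * w)
    else numeric(0)
    # body: member-bin values at their centers, re-gridded to n_body columns
    hits <- GenomicRanges::findOverlaps(
      regions[i], grid$bins, ignore.strand = TRUE)
    bidx <- S4Vectors::subjectHits(hits)
    vals <- track$values[bidx]
    if (length(bidx) == 0L) {
      body <- rep(0, n_body)
    } else if (length(bidx) == 1L) {
      body <- rep(vals, n_body)
    } else {
      centers <- (GenomicRanges::start(grid$bins)[bidx] - 1L +
                    GenomicRanges::end(grid$bins)[bidx]) / 2
      rel <- (centers - start0[i]) / (end0[i] - start0[i])
      targets <- (seq_len(n_body) - 0.5) / n_body
      body <- approx(rel, vals, xout = targets, rule = 2)$y
    }
    c(up, body, dn)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c(if (n_flank > 0L) paste0("up", seq_len(n_flank)),
                   paste0("body", seq_len(n_body)),
                   if (n_flank > 0L) paste0("down", seq_len(n_flank)))
  attr(m, "colmeans") <- colMeans(m)
  attr(m, "n_blacklisted") <- n_bl
  attr(m, "col_type") <- c(rep("upstream", n_flank), rep("body", n_body),
                           rep("downstream", n_flank))
  m
}

#' Write a region set as BED with a full-precision sidecar TSV
#'
#' BED name field carries the source condition; the BED score is the region
#' score scaled by 1000 and capped at 1000 (BED convention). A sidecar TSV
#' (`<path>.scores.tsv`) keeps full-precision scores.
#'
#' @param regions A `RegionSet` from [merge_and_filter()].
#' @param path Output BED path.
#' @param run_id Optional provenance string written as a `#` header line.
#' @export
write_regions_bed <- function(regions, path, run_id = NULL) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions),
    name = regions$source_condition %||% rep(".", length(regions)),
    score = pmin(1000L, as.integer(round(regions$score * 1000))),
    strand = ".")
  con <- file(path, "w")
  if (!is.null(run_id)) writeLines(paste0("# oncomark run ", run_id), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)
  side <- data.frame(df[1:3], score = regions$score,
                     n_bins = regions$n_bins %||% NA_integer_,
                     source_condition = df$name)
  con <- file(paste0(path, ".scores.tsv"), "w")
  if (!is.null(run_id)) writeLines(paste0("# oncomark run ", run_id), con)
  write.table(side, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
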