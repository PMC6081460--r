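# Cross-cohort harmonization and fold-change classification of regions
# against a knockout reference cohort (the "genocopy" comparison).

#' Fold-change classification configuration
#'
#' @param gain_threshold Ratio above which a region is `gained` (default 1.5).
#' @param unchanged_interval Closed interval of ratios deemed `unchanged`
#'   (default `c(0.8, 1)`).
#' @param cross_cohort_percentile Percentile a region's query-cohort score
#'   must exceed (in either condition) to be retained when harmonizing
#'   cohorts: 90 for H3K9me3, 75 for H3K36me3 (default 90).
#' @return A `FoldChangeConfig` list.
#' @export
fold_change_config <- function(gain_threshold = 1.5,
                               unchanged_interval = c(0.8, 1),
                               cross_cohort_percentile = 90) {
  stopifnot(length(unchanged_interval) == 2L,
            unchanged_interval[1] <= unchanged_interval[2],
            cross_cohort_percentile > 0, cross_cohort_percentile < 100)
  if (gain_threshold <= unchanged_interval[2])
    stop("gain_threshold must exceed the unchanged interval", call. = FALSE)
  structure(list(gain_threshold = gain_threshold,
                 unchanged_interval = unchanged_interval,
                 cross_cohort_percentile = cross_cohort_percentile),
            class = "FoldChangeConfig")
}

#' Harmonize a reference-cohort region set against the query cohort
#'
#' Keeps only reference regions that are also mark-enriched in the query
#' cohort: the region's query score must strictly exceed the nearest-rank
#' `cross_cohort_percentile` (computed over the region set, per condition) in
#' at least one query condition.
#'
#' @param regions Reference-cohort `RegionSet`.
#' @param query_wt_track,query_mut_track Query-cohort `CoverageTrack`s.
#' @param config A [fold_change_config()].
#' @return The retained subset of `regions`, with attributes `kept` (logical
#'   over the input), `threshold_wt`, `threshold_mut`, and per-region query
#'   scores in metadata columns `query_wt` / `query_mut`.
#' @export
harmonize_cohorts <- function(regions, query_wt_track, query_mut_track,
                              config = fold_change_config()) {
  if (length(regions) == 0L) {
    warning("empty region set; nothing to harmonize", call. = FALSE)
    return(regions)
  }
  s_wt <- region_scores(regions, query_wt_track)
  s_mut <- region_scores(regions, query_mut_track)
  thr_wt <- percentile_nearest_rank(s_wt, config$cross_cohort_percentile)
  thr_mut <- percentile_nearest_rank(s_mut, config$cross_cohort_percentile)
  keep <- s_wt > thr_wt | s_mut > thr_mut
  out <- regions[keep]
  out$query_wt <- s_wt[keep]
  out$query_mut <- s_mut[keep]
  attr(out, "kept") <- keep
  attr(out, "threshold_wt") <- thr_wt
  attr(out, "threshold_mut") <- thr_mut
  out
}

#' Classify per-region fold changes against the reference cohort
#'
#' `ratio = ko / wt`; a region is `gained` when the ratio exceeds
#' `gain_threshold`, `unchanged` when the ratio lies in the closed
#' `unchanged_interval`, and `other` otherwise. Zero denominators are
#' flagged: `wt = 0, ko > 0` is `gained` with an `infinite_ratio` flag;
#' `wt = ko = 0` is `other` with a `zero` flag.
#'
#' @param wt,ko Non-negative per-region scores in the reference cohort
#'   (e.g. WT-KDM4 and KDM4-tKO), equal length.
#' @param config A [fold_change_config()].
#' @return Data frame with columns `wt`, `ko`, `ratio`, `label` (factor
#'   `gained`/`unchanged`/`other`) and `flag` (`""`, `"infinite_ratio"` or
#'   `"zero"`).
#' @export
classify_fold_change <- function(wt, ko, config = fold_change_config()) {
  stopifnot(length(wt) == length(ko), all(wt >= 0), all(ko >= 0))
  ratio <- ko / wt # Inf when wt=0,ko>0; NaN when both 0
  label <- rep("other", length(wt))
  flag <- rep("", length(wt))
  pos <- wt > 0
  label[pos & ratio > config$gain_threshold] <- "gained"
  label[pos & ratio >= config$unchanged_interval[1] &
          ratio <= config$unchanged_interval[2]] <- "unchanged"
  inf <- wt == 0 & ko > 0
  label[inf] <- "gained"
  flag[inf] <- "infinite_ratio"
  zz <- wt == 0 & ko == 0
  label[zz] <- "other"
  flag[zz] <- "zero"
  data.frame(wt = wt, ko = ko, ratio = ratio,
             label = factor(label, levels = c("gained", "unchanged",
                                              "other")),
             flag = flag)
}

#' Query-cohort log2-ratio distributions per reference label
#'
#' For each reference-cohort label class (`gained`, `unchanged`), the
#' distribution of `log2(query_mut / query_wt)` over the regions in that
#' class, with a [quantile_summary()] — the mutant-genocopies-knockout
#' readout. Regions with a non-positive query score in either condition are
#' dropped from the log ratio and reported.
#'
#' @param labels Labels from [classify_fold_change()] (its `label` column or
#'   the full data frame).
#' @param query_wt,query_mut Per-region query-cohort scores aligned to
#'   `labels`.
#' @param classes Label classes to report (default gained and unchanged).
#' @return Named list per class: `log2_ratio` (vector), `summary`
#'   ([quantile_summary()]), `n`, `n_dropped_nonpositive`. Empty classes are
#'   omitted with a warning.
#' @export
mirror_comparison <- function(labels, query_wt, query_mut,
                              classes = c("gained", "unchanged")) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- as.character(labels)
  stopifnot(length(labels) == length(query_wt),
            length(labels) == length(query_mut))
  out <- list()
  for (cl in classes) {
    in_cl <- labels == cl
    if (!any(in_cl)) {
      warning("label class '", cl, "' is empty; omitted", call. = FALSE)
      next
    }
    ok <- in_cl & query_wt > 0 & query_mut > 0
    lr <- log2(query_mut[ok] / query_wt[ok])
    if (length(lr) == 0L) {
      warning("label class '", cl,
              "' has no regions with positive query scores; omitted",
              call. = FALSE)
      next
    }
    out[[cl]] <- list(log2_ratio = lr, summary = quantile_summary(lr),
                      n = length(lr),
                      n_dropped_nonpositive = sum(in_cl) - length(lr))
  }
  out
}
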