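# Shared in-code fixtures: tiny grids, tracks and annotations built fresh at
# test time. No data files.

toy_grid <- function(n_bins = 10L, bin_width = 200L, chrom = "chrA") {
  sizes <- setNames(n_bins * bin_width, chrom)
  bin_genome(sizes, bin_width)
}

toy_track <- function(values, grid = toy_grid(length(values)),
                      state = "per_million", id = "toy") {
  coverage_track(grid, values, sample_id = id, normalization_state = state)
}

# GRanges of reads from 0-based (chrom, start, end, strand) triples
toy_reads <- function(chrom, start0, end0, strand = "+") {
  if (length(start0) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1L, end = end0),
                         strand = strand)
}

gene_spanning <- function(grid, chrom = NULL, from0 = 0L, to0 = NULL) {
  chrom <- chrom %||% names(grid$chrom_sizes)[1]
  to0 <- to0 %||% grid$chrom_sizes[[chrom]]
  GenomicRanges::GRanges(chrom, IRanges::IRanges(from0 + 1L, to0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force reference implementations (independent oracles) -------------

# per-read loop: 5' start binning with explicit dedup and skip accounting
oracle_count <- function(reads, grid, drop_duplicates = TRUE) {
  values <- numeric(grid$n_bins)
  seen <- character(0)
  kept <- 0L
  for (i in seq_along(reads)) {
    r <- reads[i]
    key <- paste(as.character(GenomicRanges::seqnames(r)),
                 GenomicRanges::start(r), GenomicRanges::end(r),
                 as.character(GenomicRanges::strand(r)))
    if (drop_duplicates && key %in% seen) next
    seen <- c(seen, key)
    chrom <- as.character(GenomicRanges::seqnames(r))
    if (!chrom %in% names(grid$chrom_sizes)) next
    pos0 <- if (as.character(GenomicRanges::strand(r)) == "-")
      GenomicRanges::end(r) - 1L else GenomicRanges::start(r) - 1L
    pos0 <- max(0L, min(pos0, grid$chrom_sizes[[chrom]] - 1L))
    bins <- grid$bins
    for (b in seq_along(bins)) {
      if (as.character(GenomicRanges::seqnames(bins))[b] == chrom &&
          pos0 >= GenomicRanges::start(bins)[b] - 1L &&
          pos0 < GenomicRanges::end(bins)[b]) {
        values[b] <- values[b] + 1
        break
      }
    }
    kept <- kept + 1L
  }
  list(values = values, total = kept)
}

# O(n^2) merge: repeatedly fuse any two intervals with gap <= d, then score
oracle_merge <- function(df, d, max_len, top_frac) {
  # df: chrom, start0, end0, score (one row per bin)
  items <- split(df, seq_len(nrow(df)))
  repeat {
    fused <- FALSE
    for (i in seq_along(items)) {
      for (j in seq_along(items)) {
        if (i >= j) next
        a <- items[[i]]; b <- items[[j]]
        if (a$chrom[1] != b$chrom[1]) next
        gap <- max(min(a$start0), min(b$start0)) -
          min(max(a$end0), max(b$end0))
        if (gap <= d) {
          items[[i]] <- rbind(a, b)
          items[[j]] <- NULL
          fused <- TRUE
          break
        }
      }
      if (fused) break
    }
    if (!fused) break
  }
  regs <- do.call(rbind, lapply(items, function(x)
    data.frame(chrom = x$chrom[1], start0 = min(x$start0),
               end0 = max(x$end0), score = mean(x$score))))
  regs <- regs[order(regs$chrom, regs$start0), , drop = FALSE]
  regs <- regs[regs$end0 - regs$start0 <= max_len, , drop = FALSE]
  n_x <- floor(nrow(regs) * top_frac)
  if (n_x > 0) regs <- regs[-order(regs$score,
                                   decreasing = TRUE)[seq_len(n_x)], ,
                            drop = FALSE]
  rownames(regs) <- NULL
  regs
}

# nearest-rank percentile by direct sorted-vector indexing
oracle_percentile <- function(x, p) {
  xs <- sort(x)
  xs[ceiling(p / 100 * length(xs))]
}

oracle_fold_label <- function(wt, ko, gain = 1.5, lo = 0.8, hi = 1.0) {
  mapply(function(w, k) {
    if (w == 0 && k == 0) return("other")
    if (w == 0) return("gained")
    r <- k / w
    if (r > gain) "gained" else if (r >= lo && r <= hi) "unchanged"
    else "other"
  }, wt, ko)
}
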