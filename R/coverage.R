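# Fixed-width genome binning, deduplicated read counting, and track
# normalization (per-million scaling and rank-based distribution matching).

#' Tile a genome into fixed-width bins
#'
#' Builds the fixed grid over which all ChIP-seq quantitation happens. Bins are
#' half-open intervals `[k*w, (k+1)*w)` in 0-based coordinates; the last bin of
#' each chromosome is truncated at the chromosome end, and bins never cross
#' chromosome boundaries.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp), a
#'   two-column data frame (name, length), or the path of a two-column TSV.
#' @param bin_width Bin width in bp (default 200).
#' @return A `GenomeGrid` object: list with `chrom_sizes`, `bin_width`,
#'   `bins` (a [GenomicRanges::GRanges] of all bins, in chromosome order) and
#'   `n_bins`.
#' @examples
#' grid <- bin_genome(c(chr1 = 1000, chr2 = 450), bin_width = 200)
#' grid$n_bins  # 5 + 3
#' @export
bin_genome <- function(chrom_sizes, bin_width = 200L) {
  chrom_sizes <- read_chrom_sizes(chrom_sizes)
  if (length(chrom_sizes) == 0L)
    stop("chrom_sizes is empty", call. = FALSE)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a single positive number", call. = FALSE)
  if (any(chrom_sizes <= 0))
    stop("all chromosome lengths must be > 0", call. = FALSE)
  bin_width <- as.integer(bin_width)
  per_chrom <- as.integer(ceiling(chrom_sizes / bin_width))
  starts0 <- unlist(lapply(per_chrom, function(n) (seq_len(n) - 1L) * bin_width),
                    use.names = FALSE)
  ends0 <- pmin(starts0 + bin_width,
                rep(as.numeric(chrom_sizes), per_chrom))
  bins <- GenomicRanges::GRanges(
    seqnames = rep(names(chrom_sizes), per_chrom),
    ranges = IRanges::IRanges(start = starts0 + 1L, end = ends0),
    seqlengths = setNames(as.integer(chrom_sizes), names(chrom_sizes)))
  structure(list(chrom_sizes = setNames(as.integer(chrom_sizes),
                                        names(chrom_sizes)),
                 bin_width = bin_width,
                 bins = bins,
                 n_bins = length(bins)),
            class = "GenomeGrid")
}

#' @export
print.GenomeGrid <- function(x, ...) {
  cat(sprintf("GenomeGrid: %d chromosome(s), bin width %d bp, %d bins\n",
              length(x$chrom_sizes), x$bin_width, x$n_bins))
  invisible(x)
}

#' Read a two-column chromosome-sizes table
#'
#' @param x Path to a TSV with columns (chromosome, length), a data frame, or
#'   an already-named numeric vector (returned as integer unchanged).
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- read.table(x, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("chrom sizes table needs two columns", call. = FALSE)
    x <- setNames(as.numeric(x[[2]]), as.character(x[[1]]))
  }
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop("chrom_sizes must be a named numeric vector, data frame or TSV path",
         call. = FALSE)
  setNames(as.integer(x), names(x))
}

same_grid <- function(a, b) {
  identical(a$bin_width, b$bin_width) &&
    identical(a$chrom_sizes, b$chrom_sizes)
}

# Map (chrom, 0-based position) to global bin index; NA off-grid.
bin_index <- function(grid, chrom, pos0) {
  per_chrom <- ceiling(grid$chrom_sizes / grid$bin_width)
  offset <- c(0L, cumsum(per_chrom))[-(length(per_chrom) + 1L)]
  names(offset) <- names(per_chrom)
  ci <- match(chrom, names(grid$chrom_sizes))
  ok <- !is.na(ci) & pos0 >= 0 & pos0 < grid$chrom_sizes[ci]
  idx <- rep(NA_integer_, length(chrom))
  idx[ok] <- offset[ci[ok]] + pos0[ok] %/% grid$bin_width + 1L
  idx
}

new_coverage_track <- function(grid, sample_id, values, total_reads,
                               normalization_state,
                               n_skipped = 0L, n_duplicates_removed = 0L) {
  stopifnot(length(values) == grid$n_bins, all(values >= 0), total_reads >= 0)
  structure(list(grid = grid, sample_id = sample_id, values = values,
                 total_reads = total_reads,
                 normalization_state = normalization_state,
                 n_skipped = n_skipped,
                 n_duplicates_removed = n_duplicates_removed),
            class = "CoverageTrack")
}

#' Construct a coverage track from raw values
#'
#' Mostly useful for tests and for importing externally quantitated tracks;
#' analysis tracks are normally produced by [count_reads()].
#'
#' @param grid A `GenomeGrid`.
#' @param values Numeric vector, one value per grid bin, non-negative.
#' @param sample_id Sample label.
#' @param total_reads Library size; defaults to `sum(values)`.
#' @param normalization_state One of `"raw"`, `"per_million"`, `"matched"`.
#' @return A `CoverageTrack`.
#' @export
coverage_track <- function(grid, values, sample_id = "sample",
                           total_reads = sum(values),
                           normalization_state = "raw") {
  normalization_state <- match.arg(normalization_state,
                                   c("raw", "per_million", "matched"))
  new_coverage_track(grid, sample_id, as.numeric(values),
                     total_reads, normalization_state)
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack '%s': %d bins, %s, total_reads=%s\n",
              x$sample_id, length(x$values), x$normalization_state,
              format(x$total_reads, big.mark = ",")))
  invisible(x)
}

#' Count reads per genome bin
#'
#' Each retained read increments exactly one bin: the bin containing its 5'
#' start (the leftmost base for `+`/unstranded reads, the rightmost base for
#' `-` reads). PCR duplicates — reads identical in (chromosome, start, end,
#' strand) — are collapsed when `drop_duplicates = TRUE`. Reads on
#' chromosomes absent from the grid are skipped with a warning, not an error.
#' An alternative overlap-fraction assignment (each read contributes
#' `overlap/width` to every bin it touches) is available via `assign`.
#'
#' @param reads A [GenomicRanges::GRanges] of aligned reads, or the path of a
#'   BED file (see [read_alignments()]).
#' @param grid A `GenomeGrid` from [bin_genome()].
#' @param drop_duplicates Collapse coordinate-identical reads first
#'   (default `TRUE`).
#' @param sample_id Sample label stored on the track.
#' @param assign `"fiveprime"` (default, one bin per read) or `"overlap"`
#'   (fractional assignment over all overlapped bins).
#' @return A `CoverageTrack` with `normalization_state = "raw"`,
#'   `total_reads` equal to the number of retained reads, and bookkeeping
#'   fields `n_skipped` and `n_duplicates_removed` so that
#'   `total_reads + n_skipped + n_duplicates_removed == length(reads)`.
#' @export
count_reads <- function(reads, grid, drop_duplicates = TRUE,
                        sample_id = "sample",
                        assign = c("fiveprime", "overlap")) {
  assign <- match.arg(assign)
  if (is.character(reads)) reads <- read_alignments(reads)
  if (!methods::is(reads, "GRanges"))
    stop("reads must be a GRanges or a file path", call. = FALSE)
  if (!inherits(grid, "GenomeGrid")) stop("grid must be a GenomeGrid",
                                          call. = FALSE)
  n_in <- length(reads)
  n_dup <- 0L
  if (drop_duplicates && n_in > 0L) {
    dup <- duplicated(paste(as.character(GenomicRanges::seqnames(reads)),
                            GenomicRanges::start(reads),
                            GenomicRanges::end(reads),
                            as.character(GenomicRanges::strand(reads))))
    n_dup <- sum(dup)
    reads <- reads[!dup]
  }
  chrom <- as.character(GenomicRanges::seqnames(reads))
  on_grid <- chrom %in% names(grid$chrom_sizes)
  n_skip <- sum(!on_grid)
  if (n_skip > 0L) {
    warning(sprintf("%d read(s) on chromosomes absent from the grid skipped",
                    n_skip), call. = FALSE)
    reads <- reads[on_grid]
    chrom <- chrom[on_grid]
  }
  values <- numeric(grid$n_bins)
  if (length(reads) > 0L) {
    if (assign == "fiveprime") {
      minus <- as.character(GenomicRanges::strand(reads)) == "-"
      pos0 <- ifelse(minus, GenomicRanges::end(reads) - 1L,
                     GenomicRanges::start(reads) - 1L)
      # clamp 5' positions that fall off the chromosome end
      pos0 <- pmax(0, pmin(pos0, grid$chrom_sizes[chrom] - 1L))
      idx <- bin_index(grid, chrom, pos0)
      tab <- tabulate(idx, nbins = grid$n_bins)
      values <- as.numeric(tab)
    } else {
      hits <- GenomicRanges::findOverlaps(reads, grid$bins)
      ov <- GenomicRanges::pintersect(
        reads[S4Vectors::queryHits(hits)],
        grid$bins[S4Vectors::subjectHits(hits)])
      frac <- GenomicRanges::width(ov) /
        GenomicRanges::width(reads)[S4Vectors::queryHits(hits)]
      agg <- tapply(frac, S4Vectors::subjectHits(hits), sum)
      values[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  new_coverage_track(grid, sample_id, values,
                     total_reads = length(reads),
                     normalization_state = "raw",
                     n_skipped = n_skip, n_duplicates_removed = n_dup)
}

#' Scale a raw track to reads per million
#'
#' Each bin value `v` becomes `v * 1e6 / total_reads`. Ratios between bins are
#' preserved exactly.
#'
#' @param track A raw `CoverageTrack` with `total_reads > 0`.
#' @return The per-million-normalized `CoverageTrack`.
#' @export
normalize_per_million <- function(track) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (track$normalization_state != "raw")
    stop("track is already normalized (state: ", track$normalization_state,
         ")", call. = FALSE)
  if (track$total_reads <= 0)
    stop("cannot per-million normalize a track with total_reads = 0",
         call. = FALSE)
  track$values <- track$values * 1e6 / track$total_reads
  track$normalization_state <- "per_million"
  track
}

# Quantile-match a value vector onto a reference sorted vector;
# tied values receive the mean reference value over their tied ranks.
match_to_reference <- function(v, ref) {
  rmin <- rank(v, ties.method = "min")
  rmax <- rank(v, ties.method = "max")
  cs <- c(0, cumsum(ref))
  (cs[rmax + 1L] - cs[rmin]) / (rmax - rmin + 1L)
}

#' Match the value distributions of two tracks
#'
#' Rank-based quantile matching of two per-million tracks onto their common
#' reference distribution, the element-wise mean of the two sorted value
#' vectors. Within-track rank order is preserved; tied values receive the mean
#' reference value over their tied ranks. For tie-free inputs the two output
#' tracks have identical value multisets (to numerical tolerance).
#'
#' @param track_a,track_b `CoverageTrack`s on the same grid with
#'   `normalization_state = "per_million"`.
#' @return List of the two matched tracks (`normalization_state = "matched"`),
#'   in input order.
#' @export
match_distributions <- function(track_a, track_b) {
  stopifnot(inherits(track_a, "CoverageTrack"),
            inherits(track_b, "CoverageTrack"))
  if (!same_grid(track_a$grid, track_b$grid))
    stop("tracks are on different grids", call. = FALSE)
  if (track_a$normalization_state != "per_million" ||
      track_b$normalization_state != "per_million")
    stop("match_distributions requires per-million-normalized tracks",
         call. = FALSE)
  ref <- (sort(track_a$values) + sort(track_b$values)) / 2
  track_a$values <- match_to_reference(track_a$values, ref)
  track_b$values <- match_to_reference(track_b$values, ref)
  track_a$normalization_state <- "matched"
  track_b$normalization_state <- "matched"
  list(track_a, track_b)
}

#' Read aligned-read intervals
#'
#' BED (via rtracklayer) is the first-class format; BAM files are read through
#' Rsamtools when available, and SAM input is converted with
#' [Rsamtools::asBam()] first.
#'
#' @param path File path (`.bed`, `.bam` or `.sam`).
#' @return A [GenomicRanges::GRanges] of read intervals with strand.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") return(rtracklayer::import(path, format = "BED"))
  if (ext %in% c("bam", "sam")) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("Rsamtools is required for SAM/BAM input", call. = FALSE)
    if (ext == "sam")
      path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
    b <- Rsamtools::scanBam(
      path, param = Rsamtools::ScanBamParam(
        what = c("rname", "pos", "qwidth", "strand")))[[1]]
    keep <- !is.na(b$pos)
    return(GenomicRanges::GRanges(
      seqnames = as.character(b$rname)[keep],
      ranges = IRanges::IRanges(start = b$pos[keep],
                                width = b$qwidth[keep]),
      strand = b$strand[keep]))
  }
  stop("unsupported alignment format: .", ext, call. = FALSE)
}

#' Write a coverage track as bedGraph
#'
#' @param track A `CoverageTrack`.
#' @param path Output path.
#' @param run_id Optional provenance string written as a `#` header line.
#' @export
write_bedgraph <- function(track, path, run_id = NULL) {
  b <- track$grid$bins
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(b)),
                   start = GenomicRanges::start(b) - 1L,
                   end = GenomicRanges::end(b),
                   value = track$values)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(run_id)) writeLines(paste0("# oncomark run ", run_id), con)
  writeLines(sprintf("track type=bedGraph name=\"%s\"", track$sample_id), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a multi-sample bin matrix as TSV
#'
#' @param tracks Named list of `CoverageTrack`s on one grid.
#' @param path Output path.
#' @param run_id Optional provenance string written as a `#` header line.
#' @export
write_bin_matrix <- function(tracks, path, run_id = NULL) {
  stopifnot(length(tracks) >= 1L)
  g <- tracks[[1]]$grid
  for (t in tracks) if (!same_grid(t$grid, g))
    stop("all tracks must share one grid", call. = FALSE)
  b <- g$bins
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(b)),
                   start = GenomicRanges::start(b) - 1L,
                   end = GenomicRanges::end(b))
  for (nm in names(tracks)) df[[nm]] <- tracks[[nm]]$values
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(run_id)) writeLines(paste0("# oncomark run ", run_id), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
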