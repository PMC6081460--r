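# Seeded generators for every input the pipeline consumes, with planted
# ground truth serialized alongside. All randomness comes from one private
# seeded stream per call; identical (config, seed) gives identical output.

#' ChIP-seq simulation configuration
#'
#' The stated world of the ChIP generator: a 2 x 2 Mb toy genome quantitated
#' in 200 bp bins, ~45\% genic, with 200 planted mark domains inside genes.
#' Domains occupy whole quantitation bins (1-2 bins, i.e. 200/400 bp, drawn
#' as `round(U(block_length_range)/bin_width)`); see the methods vignette for
#' why grid alignment is the default (`align_to_grid = FALSE` plants
#' arbitrary-phase blocks instead). Background bins draw negative-binomial
#' counts with mean `depth_per_bin` and dispersion `dispersion`; domain bins
#' are elevated `enrichment`-fold, and in the mutant the domains overlapping
#' factor-binding sites are further multiplied by `gain_factor`.
#'
#' @param chrom_sizes Named chromosome lengths (default 2 x 2 Mb).
#' @param bin_width Quantitation bin width, bp (default 200).
#' @param n_genes Number of genes (default 60, lengths
#'   `U(gene_length_range)`).
#' @param gene_length_range Gene length range, bp (default 10-50 kb).
#' @param n_blocks Planted mark domains (default 200).
#' @param block_length_range Domain length range, bp (default 100-500).
#' @param align_to_grid Plant domains in whole bins (default `TRUE`).
#' @param min_block_gap Minimum gap between planted domains, bp
#'   (default 2000).
#' @param enrichment Domain mean elevation over background (default 8).
#' @param gain_factor Mutant gain at factor-bound domains (default 2).
#' @param factor_overlap_fraction Fraction of domains that are factor-binding
#'   sites (default 0.5).
#' @param factor_enrichment Factor-track elevation at factor sites
#'   (default 8).
#' @param depth_per_bin Background mean reads per bin per condition
#'   (default 20).
#' @param dispersion Negative-binomial dispersion (default 0.2; 0 gives
#'   Poisson).
#' @param read_length Emitted read length, bp (default 50, single-end).
#' @param n_blacklist Number of 1 kb blacklist intervals (default 10).
#' @return A `SimChipConfig` list.
#' @export
sim_chipseq_config <- function(chrom_sizes = c(chrS1 = 2e6, chrS2 = 2e6),
                               bin_width = 200L,
                               n_genes = 60L,
                               gene_length_range = c(10000, 50000),
                               n_blocks = 200L,
                               block_length_range = c(100, 500),
                               align_to_grid = TRUE,
                               min_block_gap = 2000L,
                               enrichment = 8,
                               gain_factor = 2,
                               factor_overlap_fraction = 0.5,
                               factor_enrichment = 8,
                               depth_per_bin = 20,
                               dispersion = 0.2,
                               read_length = 50L,
                               n_blacklist = 10L) {
  stopifnot(all(chrom_sizes > 0), bin_width > 0, n_genes > 0, n_blocks >= 0,
            enrichment >= 1, gain_factor >= 1, depth_per_bin > 0,
            dispersion >= 0,
            factor_overlap_fraction >= 0, factor_overlap_fraction <= 1)
  if (n_genes * mean(gene_length_range) > 0.9 * sum(chrom_sizes))
    stop("infeasible config: genes exceed the genome", call. = FALSE)
  structure(as.list(environment()), class = "SimChipConfig")
}

# negative binomial with Poisson as the dispersion-0 limit
rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, mu = mu,
                                                 size = 1 / dispersion)
}

# place n non-overlapping intervals of the given lengths on [1, size]
scatter_intervals <- function(size, lengths) {
  free <- size - sum(lengths)
  if (free < 0) stop("infeasible config: intervals exceed the chromosome",
                     call. = FALSE)
  gaps <- diff(c(0, sort(runif(length(lengths), 0, free)), free))
  starts <- cumsum(gaps[seq_along(lengths)]) +
    c(0, cumsum(lengths))[seq_along(lengths)] + 1
  IRanges::IRanges(start = round(starts), width = lengths)
}

# emit reads consistent with per-bin counts
reads_from_counts <- function(counts, grid, read_length) {
  bins <- grid$bins
  tot <- sum(counts)
  if (tot == 0L)
    return(GenomicRanges::GRanges(seqlengths = grid$chrom_sizes))
  idx <- rep(seq_along(counts), counts)
  w <- GenomicRanges::width(bins)[idx]
  # the sampled position is the read's 5' end, so that 5'-start counting
  # reproduces the per-bin intensities the counts were drawn from
  pos <- GenomicRanges::start(bins)[idx] + floor(runif(tot) * w)
  chrom <- as.character(GenomicRanges::seqnames(bins))[idx]
  strand <- sample(c("+", "-"), tot, replace = TRUE)
  start <- ifelse(strand == "+", pos, pmax(1, pos - read_length + 1L))
  end <- ifelse(strand == "+",
                pmin(pos + read_length - 1L, grid$chrom_sizes[chrom]), pos)
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = start, end = end),
                         strand = strand,
                         seqlengths = grid$chrom_sizes)
}

#' Simulate a two-condition ChIP-seq experiment with planted truth
#'
#' Generates WT and mutant mark reads, a factor-occupancy read set, gene
#' annotation and a blacklist, all consistent with a planted set of enriched
#' domains: every domain is elevated `enrichment`-fold in both conditions,
#' and domains flagged as factor sites additionally gain `gain_factor`-fold
#' in the mutant (the factor-dependent gain the downstream comparison is
#' meant to detect).
#'
#' @param config A [sim_chipseq_config()].
#' @param seed Integer seed (mandatory; same seed, same output).
#' @param layout Optional `layout` element from a previous call: reuse the
#'   same genes/domains/factor sites and redraw only counts — this is how a
#'   second (reference) cohort sharing the genomic truth is generated.
#' @return List with `reads_wt`, `reads_mut`, `reads_factor`
#'   ([GenomicRanges::GRanges]), `genes`, `blacklist`, `grid`, `truth`
#'   (planted domains with `factor_site` flag, factor sites, config, seed)
#'   and `layout` (for cohort reuse).
#' @export
simulate_chipseq <- function(config = sim_chipseq_config(), seed,
                             layout = NULL) {
  stopifnot(inherits(config, "SimChipConfig"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  with_seed(seed, {
    grid <- bin_genome(config$chrom_sizes, config$bin_width)
    if (is.null(layout)) {
      # genes: scattered non-overlapping, split evenly across chromosomes
      n_chr <- length(config$chrom_sizes)
      per_chr <- diff(round(seq(0, config$n_genes, length.out = n_chr + 1)))
      genes <- do.call(c, lapply(seq_len(n_chr), function(ci) {
        n <- per_chr[ci]
        lens <- round(runif(n, config$gene_length_range[1],
                            config$gene_length_range[2]))
        GenomicRanges::GRanges(
          seqnames = names(config$chrom_sizes)[ci],
          ranges = scatter_intervals(config$chrom_sizes[ci], lens),
          strand = sample(c("+", "-"), n, replace = TRUE),
          seqlengths = grid$chrom_sizes)
      }))
      genes$gene_id <- sprintf("gene%03d", seq_along(genes))
      # planted domains inside genes, whole bins by default, min gap apart
      w <- config$bin_width
      n_bins_blk <- pmax(1L, as.integer(round(
        runif(config$n_blocks, config$block_length_range[1],
              config$block_length_range[2]) / w)))
      blocks <- GenomicRanges::GRanges(seqlengths = grid$chrom_sizes)
      tries <- 0L
      while (length(blocks) < config$n_blocks && tries < 50L * config$n_blocks) {
        tries <- tries + 1L
        i <- length(blocks) + 1L
        g <- genes[sample.int(length(genes), 1L)]
        if (config$align_to_grid) {
          len <- n_bins_blk[i] * w
          lo_bin <- ceiling((GenomicRanges::start(g) - 1) / w)
          hi_bin <- floor((GenomicRanges::end(g) - len) / w)
          if (hi_bin < lo_bin) next
          b0 <- sample(lo_bin:hi_bin, 1L) * w
          cand <- GenomicRanges::GRanges(
            GenomicRanges::seqnames(g),
            IRanges::IRanges(start = b0 + 1L, width = len),
            seqlengths = grid$chrom_sizes)
        } else {
          len <- round(runif(1, config$block_length_range[1],
                             config$block_length_range[2]))
          if (GenomicRanges::width(g) <= len) next
          s <- GenomicRanges::start(g) +
            sample.int(GenomicRanges::width(g) - len, 1L) - 1L
          cand <- GenomicRanges::GRanges(
            GenomicRanges::seqnames(g),
            IRanges::IRanges(start = s, width = len),
            seqlengths = grid$chrom_sizes)
        }
        if (length(blocks) > 0L &&
            any(IRanges::overlapsAny(
              cand + config$min_block_gap, blocks, ignore.strand = TRUE)))
          next
        blocks <- c(blocks, cand)
      }
      if (length(blocks) < config$n_blocks)
        stop("infeasible config: could not place all planted domains",
             call. = FALSE)
      blocks$block_id <- sprintf("block%03d", seq_along(blocks))
      blocks$factor_site <- as.logical(
        rbinom(length(blocks), 1L, config$factor_overlap_fraction))
      factor_sites <- blocks[blocks$factor_site]
      blacklist <- do.call(c, lapply(seq_len(n_chr), function(ci) {
        n <- diff(round(seq(0, config$n_blacklist,
                            length.out = n_chr + 1)))[ci]
        GenomicRanges::GRanges(
          seqnames = names(config$chrom_sizes)[ci],
          ranges = IRanges::IRanges(
            start = sort(sample.int(config$chrom_sizes[ci] - 1000L, n)),
            width = 1000L),
          seqlengths = grid$chrom_sizes)
      }))
      layout <- list(genes = genes, blocks = blocks,
                     factor_sites = factor_sites, blacklist = blacklist)
    }
    genes <- layout$genes
    blocks <- layout$blocks
    factor_sites <- layout$factor_sites
    # per-bin overlap fractions with domains / factor-bound domains
    frac_of <- function(feat) {
      f <- numeric(grid$n_bins)
      if (length(feat) == 0L) return(f)
      hits <- GenomicRanges::findOverlaps(grid$bins, feat,
                                          ignore.strand = TRUE)
      ov <- GenomicRanges::pintersect(
        grid$bins[S4Vectors::queryHits(hits)],
        feat[S4Vectors::subjectHits(hits)], ignore.strand = TRUE)
      agg <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
      f[as.integer(names(agg))] <- pmin(1, as.numeric(agg) /
                                          GenomicRanges::width(grid$bins)[
                                            as.integer(names(agg))])
      f
    }
    fb <- frac_of(blocks)
    ff <- frac_of(factor_sites)
    mu_wt <- config$depth_per_bin * (1 + (config$enrichment - 1) * fb)
    mu_mut <- mu_wt * config$gain_factor^ff
    mu_fac <- config$depth_per_bin *
      (1 + (config$factor_enrichment - 1) * ff)
    reads_wt <- reads_from_counts(
      rcounts(grid$n_bins, mu_wt, config$dispersion), grid,
      config$read_length)
    reads_mut <- reads_from_counts(
      rcounts(grid$n_bins, mu_mut, config$dispersion), grid,
      config$read_length)
    reads_factor <- reads_from_counts(
      rcounts(grid$n_bins, mu_fac, config$dispersion), grid,
      config$read_length)
    list(reads_wt = reads_wt, reads_mut = reads_mut,
         reads_factor = reads_factor,
         genes = genes, blacklist = layout$blacklist, grid = grid,
         truth = list(blocks = blocks, factor_sites = factor_sites,
                      genes = genes, config = config, seed = seed),
         layout = layout)
  })
}

#' RNA-seq + allele simulation configuration
#'
#' Gene expression follows a lognormal across genes; per-gene read counts are
#' Poisson around `expression * depth_factor`, reads are placed uniformly in
#' union exons with reverse-stranded orientation. A designated gene set is
#' multiplied by `set_effect` in the mutant. The allele component builds
#' three positionally aligned coding sequences — a mutant transgene differing
#' from wild-type gene A only at codon 34, and gene B differing from A at
#' synonymous third-codon positions flanking codon 34 (plus distant
#' synonymous sites) — and draws reads from them at the configured mixture.
#'
#' @param n_genes Number of genes (default 300).
#' @param chrom_sizes Transcriptome toy genome (default 2 x 1.5 Mb).
#' @param exons_per_gene Range of exon counts (default 1-3).
#' @param exon_length_range,intron_length_range Exon/intron lengths, bp.
#' @param expr_meanlog,expr_sdlog Lognormal expression parameters
#'   (default meanlog log(30), sdlog 1).
#' @param depth_factor Expected reads per expression unit (default 10).
#' @param n_set_genes Gene-set size (default 30; a small fraction of all
#'   genes, so set effects do not distort per-million totals).
#' @param set_effect Mutant fold effect on set genes (default 0.5).
#' @param cds_length Allele CDS length, nt (default 408; codon 34 at
#'   nt 100-102).
#' @param n_allele_reads Allele-library reads drawn (default 300).
#' @param allele_proportions Mixture over (transgene, gene A WT, gene B WT);
#'   must sum to 1.
#' @param per_base_error Per-base substitution error rate (default 0).
#' @param n_duplicates Exact duplicate reads appended (default 20). The
#'   truth records the realized duplicate-sequence count, which also covers
#'   rare chance collisions when `n_allele_reads` exceeds the number of
#'   distinct placements.
#' @param read_length Read length, nt (default 50).
#' @return A `SimRnaConfig` list.
#' @export
sim_rnaseq_config <- function(n_genes = 300L,
                              chrom_sizes = c(chrT1 = 1.5e6, chrT2 = 1.5e6),
                              exons_per_gene = c(1L, 3L),
                              exon_length_range = c(200, 1000),
                              intron_length_range = c(200, 2000),
                              expr_meanlog = log(30), expr_sdlog = 1,
                              depth_factor = 10,
                              n_set_genes = 30L, set_effect = 0.5,
                              cds_length = 408L,
                              n_allele_reads = 300L,
                              allele_proportions = c(G34R = 0.2,
                                                     geneA_WT = 0.4,
                                                     geneB_WT = 0.4),
                              per_base_error = 0,
                              n_duplicates = 20L,
                              read_length = 50L) {
  stopifnot(n_genes > 0, n_set_genes < n_genes, set_effect > 0,
            per_base_error >= 0, per_base_error < 1,
            length(allele_proportions) == 3L)
  if (abs(sum(allele_proportions) - 1) > 1e-9)
    stop("allele_proportions must sum to 1", call. = FALSE)
  structure(as.list(environment()), class = "SimRnaConfig")
}

# Per-base substitution with fixed RNG consumption (2 uniforms per base),
# so that under one seed the error set at a higher rate is a superset of the
# error set at a lower rate: accuracy degradation is exactly monotone in the
# rate (common-random-numbers coupling).
mutate_bases <- function(chars, rate) {
  u <- runif(length(chars))
  v <- runif(length(chars))
  if (rate <= 0) return(chars)
  hit <- which(u < rate)
  bases <- c("A", "C", "G", "T")
  for (i in hit)
    chars[i] <- setdiff(bases, chars[i])[ceiling(v[i] * 3)]
  chars
}

#' Simulate stranded RNA-seq with a three-allele histone locus
#'
#' @param config A [sim_rnaseq_config()].
#' @param seed Integer seed (mandatory).
#' @return List with `alignments` (named list of WT / G34R
#'   [GenomicRanges::GRanges]), `gene_models` (a `GeneModels`), `gene_set`
#'   (down-regulated gene ids), `allele_library` (an `AlleleLibrary`),
#'   `allele_reads` (character vector of read sequences), and `truth`
#'   (per-gene expression and set membership, per-read allele and
#'   informativeness, planted duplicate count).
#' @export
simulate_rnaseq_alleles <- function(config = sim_rnaseq_config(), seed) {
  stopifnot(inherits(config, "SimRnaConfig"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  with_seed(seed, {
    n_chr <- length(config$chrom_sizes)
    per_chr <- diff(round(seq(0, config$n_genes, length.out = n_chr + 1)))
    exon_list <- list()
    gid <- 0L
    for (ci in seq_len(n_chr)) {
      n <- per_chr[ci]
      nex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2],
                    n, replace = TRUE)
      spans <- numeric(n)
      exonsets <- vector("list", n)
      for (i in seq_len(n)) {
        el <- round(runif(nex[i], config$exon_length_range[1],
                          config$exon_length_range[2]))
        il <- if (nex[i] > 1L)
          round(runif(nex[i] - 1L, config$intron_length_range[1],
                      config$intron_length_range[2]))
        else numeric(0)
        starts <- cumsum(c(1, head(el, -1) + il))
        exonsets[[i]] <- IRanges::IRanges(start = starts, width = el)
        spans[i] <- max(starts + el - 1)
      }
      offs <- scatter_intervals(config$chrom_sizes[ci], spans)
      for (i in seq_len(n)) {
        gid <- gid + 1L
        str <- sample(c("+", "-"), 1L)
        exon_list[[sprintf("tgene%03d", gid)]] <- GenomicRanges::GRanges(
          seqnames = names(config$chrom_sizes)[ci],
          ranges = IRanges::shift(exonsets[[i]],
                                  GenomicRanges::start(offs)[i] - 1L),
          strand = str,
          seqlengths = setNames(as.integer(config$chrom_sizes),
                                names(config$chrom_sizes)))
      }
    }
    gm <- gene_models(methods::as(exon_list, "GRangesList"))
    ids <- names(gm$exons)
    expr <- rlnorm(length(ids), config$expr_meanlog, config$expr_sdlog)
    names(expr) <- ids
    gene_set <- sample(ids, config$n_set_genes)
    # reads per sample, uniform over union exons, reverse-stranded
    draw_sample <- function(effect_on_set) {
      lam <- expr * config$depth_factor
      lam[gene_set] <- lam[gene_set] * effect_on_set
      counts <- rpois(length(ids), lam)
      names(counts) <- ids
      grs <- lapply(ids[counts > 0], function(g) {
        ex <- gm$exons[[g]]
        tot <- sum(GenomicRanges::width(ex))
        off <- sample.int(tot, counts[g], replace = TRUE) - 1L
        cum <- c(0, cumsum(GenomicRanges::width(ex)))
        ei <- findInterval(off, cum, rightmost.closed = FALSE) # 1-based exon
        pos <- GenomicRanges::start(ex)[ei] + (off - cum[ei])
        gstrand <- as.character(GenomicRanges::strand(gm$genes[g]))
        rstrand <- if (gstrand == "+") "-" else "+"
        # 5' start of a reverse-protocol read sits at the sampled position
        st <- if (rstrand == "+") pos else pos - config$read_length + 1L
        GenomicRanges::GRanges(
          seqnames = as.character(GenomicRanges::seqnames(ex))[1],
          ranges = IRanges::IRanges(start = pmax(1L, st),
                                    width = config$read_length),
          strand = rstrand,
          seqlengths = setNames(as.integer(config$chrom_sizes),
                                names(config$chrom_sizes)))
      })
      if (length(grs) > 0L) do.call(c, grs)
      else GenomicRanges::GRanges(
        seqlengths = setNames(as.integer(config$chrom_sizes),
                              names(config$chrom_sizes)))
    }
    reads_wt <- draw_sample(1)
    reads_mut <- draw_sample(config$set_effect)
    # allele library: aligned CDS trio differing near codon 34
    L <- config$cds_length
    c34 <- 100L
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    base[c34:(c34 + 2L)] <- c("G", "G", "A")            # Gly34 (GGA)
    base[c(99L, 108L, 30L, 300L)] <- c("T", "C", "A", "G")
    tg <- base; tg[c34] <- "A"                          # G34R (AGA)
    gb <- base; gb[99L] <- "C"; gb[108L] <- "T"         # synonymous, near
    gb[30L] <- "T"; gb[300L] <- "A"                     # synonymous, distant
    lib <- allele_library(
      setNames(c(paste(tg, collapse = ""), paste(base, collapse = ""),
                 paste(gb, collapse = "")),
               names(config$allele_proportions)),
      codon34_start = c34)
    seq_chars <- list(tg, base, gb)
    # distinct (start, orientation) pairs where possible, so that planted
    # duplicates dominate; the truth records the realized duplicate count
    rl <- config$read_length
    n_start <- L - rl + 1L
    pool <- sample.int(2L * n_start, config$n_allele_reads,
                       replace = config$n_allele_reads > 2L * n_start)
    starts <- (pool - 1L) %% n_start + 1L
    revd <- pool > n_start
    allele <- sample(names(config$allele_proportions),
                     config$n_allele_reads, replace = TRUE,
                     prob = config$allele_proportions)
    dp <- lib$diagnostic_positions
    make_read <- function(i) {
      k <- match(allele[i], names(config$allele_proportions))
      chars <- mutate_bases(seq_chars[[k]][starts[i]:(starts[i] + rl - 1L)],
                            config$per_base_error)
      s <- paste(chars, collapse = "")
      if (revd[i])
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      s
    }
    reads <- vapply(seq_len(config$n_allele_reads), make_read, character(1))
    informative <- starts <= min(dp) & starts + rl - 1L >= max(dp) &
      starts <= c34 & starts + rl - 1L >= c34 + 2L
    dup_pool <- which(informative)
    if (length(dup_pool) == 0L) dup_pool <- seq_along(reads)
    dup_of <- sample(dup_pool, config$n_duplicates, replace = TRUE)
    all_reads <- c(reads, reads[dup_of])
    truth_reads <- data.frame(
      read = all_reads,
      allele = c(allele, allele[dup_of]),
      start = c(starts, starts[dup_of]),
      informative = c(informative, informative[dup_of]),
      is_planted_duplicate = c(rep(FALSE, length(reads)),
                               rep(TRUE, length(dup_of))),
      stringsAsFactors = FALSE)
    list(alignments = list(WT = reads_wt, G34R = reads_mut),
         gene_models = gm, gene_set = gene_set,
         allele_library = lib, allele_reads = all_reads,
         truth = list(expression = expr, gene_set = gene_set,
                      set_effect = config$set_effect,
                      reads = truth_reads,
                      n_planted_duplicates = sum(duplicated(all_reads)),
                      allele_proportions = config$allele_proportions,
                      config = config, seed = seed))
  })
}

#' MALDI spectrum simulation configuration
#'
#' Gaussian peaks at the me0..me3 ladder masses of a synthetic stand-in
#' peptide (the real peptide sequences are not public, so the base mass is a
#' configurable stand-in), plus a flat baseline and Gaussian noise over the
#' instrument window.
#'
#' @param base_mz me0 mass of the synthetic peptide stand-in (default
#'   2000 Da).
#' @param abundances Relative state abundances, me0..me3, summing to 1.
#' @param peak_sd Gaussian peak width, Da (default 0.1).
#' @param amplitude Total peak apex scale (default 1000).
#' @param baseline Flat baseline intensity (default 5).
#' @param noise_sd Additive noise sd (default 2).
#' @param mz_range Acquisition window, Da (default 1200-3500).
#' @param mz_step Grid step, Da (default 0.05).
#' @return A `SimSpectrumConfig` list.
#' @export
sim_spectrum_config <- function(base_mz = 2000,
                                abundances = c(me0 = 0.1, me1 = 0.2,
                                               me2 = 0.3, me3 = 0.4),
                                peak_sd = 0.1, amplitude = 1000,
                                baseline = 5, noise_sd = 2,
                                mz_range = c(1200, 3500), mz_step = 0.05) {
  stopifnot(base_mz > 0, all(abundances >= 0), peak_sd > 0, amplitude > 0,
            noise_sd >= 0, mz_range[1] < mz_range[2], mz_step > 0)
  if (abs(sum(abundances) - 1) > 1e-9)
    stop("abundances must sum to 1", call. = FALSE)
  structure(as.list(environment()), class = "SimSpectrumConfig")
}

#' Simulate a MALDI spectrum of a methylation-state mixture
#'
#' @param config A [sim_spectrum_config()].
#' @param seed Integer seed (mandatory).
#' @return List with `spectrum` (a `Spectrum`), `series` (the
#'   [methyl_mass_series()] used) and `truth` (the planted abundances and
#'   config).
#' @export
simulate_spectrum <- function(config = sim_spectrum_config(), seed) {
  stopifnot(inherits(config, "SimSpectrumConfig"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  with_seed(seed, {
    series <- methyl_mass_series(config$base_mz,
                                 n_states = length(config$abundances))
    mz <- seq(config$mz_range[1], config$mz_range[2], by = config$mz_step)
    intensity <- rep(config$baseline, length(mz)) +
      pmax(0, rnorm(length(mz), 0, config$noise_sd))
    for (i in seq_along(series$states))
      intensity <- intensity + config$amplitude * config$abundances[i] *
        exp(-(mz - series$states[i])^2 / (2 * config$peak_sd^2))
    list(spectrum = spectrum(mz, intensity), series = series,
         truth = list(abundances = config$abundances, config = config,
                      seed = seed))
  })
}

#' Simulate per-region cohort scores with a planted gain fraction
#'
#' Region-score level cohort generator for fold-change recovery checks: a
#' fraction `gain_fraction` of regions carries a true fold change of `fold`
#' between the reference conditions, the rest 1.0; both measurements carry
#' multiplicative lognormal noise of log-sd `sigma`.
#'
#' @param n_regions Number of regions (default 1000).
#' @param gain_fraction Fraction with the true gain (default 0.3).
#' @param fold True fold change of gained regions (default 2).
#' @param sigma Lognormal noise log-sd per measurement (default 0.1).
#' @param seed Integer seed (mandatory).
#' @return Data frame `wt`, `ko`, `true_gained`.
#' @export
simulate_score_cohort <- function(n_regions = 1000L, gain_fraction = 0.3,
                                  fold = 2, sigma = 0.1, seed) {
  stopifnot(gain_fraction >= 0, gain_fraction <= 1, fold > 0, sigma >= 0)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  with_seed(seed, {
    base <- rlnorm(n_regions, log(10), 0.5)
    gained <- seq_len(n_regions) <= round(gain_fraction * n_regions)
    gained <- sample(gained)
    wt <- base * rlnorm(n_regions, 0, sigma)
    ko <- base * ifelse(gained, fold, 1) * rlnorm(n_regions, 0, sigma)
    data.frame(wt = wt, ko = ko, true_gained = gained)
  })
}
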