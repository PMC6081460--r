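# RPKM quantitation over merged-isoform gene models, gene-set log2-ratio
# comparisons with random-gene controls, and allele-informative read
# classification at histone H3 codon 34.

#' Build gene models with merged isoforms
#'
#' Normalizes gene annotation into the form RPKM quantitation needs: one
#' strand-aware exon set per gene with isoforms merged (overlapping exons
#' reduced), plus the union exon length used for transcript-length
#' correction.
#'
#' @param x One of: a named [GenomicRanges::GRangesList] of exons per gene; a
#'   [GenomicRanges::GRanges] of gene bodies (single-exon models) with a
#'   `gene_id` metadata column or names; a GTF/GFF path (exon features,
#'   grouped by `gene_id`); or a BED12 path (blocks are exons, name is the
#'   gene id).
#' @return A `GeneModels` object: list with `genes` (gene-span GRanges),
#'   `exons` (reduced GRangesList, same order) and `union_exon_length`
#'   (named integer).
#' @export
gene_models <- function(x) {
  if (inherits(x, "GeneModels")) return(x)
  if (is.character(x) && length(x) == 1L) {
    ext <- tolower(tools::file_ext(x))
    if (ext %in% c("gtf", "gff", "gff3")) {
      g <- rtracklayer::import(x)
      g <- g[tolower(as.character(g$type)) == "exon"]
      if (length(g) == 0L) stop("no exon features in ", x, call. = FALSE)
      x <- GenomicRanges::split(g, S4Vectors::mcols(g)$gene_id)
    } else if (ext == "bed") {
      g <- rtracklayer::import(x, format = "BED")
      if (!is.null(g$blocks)) {
        ex <- rtracklayer::blocks(g)
        names(ex) <- g$name
        x <- ex
      } else {
        names(g) <- g$name
        x <- g
      }
    } else stop("unsupported gene-model format: .", ext, call. = FALSE)
  }
  if (methods::is(x, "GRanges")) {
    ids <- if (!is.null(x$gene_id)) x$gene_id else names(x)
    if (is.null(ids)) stop("gene GRanges needs names or a gene_id column",
                           call. = FALSE)
    x <- GenomicRanges::split(GenomicRanges::granges(x), ids)
  }
  if (!methods::is(x, "GRangesList"))
    stop("cannot interpret gene models input", call. = FALSE)
  if (is.null(names(x))) stop("gene models must be named by gene id",
                              call. = FALSE)
  exons <- GenomicRanges::reduce(x) # merge transcript isoforms
  len <- sum(GenomicRanges::width(exons))
  if (any(len <= 0)) stop("gene(s) with zero union exon length",
                          call. = FALSE)
  genes <- unlist(range(exons, ignore.strand = FALSE))
  structure(list(genes = genes, exons = exons,
                 union_exon_length = setNames(as.integer(len), names(exons))),
            class = "GeneModels")
}

#' @export
print.GeneModels <- function(x, ...) {
  cat(sprintf("GeneModels: %d gene(s), median union exon length %d bp\n",
              length(x$genes), as.integer(median(x$union_exon_length))))
  invisible(x)
}

#' Reads per kilobase of transcript per million assigned reads
#'
#' `rpkm = count * 1e9 / (union_exon_length * total_assigned)`. Invariant
#' under joint scaling of counts and totals.
#'
#' @param count Assigned read count(s).
#' @param union_exon_length Merged-isoform exon length(s), bp.
#' @param total_assigned Total assigned reads in the sample.
#' @return RPKM value(s).
#' @export
rpkm <- function(count, union_exon_length, total_assigned) {
  stopifnot(all(union_exon_length > 0), all(total_assigned > 0))
  count * 1e9 / (union_exon_length * total_assigned)
}

#' Quantify gene expression as RPKM
#'
#' A read is assigned to a gene when its 5' start lies in a union exon of
#' that gene and its strand is compatible with the library protocol
#' (`reverse`, the dUTP convention, is the default: read strand opposite the
#' gene strand). Reads assignable to more than one gene are left unassigned
#' and tallied. RPKM = `count * 1e9 / (union_exon_length *
#' total_assigned_reads)` per sample; genes with zero counts in every sample
#' are excluded from the table.
#'
#' @param alignments Named list of [GenomicRanges::GRanges] (one per sample),
#'   or a single GRanges (treated as one sample).
#' @param genes Anything accepted by [gene_models()].
#' @param strandedness `"reverse"` (default), `"forward"` or `"unstranded"`.
#' @return An `ExpressionTable`: data frame with `gene_id`,
#'   `union_exon_length`, and per-sample `count_*` / `rpkm_*` columns;
#'   attributes `total_assigned`, `n_multi_gene`, `n_unassigned`.
#' @export
quantify_rpkm <- function(alignments, genes,
                          strandedness = c("reverse", "forward",
                                           "unstranded")) {
  strandedness <- match.arg(strandedness)
  gm <- gene_models(genes)
  if (methods::is(alignments, "GRanges")) alignments <- list(sample = alignments)
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    stop("alignments must be a named list of GRanges", call. = FALSE)
  ex <- unlist(gm$exons)
  ex_gene <- rep(names(gm$exons), lengths(gm$exons))
  ex_strand <- as.character(GenomicRanges::strand(ex))
  counts <- matrix(0L, nrow = length(gm$exons), ncol = length(alignments),
                   dimnames = list(names(gm$exons), names(alignments)))
  totals <- setNames(integer(length(alignments)), names(alignments))
  n_multi <- setNames(integer(length(alignments)), names(alignments))
  for (s in names(alignments)) {
    reads <- alignments[[s]]
    rs <- as.character(GenomicRanges::strand(reads))
    minus <- rs == "-"
    p5 <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(reads),
      ranges = IRanges::IRanges(
        start = ifelse(minus, GenomicRanges::end(reads),
                       GenomicRanges::start(reads)),
        width = 1L))
    hits <- GenomicRanges::findOverlaps(p5, ex, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits)
    gs <- ex_strand[S4Vectors::subjectHits(hits)]
    compatible <- switch(strandedness,
      reverse = (rs[q] == "+" & gs == "-") | (rs[q] == "-" & gs == "+"),
      forward = rs[q] == gs,
      unstranded = rep(TRUE, length(q)))
    hit_gene <- ex_gene[S4Vectors::subjectHits(hits)][compatible]
    q <- q[compatible]
    # a read hitting exons of >1 gene is unassigned
    per_read <- split(hit_gene, q)
    genes_per_read <- vapply(per_read, function(g) length(unique(g)),
                             integer(1))
    uni <- genes_per_read == 1L
    n_multi[s] <- sum(!uni)
    assigned <- vapply(per_read[uni], `[[`, character(1), 1L)
    tab <- table(assigned)
    counts[names(tab), s] <- as.integer(tab)
    totals[s] <- length(assigned)
  }
  keep <- rowSums(counts) > 0L # exclude probes with no counts
  counts <- counts[keep, , drop = FALSE]
  out <- data.frame(gene_id = rownames(counts),
                    union_exon_length =
                      unname(gm$union_exon_length[rownames(counts)]),
                    stringsAsFactors = FALSE)
  for (s in names(alignments)) {
    out[[paste0("count_", s)]] <- counts[, s]
    out[[paste0("rpkm_", s)]] <- rpkm(counts[, s], out$union_exon_length,
                                      totals[s])
  }
  rownames(out) <- NULL
  class(out) <- c("ExpressionTable", "data.frame")
  attr(out, "total_assigned") <- totals
  attr(out, "n_multi_gene") <- n_multi
  out
}

#' Gene-set log2 expression ratios with a random-gene control
#'
#' Computes `log2(mut / wt)` RPKM per resolvable gene of `gene_set`, sorted
#' ascending, together with a size-matched uniform random control drawn
#' without replacement from genes outside the set. Genes with zero RPKM in
#' either sample of the pair are excluded from the ratios (no pseudocount)
#' and reported separately.
#'
#' @param table An `ExpressionTable` from [quantify_rpkm()].
#' @param gene_set Character vector of gene ids.
#' @param sample_pair Length-2 character vector `c(wt, mut)` naming the two
#'   samples.
#' @param random_control_size Control size (default: the number of resolvable
#'   set genes).
#' @param seed Mandatory RNG seed for the control draw.
#' @return List with `set` (data frame `gene_id`, `log2_ratio`, ascending),
#'   `control` (same structure), `missing_ids`, `zero_excluded` (per
#'   component).
#' @export
gene_set_log_ratio <- function(table, gene_set, sample_pair,
                               random_control_size = NULL, seed) {
  stopifnot(inherits(table, "data.frame"), length(sample_pair) == 2L)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  rp <- paste0("rpkm_", sample_pair)
  if (!all(rp %in% names(table)))
    stop("samples not found in table: ",
         paste(sample_pair[!rp %in% names(table)], collapse = ", "),
         call. = FALSE)
  missing_ids <- setdiff(gene_set, table$gene_id)
  set_ids <- intersect(gene_set, table$gene_id)
  if (length(set_ids) == 0L)
    stop("no gene_set ids found in the expression table; missing: ",
         paste(head(missing_ids, 10), collapse = ", "), call. = FALSE)
  if (length(missing_ids) > 0L)
    warning(length(missing_ids), " gene-set id(s) absent from the table",
            call. = FALSE)
  ratios <- function(ids) {
    wt <- table[[rp[1]]][match(ids, table$gene_id)]
    mut <- table[[rp[2]]][match(ids, table$gene_id)]
    ok <- wt > 0 & mut > 0
    df <- data.frame(gene_id = ids[ok],
                     log2_ratio = log2(mut[ok] / wt[ok]))
    df <- df[order(df$log2_ratio), , drop = FALSE] # sorted ascending
    rownames(df) <- NULL
    attr(df, "zero_excluded") <- ids[!ok]
    df
  }
  set_df <- ratios(set_ids)
  pool <- setdiff(table$gene_id, gene_set)
  n_ctrl <- random_control_size %||% length(set_ids)
  if (n_ctrl > length(pool))
    stop("random_control_size exceeds the number of non-set genes",
         call. = FALSE)
  ctrl_ids <- with_seed(seed, sample(pool, n_ctrl))
  ctrl_df <- ratios(ctrl_ids)
  list(set = set_df, control = ctrl_df, missing_ids = missing_ids,
       zero_excluded = list(set = attr(set_df, "zero_excluded"),
                            control = attr(ctrl_df, "zero_excluded")))
}

#' Build an allele library for codon-34 read classification
#'
#' The three coding sequences (mutant transgene and the two wild-type genes)
#' are near-identical and positionally aligned; the diagnostic positions are
#' the nucleotide positions where they are not all identical, restricted to
#' the read-spanning window around codon 34.
#'
#' @param sequences Named character vector or
#'   [Biostrings::DNAStringSet] of the three coding sequences (equal length).
#' @param codon34_start 1-based position of the first base of codon 34.
#' @param window Length-2 integer window (library coordinates) within which
#'   diagnostic positions are taken; default `codon34_start + c(-45, 47)`,
#'   the span reachable by a 50 bp read that still covers the codon.
#' @return An `AlleleLibrary`: list with `sequences` (DNAStringSet),
#'   `codon34_start`, `window`, `diagnostic_positions`.
#' @export
allele_library <- function(sequences, codon34_start, window = NULL) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  if (length(sequences) != 3L)
    stop("an allele library has exactly three sequences", call. = FALSE)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("library sequences must be named", call. = FALSE)
  L <- unique(Biostrings::width(sequences))
  if (length(L) != 1L)
    stop("library sequences must be positionally aligned (equal length)",
         call. = FALSE)
  if (codon34_start < 1L || codon34_start + 2L > L)
    stop("codon 34 not contained in the sequences", call. = FALSE)
  window <- as.integer(window %||% pmax(1L, pmin(L, codon34_start + c(-45L, 47L))))
  stopifnot(length(window) == 2L, window[1] <= window[2])
  m <- do.call(rbind, strsplit(as.character(sequences), ""))
  diffs <- which(apply(m, 2, function(col) length(unique(col)) > 1L))
  diag_pos <- diffs[diffs >= window[1] & diffs <= window[2]]
  if (length(diag_pos) == 0L)
    stop("sequences are identical within the codon-34 window", call. = FALSE)
  sig <- apply(m[, diag_pos, drop = FALSE], 1, paste, collapse = "")
  if (anyDuplicated(sig))
    stop("library sequences are not pairwise distinct at the diagnostic ",
         "positions", call. = FALSE)
  structure(list(sequences = sequences, codon34_start = as.integer(codon34_start),
                 window = window, diagnostic_positions = as.integer(diag_pos)),
            class = "AlleleLibrary")
}

# Best ungapped placement of one read against one library sequence:
# returns c(offset, n_mismatch) minimizing Hamming mismatches.
best_placement <- function(read, subject) {
  n_off <- length(subject) - length(read) + 1L
  if (n_off < 1L) return(c(NA_integer_, NA_integer_))
  ed <- Biostrings::neditStartingAt(read, subject, starting.at = seq_len(n_off),
                                    with.indels = FALSE)
  off <- which.min(ed)
  c(off, ed[off])
}

#' Classify allele-informative reads spanning codon 34
#'
#' Exact-sequence duplicates are collapsed first. Each unique read is placed
#' ungapped (best placement, both orientations) against each library
#' sequence; a read is informative only if its placement covers codon 34 and
#' all diagnostic positions. An informative read is assigned to the unique
#' library sequence it matches at every diagnostic position with at most
#' `max_mismatch` mismatches elsewhere; reads matching none or more than one
#' sequence are uninformative (ambiguous reads are tallied).
#'
#' @param reads Character vector or [Biostrings::DNAStringSet] of read
#'   sequences.
#' @param library An [allele_library()].
#' @param max_mismatch Mismatches tolerated outside diagnostic positions
#'   (default 2).
#' @param check_revcomp Also try the reverse complement (default `TRUE`).
#' @return An `AlleleCallSummary`: list with `counts` (named per library
#'   sequence plus `uninformative`), `n_duplicates_removed`, `n_ambiguous`,
#'   and `assignments` (per unique read).
#' @export
classify_codon_reads <- function(reads, library, max_mismatch = 2L,
                                 check_revcomp = TRUE) {
  stopifnot(inherits(library, "AlleleLibrary"))
  reads <- as.character(reads)
  n_in <- length(reads)
  uniq <- unique(reads)
  n_dup <- n_in - length(uniq)
  nms <- names(library$sequences)
  counts <- setNames(integer(length(nms) + 1L), c(nms, "uninformative"))
  n_amb <- 0L
  lib_chars <- strsplit(as.character(library$sequences), "")
  dp <- library$diagnostic_positions
  c34 <- library$codon34_start
  assign_one <- function(rd) {
    cand <- Biostrings::DNAStringSet(rd)
    if (check_revcomp)
      cand <- c(cand, Biostrings::reverseComplement(cand))
    best <- NULL # list(orient, per-seq placements)
    for (o in seq_along(cand)) {
      pl <- lapply(seq_along(nms), function(k)
        best_placement(cand[[o]], library$sequences[[k]]))
      tot <- min(vapply(pl, `[`, numeric(1), 2), na.rm = TRUE)
      if (is.null(best) || tot < best$tot)
        best <- list(o = o, pl = pl, tot = tot)
    }
    rl <- nchar(rd)
    rchars <- strsplit(as.character(cand[[best$o]]), "")[[1]]
    qualifying <- character(0)
    for (k in seq_along(nms)) {
      off <- best$pl[[k]][1]
      mis <- best$pl[[k]][2]
      if (is.na(off)) next
      lo <- off; hi <- off + rl - 1L
      covers <- lo <= min(dp) && hi >= max(dp) && lo <= c34 && hi >= c34 + 2L
      if (!covers) next
      diag_ok <- all(rchars[dp - lo + 1L] == lib_chars[[k]][dp])
      if (!diag_ok) next
      n_diag_mismatch <- sum(rchars[dp - lo + 1L] != lib_chars[[k]][dp])
      if (mis - n_diag_mismatch > max_mismatch) next
      qualifying <- c(qualifying, nms[k])
    }
    if (length(qualifying) == 1L) qualifying else
      if (length(qualifying) > 1L) "ambiguous" else "uninformative"
  }
  assignments <- vapply(uniq, assign_one, character(1), USE.NAMES = FALSE)
  n_amb <- sum(assignments == "ambiguous")
  assignments[assignments == "ambiguous"] <- "uninformative"
  tab <- table(factor(assignments, levels = names(counts)))
  counts[] <- as.integer(tab)
  structure(list(counts = counts,
                 n_duplicates_removed = n_dup,
                 n_ambiguous = n_amb,
                 assignments = data.frame(read = uniq, class = assignments,
                                          stringsAsFactors = FALSE)),
            class = "AlleleCallSummary")
}

#' @export
print.AlleleCallSummary <- function(x, ...) {
  cat("AlleleCallSummary\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-16s %d\n", nm, x$counts[[nm]]))
  cat(sprintf("  duplicates removed: %d; ambiguous: %d\n",
              x$n_duplicates_removed, x$n_ambiguous))
  invisible(x)
}
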