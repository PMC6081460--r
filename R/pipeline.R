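# End-to-end orchestration: simulate -> bin -> normalize -> call -> classify
# -> cohort comparison -> expression/alleles -> spectrum, with a
# machine-readable run report and provenance headers on every output.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    coverage = list(bin_width = 200L, dedup = TRUE),
    regions = list(select_percentile = 95, merge_distance = 100,
                   max_region_length = 500, extreme_top_fraction = 1e-4,
                   factor_enriched_percentile = 75,
                   factor_depleted_percentile = 25),
    differential = list(gain_threshold = 1.5, unchanged_interval = c(0.8, 1),
                        cross_cohort_percentile = 90),
    rnaseq = list(strandedness = "reverse"),
    methylspec = list(tolerance_ppm = 200),
    simulate = list(chipseq = list(), rnaseq = list(), spectrum = list())
  )
}

#' Load and validate a pipeline configuration
#'
#' YAML file (or list) with sections `coverage`, `regions`, `differential`,
#' `rnaseq`, `methylspec`, `simulate` mirroring the module configuration
#' objects; every threshold of the analysis is a named, defaulted key.
#' Unknown keys are a validation error naming the key.
#'
#' @param x Path to a YAML file, a list of overrides, or `NULL` for
#'   defaults.
#' @return The merged, validated configuration list.
#' @export
pipeline_config <- function(x = NULL) {
  base <- default_pipeline_config()
  if (is.null(x)) return(base)
  if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    x <- yaml::read_yaml(x)
  }
  check <- function(user, ref, path = "") {
    bad <- setdiff(names(user), names(ref))
    if (length(bad) > 0L)
      stop("unknown config key(s): ",
           paste0(path, bad, collapse = ", "), call. = FALSE)
    for (nm in names(user))
      if (is.list(ref[[nm]]) && is.list(user[[nm]]) &&
          !is.null(names(ref[[nm]])))
        check(user[[nm]], ref[[nm]], paste0(path, nm, "."))
  }
  # simulate.* sections take generator arguments verbatim
  ref <- base
  ref$simulate <- NULL
  user <- x
  user$simulate <- NULL
  check(user, ref)
  for (sec in names(x)) {
    if (is.list(base[[sec]]) && is.list(x[[sec]]))
      base[[sec]] <- modifyList(base[[sec]], x[[sec]])
    else base[[sec]] <- x[[sec]]
  }
  base
}

write_tsv_with_header <- function(df, path, run_id) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# oncomark run ", run_id), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-data pipeline
#'
#' Executes every stage in dependency order on seeded synthetic inputs:
#' ChIP simulation, binning and counting, per-million and
#' match-distribution normalization, genic enrichment-region calling,
#' factor stratification, reference-cohort fold-change classification and
#' mirror comparison, RPKM quantitation, gene-set log ratios, allele read
#' classification, and spectrum readout. Failure in one branch does not
#' abort independent branches; the run fails (status != 0) iff any stage
#' failed. All outputs carry the run id; the run report is deterministic
#' for a fixed (config, seed).
#'
#' @param config A [pipeline_config()] (path, list of overrides, or `NULL`).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the `PipelineRun` report list (also written as
#'   `run_report.json`): config snapshot, package version, run id, input
#'   checksums, per-stage record counts, per-stage status, overall `status`.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_id <- substr(tools::md5sum(
    {f <- tempfile(); writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                                  digits = NA), f); f}),
    1, 12)
  report <- list(tool = "oncomark",
                 version = as.character(utils::packageVersion("oncomark")),
                 run_id = unname(run_id), config = cfg,
                 stages = list(), counts = list())
  status <- 0L
  stage <- function(name, expr) {
    res <- tryCatch(list(value = expr, error = NULL),
                    error = function(e) list(value = NULL,
                                             error = conditionMessage(e)))
    if (is.null(res$error)) {
      report$stages[[name]] <<- "ok"
    } else {
      report$stages[[name]] <<- paste("failed:", res$error)
      status <<- 1L
    }
    res$value
  }
  seed <- cfg$seed

  chip <- stage("chipseq", {
    sim <- do.call(sim_chipseq_config, cfg$simulate$chipseq)
    simulate_chipseq(sim, seed = seed)
  })
  regions <- NULL
  if (!is.null(chip)) {
    regions <- stage("regions", {
      grid <- chip$grid
      dedup <- isTRUE(cfg$coverage$dedup)
      t_wt <- count_reads(chip$reads_wt, grid, drop_duplicates = dedup,
                          sample_id = "WT")
      t_mut <- count_reads(chip$reads_mut, grid, drop_duplicates = dedup,
                           sample_id = "mutant")
      t_fac <- count_reads(chip$reads_factor, grid, drop_duplicates = dedup,
                           sample_id = "factor")
      m <- match_distributions(normalize_per_million(t_wt),
                               normalize_per_million(t_mut))
      t_fac <- normalize_per_million(t_fac)
      ec <- do.call(enrichment_config, cfg$regions)
      sel <- select_enriched_genic_bins(m[[1]], m[[2]], chip$genes, ec)
      regs <- merge_and_filter(sel, ec)
      report$counts$bins_counted <- grid$n_bins
      report$counts$bins_selected <- length(sel)
      lg <- attr(regs, "log")
      report$counts$regions_merged <- unname(lg[["merged"]])
      report$counts$regions_excluded_length <-
        unname(lg[["excluded_length"]])
      report$counts$regions_excluded_extreme <-
        unname(lg[["excluded_extreme"]])
      report$counts$regions_called <- unname(lg[["retained"]])
      write_bedgraph(m[[1]], file.path(out_dir, "wt.matched.bedgraph"),
                     run_id)
      write_bedgraph(m[[2]], file.path(out_dir, "mutant.matched.bedgraph"),
                     run_id)
      write_regions_bed(regs, file.path(out_dir, "regions.bed"), run_id)
      cls <- classify_by_factor(regs, t_fac, ec)
      write_tsv_with_header(
        data.frame(chrom = as.character(GenomicRanges::seqnames(regs)),
                   start = GenomicRanges::start(regs) - 1L,
                   end = GenomicRanges::end(regs),
                   factor_score = attr(cls, "scores"),
                   label = as.character(cls)),
        file.path(out_dir, "factor_classification.tsv"), run_id)
      prof <- scaled_region_matrix(regs, m[[2]], blacklist = chip$blacklist)
      write_tsv_with_header(as.data.frame(prof),
                            file.path(out_dir, "profile_matrix.tsv"),
                            run_id)
      list(regions = regs, tracks = list(wt = m[[1]], mut = m[[2]],
                                         factor = t_fac),
           classification = cls)
    })
  }
  if (!is.null(chip) && !is.null(regions)) {
    stage("differential", {
      # reference cohort: same genomic layout, independent counts, with the
      # factor-bound domains gained in the knockout-like condition
      ref <- simulate_chipseq(do.call(sim_chipseq_config,
                                      cfg$simulate$chipseq),
                              seed = seed + 1L, layout = chip$layout)
      dedup <- isTRUE(cfg$coverage$dedup)
      r_wt <- normalize_per_million(
        count_reads(ref$reads_wt, chip$grid, dedup, sample_id = "ref_wt"))
      r_ko <- normalize_per_million(
        count_reads(ref$reads_mut, chip$grid, dedup, sample_id = "ref_ko"))
      fc <- do.call(fold_change_config, cfg$differential)
      harm <- harmonize_cohorts(regions$regions, regions$tracks$wt,
                                regions$tracks$mut, fc)
      cls <- classify_fold_change(region_scores(harm, r_wt),
                                  region_scores(harm, r_ko), fc)
      mirror <- mirror_comparison(cls, harm$query_wt, harm$query_mut)
      report$counts$regions_harmonized <- length(harm)
      report$counts$regions_gained_ref <- sum(cls$label == "gained")
      df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(harm)),
        start = GenomicRanges::start(harm) - 1L,
        end = GenomicRanges::end(harm),
        wt_ref = cls$wt, ko_ref = cls$ko, ratio = cls$ratio,
        label = as.character(cls$label),
        query_wt = harm$query_wt, query_mut = harm$query_mut,
        query_log2 = ifelse(harm$query_wt > 0 & harm$query_mut > 0,
                            log2(harm$query_mut / harm$query_wt), NA))
      write_tsv_with_header(df, file.path(out_dir, "diffmark.tsv"), run_id)
      mirror
    })
  }
  stage("rnaseq", {
    sim <- do.call(sim_rnaseq_config, cfg$simulate$rnaseq)
    rna <- simulate_rnaseq_alleles(sim, seed = seed)
    tab <- quantify_rpkm(rna$alignments, rna$gene_models,
                         strandedness = cfg$rnaseq$strandedness)
    write_tsv_with_header(as.data.frame(tab),
                          file.path(out_dir, "expression.tsv"), run_id)
    gsr <- gene_set_log_ratio(tab, rna$gene_set, c("WT", "G34R"),
                              seed = seed)
    write_tsv_with_header(gsr$set, file.path(out_dir, "geneset_log2.tsv"),
                          run_id)
    write_tsv_with_header(gsr$control,
                          file.path(out_dir, "geneset_control_log2.tsv"),
                          run_id)
    alle <- classify_codon_reads(rna$allele_reads, rna$allele_library)
    jsonlite::write_json(
      list(run_id = unname(run_id),
           counts = as.list(alle$counts),
           n_duplicates_removed = alle$n_duplicates_removed,
           n_ambiguous = alle$n_ambiguous),
      file.path(out_dir, "allele_calls.json"), auto_unbox = TRUE)
    report$counts$genes_quantified <- nrow(tab)
    report$counts$allele_reads_classified <-
      sum(alle$counts) + alle$n_duplicates_removed
    NULL
  })
  stage("methylspec", {
    sim <- do.call(sim_spectrum_config, cfg$simulate$spectrum)
    sp <- simulate_spectrum(sim, seed = seed)
    prof <- assign_methyl_states(sp$spectrum, sp$series,
                                 tolerance_ppm = cfg$methylspec$tolerance_ppm)
    write_tsv_with_header(
      data.frame(state = names(prof$abundance),
                 expected_mz = sp$series$states,
                 matched_mz = unname(prof$matched_mz),
                 mass_error_ppm = unname(prof$mass_error_ppm),
                 abundance = unname(prof$abundance)),
      file.path(out_dir, "methyl_profile.tsv"), run_id)
    NULL
  })
  report$status <- status
  report$outputs <- sort(list.files(out_dir))
  report$checksums <- as.list(tools::md5sum(
    file.path(out_dir, setdiff(report$outputs, "run_report.json"))))
  names(report$checksums) <- basename(names(report$checksums))
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
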