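# Orchestrates simulate -> call peaks -> motif -> scan -> differential
# expression -> integrate with one configuration and one seed, producing
# a run manifest. Each stochastic stage draws from its own
# stage-name-salted seed so adding a stage never perturbs earlier ones.

#' Stage-salted seed
#'
#' Deterministically derives one 31-bit seed per pipeline stage from the
#' run seed, so stage order and count never affect another stage's random
#' stream.
#'
#' @param seed run seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  salt <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + salt * 7919) %% 2147483646) + 1L
}

#' Default simulation parameters
#'
#' The study conditions the synthetic generator emulates: a gene-dense
#' circular bacterial chromosome (GC 0.66, 9.19 % intergenic), tens of
#' planted 14-bp sites split between promoter, intragenic and silent
#' locations, ChIP enrichment of 10-30x over a background depth of 20,
#' and three biological replicates per condition with planted |log2FC|
#' between 1.5 and 3.5 on direct and indirect genes. The 1 Mb / 900-gene
#' default keeps a full run in the low seconds while preserving realistic
#' gene and gap geometry.
#'
#' @param ... overrides for any listed field.
#' @return named list of generator settings.
#' @export
simulation_params <- function(...) {
  p <- list(
    genome_length = 1e6, gc = 0.66,
    n_genes = 900L, mean_gene_len = 1000L,
    target_intergenic_fraction = 0.0919,
    n_intergenic = 20L, n_intragenic = 8L, n_silent = 6L,
    n_indirect = 120L,
    lfc_range = c(1.5, 3.5), prob_activated = 0.6,
    depth_bg = 20, enrich_range = c(10, 30), frag_len = 200L,
    n_reps = 3L, base_mean_meanlog = 4, base_mean_sdlog = 1,
    dispersion = 0.1
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad) > 0L) {
    stop("unknown simulation parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p[names(dots)] <- dots
  p
}

#' Run the full regulon-reconstruction pipeline
#'
#' With `inputs = NULL` (the default) all inputs are simulated with known
#' truth; otherwise `inputs` supplies paths: `genome_fasta` and `gff` are
#' then required, plus either `peaks` (a called peak file) or nothing
#' ChIP-based, and optionally `deg` (an external DEG table, which takes
#' precedence over the internal count-based test) and `cog` (a COG
#' table). Stages run in order: peak calling, summit classification,
#' motif discovery from peak regions (one best site per peak), two-strand
#' genome scanning, differential expression, integration, summaries. A
#' stage failure stops the run with the stage name in the error.
#'
#' @param config an [analysis_config()]; `config$seed` seeds every
#'   stochastic stage through [stage_seed()].
#' @param sim a [simulation_params()] list (ignored when `inputs` given).
#' @param inputs optional named list of file paths, see above.
#' @param outdir optional directory; when given, all stage outputs are
#'   written there (FASTA, GFF3, peaks, regulon table, DEG table, summary
#'   and manifest files).
#' @return list of class `"regulon_run"`: `genome`, `annotation`,
#'   `truth` (NULL for real inputs), `coverage`, `peaks`,
#'   `peak_locations`, `motif` (discovery result), `pwm`, `consensus`,
#'   `scan_sites`, `deg`, `assignments`, `peak_flags`, `summary`,
#'   `cog`, `enrichment` (promoter chi-squared), `manifest`.
#' @export
run_regulon_pipeline <- function(config = analysis_config(),
                                 sim = simulation_params(),
                                 inputs = NULL, outdir = NULL) {
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  truth <- NULL
  coverage <- NULL
  counts <- NULL
  peaks_in <- NULL
  deg_ext <- NULL
  cog_map <- NULL

  if (is.null(inputs)) {
    genome <- stage("simulate_genome",
      simulate_genome(sim$genome_length, sim$gc,
                      seed = stage_seed(seed, "genome")))
    annotation <- stage("simulate_annotation",
      simulate_annotation(genome, sim$n_genes, sim$mean_gene_len,
                          sim$target_intergenic_fraction,
                          seed = stage_seed(seed, "annotation")))
    site_model <- fnr_site_pwm(pseudocount = config$pseudocount)
    planted <- stage("plant_sites",
      plant_sites(genome, annotation, site_model,
                  n_intergenic = sim$n_intergenic,
                  n_intragenic = sim$n_intragenic,
                  n_silent = sim$n_silent, n_indirect = sim$n_indirect,
                  max_upstream_dist = config$max_upstream_dist,
                  operon_gap = config$operon_gap,
                  lfc_range = sim$lfc_range,
                  prob_activated = sim$prob_activated,
                  seed = stage_seed(seed, "sites")))
    genome <- planted$genome
    truth <- planted$truth
    coverage <- stage("simulate_chip",
      simulate_chip(genome, truth, depth_bg = sim$depth_bg,
                    enrich_range = sim$enrich_range,
                    frag_len = sim$frag_len,
                    seed = stage_seed(seed, "chip")))
    counts <- stage("simulate_counts",
      simulate_counts(annotation, truth, n_reps = sim$n_reps,
                      base_mean_meanlog = sim$base_mean_meanlog,
                      base_mean_sdlog = sim$base_mean_sdlog,
                      dispersion = sim$dispersion,
                      seed = stage_seed(seed, "counts")))
    set.seed(stage_seed(seed, "cog"))
    cog_map <- data.frame(
      gene_id = annotation$gene_id,
      cog = sample(strsplit("CEFGHIJKLMNOPRSTUVX", "")[[1]],
                   nrow(annotation), replace = TRUE),
      stringsAsFactors = FALSE)
  } else {
    genome <- stage("read_genome",
                    read_genome_fasta(inputs$genome_fasta))
    annotation <- stage("read_annotation",
                        read_annotation_gff(inputs$gff,
                                            genome_length = genome$length))
    if (!is.null(inputs$peaks)) {
      peaks_in <- stage("read_peaks",
                        read_peaks(inputs$peaks,
                                   dialect = inputs$peaks_dialect %||%
                                     "tabular"))
    }
    if (!is.null(inputs$deg)) {
      deg_ext <- stage("read_deg", read_deg_table(inputs$deg))
    }
    if (!is.null(inputs$cog)) {
      cog_map <- stage("read_cog", read_cog_table(inputs$cog))
    }
  }

  peaks <- if (!is.null(peaks_in)) peaks_in else if (!is.null(coverage)) {
    stage("call_peaks",
          call_peaks(coverage$ip, coverage$input, window = config$window,
                     local_window = config$local_window,
                     peak_fdr = config$peak_fdr,
                     circular = genome$circular))
  } else {
    stop("pipeline stage 'call_peaks' failed: no peaks and no coverage ",
         "available", call. = FALSE)
  }
  peak_locations <- stage("classify_location",
    classify_location(peaks, annotation, genome$length,
                      config$max_upstream_dist, config$operon_gap,
                      circular = genome$circular))

  bg <- letter_frequencies(genome)
  motif <- NULL
  pwm <- NULL
  consensus <- NULL
  scan_sites <- data.frame(position = integer(0), strand = character(0),
                           sequence = character(0), score = numeric(0))
  if (nrow(peaks) >= 5L) {
    # flank of twice the motif width: summits locate the binding site only
    # to within a few tens of bp, and the site must fall fully inside the
    # extracted region for the one-occurrence finder to align it
    regions <- extract_peak_regions(genome, peaks,
                                    flank = 2L * config$motif_width)
    motif <- stage("discover_motif",
      discover_motif(regions, width = config$motif_width,
                     pseudocount = config$pseudocount, background = bg,
                     both_strands = TRUE,
                     seed = stage_seed(seed, "motif")))
    pwm <- stage("build_pwm",
      build_pwm(motif$sites, pseudocount = config$pseudocount,
                background = bg))
    consensus <- consensus_string(pwm, config$invariant_thresh,
                                  config$include_thresh)
    scan_sites <- stage("scan_pwm",
      scan_pwm(genome, pwm, config$scan_score_thresh, background = bg))
  }

  deg <- if (!is.null(deg_ext)) {
    pcol <- if (config$use_adjusted) deg_ext$padj else deg_ext$pvalue
    deg_ext$significant <- !is.na(pcol) & pcol <= config$alpha_deg
    deg_ext
  } else if (!is.null(counts)) {
    stage("de_test",
          de_test(counts$wt, counts$mut, alpha_deg = config$alpha_deg,
                  use_adjusted = config$use_adjusted))
  } else {
    stop("pipeline stage 'de_test' failed: no DEG table and no counts ",
         "available", call. = FALSE)
  }

  integrated <- stage("integrate",
    integrate_regulon(peak_locations, scan_sites, deg, annotation,
                      genome$length, config,
                      circular = genome$circular))
  summary <- summarize_regulon(integrated$assignments,
                               integrated$peak_flags)
  cog <- if (!is.null(cog_map)) {
    cog_summary(integrated$assignments, cog_map)
  } else NULL

  ifrac <- intergenic_fraction(annotation, genome$length)
  inter_peaks <- unique(peak_locations$peak_id[
    peak_locations$klass == "intergenic"])
  enrichment <- if (nrow(peaks) > 0L) {
    promoter_enrichment(length(inter_peaks), nrow(peaks), ifrac)
  } else NULL

  run <- structure(list(
    genome = genome, annotation = annotation, truth = truth,
    coverage = coverage, counts = counts, peaks = peaks,
    peak_locations = peak_locations, motif = motif, pwm = pwm,
    consensus = consensus, scan_sites = scan_sites, deg = deg,
    assignments = integrated$assignments,
    peak_flags = integrated$peak_flags,
    summary = summary, cog = cog,
    intergenic_fraction = ifrac, enrichment = enrichment,
    manifest = NULL
  ), class = "regulon_run")

  digests <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    pth <- function(f) file.path(outdir, f)
    write_genome_fasta(genome, pth("genome.fasta"))
    write_annotation_gff(annotation, pth("annotation.gff3"),
                         seq_id = genome$id)
    if (nrow(peaks) > 0L) write_peaks(peaks, pth("peaks.narrowPeak"),
                                      seq_id = genome$id)
    write_deg_table(deg, pth("deg.tsv"))
    write_regulon_table(run$assignments, pth("regulon.tsv"))
    write.table(run$peak_flags, pth("peak_flags.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(cog)) {
      write.table(cog, pth("cog_summary.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    if (!is.null(truth)) {
      write.table(truth$planted_sites, pth("truth_sites.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(truth$direct_genes, pth("truth_direct.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    files <- list.files(outdir, full.names = TRUE)
    digests <- tools::md5sum(files)
    names(digests) <- basename(files)
  }
  run$manifest <- list(
    package_version = as.character(utils::packageVersion("regulonscan")),
    seed = seed,
    config = unclass(config),
    config_hash = config_hash(config),
    simulated = is.null(inputs),
    sim = if (is.null(inputs)) sim else NULL,
    inputs = inputs,
    n_peaks = nrow(peaks),
    n_significant = summary$n_significant,
    file_digests = digests
  )
  if (!is.null(outdir)) {
    write_manifest(run$manifest, file.path(outdir, "manifest.txt"))
  }
  run
}

write_manifest <- function(manifest, path) {
  flat <- c(
    sprintf("package_version=%s", manifest$package_version),
    sprintf("seed=%d", manifest$seed),
    sprintf("config_hash=%s", manifest$config_hash),
    sprintf("config.%s=%s", names(manifest$config),
            vapply(manifest$config, format, "")),
    if (!is.null(manifest$sim)) {
      sprintf("sim.%s=%s", names(manifest$sim),
              vapply(manifest$sim, function(x) paste(format(x),
                                                     collapse = ","), ""))
    },
    sprintf("n_peaks=%d", manifest$n_peaks),
    sprintf("n_significant=%d", manifest$n_significant),
    if (length(manifest$file_digests) > 0L) {
      sprintf("md5.%s=%s", names(manifest$file_digests),
              manifest$file_digests)
    }
  )
  writeLines(flat, path)
  invisible(path)
}

#' @export
print.regulon_run <- function(x, ...) {
  s <- x$summary
  cat("regulon pipeline run\n")
  cat(sprintf("  genome: %d bp (%s), %d genes, intergenic fraction %.4f\n",
              x$genome$length,
              if (x$genome$circular) "circular" else "linear",
              nrow(x$annotation), x$intergenic_fraction))
  cat(sprintf("  peaks: %d (%d productive, %d silent)\n",
              s$n_peaks, s$n_productive, s$n_silent))
  cat(sprintf("  significant DEGs: %d  (direct %d, scan candidates %d, indirect %d)\n",
              s$n_significant, s$n_direct, s$n_scan_candidate,
              s$n_indirect))
  if (!is.null(x$consensus)) {
    cat("  motif consensus:", format(x$consensus), "\n")
  }
  invisible(x)
}

#' Score planted-truth recovery of a simulated run
#'
#' Compares the run's direct-gene calls with the planted direct set
#' (precision and recall) and checks that planted silent sites were
#' called as peaks and flagged non-productive.
#'
#' @param run a simulated `"regulon_run"` (with non-NULL `truth`).
#' @return list with `precision`, `recall`, `silent_fraction` (planted
#'   silent sites covered by a non-productive called peak, over all
#'   planted silent sites), `n_true_direct`, `n_called_direct`.
#' @export
evaluate_recovery <- function(run) {
  if (is.null(run$truth)) {
    stop("recovery can only be evaluated for simulated runs",
         call. = FALSE)
  }
  truth_direct <- run$truth$direct_genes$gene_id
  called <- run$assignments$gene_id[run$assignments$category == "direct"]
  tp <- length(intersect(called, truth_direct))
  precision <- if (length(called) == 0L) NA_real_ else tp / length(called)
  recall <- if (length(truth_direct) == 0L) NA_real_ else
    tp / length(truth_direct)
  silent_pos <- run$truth$silent_sites
  silent_ok <- vapply(silent_pos, function(p) {
    hit <- run$peaks$start <= p & run$peaks$end >= p
    any(hit) && all(!run$peak_flags$productive[
      match(run$peaks$id[hit], run$peak_flags$peak_id)])
  }, logical(1L))
  list(precision = precision, recall = recall,
       silent_fraction = if (length(silent_pos) == 0L) NA_real_ else
         mean(silent_ok),
       n_true_direct = length(truth_direct),
       n_called_direct = length(called))
}
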