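# Generators for genomes, annotations, planted binding sites, ChIP
# coverage and replicated count matrices with known truth, so every
# downstream stage is testable without external data.

#' Simulate a random genome sequence
#'
#' I.i.d. letters with `P(G) = P(C) = gc / 2`. The result is flagged
#' circular: bacterial chromosomes are, and all downstream interval math
#' honours the wraparound.
#'
#' @param length genome length in bp (>= 1000).
#' @param gc GC content in (0, 1].
#' @param seed integer seed.
#' @return a [genome_seq()].
#' @export
simulate_genome <- function(length, gc = 0.5, seed = 1L) {
  stopifnot(length >= 1000, gc > 0, gc <= 1)
  set.seed(as.integer(seed))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- paste(sample(names(p), length, replace = TRUE, prob = p),
             collapse = "")
  genome_seq("synthetic_genome", s, circular = TRUE)
}

#' Simulate a gene annotation with a target intergenic fraction
#'
#' Packs `n_genes` non-overlapping genes onto the circular genome with
#' lognormal length variation around `mean_gene_len`, exponential gap
#' variation, random strands, and at least one divergently transcribed
#' (head-to-head) pair by construction. The realised intergenic fraction
#' lands within 0.01 of `target_intergenic_fraction`.
#'
#' @param genome a [genome_seq()].
#' @param n_genes number of genes.
#' @param mean_gene_len mean gene length in bp.
#' @param target_intergenic_fraction fraction of the genome left between
#'   genes; the 0.0919 default matches a gene-dense bacterial chromosome.
#' @param seed integer seed.
#' @param min_gene_len shortest gene emitted.
#' @return annotation data.frame (`gene_id`, `start`, `end`, `strand`,
#'   `name`, `cog`), sorted, non-overlapping.
#' @export
simulate_annotation <- function(genome, n_genes, mean_gene_len = 1000L,
                                target_intergenic_fraction = 0.0919,
                                seed = 1L, min_gene_len = 90L) {
  L <- genome$length
  tf <- target_intergenic_fraction
  stopifnot(tf >= 0, tf <= 1)
  if (n_genes == 0L) {
    return(data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      name = character(0), cog = character(0),
                      stringsAsFactors = FALSE))
  }
  if (n_genes * mean_gene_len > (1 - tf) * L * 1.05) {
    stop("infeasible packing: ", n_genes, " genes of mean length ",
         mean_gene_len, " do not fit into ",
         round((1 - tf) * L), " genic bp", call. = FALSE)
  }
  set.seed(as.integer(seed))
  genic_total <- round((1 - tf) * L)
  sdlog <- 0.45
  meanlog <- log(mean_gene_len) - sdlog^2 / 2
  len <- pmax(min_gene_len, round(rlnorm(n_genes, meanlog, sdlog)))
  len <- pmax(min_gene_len, round(len * genic_total / sum(len)))
  resid <- genic_total - sum(len)
  len[which.max(len)] <- max(min_gene_len, len[which.max(len)] + resid)
  inter_total <- L - sum(len)
  if (inter_total < n_genes) {
    stop("infeasible packing: no room left for intergenic gaps",
         call. = FALSE)
  }
  raw <- rexp(n_genes)
  gaps <- pmax(1L, floor(raw / sum(raw) * inter_total))
  resid <- inter_total - sum(gaps)
  while (resid != 0L) {
    i <- sample.int(n_genes, 1L)
    step <- sign(resid)
    if (gaps[i] + step >= 1L) {
      gaps[i] <- gaps[i] + step
      resid <- resid - step
    }
  }
  start <- integer(n_genes)
  end <- integer(n_genes)
  pos <- 1L
  for (i in seq_len(n_genes)) {
    pos <- pos + gaps[i]
    start[i] <- pos
    end[i] <- pos + len[i] - 1L
    pos <- end[i] + 1L
  }
  stopifnot(pos - 1L == L)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  divergent <- which(strand[-n_genes] == "-" & strand[-1L] == "+")
  if (length(divergent) == 0L && n_genes >= 2L) {
    k <- sample.int(n_genes - 1L, 1L)
    strand[k] <- "-"
    strand[k + 1L] <- "+"
  }
  ids <- sprintf("g%05d", seq_len(n_genes))
  ann <- data.frame(gene_id = ids, start = start, end = end,
                    strand = strand, name = ids, cog = NA_character_,
                    stringsAsFactors = FALSE)
  validate_annotation(ann, L)
  ann
}

#' FNR-family binding-site model used for planting
#'
#' A width-14 frequency model of the oxygen-responsive FNR/FnrL
#' recognition site: invariant TG at positions 2-3 and CA at 12-13, a
#' T/C/A-degenerate first position, a strongly preferred A at positions 4
#' and 14, a T-leaning position 11, and an unconstrained 6-bp spacer — the
#' classic `(T/C/A)TGA-N6-TCAA` architecture of this regulator family.
#'
#' @param pseudocount smoothing carried on the returned model.
#' @param background base composition carried on the returned model.
#' @return a `"pwm"` whose counts encode the frequencies above (scaled to
#'   100 sites).
#' @export
fnr_site_pwm <- function(pseudocount = 0.5, background = rep(0.25, 4)) {
  f <- cbind(
    c(0.24, 0.34, 0.05, 0.37),   # 1: (T/C/A)
    c(0, 0, 0, 1),               # 2: T
    c(0, 0, 1, 0),               # 3: G
    c(0.90, 0.03, 0.03, 0.04),   # 4: A
    matrix(0.25, 4, 6),          # 5-10: spacer
    c(0.10, 0.10, 0.20, 0.60),   # 11: T-leaning
    c(0, 1, 0, 0),               # 12: C
    c(1, 0, 0, 0),               # 13: A
    c(0.90, 0.03, 0.02, 0.05)    # 14: A
  )
  new_pwm(f * 100, nsites = 100L, pseudocount = pseudocount,
          background = background)
}

sample_site_from_pwm <- function(pwm) {
  f <- pwm_frequencies(pwm, smoothed = FALSE)
  paste(vapply(seq_len(pwm$width), function(j) {
    sample(DNA, 1L, prob = f[, j])
  }, character(1L)), collapse = "")
}

write_into_genome <- function(genome, position, site_seq, strand) {
  written <- if (strand == "-") revcomp(site_seq) else site_seq
  w <- nchar(written)
  stopifnot(position >= 1L, position + w - 1L <= genome$length)
  substr(genome$seq, position, position + w - 1L) <- written
  genome
}

#' Plant binding sites onto a genome and record the regulatory truth
#'
#' Writes motif instances (sampled column-wise from `pwm`, random strand)
#' onto the genome at three kinds of locations: intergenic positions
#' within `max_upstream_dist` of a facing gene start (the promoter case;
#' sites in divergent gaps target both flanking genes), intragenic
#' positions inside a gene body (at least `edge_margin` bp from the gene
#' edges), and silent positions more than `2 * max_upstream_dist` from
#' every gene start, whose neighbours are guaranteed not to be planted as
#' differentially expressed. Target genes are derived with the same
#' geometric rule the peak classifier uses, so the recorded truth and the
#' pipeline's assignments are directly comparable. Genes targeted by
#' non-silent sites become the direct set with planted log2 fold changes;
#' `n_indirect` further genes (never silent-site hosts) form the indirect
#' set.
#'
#' @param genome a [genome_seq()].
#' @param annotation gene annotation data.frame.
#' @param pwm site model, e.g. [fnr_site_pwm()].
#' @param n_intergenic,n_intragenic,n_silent site counts per location
#'   class.
#' @param n_indirect genes planted as differentially expressed without a
#'   binding site.
#' @param max_upstream_dist,operon_gap geometry, as in
#'   [analysis_config()].
#' @param lfc_range magnitude range of planted log2 fold changes (wild
#'   type over mutant).
#' @param prob_activated probability that a planted change is an
#'   activation (positive log2FC).
#' @param edge_margin minimum distance of an intragenic site from the
#'   host gene's edges.
#' @param seed integer seed.
#' @param max_tries placement retries before giving up.
#' @return list with `genome` (sites written in) and `truth`, a list with
#'   `planted_sites` (position, strand, sequence, kind, in_intergenic,
#'   target_gene_ids), `direct_genes` (gene_id, log2fc), `indirect_genes`,
#'   `silent_sites` (positions) and `silent_host_genes`.
#' @export
plant_sites <- function(genome, annotation, pwm,
                        n_intergenic = 20L, n_intragenic = 8L,
                        n_silent = 6L, n_indirect = 120L,
                        max_upstream_dist = 600L, operon_gap = 100L,
                        lfc_range = c(1.5, 3.5), prob_activated = 0.6,
                        edge_margin = 150L, seed = 1L, max_tries = 200L) {
  set.seed(as.integer(seed))
  w <- pwm$width
  L <- genome$length
  ann <- annotation
  occupied <- IRanges::IRanges()
  free <- function(st, en) {
    length(IRanges::findOverlaps(IRanges::IRanges(st, en), occupied)) == 0L
  }
  claim <- function(st, en) {
    occupied <<- c(occupied, IRanges::IRanges(st, en))
  }
  site_rows <- list()
  add_site <- function(position, kind, targets, in_intergenic) {
    strand <- sample(c("+", "-"), 1L)
    site_seq <- sample_site_from_pwm(pwm)
    genome <<- write_into_genome(genome, position, site_seq, strand)
    claim(position, position + w - 1L)
    site_rows[[length(site_rows) + 1L]] <<- data.frame(
      position = position, strand = strand, sequence = site_seq,
      kind = kind, in_intergenic = in_intergenic,
      target_gene_ids = paste(targets, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  targets_of <- function(center) {
    asn <- assign_position_to_genes(center, ann, L, max_upstream_dist,
                                    operon_gap, circular = genome$circular)
    asn$gene_id
  }

  # --- intergenic sites: gaps whose right flank is '+' or left flank '-'
  gaps <- IRanges::gaps(IRanges::IRanges(ann$start, ann$end),
                        start = 1L, end = L)
  gap_df <- data.frame(start = IRanges::start(gaps),
                       end = IRanges::end(gaps))
  gap_df <- gap_df[gap_df$end - gap_df$start + 1L >= w + 4L, , drop = FALSE]
  eligible <- vapply(seq_len(nrow(gap_df)), function(i) {
    center <- (gap_df$start[i] + gap_df$end[i]) %/% 2L
    length(targets_of(center)) > 0L
  }, logical(1L))
  gap_df <- gap_df[eligible, , drop = FALSE]
  if (nrow(gap_df) < n_intergenic) {
    stop("placement failure: only ", nrow(gap_df),
         " eligible intergenic gaps for ", n_intergenic, " sites",
         call. = FALSE)
  }
  chosen <- sample.int(nrow(gap_df), n_intergenic)
  for (i in chosen) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      st <- sample(gap_df$start[i]:(gap_df$end[i] - w + 1L), 1L)
      center <- st + w %/% 2L
      tg <- targets_of(center)
      if (length(tg) > 0L && free(st, st + w - 1L)) {
        add_site(st, "intergenic", tg, TRUE)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("placement failure for an intergenic site",
                      call. = FALSE)
  }

  # --- intragenic sites
  roomy <- which(ann$end - ann$start + 1L >= w + 2L * edge_margin)
  if (length(roomy) < n_intragenic) {
    stop("placement failure: too few genes long enough for intragenic ",
         "sites", call. = FALSE)
  }
  hosts <- sample(roomy, n_intragenic)
  for (g in hosts) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      st <- sample((ann$start[g] + edge_margin):
                     (ann$end[g] - edge_margin - w + 1L), 1L)
      if (free(st, st + w - 1L)) {
        tg <- targets_of(st + w %/% 2L)
        add_site(st, "intragenic", tg, FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("placement failure for an intragenic site",
                      call. = FALSE)
  }

  # --- silent sites: far from every strand-aware gene start, and never
  # inside a gene already targeted by a non-silent site (such a host would
  # be differentially expressed, and the site not silent)
  start_pos <- ifelse(ann$strand == "+", ann$start, ann$end)
  sites_so_far <- do.call(rbind, site_rows)
  direct_so_far <- setdiff(unique(unlist(strsplit(
    sites_so_far$target_gene_ids, ";", fixed = TRUE))), "")
  tgt <- ann$gene_id %in% direct_so_far
  excl <- IRanges::reduce(c(
    IRanges::IRanges(pmax(1L, start_pos - 2L * max_upstream_dist),
                     pmin(L, start_pos + 2L * max_upstream_dist)),
    IRanges::IRanges(ann$start[tgt], ann$end[tgt])))
  allowed <- IRanges::gaps(excl, start = 1L, end = L)
  allowed <- allowed[IRanges::width(allowed) >= w + 2L]
  if (n_silent > 0L && length(allowed) == 0L) {
    stop("placement failure: no region far enough from gene starts for ",
         "silent sites", call. = FALSE)
  }
  silent_hosts <- character(0)
  if (n_silent > 0L) {
    wts <- IRanges::width(allowed)
    for (k in seq_len(n_silent)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        iv <- sample.int(length(allowed), 1L, prob = wts)
        st <- sample(IRanges::start(allowed)[iv]:
                       (IRanges::end(allowed)[iv] - w + 1L), 1L)
        if (free(st, st + w - 1L)) {
          host <- ann$gene_id[ann$start <= st & ann$end >= st + w - 1L]
          silent_hosts <- union(silent_hosts, host)
          add_site(st, "silent", character(0), length(host) == 0L)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("placement failure for a silent site",
                        call. = FALSE)
    }
  }

  sites <- do.call(rbind, site_rows)
  direct_ids <- unique(unlist(strsplit(
    sites$target_gene_ids[sites$kind != "silent"], ";", fixed = TRUE)))
  direct_ids <- setdiff(direct_ids, "")
  draw_lfc <- function(n) {
    sgn <- ifelse(runif(n) < prob_activated, 1, -1)
    sgn * runif(n, lfc_range[1L], lfc_range[2L])
  }
  direct <- data.frame(gene_id = direct_ids,
                       log2fc = draw_lfc(length(direct_ids)),
                       stringsAsFactors = FALSE)
  pool <- setdiff(ann$gene_id, c(direct_ids, silent_hosts))
  n_ind <- min(n_indirect, length(pool))
  ind_ids <- sample(pool, n_ind)
  indirect <- data.frame(gene_id = ind_ids, log2fc = draw_lfc(n_ind),
                         stringsAsFactors = FALSE)
  truth <- list(
    planted_sites = sites,
    direct_genes = direct,
    indirect_genes = indirect,
    silent_sites = sites$position[sites$kind == "silent"],
    silent_host_genes = silent_hosts
  )
  list(genome = genome, truth = truth)
}

#' Simulate ChIP IP and input coverage
#'
#' Input coverage is i.i.d. Poisson with mean `depth_bg` per base. IP
#' coverage uses the same background, except that around every planted
#' site (silent ones included — silent sites are bound, just not
#' productive) the rate is multiplied by a factor drawn uniformly from
#' `enrich_range` over a plateau of `frag_len` bp centred on the site.
#'
#' @param genome a [genome_seq()].
#' @param truth truth list from [plant_sites()].
#' @param depth_bg mean background coverage per base.
#' @param enrich_range `(lo, hi)` fold-enrichment range, `hi >= lo > 1`.
#' @param frag_len plateau width in bp (sonicated fragment length).
#' @param seed integer seed.
#' @return list with integer vectors `ip` and `input` (length = genome
#'   length) and `enrich_factors`, the factor drawn per site.
#' @export
simulate_chip <- function(genome, truth, depth_bg = 20,
                          enrich_range = c(10, 30), frag_len = 200L,
                          seed = 1L) {
  stopifnot(depth_bg > 0, enrich_range[2L] >= enrich_range[1L],
            enrich_range[1L] > 1)
  set.seed(as.integer(seed))
  L <- genome$length
  lambda <- rep(depth_bg, L)
  sites <- truth$planted_sites
  factors <- numeric(nrow(sites))
  half <- frag_len %/% 2L
  for (i in seq_len(nrow(sites))) {
    f <- runif(1L, enrich_range[1L], enrich_range[2L])
    factors[i] <- f
    center <- sites$position[i] + nchar(sites$sequence[i]) %/% 2L
    idx <- (center - half):(center + half)
    idx <- if (genome$circular) ((idx - 1L) %% L) + 1L else
      idx[idx >= 1L & idx <= L]
    lambda[idx] <- depth_bg * f
  }
  list(ip = rpois(L, lambda), input = rpois(L, depth_bg),
       enrich_factors = factors)
}

#' Simulate replicated two-condition count matrices
#'
#' Per-gene negative-binomial counts with dispersion `dispersion` and
#' base means drawn lognormally. The mutant mean is the base mean; the
#' wild-type mean is multiplied by `2^log2fc` for genes in the planted
#' direct and indirect sets (positive log2FC = higher in wild type =
#' activated by the factor). Per-sample library-size factors are drawn
#' uniformly from 0.7 to 1.3 and recorded.
#'
#' @param annotation gene annotation data.frame.
#' @param truth truth list from [plant_sites()].
#' @param n_reps biological replicates per condition (>= 2).
#' @param base_mean_meanlog,base_mean_sdlog lognormal parameters of the
#'   per-gene base mean.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   must be positive.
#' @param seed integer seed.
#' @return list with integer matrices `wt` and `mut` (genes x replicates),
#'   `size_factors` (length `2 * n_reps`, wild type first) and `mu`, the
#'   per-gene base means.
#' @export
simulate_counts <- function(annotation, truth, n_reps = 3L,
                            base_mean_meanlog = 4, base_mean_sdlog = 1,
                            dispersion = 0.1, seed = 1L) {
  stopifnot(dispersion > 0, n_reps >= 2L)
  set.seed(as.integer(seed))
  ids <- annotation$gene_id
  G <- length(ids)
  mu <- rlnorm(G, base_mean_meanlog, base_mean_sdlog)
  lfc <- setNames(rep(0, G), ids)
  planted <- rbind(truth$direct_genes, truth$indirect_genes)
  lfc[planted$gene_id] <- planted$log2fc
  sf <- runif(2L * n_reps, 0.7, 1.3)
  mu_wt <- mu * 2^lfc
  draw <- function(mu_vec, sf_part) {
    m <- vapply(sf_part, function(s) {
      rnbinom(G, size = 1 / dispersion, mu = mu_vec * s)
    }, numeric(G))
    m <- matrix(m, nrow = G)
    dimnames(m) <- list(ids, NULL)
    m
  }
  wt <- draw(mu_wt, sf[seq_len(n_reps)])
  mut <- draw(mu, sf[n_reps + seq_len(n_reps)])
  colnames(wt) <- sprintf("wt_%d", seq_len(n_reps))
  colnames(mut) <- sprintf("mut_%d", seq_len(n_reps))
  list(wt = wt, mut = mut, size_factors = sf, mu = setNames(mu, ids))
}
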