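# The core inference: fuse peak locations, motif-scan sites and
# differential-expression calls into per-gene regulon categories and
# per-peak productive/silent flags, then summarise, optionally by COG.

#' Integrate binding and expression evidence into regulon assignments
#'
#' Categories are exhaustive and mutually exclusive for every gene:
#' `direct` — at least one assigned ChIP peak and a significant expression
#' change; `scan_candidate` — no peak, but at least one genome-scan motif
#' site assigned by the same geometric rule, plus a significant change;
#' `indirect` — significant change with neither kind of binding evidence;
#' `none` — everything else (including genes under a peak with no
#' expression change). Peak evidence dominates scan evidence. Each peak is
#' flagged productive when at least one of its assigned genes is
#' significant, silent otherwise. Location flags follow the published
#' convention: `a` = site/peak within a coding region, `b` = upstream
#' intergenic (promoter) region.
#'
#' @param peak_locations long-format table from [classify_location()].
#' @param scan_sites data.frame from [scan_pwm()] (may have zero rows).
#' @param deg DEG table from [de_test()] or [read_deg_table()].
#' @param annotation gene annotation data.frame.
#' @param genome_length genome length in bp.
#' @param config an [analysis_config()].
#' @param circular wrap distances across the origin.
#' @param fold_scan_into_indirect compatibility switch: report
#'   scan-supported candidates under `indirect`, as studies that keep
#'   scan-only genes in their indirect tables do. Evidence columns are
#'   retained either way.
#' @return list with `assignments` (one row per gene: `gene_id`, `name`,
#'   `category`, `regulation`, `log2fc`, `pvalue`, `padj`, `significant`,
#'   `evidence_peaks`, `evidence_sites`, `site_sequences`,
#'   `location_flags`) and `peak_flags` (`peak_id`, `productive`).
#' @export
integrate_regulon <- function(peak_locations, scan_sites, deg, annotation,
                              genome_length, config = analysis_config(),
                              circular = TRUE,
                              fold_scan_into_indirect = FALSE) {
  alpha <- config$alpha_deg
  use_adj <- config$use_adjusted
  deg <- deg[order(deg$gene_id), , drop = FALSE]
  pcol <- if (use_adj) deg$padj else deg$pvalue
  sig_ids <- deg$gene_id[!is.na(pcol) & pcol <= alpha]
  unknown <- setdiff(deg$gene_id, annotation$gene_id)
  if (length(unknown) > 0L) {
    warning(length(unknown), " DEG gene id(s) absent from the annotation",
            " (kept): ", paste(head(unknown, 5L), collapse = ", "),
            if (length(unknown) > 5L) ", ..." else "")
  }
  genes <- sort(union(annotation$gene_id, deg$gene_id))

  # per-gene peak evidence
  pl <- peak_locations[!is.na(peak_locations$gene_id), , drop = FALSE]
  peak_by_gene <- split(pl$peak_id, pl$gene_id)
  # a peak assigned via an intergenic summit is promoter evidence (b); an
  # intragenic summit is coding-region evidence (a) for both the host and
  # the operonic downstream gene
  pl$flag <- ifelse(pl$klass == "intergenic", "b", "a")
  flags_by_gene <- split(pl$flag, pl$gene_id)

  # scan-site evidence via the same geometric rule
  site_by_gene <- list()
  siteseq_by_gene <- list()
  siteflag_by_gene <- list()
  if (!is.null(scan_sites) && nrow(scan_sites) > 0L) {
    for (i in seq_len(nrow(scan_sites))) {
      center <- scan_sites$position[i] +
        nchar(scan_sites$sequence[i]) %/% 2L
      center <- if (circular) ((center - 1L) %% genome_length) + 1L else
        min(center, genome_length)
      asn <- assign_position_to_genes(center, annotation, genome_length,
                                      config$max_upstream_dist,
                                      config$operon_gap, circular)
      if (nrow(asn) == 0L) next
      lab <- sprintf("%d(%s)", scan_sites$position[i],
                     scan_sites$strand[i])
      fl <- if (attr(asn, "klass") == "intergenic") "b" else "a"
      for (g in asn$gene_id) {
        site_by_gene[[g]] <- c(site_by_gene[[g]], lab)
        siteseq_by_gene[[g]] <- c(siteseq_by_gene[[g]],
                                  scan_sites$sequence[i])
        siteflag_by_gene[[g]] <- c(siteflag_by_gene[[g]], fl)
      }
    }
  }

  deg_idx <- match(genes, deg$gene_id)
  lfc <- deg$log2fc[deg_idx]
  pv <- deg$pvalue[deg_idx]
  pa <- deg$padj[deg_idx]
  sig <- genes %in% sig_ids
  has_peak <- genes %in% names(peak_by_gene)
  has_site <- genes %in% names(site_by_gene)
  category <- ifelse(sig & has_peak, "direct",
              ifelse(sig & has_site, "scan_candidate",
              ifelse(sig, "indirect", "none")))
  if (fold_scan_into_indirect) {
    category[category == "scan_candidate"] <- "indirect"
  }
  regulation <- rep("none", length(genes))
  regulation[sig & !is.na(lfc) & lfc > 0] <- "activated"
  regulation[sig & !is.na(lfc) & lfc < 0] <- "repressed"
  odd <- sig & !is.na(lfc) & lfc == 0
  if (any(odd)) {
    message(sum(odd), " significant gene(s) with log2fc exactly 0; ",
            "regulation left as 'none'")
  }
  collapse <- function(lst, g) {
    x <- lst[[g]]
    if (is.null(x)) "" else paste(unique(x), collapse = ",")
  }
  assignments <- data.frame(
    gene_id = genes,
    name = annotation$name[match(genes, annotation$gene_id)],
    category = category,
    regulation = regulation,
    log2fc = lfc, pvalue = pv, padj = pa, significant = sig,
    evidence_peaks = vapply(genes, collapse, "", lst = peak_by_gene),
    evidence_sites = vapply(genes, collapse, "", lst = site_by_gene),
    site_sequences = vapply(genes, collapse, "", lst = siteseq_by_gene),
    stringsAsFactors = FALSE, row.names = NULL
  )
  assignments$name[is.na(assignments$name)] <- assignments$gene_id[
    is.na(assignments$name)]
  gene_flags <- function(g, cat) {
    fl <- character(0)
    if (cat == "direct") fl <- flags_by_gene[[g]]
    if (cat == "scan_candidate") fl <- siteflag_by_gene[[g]]
    paste(sort(unique(fl)), collapse = "")
  }
  assignments$location_flags <- mapply(gene_flags, assignments$gene_id,
                                       assignments$category)

  all_peaks <- unique(peak_locations$peak_id)
  productive <- vapply(all_peaks, function(pid) {
    g <- pl$gene_id[pl$peak_id == pid]
    length(g) > 0L && any(g %in% sig_ids)
  }, logical(1L))
  peak_flags <- data.frame(peak_id = all_peaks,
                           productive = unname(productive),
                           stringsAsFactors = FALSE)
  list(assignments = assignments, peak_flags = peak_flags)
}

#' Summary counts of a regulon assignment
#'
#' @param assignments,peak_flags as returned by [integrate_regulon()].
#' @return list with scalar counts (`n_significant`, `n_direct`,
#'   `n_scan_candidate`, `n_indirect`, `n_peaks`, `n_productive`,
#'   `n_silent`) and `by_category`, a data.frame of activated/repressed
#'   tallies per category.
#' @export
summarize_regulon <- function(assignments, peak_flags) {
  cats <- c("direct", "scan_candidate", "indirect")
  by_cat <- do.call(rbind, lapply(cats, function(cc) {
    sel <- assignments$category == cc
    data.frame(category = cc,
               activated = sum(sel & assignments$regulation == "activated"),
               repressed = sum(sel & assignments$regulation == "repressed"),
               total = sum(sel), stringsAsFactors = FALSE)
  }))
  list(
    n_significant = sum(assignments$significant),
    n_direct = sum(assignments$category == "direct"),
    n_scan_candidate = sum(assignments$category == "scan_candidate"),
    n_indirect = sum(assignments$category == "indirect"),
    n_peaks = nrow(peak_flags),
    n_productive = sum(peak_flags$productive),
    n_silent = sum(!peak_flags$productive),
    by_category = by_cat
  )
}

#' Activated/repressed tallies per COG category
#'
#' Counts significant genes only. Genes missing from the COG map fall
#' into the `S` (function unknown) bucket.
#'
#' @param assignments from [integrate_regulon()].
#' @param cog_map data.frame with columns `gene_id`, `cog`.
#' @return data.frame `cog`, `activated`, `repressed`, `total`, sorted by
#'   COG letter.
#' @export
cog_summary <- function(assignments, cog_map) {
  sig <- assignments[assignments$significant, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(cog = character(0), activated = integer(0),
                      repressed = integer(0), total = integer(0),
                      stringsAsFactors = FALSE))
  }
  cog <- cog_map$cog[match(sig$gene_id, cog_map$gene_id)]
  cog[is.na(cog) | !nzchar(cog)] <- "S"
  out <- do.call(rbind, lapply(sort(unique(cog)), function(cc) {
    sel <- cog == cc
    data.frame(cog = cc,
               activated = sum(sel & sig$regulation == "activated"),
               repressed = sum(sel & sig$regulation == "repressed"),
               total = sum(sel), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
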