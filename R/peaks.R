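# Simplified local-Poisson peak calling from IP/input coverage, summit
# location classification against the gene annotation, and the
# promoter-enrichment goodness-of-fit test.

#' Call enriched intervals from IP and input coverage
#'
#' Input coverage is scaled to the IP library total, the genome is tiled
#' with non-overlapping windows of `window` bp, and each window's IP count
#' sum is tested against a Poisson upper tail with rate
#' `lambda = max(lambda_genome, lambda_local)`, where `lambda_local` is
#' the scaled input mean over `local_window` bp centred on the window,
#' excluding the tested window itself. Benjamini-Hochberg adjustment runs
#' over all tested windows; windows with `q <= peak_fdr` are merged when
#' adjacent. The summit is the argmax of the smoothed IP-minus-input
#' difference inside the merged interval (leftmost on ties); enrichment is
#' `(IP_summit + 1) / (scaled_input_summit + 1)`. Trailing bases shorter
#' than one window are not tested.
#'
#' @param ip,input equal-length integer per-base coverage vectors.
#' @param window tested window width in bp.
#' @param local_window local background span in bp (>= `window`).
#' @param peak_fdr BH FDR threshold.
#' @param circular treat the coverage as circular when computing local
#'   background.
#' @param summit_smooth width (bp) of the moving average used only to
#'   locate the summit; roughly the fragment length, so a flat coverage
#'   plateau smooths into a peak at its centre.
#' @return data.frame of peaks (`id`, `start`, `end`, `summit`,
#'   `enrichment`, `pvalue`, `qvalue`, 1-based inclusive coordinates) with
#'   the per-window test table in `attr(, "windows")`.
#' @export
call_peaks <- function(ip, input, window = 50L, local_window = 5000L,
                       peak_fdr = 0.05, circular = TRUE,
                       summit_smooth = 201L) {
  if (length(ip) != length(input)) {
    stop("ip and input coverage have different lengths", call. = FALSE)
  }
  if (sum(input) == 0) stop("input coverage is all zero", call. = FALSE)
  if (window > local_window) {
    stop("window must not exceed local_window", call. = FALSE)
  }
  L <- length(ip)
  nw <- L %/% window
  if (nw < 1L) stop("coverage shorter than one window", call. = FALSE)
  scale <- sum(ip) / sum(input)
  sin_cov <- input * scale
  used <- nw * window
  ip_w <- colSums(matrix(ip[seq_len(used)], nrow = window))
  sin_w <- colSums(matrix(sin_cov[seq_len(used)], nrow = window))
  lambda_genome <- sum(sin_cov) / L * window
  k <- max(1L, round(local_window / window))
  h <- k %/% 2L
  if (h >= 1L && nw > 1L) {
    if (circular && nw > 2L * h) {
      pad <- c(tail(sin_w, h), sin_w, head(sin_w, h))
      cs <- cumsum(c(0, pad))
      S <- cs[seq_len(nw) + 2L * h + 1L] - cs[seq_len(nw)]
      n_incl <- rep(2L * h + 1L, nw)
    } else {
      cs <- cumsum(c(0, sin_w))
      lo <- pmax(1L, seq_len(nw) - h)
      hi <- pmin(nw, seq_len(nw) + h)
      S <- cs[hi + 1L] - cs[lo]
      n_incl <- hi - lo + 1L
    }
    lambda_local <- ifelse(n_incl > 1L, (S - sin_w) / (n_incl - 1L),
                           lambda_genome)
  } else {
    lambda_local <- rep(lambda_genome, nw)
  }
  lambda <- pmax(lambda_genome, lambda_local)
  pv <- ppois(ip_w - 1, lambda, lower.tail = FALSE)
  qv <- p.adjust(pv, method = "BH")
  win_tab <- data.frame(
    index = seq_len(nw),
    start = (seq_len(nw) - 1L) * window + 1L,
    end = seq_len(nw) * window,
    ip_sum = ip_w, input_sum = sin_w, lambda = lambda,
    pvalue = pv, qvalue = qv
  )
  sig <- which(qv <= peak_fdr)
  peaks <- data.frame(id = character(0), start = integer(0),
                      end = integer(0), summit = integer(0),
                      enrichment = numeric(0), pvalue = numeric(0),
                      qvalue = numeric(0), stringsAsFactors = FALSE)
  if (length(sig) > 0L) {
    runs <- split(sig, cumsum(c(1L, diff(sig) != 1L)))
    rows <- lapply(runs, function(idx) {
      st <- (idx[1L] - 1L) * window + 1L
      en <- idx[length(idx)] * window
      diffcov <- ip[st:en] - sin_cov[st:en]
      len <- length(diffcov)
      kk <- min(summit_smooth, if (len %% 2L == 1L) len else len - 1L)
      if (kk %% 2L == 0L) kk <- kk - 1L
      sm <- if (kk >= 3L) {
        as.numeric(stats::filter(diffcov, rep(1 / kk, kk)))
      } else diffcov
      if (all(is.na(sm))) sm <- diffcov
      sm[is.na(sm)] <- -Inf
      summit <- st - 1L + which.max(sm)
      data.frame(start = st, end = en, summit = summit,
                 enrichment = (ip[summit] + 1) / (sin_cov[summit] + 1),
                 pvalue = min(pv[idx]), qvalue = min(qv[idx]))
    })
    peaks <- do.call(rbind, rows)
    peaks <- peaks[order(peaks$start), , drop = FALSE]
    peaks <- cbind(id = sprintf("peak_%03d", seq_len(nrow(peaks))), peaks,
                   stringsAsFactors = FALSE)
    rownames(peaks) <- NULL
  }
  attr(peaks, "windows") <- win_tab
  peaks
}

# Assign one genomic position (a summit or motif-site centre) to genes.
# Intragenic: the (first) gene containing the position is the host; the
# next same-strand gene whose start lies within operon_gap downstream of
# the position is added (operon read-through). Intergenic: every gene
# whose start faces the position within max_upstream_dist is listed —
# for '+' genes the start lies ahead of the position, for '-' genes the
# start (the interval end) lies behind it; distances wrap on circular
# genomes. Returns a data.frame (possibly with zero gene rows) plus a
# "klass" attribute.
assign_position_to_genes <- function(position, annotation, genome_length,
                                     max_upstream_dist = 600L,
                                     operon_gap = 100L, circular = TRUE) {
  p <- as.integer(position)
  if (p < 1L || p > genome_length) {
    stop("position ", p, " outside the genome", call. = FALSE)
  }
  ann <- annotation
  dist_fwd <- function(from, to) {       # bp from 'from' to 'to' going right
    d <- to - from
    if (circular) d %% genome_length else d
  }
  inside <- which(ann$start <= p & ann$end >= p)
  if (length(inside) > 0L) {
    host <- inside[1L]
    d_host <- if (ann$strand[host] == "+") p - ann$start[host] else
      ann$end[host] - p
    rows <- data.frame(gene_id = ann$gene_id[host], distance = d_host,
                       orientation = "inside", stringsAsFactors = FALSE)
    same <- which(ann$strand == ann$strand[host] &
                    ann$gene_id != ann$gene_id[host])
    if (length(same) > 0L) {
      d <- if (ann$strand[host] == "+") {
        dist_fwd(p, ann$start[same])
      } else {
        dist_fwd(ann$end[same], p)
      }
      ok <- which(d >= 0 & d <= operon_gap)
      if (length(ok) > 0L) {
        nb <- ok[which.min(d[ok])]
        rows <- rbind(rows, data.frame(
          gene_id = ann$gene_id[same[nb]], distance = d[nb],
          orientation = "downstream_of", stringsAsFactors = FALSE))
      }
    }
    attr(rows, "klass") <- "intragenic"
    return(rows)
  }
  d_plus <- ifelse(ann$strand == "+",
                   dist_fwd(p, ann$start),
                   dist_fwd(ann$end, p))
  facing <- which(d_plus >= 0 & d_plus <= max_upstream_dist)
  rows <- if (length(facing) > 0L) {
    out <- data.frame(gene_id = ann$gene_id[facing],
                      distance = d_plus[facing],
                      orientation = "upstream_of", stringsAsFactors = FALSE)
    out[order(out$distance), , drop = FALSE]
  } else {
    data.frame(gene_id = character(0), distance = numeric(0),
               orientation = character(0), stringsAsFactors = FALSE)
  }
  attr(rows, "klass") <- "intergenic"
  rows
}

#' Classify peak locations against the gene annotation
#'
#' The summit alone decides: a summit inside a gene interval makes the
#' peak intragenic (host gene listed, plus the next same-strand gene when
#' its start is within `operon_gap` of the summit); otherwise the peak is
#' intergenic and every gene whose start faces the summit within
#' `max_upstream_dist` is listed — a divergently transcribed head-to-head
#' pair yields two target genes. Intergenic summits facing no start in
#' range are kept as "orphan" intergenic rows with `NA` gene.
#'
#' @param peaks peak data.frame with `id` and `summit`.
#' @param annotation gene annotation data.frame.
#' @param genome_length genome length in bp.
#' @param max_upstream_dist,operon_gap see [analysis_config()].
#' @param circular wrap distances across the origin.
#' @return long-format data.frame: one row per (peak, assigned gene) with
#'   columns `peak_id`, `klass` (`intergenic`/`intragenic`), `gene_id`,
#'   `distance` (strand-oriented bp from gene start to summit),
#'   `orientation` (`upstream_of`/`inside`/`downstream_of`).
#' @export
classify_location <- function(peaks, annotation, genome_length,
                              max_upstream_dist = 600L, operon_gap = 100L,
                              circular = TRUE) {
  validate_annotation(annotation, genome_length)
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    asn <- assign_position_to_genes(peaks$summit[i], annotation,
                                    genome_length, max_upstream_dist,
                                    operon_gap, circular)
    klass <- attr(asn, "klass")
    if (nrow(asn) == 0L) {
      data.frame(peak_id = peaks$id[i], klass = klass,
                 gene_id = NA_character_, distance = NA_real_,
                 orientation = NA_character_, stringsAsFactors = FALSE)
    } else {
      cbind(peak_id = peaks$id[i], klass = klass, asn,
            stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chi-squared promoter-enrichment test
#'
#' One-degree-of-freedom goodness of fit of the observed split of binding
#' sites between intergenic and genic space against the genomic baseline:
#' with `E_intergenic = n_total * intergenic_fraction`,
#' `chi2 = sum (O - E)^2 / E` over the two cells, and the p-value is the
#' upper tail of the chi-squared distribution with 1 df.
#'
#' @param n_intergenic number of sites whose summit is intergenic.
#' @param n_total total number of sites.
#' @param intergenic_fraction fraction of the genome that is intergenic,
#'   in (0, 1).
#' @return list with `statistic`, `pvalue`, `expected` (length-2 vector).
#' @export
promoter_enrichment <- function(n_intergenic, n_total,
                                intergenic_fraction) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  if (n_intergenic < 0 || n_intergenic > n_total) {
    stop("n_intergenic must be between 0 and n_total", call. = FALSE)
  }
  if (intergenic_fraction <= 0 || intergenic_fraction >= 1) {
    stop("intergenic_fraction must be in (0, 1)", call. = FALSE)
  }
  e1 <- n_total * intergenic_fraction
  e2 <- n_total * (1 - intergenic_fraction)
  o1 <- n_intergenic
  o2 <- n_total - n_intergenic
  chi2 <- (o1 - e1)^2 / e1 + (o2 - e2)^2 / e2
  list(statistic = chi2,
       pvalue = pchisq(chi2, df = 1, lower.tail = FALSE),
       expected = c(intergenic = e1, genic = e2))
}

#' Intergenic fraction of a genome
#'
#' One minus the covered fraction of the union of gene intervals.
#'
#' @param annotation gene annotation data.frame.
#' @param genome_length genome length in bp.
#' @return fraction between 0 and 1.
#' @export
intergenic_fraction <- function(annotation, genome_length) {
  if (nrow(annotation) == 0L) return(1)
  validate_annotation(annotation, genome_length)
  covered <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(annotation$start, annotation$end))))
  1 - covered / genome_length
}
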