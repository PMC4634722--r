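# Readers and writers for the on-disk formats the pipeline consumes and
# emits. Internal coordinates are 1-based inclusive throughout (the
# GRanges/IRanges convention); BED I/O converts at the boundary.

#' Construct a genome sequence object
#'
#' @param id sequence identifier.
#' @param seq DNA string over A, C, G, T, N (uppercase).
#' @param circular logical; circular genomes wrap in all interval and
#'   scanning arithmetic.
#' @return a list of class `"genome_seq"` with fields `id`, `seq`,
#'   `length`, `circular`.
#' @export
genome_seq <- function(id, seq, circular = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  seq <- toupper(seq)
  letters_seen <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
  bad <- setdiff(letters_seen, c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop("illegal letters in genome sequence: ",
         paste(bad, collapse = ", "),
         if ("U" %in% bad) " (RNA input? U is not accepted)" else "",
         call. = FALSE)
  }
  structure(list(id = as.character(id), seq = seq, length = nchar(seq),
                 circular = isTRUE(circular)),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("genome_seq '%s': %d bp, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a genome from FASTA
#'
#' The first record is used; additional records trigger a warning. Letters
#' are uppercased and validated against the DNA alphabet (A/C/G/T/N); U is
#' rejected with a pointer to its RNA origin.
#'
#' @param path FASTA file.
#' @param circular logical, stored on the returned object.
#' @return a [genome_seq()].
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  if (length(recs) > 1L) {
    warning("FASTA has ", length(recs),
            " records; using the first and ignoring the rest")
  }
  id <- sub("\\s.*$", "", names(recs)[1L])
  genome_seq(id, as.character(recs[[1L]]), circular = circular)
}

#' @rdname read_genome_fasta
#' @param genome a `genome_seq`.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$seq)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

validate_annotation <- function(ann, genome_length = NULL) {
  need <- c("gene_id", "start", "end", "strand")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0L) {
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ann$gene_id)) {
    stop("duplicated gene_id in annotation: ",
         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(ann$end < ann$start)) {
    stop("annotation has end < start (origin-spanning genes are not ",
         "supported); offending gene(s): ",
         paste(ann$gene_id[ann$end < ann$start], collapse = ", "),
         call. = FALSE)
  }
  if (any(ann$start < 1L)) stop("gene start below 1", call. = FALSE)
  if (!is.null(genome_length) && any(ann$end > genome_length)) {
    stop("gene interval extends beyond the genome", call. = FALSE)
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  invisible(ann)
}

#' Read gene annotation from GFF3
#'
#' Rows of the requested feature type(s) become genes. The gene identifier
#' is taken from the `ID` attribute, falling back to `locus_tag`; a row
#' with neither is an error. Coordinates stay 1-based inclusive. An
#' optional `cog` attribute (single-letter COG category) is carried along.
#'
#' @param path GFF3 file.
#' @param feature_types character vector of feature types to keep
#'   (default `"gene"`; use `"CDS"` for CDS-only annotations).
#' @param genome_length optional, used to reject genes running off the
#'   sequence end (origin-spanning genes are rejected by design).
#' @return data.frame with columns `gene_id`, `start`, `end`, `strand`,
#'   `name`, `cog`, sorted by `start`.
#' @export
read_annotation_gff <- function(path, feature_types = "gene",
                                genome_length = NULL) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("failed to parse GFF3 (check that end >= start ",
                             "on every row): ", conditionMessage(e),
                             call. = FALSE))
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (length(gr) == 0L) {
    stop("no rows of feature type ", paste(feature_types, collapse = "/"),
         " in ", path, call. = FALSE)
  }
  mc <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else
    rep(NA_character_, length(gr))
  if ("locus_tag" %in% names(mc)) {
    lt <- as.character(mc$locus_tag)
    ids[is.na(ids)] <- lt[is.na(ids)]
  }
  if (anyNA(ids)) {
    stop("GFF row(s) without ID or locus_tag attribute", call. = FALSE)
  }
  nm <- if ("Name" %in% names(mc)) as.character(mc$Name) else ids
  nm[is.na(nm)] <- ids[is.na(nm)]
  cog <- if ("cog" %in% names(mc)) as.character(mc$cog) else
    rep(NA_character_, length(gr))
  ann <- data.frame(
    gene_id = ids,
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    name = nm,
    cog = cog,
    stringsAsFactors = FALSE
  )
  ann <- ann[order(ann$start, ann$end), , drop = FALSE]
  rownames(ann) <- NULL
  validate_annotation(ann, genome_length)
  ann
}

#' @rdname read_annotation_gff
#' @param annotation annotation data.frame.
#' @param seq_id sequence name written to column 1.
#' @export
write_annotation_gff <- function(annotation, path, seq_id = "genome") {
  validate_annotation(annotation)
  gr <- GenomicRanges::GRanges(
    seqnames = seq_id,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  S4Vectors::mcols(gr)$Name <- annotation$name %||% annotation$gene_id
  if (!is.null(annotation$cog)) S4Vectors::mcols(gr)$cog <- annotation$cog
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read called peaks
#'
#' Three dialects are supported. `"bed"`: BED with 0-based half-open
#' coordinates and the enrichment in the score column (column 5).
#' `"tabular"`: a peak-caller table with 1-based inclusive `start`/`end`,
#' a `fold_enrichment` column, and optional `summit`, `pvalue`, `qvalue`,
#' `id` columns. `"narrowpeak"`: the 10-column format written by
#' [write_peaks()]. All coordinates are normalised to the internal 1-based
#' inclusive convention; a missing summit defaults to the interval
#' midpoint. The enrichment column of peak tables is treated as fold
#' enrichment (IP over scaled input).
#'
#' @param path file path.
#' @param dialect one of `"bed"`, `"tabular"`, `"narrowpeak"`.
#' @return data.frame with columns `id`, `start`, `end`, `summit`,
#'   `enrichment`, `pvalue`, `qvalue`.
#' @export
read_peaks <- function(path, dialect = c("bed", "tabular", "narrowpeak")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    if (length(gr) == 0L) stop("no peaks in ", path, call. = FALSE)
    sc <- S4Vectors::mcols(gr)$score
    if (is.null(sc) || all(is.na(sc))) {
      stop("BED peak file lacks the enrichment (score) column", call. = FALSE)
    }
    nm <- S4Vectors::mcols(gr)$name
    if (is.null(nm) || anyNA(nm)) nm <- sprintf("peak_%03d", seq_along(gr))
    out <- data.frame(
      id = as.character(nm),
      start = BiocGenerics::start(gr),
      end = BiocGenerics::end(gr),
      summit = NA_integer_,
      enrichment = as.numeric(sc),
      pvalue = NA_real_, qvalue = NA_real_,
      stringsAsFactors = FALSE
    )
  } else if (dialect == "tabular") {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    for (col in c("start", "end", "fold_enrichment")) {
      if (!col %in% names(tab)) {
        stop("tabular peak file lacks required column '", col, "'",
             call. = FALSE)
      }
    }
    out <- data.frame(
      id = if ("id" %in% names(tab)) as.character(tab$id) else
        sprintf("peak_%03d", seq_len(nrow(tab))),
      start = as.integer(tab$start),
      end = as.integer(tab$end),
      summit = if ("summit" %in% names(tab)) as.integer(tab$summit) else
        NA_integer_,
      enrichment = as.numeric(tab$fold_enrichment),
      pvalue = if ("pvalue" %in% names(tab)) as.numeric(tab$pvalue) else
        NA_real_,
      qvalue = if ("qvalue" %in% names(tab)) as.numeric(tab$qvalue) else
        NA_real_,
      stringsAsFactors = FALSE
    )
  } else {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 10L) {
      stop("narrowPeak file must have 10 columns", call. = FALSE)
    }
    names(tab) <- c("chrom", "start0", "end0", "id", "score", "strand",
                    "enrichment", "nlog10p", "nlog10q", "summit_offset")
    out <- data.frame(
      id = as.character(tab$id),
      start = as.integer(tab$start0) + 1L,
      end = as.integer(tab$end0),
      summit = as.integer(tab$start0) + 1L + as.integer(tab$summit_offset),
      enrichment = as.numeric(tab$enrichment),
      pvalue = ifelse(tab$nlog10p < 0, NA_real_, 10^(-tab$nlog10p)),
      qvalue = ifelse(tab$nlog10q < 0, NA_real_, 10^(-tab$nlog10q)),
      stringsAsFactors = FALSE
    )
  }
  if (any(out$start < 1L | out$end < out$start)) {
    stop("peak file contains negative or inverted coordinates", call. = FALSE)
  }
  mid <- (out$start + out$end) %/% 2L
  out$summit <- ifelse(is.na(out$summit), mid, out$summit)
  rownames(out) <- NULL
  out
}

#' Write peaks as narrowPeak-style BED6+4
#'
#' Columns: chrom, 0-based start, half-open end, id, integer score
#' (enrichment x 10, capped at 1000), strand ".", fold enrichment,
#' -log10 p, -log10 q (-1 when unavailable), summit offset from start.
#'
#' @param peaks peak data.frame as returned by [call_peaks()].
#' @param path output path.
#' @param seq_id chromosome name for column 1.
#' @export
write_peaks <- function(peaks, path, seq_id = "genome") {
  nl10 <- function(p) ifelse(is.na(p), -1,
                             round(-log10(pmax(p, 1e-300)), 4))
  tab <- data.frame(
    chrom = seq_id,
    start0 = peaks$start - 1L,
    end0 = peaks$end,
    id = peaks$id,
    score = pmin(1000L, as.integer(round(peaks$enrichment * 10))),
    strand = ".",
    enrichment = round(peaks$enrichment, 4),
    nlog10p = nl10(peaks$pvalue),
    nlog10q = nl10(peaks$qvalue),
    summit_offset = peaks$summit - peaks$start
  )
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write differential-expression tables
#'
#' TSV with named header columns `gene_id`, `base_mean`, `log2fc`,
#' `pvalue`, `padj`. The log2 fold change convention is wild type over
#' mutant: positive means higher in wild type, i.e. activated by the
#' factor. The reader validates p-value ranges and the `padj >= pvalue`
#' invariant.
#'
#' @param path file path.
#' @return data.frame with the five columns above.
#' @export
read_deg_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_id", "base_mean", "log2fc", "pvalue", "padj")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("DEG table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok <- is.na(tab$pvalue) | (tab$pvalue >= 0 & tab$pvalue <= 1)
  if (!all(ok)) stop("pvalue outside [0, 1] in DEG table", call. = FALSE)
  ok <- is.na(tab$padj) | (tab$padj >= 0 & tab$padj <= 1)
  if (!all(ok)) stop("padj outside [0, 1] in DEG table", call. = FALSE)
  bad <- !is.na(tab$padj) & !is.na(tab$pvalue) &
    tab$padj < tab$pvalue - 1e-12
  if (any(bad)) stop("padj < pvalue in DEG table", call. = FALSE)
  tab[need]
}

#' @rdname read_deg_table
#' @param deg DEG data.frame.
#' @export
write_deg_table <- function(deg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# log2fc convention: positive = higher in wild type = activated by the factor",
             con)
  cols <- intersect(c("gene_id", "base_mean", "log2fc", "pvalue", "padj",
                      "significant"), names(deg))
  write.table(deg[cols], con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read the per-gene regulon table
#'
#' One row per gene, mirroring the usual published layout: locus id, gene
#' name, category, sign of regulation, fold change, supporting peak ids and
#' site sequences, and a location flag per piece of evidence — `a` for a
#' site within the coding region, `b` for a site in the upstream intergenic
#' (promoter) region.
#'
#' @param assignments assignments data.frame from [integrate_regulon()].
#' @param path output TSV.
#' @export
write_regulon_table <- function(assignments, path) {
  cols <- c("gene_id", "name", "category", "regulation", "log2fc",
            "pvalue", "padj", "evidence_peaks", "evidence_sites",
            "site_sequences", "location_flags")
  out <- assignments[intersect(cols, names(assignments))]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_regulon_table
#' @export
read_regulon_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  chr <- c("evidence_peaks", "evidence_sites", "site_sequences",
           "location_flags", "name")
  for (col in intersect(chr, names(tab))) {
    tab[[col]] <- ifelse(is.na(tab[[col]]), "", as.character(tab[[col]]))
  }
  tab
}

#' Read an orthologue map / a COG assignment table
#'
#' The orthologue map is a two-column TSV `id_a`, `id_b`; the COG table a
#' two-column TSV `gene_id`, `cog` (one-letter category).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_ortholog_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id_a", "id_b") %in% names(tab))) {
    stop("orthologue map needs columns id_a and id_b", call. = FALSE)
  }
  tab[c("id_a", "id_b")]
}

#' @rdname read_ortholog_map
#' @export
read_cog_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "cog") %in% names(tab))) {
    stop("COG table needs columns gene_id and cog", call. = FALSE)
  }
  tab[c("gene_id", "cog")]
}

#' Coordinate convention conversion
#'
#' Converts between 1-based inclusive intervals (internal, GFF3) and
#' 0-based half-open intervals (BED). The two are mutually inverse for
#' every interval.
#'
#' @param start,end 1-based inclusive coordinates.
#' @param start0,end0 0-based half-open coordinates.
#' @return a two-column data.frame in the other convention.
#' @export
to_zero_based <- function(start, end) {
  stopifnot(all(end >= start), all(start >= 1))
  data.frame(start0 = start - 1L, end0 = end)
}

#' @rdname to_zero_based
#' @export
to_one_based <- function(start0, end0) {
  stopifnot(all(end0 > start0), all(start0 >= 0))
  data.frame(start = start0 + 1L, end = end0)
}
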