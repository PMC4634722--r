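#' Analysis configuration
#'
#' Bundles every tunable threshold of the regulon pipeline into one
#' validated object. Defaults follow common practice for bacterial
#' TF-mapping studies: genes are called differentially expressed at
#' p <= 0.05, ChIP peaks at a 5 % false discovery rate, and a binding site
#' is credited to a gene when it lies within 600 bp upstream of the gene
#' start (or, for intragenic sites, within 100 bp of the next same-strand
#' start, the operon read-through case).
#'
#' @param alpha_deg significance threshold for differential expression,
#'   in (0, 1).
#' @param peak_fdr Benjamini-Hochberg FDR threshold for peak calling,
#'   in (0, 1).
#' @param motif_width binding-site width in bp.
#' @param pseudocount added to each PWM cell before normalisation.
#' @param invariant_thresh raw column frequency at or above which a
#'   consensus position is rendered as a single letter, in (0, 1].
#' @param include_thresh minimum raw frequency for a letter to enter a
#'   degenerate consensus set, in (0, 1]; must be below `invariant_thresh`.
#' @param max_upstream_dist maximum distance (bp) from a summit or motif
#'   site to a facing gene start for the gene to be considered a target.
#' @param operon_gap maximum distance (bp) from an intragenic summit to the
#'   next same-strand gene start for that downstream gene to be added as a
#'   target.
#' @param scan_score_thresh minimum log-odds score (bits) for a reported
#'   genome-scan hit.
#' @param use_adjusted logical; use BH-adjusted p-values for the
#'   differential-expression significance call. Default `FALSE`: raw
#'   p-values keep results comparable across studies that filtered on raw
#'   p <= 0.05; the adjusted column is always emitted.
#' @param window peak-caller tiling window width in bp.
#' @param local_window span (bp) over which the local background rate is
#'   estimated; must be at least `window`.
#' @param seed integer seed used by the pipeline runner for all stochastic
#'   stages.
#' @return a list of class `"regulon_config"`.
#' @export
#' @examples
#' cfg <- analysis_config(alpha_deg = 0.01)
#' cfg$alpha_deg
analysis_config <- function(alpha_deg = 0.05,
                            peak_fdr = 0.05,
                            motif_width = 14L,
                            pseudocount = 0.5,
                            invariant_thresh = 0.99,
                            include_thresh = 0.20,
                            max_upstream_dist = 600L,
                            operon_gap = 100L,
                            scan_score_thresh = 8.0,
                            use_adjusted = FALSE,
                            window = 50L,
                            local_window = 5000L,
                            seed = 1L) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  chk(is.numeric(alpha_deg) && alpha_deg > 0 && alpha_deg < 1,
      "alpha_deg must be in (0, 1)")
  chk(is.numeric(peak_fdr) && peak_fdr > 0 && peak_fdr < 1,
      "peak_fdr must be in (0, 1)")
  chk(is.numeric(motif_width) && motif_width >= 2,
      "motif_width must be an integer >= 2")
  chk(is.numeric(pseudocount) && pseudocount >= 0,
      "pseudocount must be nonnegative")
  chk(is.numeric(invariant_thresh) && invariant_thresh > 0 &&
        invariant_thresh <= 1, "invariant_thresh must be in (0, 1]")
  chk(is.numeric(include_thresh) && include_thresh > 0 &&
        include_thresh <= 1, "include_thresh must be in (0, 1]")
  chk(include_thresh < invariant_thresh,
      "include_thresh must be below invariant_thresh")
  chk(is.numeric(max_upstream_dist) && max_upstream_dist >= 0,
      "max_upstream_dist must be >= 0")
  chk(is.numeric(operon_gap) && operon_gap >= 0, "operon_gap must be >= 0")
  chk(is.numeric(scan_score_thresh), "scan_score_thresh must be numeric")
  chk(is.logical(use_adjusted) && length(use_adjusted) == 1L,
      "use_adjusted must be TRUE or FALSE")
  chk(is.numeric(window) && window >= 1, "window must be >= 1")
  chk(is.numeric(local_window) && local_window >= window,
      "local_window must be >= window")
  chk(is.numeric(seed) && is.finite(seed), "seed must be a finite integer")
  structure(list(
    alpha_deg = as.numeric(alpha_deg),
    peak_fdr = as.numeric(peak_fdr),
    motif_width = as.integer(motif_width),
    pseudocount = as.numeric(pseudocount),
    invariant_thresh = as.numeric(invariant_thresh),
    include_thresh = as.numeric(include_thresh),
    max_upstream_dist = as.integer(max_upstream_dist),
    operon_gap = as.integer(operon_gap),
    scan_score_thresh = as.numeric(scan_score_thresh),
    use_adjusted = as.logical(use_adjusted),
    window = as.integer(window),
    local_window = as.integer(local_window),
    seed = as.integer(seed)
  ), class = "regulon_config")
}

#' @export
print.regulon_config <- function(x, ...) {
  cat("regulon analysis configuration\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read / write a configuration file
#'
#' Flat `key=value` text format, one field per line; `#` starts a comment.
#' Unknown keys raise an error so typos never silently fall back to a
#' default. Fields absent from the file keep their defaults.
#'
#' @param path file path.
#' @param config a [analysis_config()] object.
#' @return `read_config()` returns a validated `regulon_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(analysis_config())
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(parts, `[[`, "", 1L))
  vals <- trimws(vapply(parts, `[[`, "", 2L))
  defaults <- formals(analysis_config)
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- lapply(seq_along(keys), function(i) {
    if (keys[i] == "use_adjusted") as.logical(vals[i]) else as.numeric(vals[i])
  })
  names(args) <- keys
  do.call(analysis_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "regulon_config"))
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, format, "")), path)
  invisible(path)
}

#' Digest of a configuration, for run manifests
#' @param config a `regulon_config`.
#' @return md5 hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}
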