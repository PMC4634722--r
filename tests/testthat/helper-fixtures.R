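# Shared fixtures and independent oracles for the test suite.

DNA4 <- c("A", "C", "G", "T")

random_dna <- function(n, seed = NULL, prob = rep(0.25, 4)) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(DNA4, n, replace = TRUE, prob = prob), collapse = "")
}

# reverse complement written independently of the package (chartr-based)
rc_oracle <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""),
                ""))
}

# brute-force PWM scan: per-position substring scoring of both strands,
# an independent code path from scan_pwm's vectorised accumulation
oracle_scan <- function(seq, pwm, thresh, circular = FALSE,
                        background = NULL) {
  w <- pwm$width
  bg <- setNames(as.numeric(background %||% pwm$background), DNA4)
  f <- (pwm$counts + pwm$pseudocount) / (pwm$nsites + 4 * pwm$pseudocount)
  lo <- log2(sweep(f, 1, bg, "/"))
  s <- if (circular) paste0(seq, substr(seq, 1, w - 1)) else seq
  n <- nchar(s) - w + 1L
  rows <- list()
  for (i in seq_len(max(n, 0L))) {
    win <- substr(s, i, i + w - 1L)
    for (strand in c("+", "-")) {
      word <- if (strand == "+") win else rc_oracle(win)
      ch <- match(strsplit(word, "")[[1]], DNA4)
      if (anyNA(ch)) next
      sc <- sum(lo[cbind(ch, seq_len(w))])
      if (sc >= thresh) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = i, strand = strand, sequence = word, score = sc,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(position = integer(0), strand = character(0),
                      sequence = character(0), score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$position, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a set of sites realising an exact 4 x w count matrix, so PWMs
# with prescribed raw column frequencies can be constructed via build_pwm
sites_from_counts <- function(counts) {
  n <- unique(colSums(counts))
  stopifnot(length(n) == 1L)
  cols <- lapply(seq_len(ncol(counts)), function(j) {
    rep(DNA4, times = counts[, j])
  })
  vapply(seq_len(n), function(i) {
    paste(vapply(cols, `[`, "", i), collapse = "")
  }, character(1L))
}

# minimal annotation builder
make_ann <- function(start, end, strand, ids = NULL) {
  ids <- ids %||% sprintf("g%03d", seq_along(start))
  data.frame(gene_id = ids, start = start, end = end, strand = strand,
             name = ids, cog = NA_character_, stringsAsFactors = FALSE)
}

# compact simulation settings for pipeline smoke tests
small_sim <- function(...) {
  simulation_params(genome_length = 2e5, n_genes = 180L,
                    n_intergenic = 6L, n_intragenic = 2L, n_silent = 2L,
                    n_indirect = 30L, ...)
}
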