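# Position weight matrix model of the binding site: construction from
# bound sequences, degenerate consensus rendering, log-odds genome
# scanning on both strands, IUPAC pattern matching, and a Gibbs sampler
# for fixed-width motif discovery.

DNA <- c("A", "C", "G", "T")

# integer encoding A=1 C=2 G=3 T=4 N=5, anything else 0
.encode <- local({
  idx <- integer(128)
  idx[utf8ToInt("A")] <- 1L
  idx[utf8ToInt("C")] <- 2L
  idx[utf8ToInt("G")] <- 3L
  idx[utf8ToInt("T")] <- 4L
  idx[utf8ToInt("N")] <- 5L
  function(seq) idx[utf8ToInt(seq)]
})

#' Reverse complement of DNA strings
#' @param x character vector over A/C/G/T/N.
#' @return character vector.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1L), USE.NAMES = FALSE)
}

new_pwm <- function(counts, nsites, pseudocount, background) {
  stopifnot(nrow(counts) == 4L)
  rownames(counts) <- DNA
  background <- setNames(as.numeric(background), DNA)
  stopifnot(abs(sum(background) - 1) < 1e-9, all(background > 0))
  structure(list(counts = counts, nsites = nsites,
                 pseudocount = pseudocount, background = background,
                 width = ncol(counts)),
            class = "pwm")
}

#' Build a position weight matrix from aligned binding sites
#'
#' Counts letter occurrences per column; frequencies are
#' `(count + pseudocount) / (n + 4 * pseudocount)`. Raw (unsmoothed)
#' frequencies remain available via [pwm_frequencies()] and drive the
#' consensus rendering; smoothed frequencies drive log-odds scanning.
#'
#' @param sites character vector of equal-length DNA strings (A/C/G/T).
#' @param pseudocount nonnegative smoothing constant, default 0.5.
#' @param background length-4 base composition (A, C, G, T); defaults to
#'   uniform. For scanning, pass the genome's mononucleotide frequencies
#'   (see [letter_frequencies()]) — GC-biased genomes shift log-odds
#'   scores substantially.
#' @return an object of class `"pwm"`.
#' @export
#' @examples
#' p <- build_pwm(c("ACGT", "ACGA"), pseudocount = 0)
#' pwm_frequencies(p, smoothed = FALSE)
build_pwm <- function(sites, pseudocount = 0.5,
                      background = rep(0.25, 4)) {
  if (length(sites) == 0L) stop("no sites supplied", call. = FALSE)
  w <- unique(nchar(sites))
  if (length(w) != 1L) {
    stop("sites have ragged lengths: ", paste(sort(w), collapse = ", "),
         call. = FALSE)
  }
  sites <- toupper(sites)
  if (!all(strsplit(paste(sites, collapse = ""), "")[[1]] %in% DNA)) {
    stop("sites contain letters outside A/C/G/T", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  counts <- vapply(seq_len(w), function(j) {
    tabulate(match(mat[, j], DNA), nbins = 4L)
  }, numeric(4L))
  counts <- matrix(counts, nrow = 4L)
  new_pwm(counts, nsites = length(sites), pseudocount = pseudocount,
          background = background)
}

#' Column frequencies of a PWM
#' @param pwm a `"pwm"` object.
#' @param smoothed if `TRUE` (default) apply the pseudocount.
#' @return 4 x width matrix, rows A, C, G, T.
#' @export
pwm_frequencies <- function(pwm, smoothed = TRUE) {
  if (smoothed) {
    (pwm$counts + pwm$pseudocount) / (pwm$nsites + 4 * pwm$pseudocount)
  } else {
    pwm$counts / pwm$nsites
  }
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: width %d, %d sites, pseudocount %g\n",
              x$width, x$nsites, x$pseudocount))
  print(round(pwm_frequencies(x), 3))
  invisible(x)
}

#' Mononucleotide frequencies of a genome
#' @param genome a [genome_seq()].
#' @return named length-4 probability vector (A, C, G, T); N bases are
#'   ignored.
#' @export
letter_frequencies <- function(genome) {
  code <- .encode(genome$seq)
  n <- tabulate(code[code <= 4L], nbins = 4L)
  setNames(n / sum(n), DNA)
}

#' Degenerate consensus of a PWM
#'
#' A column renders as a single letter when its top raw frequency reaches
#' `invariant_thresh`; otherwise as the set of letters with raw frequency
#' at least `include_thresh`, ordered by descending frequency; and as `N`
#' when that set holds all four letters or even the top letter falls below
#' `include_thresh`.
#'
#' @param pwm a `"pwm"` object.
#' @param invariant_thresh,include_thresh see [analysis_config()].
#' @return object of class `"motif_consensus"`: a list with `sets` (one
#'   character vector per column) and `tokens` (rendered per-column
#'   strings). `format()` collapses runs of N, e.g. `(T/C/A)TGA-N6-TCAA`.
#' @export
consensus_string <- function(pwm, invariant_thresh = 0.99,
                             include_thresh = 0.20) {
  stopifnot(include_thresh < invariant_thresh)
  f <- pwm_frequencies(pwm, smoothed = FALSE)
  sets <- lapply(seq_len(pwm$width), function(j) {
    fr <- sort(f[, j], decreasing = TRUE)
    if (fr[1L] >= invariant_thresh) return(names(fr)[1L])
    keep <- names(fr)[fr >= include_thresh]
    if (length(keep) == 0L || length(keep) == 4L) return("N")
    keep
  })
  tokens <- vapply(sets, function(s) {
    if (length(s) == 1L) s else paste0("(", paste(s, collapse = "/"), ")")
  }, character(1L))
  structure(list(sets = sets, tokens = tokens),
            class = "motif_consensus")
}

#' @export
format.motif_consensus <- function(x, collapse_n = TRUE, ...) {
  if (!collapse_n) return(paste(x$tokens, collapse = ""))
  out <- character(0L)
  i <- 1L
  n <- length(x$tokens)
  while (i <= n) {
    if (x$tokens[i] == "N") {
      j <- i
      while (j < n && x$tokens[j + 1L] == "N") j <- j + 1L
      run <- j - i + 1L
      out <- c(out, if (run >= 2L) paste0("-N", run, "-") else "N")
      i <- j + 1L
    } else {
      out <- c(out, x$tokens[i])
      i <- i + 1L
    }
  }
  s <- paste(out, collapse = "")
  gsub("^-|-$", "", s)
}

#' @export
print.motif_consensus <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# log-odds score matrix (5 x w): rows A,C,G,T,N; N scores -Inf so any
# window containing N is never reported
.score_matrix <- function(pwm, background = NULL) {
  bg <- background %||% pwm$background
  bg <- setNames(as.numeric(bg), DNA)
  lo <- log2(pwm_frequencies(pwm, smoothed = TRUE) / bg)
  rbind(lo, N = rep(-Inf, pwm$width))
}

.scan_scores <- function(code, score5, n_win) {
  w <- ncol(score5)
  s <- numeric(n_win)
  for (j in seq_len(w)) {
    s <- s + score5[cbind(code[j:(j + n_win - 1L)], j)]
  }
  s
}

#' Scan a genome with a PWM on both strands
#'
#' Scores every window of width `width(pwm)` on the forward and reverse
#' strand as the sum over columns of `log2(freq / background)` (smoothed
#' frequencies). Circular genomes also score the windows spanning the
#' origin; reported positions are always the 1-based coordinate of the
#' window's leftmost base on the forward strand. Hits at or above
#' `score_thresh` are returned sorted by position, `+` before `-` at equal
#' position.
#'
#' @param genome a [genome_seq()].
#' @param pwm a `"pwm"`.
#' @param score_thresh minimum score in bits.
#' @param background optional length-4 base composition overriding the
#'   PWM's stored background.
#' @return data.frame with columns `position`, `strand`, `sequence`
#'   (motif-strand sequence, i.e. reverse-complemented for `-` hits) and
#'   `score`.
#' @export
scan_pwm <- function(genome, pwm, score_thresh, background = NULL) {
  w <- pwm$width
  L <- genome$length
  empty <- data.frame(position = integer(0), strand = character(0),
                      sequence = character(0), score = numeric(0))
  if (L < w) return(empty)
  s <- genome$seq
  if (genome$circular) s <- paste0(s, substr(s, 1L, w - 1L))
  code <- .encode(s)
  n_win <- nchar(s) - w + 1L
  fwd_m <- .score_matrix(pwm, background)
  # complement rows (A<->T, C<->G, N fixed) and reverse columns: scoring a
  # forward window with this matrix equals scoring its reverse complement
  # with the forward matrix
  rev_m <- fwd_m[c(4L, 3L, 2L, 1L, 5L), rev(seq_len(w)), drop = FALSE]
  hits <- list()
  for (str in c("+", "-")) {
    sc <- .scan_scores(code, if (str == "+") fwd_m else rev_m, n_win)
    keep <- which(sc >= score_thresh)
    if (length(keep) == 0L) next
    seqs <- substring(s, keep, keep + w - 1L)
    if (str == "-") seqs <- revcomp(seqs)
    hits[[str]] <- data.frame(position = keep, strand = str,
                              sequence = seqs, score = sc[keep],
                              stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$position, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# parse an IUPAC pattern with optional explicit sets "(T/C/A)", repeat
# counts ("N6") and cosmetic hyphens into a list of letter sets
parse_iupac_pattern <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  sets <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "-") { i <- i + 1L; next }
    if (ch == "(") {
      j <- i
      while (j <= n && chars[j] != ")") j <- j + 1L
      if (j > n) stop("unclosed '(' in pattern", call. = FALSE)
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      set <- setdiff(strsplit(inner, "/", fixed = TRUE)[[1]], "")
      if (!all(set %in% DNA)) {
        stop("explicit set may only contain A/C/G/T", call. = FALSE)
      }
      base <- list(set)
      i <- j + 1L
    } else {
      if (is.null(IUPAC_SETS[[ch]])) {
        stop("unknown IUPAC letter '", ch, "'", call. = FALSE)
      }
      base <- list(IUPAC_SETS[[ch]])
      i <- i + 1L
    }
    # optional repeat count
    rep_n <- 1L
    if (i <= n && grepl("[0-9]", chars[i])) {
      j <- i
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      rep_n <- as.integer(paste(chars[i:(j - 1L)], collapse = ""))
      i <- j
    }
    sets <- c(sets, rep(base, rep_n))
  }
  sets
}

#' Match a sequence against a degenerate IUPAC pattern
#'
#' @param seq DNA string, same length as the expanded pattern.
#' @param pattern IUPAC pattern; explicit sets like `(T/C/A)`, repeat
#'   counts like `N6` and hyphens are accepted, so both
#'   `"NTGNNNNNNNNCAA"` and `"(T/C/A)TGA-N6-TCAA"` work.
#' @return `TRUE` when every position's letter is in the pattern's set.
#' @export
match_iupac <- function(seq, pattern) {
  sets <- parse_iupac_pattern(pattern)
  seq <- toupper(seq)
  if (nchar(seq) != length(sets)) {
    stop("sequence length ", nchar(seq), " does not match pattern length ",
         length(sets), call. = FALSE)
  }
  letters_seq <- strsplit(seq, "", fixed = TRUE)[[1]]
  all(mapply(function(l, s) l %in% s, letters_seq, sets))
}

#' Scan a genome for IUPAC pattern matches on both strands
#'
#' A `-` strand hit at position `p` means the reverse complement of the
#' forward-strand window starting at `p` matches the pattern. Circular
#' genomes include origin-spanning windows.
#'
#' @inheritParams scan_pwm
#' @param pattern as in [match_iupac()].
#' @return data.frame with columns `position`, `strand`, `sequence`.
#' @export
scan_iupac <- function(genome, pattern) {
  sets <- parse_iupac_pattern(pattern)
  w <- length(sets)
  L <- genome$length
  empty <- data.frame(position = integer(0), strand = character(0),
                      sequence = character(0))
  if (L < w) return(empty)
  s <- genome$seq
  if (genome$circular) s <- paste0(s, substr(s, 1L, w - 1L))
  as_rx <- function(ss) {
    paste0(vapply(ss, function(x) paste0("[", paste(x, collapse = ""), "]"),
                  character(1L)), collapse = "")
  }
  find <- function(rx) {
    m <- gregexpr(paste0("(?=", rx, ")"), s, perl = TRUE)[[1]]
    if (m[1L] == -1L) integer(0) else as.integer(m)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_sets <- rev(lapply(sets, function(x) unname(comp[x])))
  hits <- list()
  pos_f <- find(as_rx(sets))
  if (length(pos_f) > 0L) {
    hits$f <- data.frame(position = pos_f, strand = "+",
                         sequence = substring(s, pos_f, pos_f + w - 1L),
                         stringsAsFactors = FALSE)
  }
  pos_r <- find(as_rx(rc_sets))
  if (length(pos_r) > 0L) {
    hits$r <- data.frame(position = pos_r, strand = "-",
                         sequence = revcomp(substring(s, pos_r,
                                                      pos_r + w - 1L)),
                         stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out <- out[out$position <= L, , drop = FALSE]
  out <- out[order(out$position, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Information content of a PWM
#'
#' Per column `sum_b f_b * log2(f_b / bg_b)`; with a uniform background
#' this is the familiar `2 + sum_b f_b log2 f_b` bits that sets letter
#' heights in sequence logos.
#'
#' @param pwm a `"pwm"`.
#' @param background optional length-4 composition; defaults to the PWM's
#'   stored background.
#' @return list with `per_column` (numeric vector) and `total`.
#' @export
information_content <- function(pwm, background = NULL) {
  bg <- setNames(as.numeric(background %||% pwm$background), DNA)
  f <- pwm_frequencies(pwm, smoothed = TRUE)
  term <- ifelse(f > 0, f * log2(f / bg), 0)
  per_col <- colSums(term)
  list(per_column = unname(per_col), total = sum(per_col))
}

#' Gibbs-sampling motif discovery (one occurrence per sequence)
#'
#' Fixed-width finder in the classic Lawrence et al. style: each sequence
#' contributes exactly one site; positions are resampled in turn from the
#' predictive distribution given the model built from the other sequences;
#' the best model over random restarts, judged by total information
#' content, is polished with deterministic argmax passes (ties break to
#' the lowest offset) and returned. Reproducible under `seed`.
#'
#' @param sequences character vector (>= 5) of DNA strings, each at least
#'   `width` long.
#' @param width motif width.
#' @param n_restarts independent random restarts.
#' @param iterations Gibbs sweeps per restart.
#' @param pseudocount smoothing for the sampled model.
#' @param background optional base composition; defaults to the pooled
#'   letter frequencies of `sequences`.
#' @param both_strands also consider the reverse complement of each
#'   window; needed when input regions carry the site in unknown
#'   orientation (e.g. ChIP peak regions). Default `FALSE`.
#' @param seed integer seed.
#' @return list with elements `pwm`, `positions` (chosen 1-based start
#'   per sequence), `strands`, and `score` (total information content).
#' @export
discover_motif <- function(sequences, width, n_restarts = 5L,
                           iterations = 100L, pseudocount = 0.5,
                           background = NULL, both_strands = FALSE,
                           seed = 1L) {
  if (length(sequences) < 5L) {
    stop("need at least 5 sequences", call. = FALSE)
  }
  if (any(nchar(sequences) < width)) {
    stop("sequence(s) shorter than the motif width", call. = FALSE)
  }
  sequences <- toupper(sequences)
  if (is.null(background)) {
    code_all <- .encode(paste(sequences, collapse = ""))
    cnt <- tabulate(code_all[code_all <= 4L], nbins = 4L)
    background <- (cnt + 1) / sum(cnt + 1)
  }
  background <- setNames(as.numeric(background), DNA)
  ns <- length(sequences)
  codes <- lapply(sequences, .encode)
  # complement: A(1)<->T(4), C(2)<->G(3): 5 - x; N(5) stays 5
  rc_codes <- lapply(codes, function(x) {
    y <- ifelse(x <= 4L, 5L - x, 5L)
    rev(y)
  })
  n_win <- nchar(sequences) - width + 1L

  count_at <- function(pos, strand, excl) {
    counts <- matrix(0, nrow = 4L, ncol = width)
    for (i in seq_len(ns)) {
      if (i == excl) next
      cd <- if (strand[i] == "+") codes[[i]] else rc_codes[[i]]
      p <- if (strand[i] == "+") pos[i] else
        nchar(sequences[i]) - (pos[i] + width - 1L) + 1L
      win <- cd[p:(p + width - 1L)]
      ok <- win <= 4L
      counts[cbind(win[ok], seq_len(width)[ok])] <-
        counts[cbind(win[ok], seq_len(width)[ok])] + 1
    }
    counts
  }
  model_scores <- function(counts, n_used, code_i) {
    f <- (counts + pseudocount) / (n_used + 4 * pseudocount)
    sm <- rbind(log2(f / background), rep(-Inf, width))
    nw <- length(code_i) - width + 1L
    .scan_scores(code_i, sm, nw)
  }
  ic_of <- function(pos, strand) {
    counts <- count_at(pos, strand, excl = 0L)
    f <- (counts + pseudocount) / (ns + 4 * pseudocount)
    sum(ifelse(f > 0, f * log2(f / background), 0))
  }

  set.seed(as.integer(seed) %% .Machine$integer.max)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    pos <- vapply(n_win, function(m) sample.int(m, 1L), integer(1L))
    strand <- rep("+", ns)
    for (it in seq_len(iterations)) {
      for (i in seq_len(ns)) {
        counts <- count_at(pos, strand, excl = i)
        sc_f <- model_scores(counts, ns - 1L, codes[[i]])
        sc <- sc_f
        str_choice <- rep("+", length(sc_f))
        if (both_strands) {
          sc_r <- model_scores(counts, ns - 1L, rc_codes[[i]])
          sc <- c(sc_f, sc_r)
          str_choice <- c(str_choice, rep("-", length(sc_r)))
        }
        wgt <- 2^(sc - max(sc[is.finite(sc)]))
        wgt[!is.finite(wgt)] <- 0
        k <- sample.int(length(wgt), 1L, prob = wgt)
        strand[i] <- str_choice[k]
        p <- if (k > length(sc_f)) k - length(sc_f) else k
        pos[i] <- if (strand[i] == "+") p else
          nchar(sequences[i]) - (p + width - 1L) + 1L
      }
    }
    # deterministic polish: argmax per sequence until stable, alternated
    # with whole-alignment phase shifts (the classic fix for the sampler
    # converging to a frame offset by a base or two)
    polish <- function(pos, strand) {
      for (pass in 1:5) {
        changed <- FALSE
        for (i in seq_len(ns)) {
          counts <- count_at(pos, strand, excl = i)
          sc_f <- model_scores(counts, ns - 1L, codes[[i]])
          best_f <- which.max(sc_f)
          p_new <- best_f; s_new <- "+"
          if (both_strands) {
            sc_r <- model_scores(counts, ns - 1L, rc_codes[[i]])
            if (max(sc_r) > sc_f[best_f]) {
              rp <- which.max(sc_r)
              p_new <- nchar(sequences[i]) - (rp + width - 1L) + 1L
              s_new <- "-"
            }
          }
          if (p_new != pos[i] || s_new != strand[i]) {
            pos[i] <- p_new; strand[i] <- s_new; changed <- TRUE
          }
        }
        if (!changed) break
      }
      list(pos = pos, strand = strand)
    }
    phase_shift <- function(pos, strand) {
      repeat {
        cur <- ic_of(pos, strand)
        moved <- FALSE
        for (delta in c(-3L, -2L, -1L, 1L, 2L, 3L)) {
          np <- ifelse(strand == "+", pos + delta, pos - delta)
          if (all(np >= 1L & np <= n_win)) {
            val <- ic_of(np, strand)
            if (val > cur + 1e-9) {
              pos <- np; cur <- val; moved <- TRUE
            }
          }
        }
        if (!moved) break
      }
      list(pos = pos, strand = strand)
    }
    for (round in 1:2) {
      st <- polish(pos, strand)
      st <- phase_shift(st$pos, st$strand)
      pos <- st$pos; strand <- st$strand
    }
    # canonicalise exact ties to the lowest offset: drift the whole frame
    # left while the information content does not drop (periodic or
    # identical inputs otherwise settle at an arbitrary common offset)
    repeat {
      np <- ifelse(strand == "+", pos - 1L, pos + 1L)
      if (all(np >= 1L & np <= n_win) &&
          ic_of(np, strand) >= ic_of(pos, strand) - 1e-9) {
        pos <- np
      } else break
    }
    score <- ic_of(pos, strand)
    if (is.null(best) || score > best$score + 1e-12) {
      best <- list(pos = pos, strand = strand, score = score)
    }
  }
  site_seq <- vapply(seq_len(ns), function(i) {
    win <- substring(sequences[i], best$pos[i], best$pos[i] + width - 1L)
    if (best$strand[i] == "-") revcomp(win) else win
  }, character(1L))
  pwm <- build_pwm(site_seq, pseudocount = pseudocount,
                   background = background)
  list(pwm = pwm, positions = best$pos, strands = best$strand,
       sites = site_seq, score = best$score)
}

#' Extract sequence regions around peak summits
#'
#' Returns the genomic sequence from `flank` bp left of each summit to
#' `flank` bp right of it (length `2 * flank + 1`), wrapping across the
#' origin on circular genomes. These regions feed motif discovery; the
#' single best-scoring window per region is the peak's site under the
#' one-occurrence assumption.
#'
#' @param genome a [genome_seq()].
#' @param peaks peak data.frame with a `summit` column.
#' @param flank bp on each side of the summit.
#' @return character vector, one region per peak.
#' @export
extract_peak_regions <- function(genome, peaks, flank) {
  L <- genome$length
  vapply(peaks$summit, function(sm) {
    idx <- (sm - flank):(sm + flank)
    if (genome$circular) {
      idx <- ((idx - 1L) %% L) + 1L
      paste(substring(genome$seq, idx, idx), collapse = "")
    } else {
      idx <- idx[idx >= 1L & idx <= L]
      substr(genome$seq, min(idx), max(idx))
    }
  }, character(1L))
}
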