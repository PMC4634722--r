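# PWM construction, consensus rendering, log-odds scanning, IUPAC
# matching and Gibbs motif discovery.

test_that("PWM counts and pseudocount smoothing follow the stated arithmetic", {
  p0 <- build_pwm("AAAAAAAAAAAAAA", pseudocount = 0)
  expect_equal(unname(pwm_frequencies(p0)["A", ]), rep(1, 14))

  p <- build_pwm(c("ACGT", "ACGA"), pseudocount = 0.5)
  f <- pwm_frequencies(p)
  expect_equal(unname(f["A", 1]), 2.5 / 4)     # (2 + 0.5) / (2 + 4 * 0.5)
  expect_equal(unname(f["C", 1]), 0.5 / 4)
  expect_equal(unname(f["T", 4]), 1.5 / 4)
  expect_equal(unname(colSums(f)), rep(1, 4), tolerance = 1e-9)

  expect_error(build_pwm(c("ACGT", "ACG")), "ragged")
  expect_error(build_pwm(character(0)), "no sites")
  expect_error(build_pwm("ACGX"), "outside")
})

test_that("degenerate consensus renders invariant, set and N columns", {
  counts <- cbind(c(24, 34, 5, 37),     # (T/C/A): T 37, C 34, A 24
                  c(0, 0, 0, 100),      # invariant T
                  c(90, 4, 3, 3),       # A at 0.90
                  c(25, 25, 25, 25))    # uniform
  p <- build_pwm(sites_from_counts(counts), pseudocount = 0.5)
  cons <- consensus_string(p, invariant_thresh = 0.99,
                           include_thresh = 0.20)
  expect_equal(cons$sets[[1]], c("T", "C", "A"))  # descending frequency
  expect_equal(cons$tokens[1], "(T/C/A)")
  expect_equal(cons$tokens[2], "T")
  expect_equal(cons$tokens[4], "N")
  # position with a 0.90 top letter renders single once the threshold allows
  cons90 <- consensus_string(p, invariant_thresh = 0.90,
                             include_thresh = 0.20)
  expect_equal(cons90$tokens[3], "A")
  # N runs collapse in the formatted string
  counts2 <- cbind(c(0, 0, 0, 100), matrix(25, 4, 3), c(100, 0, 0, 0))
  p2 <- build_pwm(sites_from_counts(counts2), pseudocount = 0.5)
  expect_equal(format(consensus_string(p2, 0.99, 0.2)), "T-N3-A")
})

test_that("information content matches closed forms", {
  ind <- build_pwm("A", pseudocount = 0)
  expect_equal(information_content(ind)$per_column, 2)
  unif <- build_pwm(sites_from_counts(cbind(c(1, 1, 1, 1))),
                    pseudocount = 0)
  expect_equal(information_content(unif)$per_column, 0)
  f <- c(0.9, 0.033, 0.033, 0.034)
  skew <- build_pwm(sites_from_counts(cbind(f * 1000)), pseudocount = 0)
  oracle <- sum(f * log2(f / 0.25))
  expect_equal(information_content(skew)$total, oracle, tolerance = 1e-12)
})

test_that("scan_pwm equals brute-force enumeration and honours thresholds", {
  set.seed(77)
  for (k in 1:10) {
    w <- sample(4:10, 1)
    n <- sample(150:600, 1)
    pwm <- build_pwm(replicate(6, random_dna(w)), pseudocount = 0.5)
    g <- genome_seq("t", random_dna(n), circular = (k %% 2 == 0))
    thresh <- runif(1, -3, 3)
    got <- scan_pwm(g, pwm, thresh)
    exp <- oracle_scan(g$seq, pwm, thresh, circular = g$circular)
    expect_equal(got$position, exp$position)
    expect_equal(got$strand, exp$strand)
    expect_equal(got$sequence, exp$sequence)
    expect_equal(got$score, exp$score, tolerance = 1e-9)
  }
  g <- genome_seq("t", random_dna(500, seed = 1), circular = FALSE)
  pwm <- build_pwm(replicate(6, random_dna(6)), pseudocount = 0.5)
  expect_equal(nrow(scan_pwm(g, pwm, Inf)), 0L)
})

test_that("a planted top-scoring word is reported with the closed-form maximal score", {
  counts <- cbind(c(50, 2, 2, 2), c(2, 50, 2, 2), c(2, 2, 50, 2),
                  c(2, 2, 2, 50), c(50, 2, 2, 2))
  pwm <- build_pwm(sites_from_counts(counts), pseudocount = 0.5)
  f <- pwm_frequencies(pwm)
  top <- sum(log2(apply(f, 2, max) / 0.25))
  word <- "ACGTA"
  g <- genome_seq("t", paste0(random_dna(200, seed = 3), word,
                              random_dna(200)), circular = FALSE)
  hits <- scan_pwm(g, pwm, top - 1e-9)
  expect_true(any(hits$position == 201 & hits$strand == "+"))
  expect_equal(hits$score[hits$position == 201 & hits$strand == "+"], top,
               tolerance = 1e-12)
})

test_that("circular genomes report origin-spanning hits, linear genomes do not", {
  word <- "ACGTACGT"
  pwm <- build_pwm(word, pseudocount = 0.1)
  body <- random_dna(200, seed = 12)
  # place the word across the origin: last 5 bases at the end, first 3 wrap
  s <- paste0(substr(word, 4, 8), body, substr(word, 1, 3))
  gc <- genome_seq("c", s, circular = TRUE)
  gl <- genome_seq("l", s, circular = FALSE)
  th <- 10
  hc <- scan_pwm(gc, pwm, th)
  expect_true((nchar(s) - 2) %in% hc$position)  # word starts 3 bases from end
  hl <- scan_pwm(gl, pwm, th)
  expect_false((nchar(s) - 2) %in% hl$position)
})

test_that("scanning is strand-symmetric under reverse complement of the genome", {
  g <- genome_seq("t", random_dna(400, seed = 5), circular = FALSE)
  pwm <- build_pwm(replicate(8, random_dna(7)), pseudocount = 0.5)
  a <- scan_pwm(g, pwm, 0.5)
  g_rc <- genome_seq("t", rc_oracle(g$seq), circular = FALSE)
  b <- scan_pwm(g_rc, pwm, 0.5)
  # a hit at p on strand s maps to L - (p + w - 1) + 1 on the other strand
  L <- g$length; w <- pwm$width
  mapped <- data.frame(position = L - (b$position + w - 1L) + 1L,
                       strand = ifelse(b$strand == "+", "-", "+"),
                       score = b$score)
  mapped <- mapped[order(mapped$position,
                         match(mapped$strand, c("+", "-"))), ]
  expect_equal(mapped$position, a$position)
  expect_equal(mapped$strand, a$strand)
  expect_equal(mapped$score, a$score, tolerance = 1e-9)
})

test_that("IUPAC matching accepts the FNR-type core and rejects a final-position mismatch", {
  expect_true(match_iupac("TTGATCAAGGTCAA", "NTGNNNNNNNNCAA"))
  expect_false(match_iupac("ATGATCCAAGTCAT", "NTGNNNNNNNNCAA"))
  expect_true(match_iupac("TTGATCAAGGTCAA", "(T/C/A)TGA-N6-TCAA"))
  expect_true(match_iupac("ATGCTCGAGTTCAA", "NTGN8CAA"))  # repeat counts
  expect_error(match_iupac("ACGT", "NTGNNNNNNNNCAA"), "length")

  g <- genome_seq("t", paste0(random_dna(50, seed = 2),
                              rc_oracle("TTGATCAAGGTCAA"),
                              random_dna(50)), circular = FALSE)
  hits <- scan_iupac(g, "TTGATCAAGGTCAA")
  expect_true(any(hits$strand == "-" & hits$position == 51))
  expect_equal(hits$sequence[hits$position == 51], "TTGATCAAGGTCAA")
})

test_that("Gibbs discovery recovers a planted word and is deterministic", {
  word <- "TTGACGATCAAG"
  ok <- 0L
  for (sd in 1:20) {
    set.seed(1000 + sd)
    seqs <- vapply(1:20, function(i) {
      s <- random_dna(100)
      p <- sample.int(100 - nchar(word) + 1L, 1)
      substr(s, p, p + nchar(word) - 1L) <- word
      s
    }, character(1))
    dm <- discover_motif(seqs, nchar(word), n_restarts = 3L,
                         iterations = 60L, seed = sd)
    f <- pwm_frequencies(dm$pwm, smoothed = FALSE)
    strict <- paste(rownames(f)[apply(f, 2, which.max)], collapse = "")
    if (strict == word) ok <- ok + 1L
  }
  expect_gte(ok, 18L)

  # identical sequences under a uniform background: every offset ties in
  # information content, and the tie canonicalises to the lowest offset
  seqs <- rep(paste0("ACGTT", random_dna(30, seed = 3)), 6)
  dm <- discover_motif(seqs, 8L, n_restarts = 2L, iterations = 20L,
                       background = rep(0.25, 4), seed = 2)
  expect_true(all(dm$positions == 1L))
  # the aligned columns are then single-letter: per-column IC at its
  # pseudocount-smoothed maximum
  f_top <- (6 + 0.5) / (6 + 2)
  f_off <- 0.5 / (6 + 2)
  ic_max <- f_top * log2(f_top / 0.25) + 3 * f_off * log2(f_off / 0.25)
  expect_equal(information_content(dm$pwm, rep(0.25, 4))$total,
               8 * ic_max, tolerance = 1e-9)

  seqs2 <- replicate(8, random_dna(60))
  d1 <- discover_motif(seqs2, 6L, seed = 9)
  d2 <- discover_motif(seqs2, 6L, seed = 9)
  expect_identical(d1$positions, d2$positions)
  expect_identical(d1$pwm$counts, d2$pwm$counts)

  expect_error(discover_motif(c("ACGT", "ACGT"), 4L), "at least 5")
  expect_error(discover_motif(replicate(6, random_dna(5)), 10L),
               "shorter")
})
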