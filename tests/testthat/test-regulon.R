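# Evidence integration: categories, peak productivity flags, summaries
# and COG tallies.

# fixture: five genes on a 10 kb linear genome, one upstream peak on a
# significant gene, one peak whose only neighbour is unaffected, one
# motif-scan site upstream of a significant gene without a peak
regulon_fixture <- function(alpha = 0.05, max_up = 600L,
                            scan_pos = 2330L) {
  ann <- make_ann(c(1000L, 2500L, 4000L, 6000L, 8000L),
                  c(2000L, 3500L, 5000L, 7000L, 9000L),
                  c("+", "+", "+", "+", "+"),
                  ids = c("gA", "gB", "gC", "gD", "gE"))
  peaks <- data.frame(id = c("peak_001", "peak_002"),
                      summit = c(850L, 5900L), stringsAsFactors = FALSE)
  loc <- classify_location(peaks, ann, 10000L, max_up, 100L,
                           circular = FALSE)
  scan_sites <- data.frame(position = scan_pos, strand = "+",
                           sequence = "TTGATCAAGGTCAA", score = 12,
                           stringsAsFactors = FALSE)
  deg <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD", "gE"),
    base_mean = rep(100, 5),
    log2fc = c(1.55, -2.1, 2.0, 0.3, -0.1),
    pvalue = c(0.01, 0.001, 0.02, 0.5, 0.9),
    padj = c(0.03, 0.005, 0.04, 0.7, 0.95),
    stringsAsFactors = FALSE)
  cfg <- analysis_config(alpha_deg = alpha, max_upstream_dist = max_up)
  list(ann = ann, loc = loc, scan = scan_sites, deg = deg, cfg = cfg)
}

test_that("categories, flags and peak productivity follow the evidence rules", {
  fx <- regulon_fixture()
  out <- integrate_regulon(fx$loc, fx$scan, fx$deg, fx$ann, 10000L,
                           fx$cfg, circular = FALSE)
  a <- out$assignments
  get <- function(g, col) a[[col]][a$gene_id == g]
  # upstream peak + significant activation: direct, promoter flag
  expect_equal(get("gA", "category"), "direct")
  expect_equal(get("gA", "regulation"), "activated")
  expect_equal(get("gA", "location_flags"), "b")
  expect_equal(get("gA", "evidence_peaks"), "peak_001")
  # scan site 170 bp upstream of gB (start 2500), significant, no peak
  expect_equal(get("gB", "category"), "scan_candidate")
  expect_equal(get("gB", "regulation"), "repressed")
  expect_equal(get("gB", "location_flags"), "b")
  # significant without any binding evidence: indirect
  expect_equal(get("gC", "category"), "indirect")
  # peak_002 neighbours only gD (not significant): gene none, peak silent
  expect_equal(get("gD", "category"), "none")
  expect_false(out$peak_flags$productive[
    out$peak_flags$peak_id == "peak_002"])
  expect_true(out$peak_flags$productive[
    out$peak_flags$peak_id == "peak_001"])
  # compatibility fold-in
  out2 <- integrate_regulon(fx$loc, fx$scan, fx$deg, fx$ann, 10000L,
                            fx$cfg, circular = FALSE,
                            fold_scan_into_indirect = TRUE)
  expect_equal(out2$assignments$category[
    out2$assignments$gene_id == "gB"], "indirect")
  expect_equal(out2$assignments$evidence_sites[
    out2$assignments$gene_id == "gB"],
    a$evidence_sites[a$gene_id == "gB"])
})

test_that("an intragenic scan site flags 'a' and peak evidence dominates scan evidence", {
  fx <- regulon_fixture(scan_pos = 2700L)   # inside gB's body
  out <- integrate_regulon(fx$loc, fx$scan, fx$deg, fx$ann, 10000L,
                           fx$cfg, circular = FALSE)
  a <- out$assignments
  expect_equal(a$location_flags[a$gene_id == "gB"], "a")
  # give gA a scan site too: still direct (peak dominates), flags from peak
  scan2 <- rbind(fx$scan,
                 data.frame(position = 700L, strand = "+",
                            sequence = "TTGATCAAGGTCAA", score = 10))
  out2 <- integrate_regulon(fx$loc, scan2, fx$deg, fx$ann, 10000L,
                            fx$cfg, circular = FALSE)
  expect_equal(out2$assignments$category[
    out2$assignments$gene_id == "gA"], "direct")
})

test_that("summaries count the partition and COG tallies conserve totals", {
  fx <- regulon_fixture()
  out <- integrate_regulon(fx$loc, fx$scan, fx$deg, fx$ann, 10000L,
                           fx$cfg, circular = FALSE)
  s <- summarize_regulon(out$assignments, out$peak_flags)
  expect_equal(s$n_direct, 1L)
  expect_equal(s$n_scan_candidate, 1L)
  expect_equal(s$n_indirect, 1L)
  expect_equal(s$n_silent, 1L)
  # partition identity: every significant gene is in exactly one category
  expect_equal(s$n_direct + s$n_scan_candidate + s$n_indirect,
               s$n_significant)
  expect_equal(s$n_productive + s$n_silent, s$n_peaks)

  cogs <- data.frame(gene_id = c("gA", "gB"), cog = c("C", "C"),
                     stringsAsFactors = FALSE)
  ct <- cog_summary(out$assignments, cogs)
  expect_equal(ct$activated[ct$cog == "C"], 1L)
  expect_equal(ct$repressed[ct$cog == "C"], 1L)
  # unmapped significant gene lands in the S bucket
  expect_equal(ct$total[ct$cog == "S"], 1L)
  expect_equal(sum(ct$total), s$n_significant)

  empty <- integrate_regulon(fx$loc[0, ], fx$scan[0, ], fx$deg[0, ],
                             fx$ann, 10000L, fx$cfg, circular = FALSE)
  s0 <- summarize_regulon(empty$assignments, empty$peak_flags)
  expect_equal(s0$n_significant + s0$n_direct + s0$n_peaks, 0L)
})

test_that("assignments are invariant to input row order and monotone in thresholds", {
  fx <- regulon_fixture()
  base <- integrate_regulon(fx$loc, fx$scan, fx$deg, fx$ann, 10000L,
                            fx$cfg, circular = FALSE)
  perm <- integrate_regulon(fx$loc[rev(seq_len(nrow(fx$loc))), ],
                            fx$scan, fx$deg[sample(5), ], fx$ann,
                            10000L, fx$cfg, circular = FALSE)
  expect_equal(perm$assignments, base$assignments)

  # shrinking alpha never grows the direct set
  direct_at <- function(alpha) {
    fx2 <- regulon_fixture(alpha = alpha)
    out <- integrate_regulon(fx2$loc, fx2$scan, fx2$deg, fx2$ann, 10000L,
                             fx2$cfg, circular = FALSE)
    out$assignments$gene_id[out$assignments$category == "direct"]
  }
  expect_true(all(direct_at(0.001) %in% direct_at(0.05)))
  # enlarging max_upstream_dist never shrinks it
  direct_dist <- function(d) {
    fx2 <- regulon_fixture(max_up = d)
    out <- integrate_regulon(fx2$loc, fx2$scan, fx2$deg, fx2$ann, 10000L,
                             fx2$cfg, circular = FALSE)
    out$assignments$gene_id[out$assignments$category == "direct"]
  }
  expect_true(all(direct_dist(100L) %in% direct_dist(600L)))

  # DEG ids missing from the annotation warn but are kept
  deg2 <- rbind(fx$deg,
                data.frame(gene_id = "ghost", base_mean = 50,
                           log2fc = 3, pvalue = 0.001, padj = 0.01))
  expect_warning(
    out <- integrate_regulon(fx$loc, fx$scan, deg2, fx$ann, 10000L,
                             fx$cfg, circular = FALSE),
    "absent from the annotation")
  expect_equal(out$assignments$category[
    out$assignments$gene_id == "ghost"], "indirect")
})
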