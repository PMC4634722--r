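# Generators: genome, annotation packing, site planting, ChIP coverage
# and count matrices, each checked against its stated generative model.

test_that("simulated genomes are seed-deterministic with the requested composition", {
  g1 <- simulate_genome(10000, 0.5, seed = 1)
  g2 <- simulate_genome(10000, 0.5, seed = 1)
  expect_identical(g1$seq, g2$seq)
  expect_true(g1$circular)

  gc1 <- simulate_genome(2000, 1.0, seed = 2)
  expect_true(all(strsplit(gc1$seq, "")[[1]] %in% c("G", "C")))

  # observed GC within 3 binomial standard deviations of the target
  n <- 100000
  g <- simulate_genome(n, 0.66, seed = 3)
  gc_obs <- sum(strsplit(g$seq, "")[[1]] %in% c("G", "C")) / n
  sd3 <- 3 * sqrt(0.66 * 0.34 / n)
  expect_lt(abs(gc_obs - 0.66), sd3)
})

test_that("annotation packing hits the intergenic target with sorted, non-overlapping genes", {
  g <- simulate_genome(2e6, 0.66, seed = 5)
  ann <- simulate_annotation(g, 1800L, 1000L, 0.0919, seed = 5)
  expect_equal(nrow(ann), 1800L)
  frac <- intergenic_fraction(ann, g$length)
  expect_gt(frac, 0.082)
  expect_lt(frac, 0.102)
  expect_true(all(diff(ann$start) > 0))
  expect_true(all(ann$start[-1] > ann$end[-nrow(ann)]))  # non-overlapping
  # at least one divergently transcribed (head-to-head) pair
  expect_true(any(ann$strand[-nrow(ann)] == "-" & ann$strand[-1] == "+"))

  expect_error(simulate_annotation(g, 5000L, 1000L, 0.5, seed = 1),
               "infeasible")
  none <- simulate_annotation(g, 0L, 1000L, 1.0, seed = 1)
  expect_equal(intergenic_fraction(none, g$length), 1)
})

test_that("planted sites are written into the genome, carry targets, and rediscoverable by consensus scan", {
  g <- simulate_genome(2e5, 0.5, seed = 11)
  ann <- simulate_annotation(g, 180L, 1000L, 0.0919, seed = 11)
  # indicator model: every sampled site is exactly this word
  word <- "TTGATCGGGATCAA"
  pwm <- build_pwm(word, pseudocount = 0.5)
  pl <- plant_sites(g, ann, pwm, n_intergenic = 5L, n_intragenic = 2L,
                    n_silent = 1L, n_indirect = 10L, seed = 11)
  tr <- pl$truth
  expect_equal(sum(tr$planted_sites$kind == "intergenic"), 5L)
  expect_equal(sum(tr$planted_sites$kind == "intragenic"), 2L)
  expect_equal(length(tr$silent_sites), 1L)
  non_silent <- tr$planted_sites[tr$planted_sites$kind != "silent", ]
  expect_true(all(nzchar(non_silent$target_gene_ids)))
  expect_true(all(nchar(tr$planted_sites$sequence) == 14L))
  # direct and indirect sets are disjoint; every direct gene has a site
  expect_length(intersect(tr$direct_genes$gene_id,
                          tr$indirect_genes$gene_id), 0L)
  targets <- unique(unlist(strsplit(non_silent$target_gene_ids, ";")))
  expect_setequal(tr$direct_genes$gene_id, targets)
  # sites are physically on the genome (motif strand sequence)
  for (i in seq_len(nrow(tr$planted_sites))) {
    s <- tr$planted_sites[i, ]
    on_genome <- substr(pl$genome$seq, s$position, s$position + 13L)
    expect_equal(if (s$strand == "-") rc_oracle(on_genome) else on_genome,
                 s$sequence)
  }
  # consensus scan of the planted genome finds at least the planted count
  hits <- scan_iupac(pl$genome, word)
  expect_gte(nrow(hits), nrow(tr$planted_sites))
  expect_true(all(tr$planted_sites$position %in% hits$position))
  # seed determinism
  pl2 <- plant_sites(g, ann, pwm, n_intergenic = 5L, n_intragenic = 2L,
                     n_silent = 1L, n_indirect = 10L, seed = 11)
  expect_identical(pl2$truth$planted_sites, tr$planted_sites)
  expect_identical(pl2$genome$seq, pl$genome$seq)
})

test_that("silent sites avoid genes that non-silent sites target", {
  g <- simulate_genome(5e5, 0.5, seed = 21)
  ann <- simulate_annotation(g, 450L, 1000L, 0.0919, seed = 21)
  pl <- plant_sites(g, ann, fnr_site_pwm(), n_intergenic = 10L,
                    n_intragenic = 4L, n_silent = 3L, n_indirect = 40L,
                    seed = 21)
  tr <- pl$truth
  expect_length(intersect(tr$silent_host_genes,
                          tr$direct_genes$gene_id), 0L)
  expect_length(intersect(tr$silent_host_genes,
                          tr$indirect_genes$gene_id), 0L)
})

test_that("ChIP coverage matches its generative model at site centres", {
  g <- simulate_genome(20000, 0.5, seed = 31)
  ann <- simulate_annotation(g, 15L, 1000L, 0.2, seed = 31)
  pl <- plant_sites(g, ann, fnr_site_pwm(), n_intergenic = 1L,
                    n_intragenic = 0L, n_silent = 0L, n_indirect = 0L,
                    seed = 31)
  center <- pl$truth$planted_sites$position[1] + 7L
  # fixed 25x enrichment over background 10: mean IP at the centre over
  # 50 replicates must sit in [200, 300] (the generative mean is 250)
  vals <- vapply(1:50, function(s) {
    cov <- simulate_chip(pl$genome, pl$truth, depth_bg = 10,
                         enrich_range = c(25, 25), frag_len = 200L,
                         seed = s)
    cov$ip[center]
  }, numeric(1))
  expect_gt(mean(vals), 200)
  expect_lt(mean(vals), 300)
  # without sites, IP and input are exchangeable in distribution
  no_truth <- pl$truth
  no_truth$planted_sites <- no_truth$planted_sites[0, ]
  cov0 <- simulate_chip(pl$genome, no_truth, depth_bg = 10, seed = 1)
  expect_lt(abs(mean(cov0$ip) - mean(cov0$input)), 0.2)
  # determinism
  c1 <- simulate_chip(pl$genome, pl$truth, seed = 5)
  c2 <- simulate_chip(pl$genome, pl$truth, seed = 5)
  expect_identical(c1$ip, c2$ip)
})

test_that("count matrices follow the negative-binomial model and the fold-change convention", {
  ann <- make_ann(c(1L, 2001L, 4001L), c(1500L, 3500L, 5500L),
                  c("+", "-", "+"), ids = c("gA", "gB", "gC"))
  truth <- list(
    planted_sites = data.frame(),
    direct_genes = data.frame(gene_id = "gA", log2fc = 2,
                              stringsAsFactors = FALSE),
    indirect_genes = data.frame(gene_id = character(0),
                                log2fc = numeric(0)),
    silent_sites = integer(0), silent_host_genes = character(0))
  cnt <- simulate_counts(ann, truth, n_reps = 200L, dispersion = 0.05,
                         seed = 7)
  sf_wt <- cnt$size_factors[1:200]
  sf_mut <- cnt$size_factors[201:400]
  # NB mean oracle: E[count_gr] = mu_g * 2^lfc * sf_r
  wt_norm <- mean(cnt$wt["gA", ] / sf_wt)
  mut_norm <- mean(cnt$mut["gA", ] / sf_mut)
  expect_equal(wt_norm / mut_norm, 4, tolerance = 0.15)
  expect_gt(wt_norm, mut_norm)      # positive log2FC = higher in wild type
  # null genes: group means equal in expectation
  expect_equal(mean(cnt$wt["gB", ] / sf_wt) / mean(cnt$mut["gB", ] / sf_mut),
               1, tolerance = 0.15)
  # Poisson limit: dispersion -> 0 gives variance ~ mean
  cnt2 <- simulate_counts(ann, truth, n_reps = 500L, dispersion = 1e-6,
                          seed = 8)
  y <- cnt2$mut["gB", ] / cnt2$size_factors[501:1000]
  # var(count/sf) = mu/sf under Poisson; compare to mu * E[1/sf]
  expected_var <- cnt2$mu[["gB"]] * mean(1 / cnt2$size_factors[501:1000])
  expect_equal(var(y), expected_var, tolerance = 0.3)
  # NB variance oracle at moderate dispersion: var = mu + disp * mu^2
  cnt3 <- simulate_counts(ann, truth, n_reps = 800L, dispersion = 0.2,
                          seed = 9)
  mu_b <- cnt3$mu[["gB"]]
  sf3 <- cnt3$size_factors[801:1600]
  y3 <- cnt3$mut["gB", ] / sf3
  # var(count/sf) = mu * E[1/sf] + disp * mu^2 from the NB variance formula
  v_expected <- mu_b * mean(1 / sf3) + 0.2 * mu_b^2
  expect_equal(var(y3) / v_expected, 1, tolerance = 0.35)
})
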