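# Generators: genome/fragment map, read pairs, ES track, SNPs, expression.

test_that("restriction sites follow the requested spacing and tile exactly", {
  gf <- make_genome(n_chrom = 2, chrom_length = 2e6,
                    site_spacing_mean = 4000, seed = 7)
  expect_equal(gf$genome$name, c("chr1", "chr2"))
  for (cn in gf$genome$name) {
    s <- gf$fragmap$sites[[cn]]
    expect_false(is.unsorted(s, strictly = TRUE))
    # expected ~500 sites; exponential-spacing oracle with 3-sigma slack
    expect_lt(abs(length(s) - 500), 3 * sqrt(500))
    fr <- fragments(gf$fragmap, cn)
    expect_equal(fr$start[1], 0)
    expect_equal(fr$end[nrow(fr)], 2e6)
    expect_equal(fr$start[-1], fr$end[-nrow(fr)])  # exact tiling
  }
})

test_that("a spacing far beyond the chromosome length leaves one fragment", {
  gf <- make_genome(n_chrom = 1, chrom_length = 1000,
                    site_spacing_mean = 1e7, seed = 1)
  fr <- fragments(gf$fragmap, "chr1")
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$start, 0)
  expect_equal(fr$end, 1000)
})

test_that("generators are deterministic for a fixed seed", {
  a <- make_genome(seed = 42)
  b <- make_genome(seed = 42)
  expect_identical(a, b)
  tr <- make_truth(a$genome, n_planted = 3, seed = 5)
  p1 <- simulate_pairs(a$genome, a$fragmap, tr, 2000,
                       contaminant_fraction = 0.2, seed = 9)
  p2 <- simulate_pairs(a$genome, a$fragmap, tr, 2000,
                       contaminant_fraction = 0.2, seed = 9)
  expect_identical(p1, p2)
  expect_identical(make_es_track(a$genome, seed = 3),
                   make_es_track(a$genome, seed = 3))
  expect_identical(make_snps(a$genome, 500, seed = 3),
                   make_snps(a$genome, 500, seed = 3))
})

test_that("simulate_pairs conserves the pair count and contaminant share", {
  gf <- toy_genome()
  tr <- make_truth(gf$genome, seed = 2)
  n <- 40000
  pairs <- simulate_pairs(gf$genome, gf$fragmap, tr, n,
                          contaminant_fraction = 0.25, seed = 4)
  expect_equal(nrow(pairs), n)
  share <- mean(pairs$truth != "valid")
  expect_lt(abs(share - 0.25), 4 * sqrt(0.25 * 0.75 / n))
  # coordinates within bounds
  len <- setNames(gf$genome$length, gf$genome$name)
  expect_true(all(pairs$pos1 >= 0 & pairs$pos1 < len[pairs$chrom1]))
  expect_true(all(pairs$pos2 >= 0 & pairs$pos2 < len[pairs$chrom2]))
})

test_that("with no contaminants no pair sits in one or adjacent fragments", {
  gf <- toy_genome()
  tr <- make_truth(gf$genome, seed = 2)
  pairs <- simulate_pairs(gf$genome, gf$fragmap, tr, 20000,
                          contaminant_fraction = 0, seed = 4)
  f1 <- assign_fragment(pairs$chrom1, pairs$pos1, gf$fragmap)
  f2 <- assign_fragment(pairs$chrom2, pairs$pos2, gf$fragmap)
  same_chr <- pairs$chrom1 == pairs$chrom2
  expect_equal(sum(same_chr & abs(f1 - f2) <= 1), 0L)
  expect_true(all(pairs$truth == "valid"))
})

test_that("contact frequency decays with the planted power-law slope", {
  gf <- toy_genome()
  tr <- make_truth(gf$genome, bias_sigma = 0, decay_exponent = 1, seed = 2)
  pairs <- simulate_pairs(gf$genome, gf$fragmap, tr, 5e5,
                          contaminant_fraction = 0, seed = 4)
  cis <- pairs$chrom1 == pairs$chrom2
  d <- abs(pairs$pos2 - pairs$pos1)[cis]
  # oracle: regression on a log-binned distance histogram, 20 kb .. 1 Mb
  br <- exp(seq(log(2e4), log(1e6), length.out = 15))
  h <- hist(d[d >= 2e4 & d <= 1e6], breaks = br, plot = FALSE)
  dens <- h$counts / diff(br)
  use <- dens > 0
  slope <- coef(lm(log(dens[use]) ~ log(h$mids[use])))[2]
  expect_lt(abs(slope + 1), 0.15)
})

test_that("a planted pair stands out against equidistant bin pairs", {
  gf <- toy_genome()
  tr <- make_truth(gf$genome, n_planted = 1, planted_fold = 10,
                   bias_sigma = 0, seed = 11)
  pairs <- simulate_pairs(gf$genome, gf$fragmap, tr, 2e5,
                          contaminant_fraction = 0, seed = 4)
  mat <- bin_pairs(pairs, gf$genome, tr$bin_size)
  pp <- tr$planted_pairs
  planted_count <- mat$observed[pp$binA, pp$binB]
  # brute-force mean count over same-chromosome pairs at the same distance
  bins <- mat$bins
  dd <- pp$binB - pp$binA
  others <- numeric(0)
  for (cn in unique(bins$chrom)) {
    ii <- which(bins$chrom == cn)
    m <- length(ii)
    if (dd < m) {
      r <- ii[1:(m - dd)]; c <- ii[(1 + dd):m]
      others <- c(others, mat$observed[cbind(r, c)])
    }
  }
  expect_gt(planted_count, mean(others))
})

test_that("ES track tiles each chromosome and matches state weights", {
  gf <- make_genome(n_chrom = 1, chrom_length = 1e7,
                    site_spacing_mean = 4000, seed = 1)
  w <- c(0.2, 0.3, 0.5)
  # 2 kb segments on 10 Mb: ~5000 segments, so the bp-share SD is ~1%
  es <- make_es_track(gf$genome, n_states = 3, mean_seg_len = 2e3,
                      state_weights = w, seed = 5)
  # tiling without gap or overlap
  expect_equal(es$start[1], 0)
  expect_equal(es$end[nrow(es)], 1e7)
  expect_equal(es$start[-1], es$end[-nrow(es)])
  # long-run bp share per state within 2 percentage points
  share <- tapply(es$end - es$start, es$label, sum) / 1e7
  expect_lt(max(abs(share[paste0("state", 1:3)] - w)), 0.02)
})

test_that("single-state track covers the whole genome with that state", {
  gf <- toy_genome(n_chrom = 1)
  es <- make_es_track(gf$genome, n_states = 1, state_weights = 1, seed = 1)
  expect_true(all(es$label == "state1"))
  expect_equal(sum(es$end - es$start), gf$genome$length[1])
})

test_that("SNP generator plants the requested depletion", {
  gf <- make_genome(n_chrom = 1, chrom_length = 1e7,
                    site_spacing_mean = 4000, seed = 1)
  dep <- data.frame(chrom = "chr1", start = c(1e6, 5e6),
                    end = c(2.5e6, 6.5e6))
  snps <- make_snps(gf$genome, 20000, depleted_regions = dep,
                    depletion_factor = 0.5, seed = 6)
  expect_equal(nrow(snps), 20000L)
  expect_false(any(duplicated(paste(snps$chrom, snps$pos))))
  expect_true(all(snps$pos >= 0 & snps$pos < 1e7))
  inside <- snp_frequency(dep, snps)
  comp <- data.frame(chrom = "chr1", start = c(0, 2.5e6, 6.5e6),
                     end = c(1e6, 5e6, 1e7))
  outside <- snp_frequency(comp, snps)
  expect_lt(abs(inside / outside - 0.5), 0.1)
  # factor 1 gives a flat ratio
  flat <- make_snps(gf$genome, 20000, depleted_regions = dep,
                    depletion_factor = 1, seed = 6)
  expect_lt(abs(snp_frequency(dep, flat) / snp_frequency(comp, flat) - 1),
            0.1)
})

test_that("expression generator recovers the planted fold change", {
  gf <- toy_genome()
  genes <- make_genes(gf$genome, n_genes = 1000, seed = 2)
  tr <- make_truth(gf$genome, genes = genes, n_effect_genes = 100,
                   effect_lfc = 2, seed = 3)
  xp <- make_expression(genes, tr$effect_genes, seed = 4)
  expect_true(all(xp$control$fpkm >= 0))
  expect_true(all(xp$treated$fpkm >= 0))
  eff <- match(tr$effect_genes$gene_id, genes$gene_id)
  lfc <- log2fc(xp$treated$fpkm[eff], xp$control$fpkm[eff])
  # oracle: mean over the effect set
  expect_lt(abs(mean(lfc) - 2), 0.2)
  # with no effect genes the expected fold change is zero
  xp0 <- make_expression(genes, NULL, seed = 4)
  lfc0 <- log2fc(xp0$treated$fpkm, xp0$control$fpkm)
  expect_lt(abs(mean(lfc0)), 0.1)
})

test_that("generator argument validation rejects nonsense", {
  expect_error(make_genome(n_chrom = 0), "n_chrom")
  expect_error(make_genome(chrom_length = -5), "chrom_length")
  gf <- toy_genome(n_chrom = 1, chrom_length = 1e5)
  tr <- make_truth(gf$genome, seed = 1)
  expect_error(simulate_pairs(gf$genome, gf$fragmap, tr, 100,
                              contaminant_fraction = 1), "contaminant")
  expect_error(make_es_track(gf$genome, n_states = 2,
                             state_weights = c(0.5, 0.2)), "sum to 1")
  expect_error(make_es_track(gf$genome, n_states = 3,
                             state_weights = c(1, 0)), "length")
  expect_error(make_snps(gf$genome, 1e9), "exceeds")
  expect_error(make_truth(gf$genome, n_planted = 2, planted_fold = 0.5),
               "planted_fold")
  expect_error(make_truth(gf$genome, depletion_factor = 1.5),
               "depletion_factor")
})
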