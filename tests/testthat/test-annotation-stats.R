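# Epigenetic-state assignment, preference testing, GWAS depletion, motif
# export.

es_fixture <- data.frame(
  chrom = "chr1",
  start = c(0, 1000, 2000, 2000),
  end = c(1000, 2000, 3000, 2500),
  label = c("state8", "state9", "state3", "state7"),
  stringsAsFactors = FALSE
)

test_that("primary state takes maximal overlap with lower-number ties", {
  anchors <- data.frame(chrom = "chr1",
                        start = c(100, 600, 2000),
                        end = c(900, 1600, 2500))
  ps <- primary_state(anchors, es_fixture)
  expect_equal(ps[1], "state8")              # fully inside state8
  expect_equal(ps[2], "state9")              # 600 bp state9 vs 400 bp state8
  expect_equal(ps[3], "state3")              # 500/500 tie -> lower number
  sets <- attr(ps, "overlap_sets")
  expect_setequal(sets[[3]], c("state3", "state7"))
  # no overlap -> unassigned
  far <- data.frame(chrom = "chr2", start = 0, end = 100)
  expect_equal(unname(primary_state(far, es_fixture)[1]), "unassigned")
})

test_that("state distribution percentages sum to 100 and recover planting", {
  gf <- toy_genome(n_chrom = 1)
  es <- make_es_track(gf$genome, n_states = 3, mean_seg_len = 5e4,
                      state_weights = c(0.3, 0.3, 0.4), seed = 2)
  # plant 70% of anchors inside state2 segments, 30% in state1
  seg2 <- es[es$label == "state2" & (es$end - es$start) > 2000, ]
  seg1 <- es[es$label == "state1" & (es$end - es$start) > 2000, ]
  pick <- function(seg, n) {
    idx <- rep_len(seq_len(nrow(seg)), n)
    data.frame(chrom = seg$chrom[idx], start = seg$start[idx] + 500,
               end = seg$start[idx] + 1500)
  }
  n <- 200
  a <- rbind(pick(seg2, 0.7 * n), pick(seg1, 0.3 * n))
  b <- a[sample(nrow(a)), ]
  rec <- make_records(a$chrom, a$start, b$chrom, b$start, width = 1000)
  dist <- state_distribution(rec, es)
  expect_equal(sum(dist$percent), 100, tolerance = 0.01)
  expect_equal(dist$percent[dist$state == "state2"], 70, tolerance = 2)
})

test_that("random controls preserve count, lengths, class and distances", {
  set.seed(3)
  gf <- toy_genome()
  n <- 400
  cis_d <- round(rlnorm(n, log(2e5), 0.4))
  a1 <- sample(seq(0, 1.5e6, by = 1000), n, replace = TRUE)
  rec <- rbind(
    data.frame(chrom1 = "chr1", start1 = a1, end1 = a1 + 1000,
               chrom2 = "chr1", start2 = pmin(a1 + cis_d, 1.99e6),
               end2 = pmin(a1 + cis_d, 1.99e6) + 1000,
               observed = 10, expected = 1, p_value = 0.01, class = "cis"),
    data.frame(chrom1 = "chr1", start1 = a1[1:100], end1 = a1[1:100] + 1000,
               chrom2 = "chr2", start2 = a1[1:100],
               end2 = a1[1:100] + 1000,
               observed = 10, expected = 1, p_value = 0.01, class = "trans")
  )
  set <- interaction_set(rec, condition = "src",
                         chrom_levels = gf$genome$name)
  ctrl <- random_control_interactions(set, gf$genome, seed = 4)
  expect_equal(nrow(ctrl), nrow(set))
  expect_equal(sum(ctrl$class == "cis"), sum(set$class == "cis"))
  expect_equal(sort(ctrl$end1 - ctrl$start1), sort(set$end1 - set$start1))
  # same seed reproduces exactly
  expect_identical(as.data.frame(random_control_interactions(set,
                                                             gf$genome,
                                                             seed = 4)),
                   as.data.frame(ctrl))
  # cis distance distribution is preserved (two-sample KS)
  dsrc <- abs((set$start2 + set$end2) - (set$start1 + set$end1))[
    set$class == "cis"] / 2
  dctl <- abs((ctrl$start2 + ctrl$end2) - (ctrl$start1 + ctrl$end1))[
    ctrl$class == "cis"] / 2
  ks <- suppressWarnings(ks.test(dsrc, dctl))
  expect_gt(ks$p.value, 0.01)
})

test_that("same-state null matches the bp-weight square-sum closed form", {
  gf <- toy_genome()
  w <- c(0.2, 0.3, 0.5)
  # segments (2 kb) much shorter than anchor distances, and many of them,
  # so realized per-chromosome state shares sit close to the weights
  es <- make_es_track(gf$genome, n_states = 3, mean_seg_len = 2e3,
                      state_weights = w, seed = 6)
  # anchors far apart (0.6-1.4 Mb, varied so control anchors are not
  # confined to fixed chromosome halves)
  set.seed(9)
  n <- 300
  d <- round(runif(n, 6e5, 1.4e6))
  a1 <- floor(runif(n) * (2e6 - d - 500))
  rec <- data.frame(chrom1 = "chr1", start1 = a1, end1 = a1 + 200,
                    chrom2 = "chr1", start2 = a1 + d,
                    end2 = a1 + d + 200,
                    observed = 5, expected = 1, p_value = 0.01,
                    class = "cis")
  set <- interaction_set(rec, chrom_levels = gf$genome$name)
  pref <- es_preference_test(set, es, gf$genome, K = 60, seed = 7)
  expect_lt(abs(pref$null_mean - sum(w^2)), 0.03)
  expect_gte(pref$p_permutation, 1 / 61)
  # all records inside same-state segments give observed 1
  seg <- es[es$label == "state3" & (es$end - es$start) > 3000, ][1:20, ]
  rec1 <- make_records(seg$chrom, seg$start + 100, seg$chrom,
                       seg$start + 1500, width = 500)
  frac <- es_preference_test(rec1, es, gf$genome, K = 5, seed = 1)
  expect_equal(frac$observed, 1)
})

test_that("snp frequency counts unique positions over the region union", {
  regions <- data.frame(chrom = "chr1", start = c(0, 500), end = c(500, 1000))
  snps <- data.frame(chrom = "chr1", pos = c(10, 10, 20, 1500,
                                             seq(100, 700, by = 100)))
  # 10, 20 and 100..700 inside; duplicate 10 counted once
  expect_equal(snp_frequency(regions, snps), 9 / 1000)
  # invariance to splitting a region into adjacent pieces
  split2 <- data.frame(chrom = "chr1", start = c(0, 250, 500),
                       end = c(250, 500, 1000))
  expect_equal(snp_frequency(split2, snps), snp_frequency(regions, snps))
  expect_error(snp_frequency(regions[0, ], snps), "empty")
})

test_that("gwas enrichment is flat for uniform SNPs, recovers depletion", {
  gf <- toy_genome()
  anchors <- seq(1e5, 1.9e6, by = 2e5)
  rec <- make_records(rep(c("chr1", "chr2"), each = 5), anchors,
                      rep("chr3", 10), rev(anchors), width = 10000)
  uni <- make_snps(gf$genome, 20000, seed = 8)
  res <- gwas_enrichment(rec, uni, gf$genome, seed = 9)
  expect_lt(abs(res$ratio - 1), 0.25)
  expect_lt(abs(res$freq_control / res$freq_background - 1), 0.1)

  dep_regions <- rbind(
    data.frame(chrom = rec$chrom1, start = rec$start1, end = rec$end1),
    data.frame(chrom = rec$chrom2, start = rec$start2, end = rec$end2))
  dep <- make_snps(gf$genome, 20000, depleted_regions = dep_regions,
                   depletion_factor = 0.5, seed = 8)
  res2 <- gwas_enrichment(rec, dep, gf$genome, seed = 9)
  expect_lt(abs(res2$ratio - 2), 0.4)
})

test_that("motif regions require a coding partner and deduplicate windows", {
  gf <- toy_genome(n_chrom = 1, chrom_length = 2e5)
  fasta <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(gf$genome, gf$fragmap, fasta, seed = 5)
  genes <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                      start = c(10000, 50000), end = c(12000, 52000),
                      strand = "+",
                      biotype = c("protein_coding",
                                  "transposable_element_gene"))
  rec <- rbind(
    as.data.frame(make_records("chr1", 10500, "chr1", 100000)),  # G1 overlap
    as.data.frame(make_records("chr1", 10500, "chr1", 150000)),  # shared
    as.data.frame(make_records("chr1", 50500, "chr1", 180000))   # TE only
  )
  set <- interaction_set(rec)
  out <- export_motif_regions(set, genes, fasta, width = 1000)
  # the shared coding anchor yields one window; the TE-only record none
  expect_equal(length(out), 1L)
  expect_equal(unique(Biostrings::width(out)), 1000L)
  expect_match(names(out), "^chr1:")
  # clipped at the chromosome start
  rec2 <- interaction_set(as.data.frame(make_records("chr1", 10500, "chr1",
                                                     100000)))
  genes2 <- data.frame(gene_id = "G3", chrom = "chr1", start = 0,
                       end = 400, strand = "+", biotype = "protein_coding")
  rec3 <- interaction_set(data.frame(
    chrom1 = "chr1", start1 = 0, end1 = 200, chrom2 = "chr1",
    start2 = 1e5, end2 = 1e5 + 200, observed = 5, expected = 1,
    p_value = 0.01, class = "cis"))
  out3 <- export_motif_regions(rec3, genes2, fasta, width = 1000)
  expect_equal(Biostrings::width(out3)[1], 600L)  # window clipped at 0
})
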