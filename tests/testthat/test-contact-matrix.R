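# Binning, decay estimation, bin-total inference, normalization,
# correlation.

test_that("bin_pairs counts pairs symmetrically and conserves mass", {
  genome <- data.frame(name = c("chr1", "chr2"), length = c(1e4, 1e4))
  one <- data.frame(name = "p1", chrom1 = "chr1", pos1 = 100,
                    strand1 = "+", chrom2 = "chr1", pos2 = 900,
                    strand2 = "-", stringsAsFactors = FALSE)
  m <- bin_pairs(one, genome, 1000)
  expect_equal(m$observed[1, 1], 1)
  expect_equal(sum(m$observed), 1)

  ten <- one[rep(1, 10), ]
  ten$pos1 <- 2500; ten$pos2 <- 5500   # bins 3 and 6 of chr1
  m <- bin_pairs(ten, genome, 1000)
  expect_equal(m$observed[3, 6], 10)
  expect_equal(m$observed[6, 3], 10)
  expect_true(isSymmetric(m$observed))

  gf <- toy_genome()
  tr <- make_truth(gf$genome, seed = 2)
  pairs <- simulate_pairs(gf$genome, gf$fragmap, tr, 1e5, seed = 3)
  mat <- bin_pairs(pairs, gf$genome, 1e4)
  mass <- (sum(mat$observed) + sum(diag(mat$observed))) / 2
  expect_equal(mass, 1e5)
  expect_error(bin_pairs(data.frame(chrom1 = "chrX", pos1 = 1,
                                    chrom2 = "chr1", pos2 = 1),
                         genome, 1000), "unknown chromosome")
})

test_that("a flat cis matrix yields a flat decay profile", {
  genome <- data.frame(name = "chr1", length = 1e4)
  bins <- bin_table(genome, 1000)
  obs <- matrix(7, 10, 10)
  mat <- structure(list(bin_size = 1000, bins = bins, observed = obs,
                        mask = rep(FALSE, 10), n_pairs = sum(obs)),
                   class = "contact_matrix")
  dec <- estimate_decay(mat, min_counts = 1)
  expect_equal(unname(dec$f), rep(7, 10))
})

test_that("decay estimation recovers the generating power law, monotone", {
  gf <- toy_genome()
  tr <- make_truth(gf$genome, bias_sigma = 0, decay_exponent = 1, seed = 2)
  pairs <- simulate_pairs(gf$genome, gf$fragmap, tr, 5e5, seed = 3)
  mat <- bin_pairs(pairs, gf$genome, 1e4)
  dec <- estimate_decay(mat)
  expect_false(is.unsorted(rev(dec$f[-1])))      # non-increasing for d >= 1
  s <- dec$strata
  use <- s$distance_bp >= 2e4 & s$distance_bp <= 1e6 & s$f > 0
  slope <- coef(lm(log(f) ~ log(distance_bp), data = s[use, ]))[2]
  expect_lt(abs(slope + 1), 0.15)
})

test_that("bias-free data gives equal bin totals; biases are recovered", {
  gf <- toy_genome()
  tr0 <- make_truth(gf$genome, bias_sigma = 0, seed = 2)
  pairs0 <- simulate_pairs(gf$genome, gf$fragmap, tr0, 3e5, seed = 3)
  mat0 <- bin_pairs(pairs0, gf$genome, 2e4)
  model0 <- contact_model(mat0)
  n <- model0$n_star[!mat0$mask]
  expect_lt(stats::sd(n) / mean(n), 0.05)

  tr <- make_truth(gf$genome, bias_sigma = 0.3, seed = 4)
  pairs <- simulate_pairs(gf$genome, gf$fragmap, tr, 5e5, seed = 3)
  mat <- bin_pairs(pairs, gf$genome, 1e4)
  model <- contact_model(mat)
  keep <- !mat$mask
  expect_gte(cor(model$n_star[keep], tr$bias[keep]), 0.9)

  # expected marginal reproduces the observed marginal of each bin
  E <- fitted(model)
  em <- rowSums(E[, keep, drop = FALSE]) + diag(E)
  om <- rowSums(mat$observed[, keep, drop = FALSE]) + diag(mat$observed)
  expect_lt(max(abs(em[keep] - om[keep]) / om[keep]), 0.05)
})

test_that("expected_count evaluates the model equation literally", {
  model <- manual_model(f_values = c(10, 8, 8), n_star = c(100, 50, 0),
                        N_star = 1000)
  expect_equal(expected_count(1, 2, model), 8 * 100 * 50 / 1000)  # 40
  expect_equal(expected_count(1, 3, model), 0)                    # n* = 0
  model2 <- manual_model(f_values = c(9, 5), n_star = c(10, 10),
                         N_star = 100)
  expect_equal(expected_count(1, 2, model2), 5)
  # trans pairs use the trans floor
  bins <- data.frame(chrom = c("chr1", "chr2"), start = 0, end = 1000,
                     bin = 1:2)
  model3 <- manual_model(f_values = 10, n_star = c(100, 100), N_star = 1000,
                         trans_floor = 2, bins = bins)
  expect_equal(expected_count(1, 2, model3), 2 * 100 * 100 / 1000)
})

test_that("normalized matrix is flat for unbiased data, flags planting", {
  gf <- toy_genome()
  tr <- make_truth(gf$genome, bias_sigma = 0, n_planted = 1,
                   planted_fold = 10, seed = 5)
  pairs <- simulate_pairs(gf$genome, gf$fragmap, tr, 5e5, seed = 3)
  mat <- bin_pairs(pairs, gf$genome, 1e4)
  model <- contact_model(mat)
  norm <- normalized_matrix(mat, model)
  expect_true(isSymmetric(unname(norm)))
  pp <- tr$planted_pairs
  val <- norm[pp$binA, pp$binB]
  # rank check against equidistant unplanted entries
  dd <- pp$binB - pp$binA
  bins <- mat$bins
  others <- numeric(0)
  for (cn in unique(bins$chrom)) {
    ii <- which(bins$chrom == cn)
    m <- length(ii)
    if (dd < m) {
      r <- ii[1:(m - dd)]; c <- ii[(1 + dd):m]
      others <- c(others, norm[cbind(r, c)])
    }
  }
  others <- others[!is.na(others)]
  expect_gt(val, quantile(others, 0.99))
  # off-planted entries average to ~1 (counts are discrete, so the mean,
  # not the median, is the calibrated summary at sparse distances)
  expect_lt(abs(mean(others) - 1), 0.15)
})

test_that("normalized matrix is invariant to a global depth rescaling", {
  gf <- toy_genome()
  tr <- make_truth(gf$genome, seed = 2)
  pairs <- simulate_pairs(gf$genome, gf$fragmap, tr, 2e5, seed = 3)
  mat <- bin_pairs(pairs, gf$genome, 2e4)
  # tight convergence: the invariance is exact at the fixed point
  model <- contact_model(mat, tol = 1e-10, max_iter = 500)
  norm <- normalized_matrix(mat, model)
  mat2 <- mat
  mat2$observed <- mat$observed * 8
  mat2$n_pairs <- mat$n_pairs * 8
  model2 <- contact_model(mat2, tol = 1e-10, max_iter = 500)
  norm2 <- normalized_matrix(mat2, model2)
  keep <- !is.na(norm) & !is.na(norm2) & norm > 0
  expect_lt(max(abs(norm2[keep] / norm[keep] - 1)), 1e-6)
})

test_that("global conservation holds after hill climbing", {
  gf <- toy_genome()
  tr <- make_truth(gf$genome, seed = 2)
  pairs <- simulate_pairs(gf$genome, gf$fragmap, tr, 3e5, seed = 3)
  mat <- bin_pairs(pairs, gf$genome, 1e4)
  model <- contact_model(mat)
  E <- fitted(model)
  keep <- !mat$mask
  tot_exp <- (sum(E[keep, keep]) + sum(diag(E)[keep])) / 2
  tot_obs <- (sum(mat$observed[keep, keep]) +
                sum(diag(mat$observed)[keep])) / 2
  expect_lt(abs(tot_exp / tot_obs - 1), 0.005)
  # objective must have descended monotonically
  obj <- model$convergence$objective
  expect_true(all(diff(obj) <= 1e-9 * pmax(obj[-length(obj)], 1)))
})

test_that("permuting chromosome order does not change called results", {
  gf <- toy_genome()
  tr <- make_truth(gf$genome, n_planted = 5, seed = 2)
  pairs <- simulate_pairs(gf$genome, gf$fragmap, tr, 2e5, seed = 3)
  cfg <- caller_config(resolution = 1e4, alpha = 0.05, min_observed = 5)
  set1 <- call_interactions(pairs, gf$genome, config = cfg)
  g2 <- gf$genome[c(3, 1, 2), ]
  set2 <- call_interactions(pairs, g2, config = cfg)
  # anchor order within a record follows the supplied chromosome order,
  # so canonicalize the unordered pair before comparing
  key <- function(s) {
    a <- sprintf("%s:%d", s$chrom1, s$start1)
    b <- sprintf("%s:%d", s$chrom2, s$start2)
    sort(paste(pmin(a, b), pmax(a, b), s$observed))
  }
  expect_equal(key(set2), key(set1))
})

test_that("correlation matrix matches brute-force Pearson on a checkerboard", {
  set.seed(21)
  # two-block obs/exp pattern: within-block 2, between-block 0.5
  nb <- 12
  block <- rep(c(1, 2), each = nb / 2)
  norm <- outer(block, block, function(a, b) ifelse(a == b, 2, 0.5))
  norm <- norm * matrix(exp(rnorm(nb * nb, 0, 0.01)), nb, nb)
  norm[lower.tri(norm)] <- t(norm)[lower.tri(norm)]
  dimnames(norm) <- list(paste0("b", 1:nb), paste0("b", 1:nb))
  C <- correlation_matrix(norm)
  # brute-force oracle on log2 values with the same column exclusions
  L <- log2(norm)
  oracle <- function(i, j) {
    cols <- setdiff(seq_len(nb), c(i, j))
    cor(L[i, cols], L[j, cols])
  }
  for (pair in list(c(1, 2), c(1, 7), c(4, 11))) {
    expect_equal(C[pair[1], pair[2]], oracle(pair[1], pair[2]),
                 tolerance = 1e-12)
  }
  expect_true(all(C[block == 1, block == 1] > 0))
  expect_true(all(C[block == 1, block == 2] < 0))
  expect_equal(unname(diag(C)), rep(1, nb))
  # duplicate rows correlate perfectly
  norm2 <- norm; norm2[2, ] <- norm2[1, ]; norm2[, 2] <- norm2[, 1]
  C2 <- correlation_matrix(norm2)
  expect_equal(unname(C2[1, 2]), 1)
})

test_that("degenerate matrices are rejected with clear errors", {
  genome <- data.frame(name = "chr1", length = 3000)
  mat <- bin_pairs(data.frame(chrom1 = character(), pos1 = integer(),
                              chrom2 = character(), pos2 = integer()),
                   genome, 1000)
  expect_error(estimate_decay(mat), "unmasked")
  expect_error(correlation_matrix(matrix(1, 2, 2)), "3 unmasked")
})
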