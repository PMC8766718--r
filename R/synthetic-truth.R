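#' Construct the ground truth for a synthetic Hi-C experiment
#'
#' The truth set fixes everything the generator knows and downstream
#' recovery tests check: the contact-decay exponent, per-bin multiplicative
#' coverage biases, planted enriched locus pairs, SNP-depleted regions and
#' expression effect genes.
#'
#' @param genome genome data.frame from [make_genome()].
#' @param bin_size bp; resolution at which biases and planted pairs are
#'   defined.
#' @param decay_exponent alpha of the cis contact decay `d^(-alpha)`.
#' @param bias_sigma sdlog of the lognormal per-bin bias factors.
#' @param n_planted number of planted enriched cis bin pairs.
#' @param planted_fold enrichment fold of planted pairs (> 1).
#' @param min_planted_distance minimum bp separation of planted pair
#'   anchors (keeps them off the matrix diagonal).
#' @param n_depleted_regions,depleted_region_length regions with reduced
#'   SNP density for the GWAS-depletion analysis.
#' @param depletion_factor SNP density inside depleted regions relative to
#'   outside, in (0, 1).
#' @param genes optional gene table from [make_genes()]; required when
#'   `n_effect_genes > 0`.
#' @param n_effect_genes,effect_lfc number of expression effect genes and
#'   their true log2 fold change.
#' @param seed integer seed.
#' @return object of class `truth_set`.
#' @export
make_truth <- function(genome, bin_size = 1e4, decay_exponent = 1,
                       bias_sigma = 0.3, n_planted = 0, planted_fold = 10,
                       min_planted_distance = 2e5,
                       n_depleted_regions = 0, depleted_region_length = 5e4,
                       depletion_factor = 0.5,
                       genes = NULL, n_effect_genes = 0, effect_lfc = 2,
                       seed = 1) {
  stop_if_not_genome(genome)
  stopifnot(bin_size > 0, decay_exponent > 0, bias_sigma >= 0)
  if (n_planted > 0 && planted_fold <= 1) stop("planted_fold must be > 1")
  if (depletion_factor <= 0 || depletion_factor >= 1) {
    stop("depletion_factor must be in (0, 1)")
  }
  bins <- bin_table(genome, bin_size)
  nb <- nrow(bins)
  with_seed(seed, {
    bias <- rlnorm(nb, meanlog = 0, sdlog = bias_sigma)

    planted <- NULL
    if (n_planted > 0) {
      mid <- (bins$start + bins$end) / 2
      cand <- which(outer(bins$chrom, bins$chrom, "==") &
                      abs(outer(mid, mid, "-")) >= min_planted_distance &
                      upper.tri(matrix(0, nb, nb)),
                    arr.ind = TRUE)
      if (nrow(cand) < n_planted) stop("genome too small for planted pairs")
      # greedy sample with distinct anchor bins so recovery counts are clean
      ord <- sample.int(nrow(cand))
      used <- logical(nb); keep <- integer(0)
      for (k in ord) {
        a <- cand[k, 1L]; b <- cand[k, 2L]
        if (!used[a] && !used[b]) {
          keep <- c(keep, k); used[a] <- TRUE; used[b] <- TRUE
          if (length(keep) == n_planted) break
        }
      }
      if (length(keep) < n_planted) stop("could not place distinct planted pairs")
      a <- cand[keep, 1L]; b <- cand[keep, 2L]
      planted <- data.frame(
        binA = a, binB = b,
        chromA = bins$chrom[a], startA = bins$start[a], endA = bins$end[a],
        chromB = bins$chrom[b], startB = bins$start[b], endB = bins$end[b],
        fold = planted_fold, stringsAsFactors = FALSE)
    }

    depleted <- NULL
    if (n_depleted_regions > 0) {
      placed <- list()
      for (k in seq_len(n_depleted_regions)) {
        for (try in 1:200) {
          ci <- sample.int(nrow(genome), 1, prob = genome$length)
          L <- genome$length[ci]
          if (L <= depleted_region_length) next
          s <- floor(runif(1) * (L - depleted_region_length))
          e <- s + depleted_region_length
          clash <- any(vapply(placed, function(p) {
            p$chrom == genome$name[ci] && s < p$end && e > p$start
          }, logical(1)))
          if (!clash) {
            placed[[k]] <- list(chrom = genome$name[ci], start = s, end = e)
            break
          }
        }
      }
      if (length(placed) < n_depleted_regions) {
        stop("could not place depleted regions without overlap")
      }
      depleted <- data.frame(
        chrom = vapply(placed, `[[`, character(1), "chrom"),
        start = vapply(placed, `[[`, numeric(1), "start"),
        end = vapply(placed, `[[`, numeric(1), "end"),
        stringsAsFactors = FALSE)
    }

    effect <- NULL
    if (n_effect_genes > 0) {
      if (is.null(genes)) stop("'genes' required when n_effect_genes > 0")
      if (n_effect_genes > nrow(genes)) stop("more effect genes than genes")
      ids <- sample(genes$gene_id, n_effect_genes)
      effect <- data.frame(gene_id = ids, true_lfc = effect_lfc,
                           stringsAsFactors = FALSE)
    }

    structure(list(
      bin_size = bin_size, bins = bins, bias = bias,
      decay_exponent = decay_exponent, cis_floor = 1000,
      trans_floor_frac = 0.05,
      planted_pairs = planted,
      depleted_regions = depleted, depletion_factor = depletion_factor,
      effect_genes = effect
    ), class = "truth_set")
  })
}

#' @export
print.truth_set <- function(x, ...) {
  cat("Synthetic truth set\n")
  cat("  bins:", nrow(x$bins), "of", fmt_count(x$bin_size), "bp;",
      "decay exponent", x$decay_exponent, "\n")
  cat("  planted pairs:",
      if (is.null(x$planted_pairs)) 0 else nrow(x$planted_pairs), "\n")
  cat("  depleted regions:",
      if (is.null(x$depleted_regions)) 0 else nrow(x$depleted_regions),
      sprintf("(factor %.2f)\n", x$depletion_factor))
  cat("  effect genes:",
      if (is.null(x$effect_genes)) 0 else nrow(x$effect_genes), "\n")
  invisible(x)
}
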