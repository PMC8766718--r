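#' Generate a synthetic epigenetic-state track
#'
#' Tiles each chromosome with contiguous segments of exponential length;
#' each segment's state is drawn independently by the given weights.  A
#' stand-in for published chromatin-state maps (e.g. the nine Arabidopsis
#' states), without their overlapping regions — overlap handling is
#' exercised separately.
#'
#' @param genome genome data.frame.
#' @param n_states number of states (>= 1).
#' @param mean_seg_len mean segment length in bp.
#' @param state_weights per-state probabilities summing to 1.
#' @param seed integer seed.
#' @return data.frame `chrom`, `start`, `end`, `label` (`"state1"` ..),
#'   segments tiling each chromosome exactly.
#' @export
make_es_track <- function(genome, n_states = 9, mean_seg_len = 2e4,
                          state_weights = rep(1 / n_states, n_states),
                          seed = 1) {
  stop_if_not_genome(genome)
  if (n_states < 1) stop("n_states must be >= 1")
  if (length(state_weights) != n_states) {
    stop("state_weights length must equal n_states")
  }
  if (abs(sum(state_weights) - 1) > 1e-8) {
    stop("state_weights must sum to 1")
  }
  if (mean_seg_len <= 0) stop("mean_seg_len must be positive")
  with_seed(seed, {
    pieces <- lapply(seq_len(nrow(genome)), function(i) {
      L <- genome$length[i]
      ends <- numeric(0); pos <- 0
      while (pos < L) {
        pos <- pos + max(1, round(rexp(1, 1 / mean_seg_len)))
        ends <- c(ends, min(pos, L))
      }
      starts <- c(0, ends[-length(ends)])
      st <- sample.int(n_states, length(ends), replace = TRUE,
                       prob = state_weights)
      data.frame(chrom = genome$name[i], start = starts, end = ends,
                 label = paste0("state", st), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out
  })
}

#' Generate synthetic GWAS SNP positions with planted depletion
#'
#' Draws unique SNP positions whose density inside the depleted regions is
#' `depletion_factor` times the outside density, in expectation.
#'
#' @param genome genome data.frame.
#' @param n_snps number of SNPs (must not exceed the genome length).
#' @param depleted_regions data.frame of intervals, or `NULL` for uniform
#'   SNPs.
#' @param depletion_factor inside/outside density ratio in (0, 1].
#' @param seed integer seed.
#' @return data.frame `chrom`, `pos` (0-based), unique positions sorted.
#' @export
make_snps <- function(genome, n_snps, depleted_regions = NULL,
                      depletion_factor = 1, seed = 1) {
  stop_if_not_genome(genome)
  if (n_snps > sum(genome$length)) stop("n_snps exceeds genome length")
  if (depletion_factor <= 0 || depletion_factor > 1) {
    stop("depletion_factor must be in (0, 1]")
  }
  if (!is.null(depleted_regions) && nrow(depleted_regions)) {
    check_intervals(depleted_regions, genome, "depleted region")
    dep <- GenomicRanges::reduce(as_granges(depleted_regions))
  } else dep <- NULL
  cum <- cumsum(as.numeric(genome$length))
  offset <- stats::setNames(c(0, cum[-length(cum)]), genome$name)
  total <- sum(genome$length)
  with_seed(seed, {
    pos <- integer(0); chrom <- character(0)
    need <- n_snps
    guard <- 0L
    while (need > 0 && guard < 50L) {
      guard <- guard + 1L
      g <- floor(runif(ceiling(need * 1.6) + 16L) * total)
      ci <- findInterval(g, cum) + 1L
      cn <- genome$name[ci]
      p <- as.integer(g - offset[cn])
      # thin SNPs falling in depleted regions
      if (!is.null(dep)) {
        sg <- GenomicRanges::GRanges(cn, IRanges::IRanges(p + 1L, p + 1L))
        inside <- IRanges::overlapsAny(sg, dep)
        keep <- !inside | runif(length(p)) < depletion_factor
        cn <- cn[keep]; p <- p[keep]
      }
      chrom <- c(chrom, cn); pos <- c(pos, p)
      dup <- duplicated(paste(chrom, pos))
      chrom <- chrom[!dup]; pos <- pos[!dup]
      need <- n_snps - length(pos)
    }
    if (need > 0) stop("could not draw enough unique SNP positions")
    keep <- seq_len(n_snps)
    out <- data.frame(chrom = chrom[keep], pos = pos[keep],
                      stringsAsFactors = FALSE)
    out <- out[order(match(out$chrom, genome$name), out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Generate matched control/treated FPKM tables
#'
#' Per-gene baseline expression is lognormal; both conditions add
#' independent lognormal measurement noise, and the treated values of
#' effect genes are shifted by their true log2 fold change.
#'
#' @param genes gene table or character vector of gene ids.
#' @param effect_genes data.frame `gene_id`, `true_lfc` (subset of
#'   `genes`), or `NULL`.
#' @param baseline_meanlog,baseline_sdlog lognormal baseline parameters
#'   (defaults give a typical FPKM around 20).
#' @param noise_sdlog sdlog of per-condition measurement noise.
#' @param seed integer seed.
#' @return list with `control` and `treated` FPKM tables.
#' @export
make_expression <- function(genes, effect_genes = NULL,
                            baseline_meanlog = log(20),
                            baseline_sdlog = 0.8, noise_sdlog = 0.25,
                            seed = 1) {
  ids <- if (is.data.frame(genes)) genes$gene_id else as.character(genes)
  if (!is.null(effect_genes) && nrow(effect_genes) &&
      !all(effect_genes$gene_id %in% ids)) {
    stop("effect_genes must be a subset of genes")
  }
  n <- length(ids)
  with_seed(seed, {
    base <- rlnorm(n, baseline_meanlog, baseline_sdlog)
    control <- base * rlnorm(n, 0, noise_sdlog)
    shift <- rep(1, n)
    if (!is.null(effect_genes) && nrow(effect_genes)) {
      m <- match(effect_genes$gene_id, ids)
      shift[m] <- 2^effect_genes$true_lfc
    }
    treated <- base * shift * rlnorm(n, 0, noise_sdlog)
    list(control = data.frame(gene_id = ids, fpkm = control,
                              stringsAsFactors = FALSE),
         treated = data.frame(gene_id = ids, fpkm = treated,
                              stringsAsFactors = FALSE))
  })
}
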