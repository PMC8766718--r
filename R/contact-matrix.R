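#' Bin read pairs into a symmetric contact matrix
#'
#' Entry (i, j) counts retained pairs with one mate in bin i and the other
#' in bin j.  The matrix is symmetric by construction; its mass (upper
#' triangle plus diagonal) equals the number of pairs.  Bins whose observed
#' marginal is below a fraction of the median marginal are masked as
#' low-coverage and excluded from all downstream statistics.
#'
#' @param pairs read-pair data.frame.
#' @param genome genome data.frame.
#' @param bin_size bp.
#' @param mask_fraction bins with marginal below this fraction of the
#'   median unmasked marginal are masked (low-coverage guard).
#' @return object of class `contact_matrix`: list with `bin_size`, `bins`
#'   (coordinates per index), `observed` (dense symmetric matrix), `mask`
#'   (logical per bin) and `n_pairs`.
#' @export
bin_pairs <- function(pairs, genome, bin_size, mask_fraction = 0.2) {
  stop_if_not_genome(genome)
  if (bin_size <= 0) stop("bin_size must be positive")
  bins <- bin_table(genome, bin_size)
  nb <- nrow(bins)
  if (nrow(pairs) == 0L) {
    obs <- matrix(0, nb, nb)
  } else {
    i <- bin_index(pairs$chrom1, pairs$pos1, genome, bin_size)
    j <- bin_index(pairs$chrom2, pairs$pos2, genome, bin_size)
    lo <- pmin(i, j); hi <- pmax(i, j)
    sp <- Matrix::sparseMatrix(i = lo, j = hi, x = 1, dims = c(nb, nb))
    up <- as.matrix(sp)
    obs <- up + t(up)
    diag(obs) <- diag(up)
  }
  dimnames(obs) <- list(bin_label(bins), bin_label(bins))
  marg <- rowSums(obs)
  med <- stats::median(marg[marg > 0])
  mask <- if (is.na(med) || med <= 0) marg <= 0 else marg < mask_fraction * med
  structure(list(bin_size = bin_size, bins = bins, observed = obs,
                 mask = mask, n_pairs = nrow(pairs)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("Contact matrix:", nrow(x$bins), "bins of", fmt_count(x$bin_size),
      "bp;", fmt_count(x$n_pairs), "pairs;", sum(x$mask), "masked bin(s)\n")
  invisible(x)
}

# matrix mass = upper triangle + diagonal
matrix_mass <- function(mat) {
  (sum(mat$observed) + sum(diag(mat$observed))) / 2
}

# Weighted pool-adjacent-violators: least-squares non-increasing fit.
pava_nonincreasing <- function(y, w) {
  n <- length(y)
  if (n <= 1L) return(y)
  # fit non-decreasing to reversed series, then reverse back
  yr <- rev(y); wr <- rev(w)
  val <- yr; wt <- wr; idx <- as.list(seq_len(n))
  k <- 1L
  for (i in 2:n) {
    k <- k + 1L
    val[k] <- yr[i]; wt[k] <- wr[i]; idx[[k]] <- i
    while (k > 1L && val[k - 1L] > val[k]) {
      wv <- wt[k - 1L] + wt[k]
      val[k - 1L] <- (val[k - 1L] * wt[k - 1L] + val[k] * wt[k]) / wv
      wt[k - 1L] <- wv
      idx[[k - 1L]] <- c(idx[[k - 1L]], idx[[k]])
      k <- k - 1L
    }
  }
  out <- numeric(n)
  for (b in seq_len(k)) out[idx[[b]]] <- val[b]
  rev(out)
}

#' Estimate the distance-decay function f
#'
#' Tabulates the mean observed count per cis bin pair as a function of
#' bin-index distance, pooled over chromosomes.  Distances are pooled into
#' log-spaced strata until each stratum holds at least `min_counts` read
#' counts (stabilizes the tail), and the profile is then smoothed to be
#' non-increasing by weighted monotone regression.  The diagonal stratum
#' (d = 0, within-bin products) is summarized separately and exempt from
#' the monotone constraint, so libraries whose within-bin products were
#' removed upstream do not distort the decay head.
#'
#' @param mat `contact_matrix`.
#' @param min_counts minimum pooled read count per distance stratum.
#' @return object of class `decay_estimate`: list with `f` (expected reads
#'   per bin pair, indexed by bin distance 0..max), `strata`
#'   (pooling table) and `bin_size`.
#' @export
estimate_decay <- function(mat, min_counts = 50) {
  stopifnot(inherits(mat, "contact_matrix"))
  bins <- mat$bins
  keep <- !mat$mask
  if (sum(keep) < 2L) stop("need at least 2 unmasked bins")
  maxd <- max(table(bins$chrom)) - 1L
  tot <- numeric(maxd + 1L)
  cnt <- numeric(maxd + 1L)
  for (cn in unique(bins$chrom)) {
    ii <- which(bins$chrom == cn)
    ok <- keep[ii]
    if (sum(ok) < 1L) next
    sub <- mat$observed[ii, ii, drop = FALSE]
    m <- length(ii)
    for (dd in 0:(m - 1L)) {
      r <- seq_len(m - dd); c <- r + dd
      use <- ok[r] & ok[c]
      if (!any(use)) next
      tot[dd + 1L] <- tot[dd + 1L] + sum(sub[cbind(r[use], c[use])])
      cnt[dd + 1L] <- cnt[dd + 1L] + sum(use)
    }
  }
  has <- cnt > 0
  if (!any(has)) stop("no cis bin pairs available")
  dmax <- max(which(has)) - 1L
  # the diagonal (d = 0, within-bin products) is summarized on its own;
  # pooling and monotone smoothing operate on d >= 1
  f0_raw <- if (cnt[1] > 0) tot[1] / cnt[1] else 0
  if (dmax >= 1L) {
    dseq <- 1:dmax
    # log-spaced pooling: stratum boundaries grow geometrically, then
    # greedy merge until each stratum carries >= min_counts reads
    bnd <- unique(pmin(c(1L, floor(1.3^(0:ceiling(log(max(dmax, 1)) /
                                                    log(1.3))))), dmax))
    bnd <- sort(bnd[bnd >= 1L])
    strat <- findInterval(dseq, bnd)
    agg_tot <- tapply(tot[dseq + 1L], strat, sum)
    ids <- as.integer(names(agg_tot))
    merged_id <- ids
    acc_t <- 0; cur <- ids[1]
    for (k in seq_along(ids)) {
      acc_t <- acc_t + agg_tot[k]
      merged_id[k] <- cur
      if (acc_t >= min_counts) { acc_t <- 0
        if (k < length(ids)) cur <- ids[k + 1] }
    }
    grp <- merged_id[match(strat, ids)]
    g_tot <- tapply(tot[dseq + 1L], grp, sum)
    g_cnt <- tapply(cnt[dseq + 1L], grp, sum)
    g_val <- ifelse(g_cnt > 0, g_tot / g_cnt, 0)
    fval <- g_val[match(grp, as.integer(names(g_val)))]
    fcnt <- g_cnt[match(grp, as.integer(names(g_val)))]
    # monotone non-increasing smoothing (weight = bin-pair count).  The
    # diagonal keeps its raw mean: within-bin products are a different
    # class of ligation event and must not constrain (or borrow from)
    # the genuine distance decay.
    ftail <- pava_nonincreasing(as.numeric(fval),
                                as.numeric(pmax(fcnt, 1)))
    f <- c(f0_raw, ftail)
  } else {
    f <- f0_raw
  }
  if (maxd > dmax) f <- c(f, rep(f[length(f)], maxd - dmax))
  strata <- data.frame(distance_bins = 0:dmax,
                       distance_bp = (0:dmax) * mat$bin_size,
                       mean_count = ifelse(has[1:(dmax + 1L)],
                                           tot[1:(dmax + 1L)] /
                                             pmax(cnt[1:(dmax + 1L)], 1), NA),
                       f = f[1:(dmax + 1L)])
  structure(list(f = f, strata = strata, bin_size = mat$bin_size),
            class = "decay_estimate")
}

# evaluate f at integer bin distances
decay_at <- function(decay, d_bins) {
  f <- decay$f
  d <- pmin(pmax(d_bins, 0L) + 1L, length(f))
  f[d]
}
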