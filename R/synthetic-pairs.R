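#' Simulate aligned Hi-C read pairs with known ground truth
#'
#' Draws informative read pairs from a contact model in which the
#' probability of a bin pair is proportional to
#' `bias_i * bias_j * d^(-alpha)` in cis (distance floored at 1 kb) and to a
#' constant trans floor between chromosomes, with planted locus pairs
#' enriched by their truth fold.  A specified fraction of pairs are
#' ligation artifacts: self-ligation/dangling products (both mates in one
#' restriction fragment) or re-ligation products (mates in adjacent
#' fragments).
#'
#' Informative contacts are drawn between distinct bins of the truth
#' resolution; sub-resolution ligation products enter only through
#' `contaminant_fraction`.  Informative mates are placed adjacent to a
#' restriction site on the 3' side of the read, as genuine
#' proximity-ligation products are, so that they survive the downstream
#' restriction-site QC; the rare pairs that would still land in the same
#' or adjacent fragments (and would be indistinguishable from artifacts)
#' are re-placed within their bins.
#'
#' @param genome,fragmap from [make_genome()].
#' @param truth a `truth_set` from [make_truth()].
#' @param n_pairs number of read pairs to emit (exactly).
#' @param contaminant_fraction expected fraction of artifact pairs, in
#'   `[0, 1)`.
#' @param seed integer seed.
#' @param insert_window bp window used when placing mates next to their
#'   restriction site; match the QC window of [filter_pairs()].
#' @return data.frame with columns `name`, `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2` and a hidden `truth` label
#'   (`valid`, `self_ligation`, `religation`) used only by recovery tests.
#' @export
simulate_pairs <- function(genome, fragmap, truth, n_pairs,
                           contaminant_fraction = 0, seed = 1,
                           insert_window = 500) {
  stop_if_not_genome(genome)
  stopifnot(inherits(fragmap, "fragment_map"), inherits(truth, "truth_set"))
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (contaminant_fraction < 0 || contaminant_fraction >= 1) {
    stop("contaminant_fraction must be in [0, 1)")
  }
  bins <- truth$bins
  nb <- nrow(bins)
  if (nb < 1) stop("empty genome")

  # bin-pair sampling weights
  mid <- (bins$start + bins$end) / 2
  cis <- outer(bins$chrom, bins$chrom, "==")
  d <- abs(outer(mid, mid, "-"))
  alpha <- truth$decay_exponent
  trans_level <- truth$trans_floor_frac * max(1e5, truth$cis_floor)^(-alpha)
  W <- ifelse(cis, pmax(d, truth$cis_floor)^(-alpha), trans_level)
  W <- W * outer(truth$bias, truth$bias)
  # informative contacts are modelled between distinct bins of the truth
  # resolution; sub-resolution products are ligation artifacts by nature
  # and enter through contaminant_fraction instead
  diag(W) <- 0
  if (!is.null(truth$planted_pairs)) {
    for (k in seq_len(nrow(truth$planted_pairs))) {
      a <- truth$planted_pairs$binA[k]; b <- truth$planted_pairs$binB[k]
      W[a, b] <- W[a, b] * truth$planted_pairs$fold[k]
      W[b, a] <- W[a, b]
    }
  }
  ut <- which(upper.tri(W, diag = TRUE))
  wts <- W[ut]

  with_seed(seed, {
    n_cont <- rbinom(1, n_pairs, contaminant_fraction)
    n_inf <- n_pairs - n_cont

    inf <- if (n_inf > 0) {
      draw_informative(n_inf, ut, wts, nb, bins, genome, fragmap,
                       insert_window)
    } else NULL
    cont <- if (n_cont > 0) {
      draw_contaminants(n_cont, genome, fragmap)
    } else NULL

    out <- rbind(inf, cont)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    out$name <- sprintf("pair%07d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out[, c("name", "chrom1", "pos1", "strand1",
            "chrom2", "pos2", "strand2", "truth")]
  })
}

# uniform integer in [lo, hi] elementwise (lo <= hi assumed)
runif_int <- function(lo, hi) {
  lo + floor(runif(length(lo)) * (hi - lo + 1))
}

# Eligible placement windows per bin: the stretches from which a read can
# start so that a restriction site lies within `window` bp downstream of
# its 3' end.  For a "+" read ending at site s the window is
# [max(prev_site, s - window), s - 1]; for a "-" read starting after s it
# is [s + 1, min(next_site - 1, s + window)].  Windows are clipped to bin
# boundaries so that a mate sampled for a bin always lands inside it.
# Returns a table of window pieces with per-bin cumulative lengths.
placement_windows <- function(bins, fragmap, window) {
  pieces <- list()
  for (cn in unique(bins$chrom)) {
    s <- fragmap$sites[[cn]]
    if (!length(s)) next
    len <- fragmap$genome$length[match(cn, fragmap$genome$name)]
    prev <- c(0, s[-length(s)])
    nxt <- c(s[-1L], len)
    w <- rbind(
      data.frame(lo = pmax(prev, s - window), hi = s - 1, strand = "+"),
      data.frame(lo = s + 1, hi = pmin(nxt - 1, s + window), strand = "-")
    )
    w <- w[w$hi >= w$lo, , drop = FALSE]
    # split windows at bin boundaries
    bsub <- bins[bins$chrom == cn, , drop = FALSE]
    for (k in seq_len(nrow(w))) {
      b_lo <- findInterval(w$lo[k], bsub$start)
      b_hi <- findInterval(w$hi[k], bsub$start)
      for (b in b_lo:b_hi) {
        lo <- max(w$lo[k], bsub$start[b]); hi <- min(w$hi[k], bsub$end[b] - 1)
        if (hi >= lo) {
          pieces[[length(pieces) + 1L]] <-
            data.frame(bin = bsub$bin[b], chrom = cn, lo = lo, hi = hi,
                       strand = w$strand[k], stringsAsFactors = FALSE)
        }
      }
    }
  }
  pw <- do.call(rbind, pieces)
  pw <- pw[order(pw$bin, pw$lo), , drop = FALSE]
  pw$len <- pw$hi - pw$lo + 1
  # per-bin cumulative weight layout for O(1) sampling
  pw$cum_end <- stats::ave(pw$len, pw$bin, FUN = cumsum)
  tot <- tapply(pw$len, pw$bin, sum)
  list(pieces = pw,
       first_row = match(sort(unique(pw$bin)), pw$bin),
       bin_ids = sort(unique(pw$bin)),
       total = stats::setNames(as.numeric(tot), names(tot)))
}

# Place one mate per entry of bin_idx, uniformly over the eligible
# placement windows of that bin (so bin-level read counts follow the
# sampled bin pairs exactly).  Bins with no eligible window fall back to a
# uniform position; such reads are later removed by the 3'-site QC, as
# site-poor regions are in a real library.
place_in_bins <- function(bin_idx, bins, fragmap, pw) {
  n <- length(bin_idx)
  chrom <- bins$chrom[bin_idx]
  pos <- integer(n)
  strand <- character(n)
  row_of <- match(bin_idx, pw$bin_ids)
  placeable <- !is.na(row_of)
  if (any(placeable)) {
    ii <- which(placeable)
    tot <- pw$total[row_of[ii]]
    u <- runif(length(ii)) * tot
    # locate the window piece holding offset u within the bin's pieces
    first <- pw$first_row[row_of[ii]]
    pieces <- pw$pieces
    # linear scan bounded by pieces-per-bin (small); vectorized by rounds
    idx <- first
    remaining <- u
    repeat {
      cum <- pieces$cum_end[idx]
      done <- remaining <= cum | idx >= nrow(pieces) |
        c(pieces$bin[pmin(idx + 1L, nrow(pieces))] != pieces$bin[idx])
      if (all(done)) break
      idx[!done] <- idx[!done] + 1L
    }
    off <- remaining - (pieces$cum_end[idx] - pieces$len[idx])
    pos[ii] <- as.integer(pieces$lo[idx] + pmin(pmax(ceiling(off) - 1, 0),
                                                pieces$len[idx] - 1))
    strand[ii] <- pieces$strand[idx]
  }
  if (any(!placeable)) {
    ii <- which(!placeable)
    pos[ii] <- runif_int(bins$start[bin_idx[ii]], bins$end[bin_idx[ii]] - 1L)
    strand[ii] <- sample(c("+", "-"), length(ii), replace = TRUE)
  }
  frag <- integer(n)
  for (cn in unique(chrom)) {
    jj <- which(chrom == cn)
    frag[jj] <- findInterval(pos[jj], fragmap$sites[[cn]])
  }
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             frag = frag, stringsAsFactors = FALSE)
}

draw_informative <- function(n_inf, ut, wts, nb, bins, genome, fragmap,
                             window) {
  pw <- placement_windows(bins, fragmap, window)
  idx <- ut[sample.int(length(ut), n_inf, replace = TRUE, prob = wts)]
  bi <- ((idx - 1L) %% nb) + 1L
  bj <- ((idx - 1L) %/% nb) + 1L
  m1 <- place_in_bins(bi, bins, fragmap, pw)
  m2 <- place_in_bins(bj, bins, fragmap, pw)
  # re-place (within the same bins, preserving bin-level counts) the rare
  # pairs that land in an artifact-like configuration: same or adjacent
  # fragments across a bin boundary, or close inward-facing mates
  for (round in 1:100) {
    same_chr <- m1$chrom == m2$chrom
    artifact <- same_chr & abs(m1$frag - m2$frag) <= 1L
    lo <- pmin(m1$pos, m2$pos); hi <- pmax(m1$pos, m2$pos)
    inward <- same_chr &
      ((m1$pos <= m2$pos & m1$strand == "+" & m2$strand == "-") |
       (m2$pos < m1$pos & m2$strand == "+" & m1$strand == "-"))
    close_inward <- inward & (hi - lo) < window
    bad <- which(artifact | close_inward)
    if (!length(bad)) break
    if (round > 10) {
      # geometrically impossible within these bins: re-draw the bin pair
      idx2 <- ut[sample.int(length(ut), length(bad), replace = TRUE,
                            prob = wts)]
      bi[bad] <- ((idx2 - 1L) %% nb) + 1L
      bj[bad] <- ((idx2 - 1L) %/% nb) + 1L
    }
    m1[bad, ] <- place_in_bins(bi[bad], bins, fragmap, pw)
    m2[bad, ] <- place_in_bins(bj[bad], bins, fragmap, pw)
  }
  data.frame(chrom1 = m1$chrom, pos1 = m1$pos, strand1 = m1$strand,
             chrom2 = m2$chrom, pos2 = m2$pos, strand2 = m2$strand,
             truth = "valid", stringsAsFactors = FALSE)
}

draw_contaminants <- function(n_cont, genome, fragmap) {
  n_self <- rbinom(1, n_cont, 0.5)
  n_rel <- n_cont - n_self
  nfrag <- vapply(fragmap$sites, length, integer(1)) + 1L
  out <- list()
  if (n_self > 0) {
    ci <- sample.int(nrow(genome), n_self, replace = TRUE, prob = nfrag)
    cn <- genome$name[ci]
    p1 <- integer(n_self); p2 <- integer(n_self)
    for (c2 in unique(cn)) {
      ii <- which(cn == c2)
      fr <- fragments(fragmap, c2)
      f <- sample.int(nrow(fr), length(ii), replace = TRUE)
      p1[ii] <- runif_int(fr$start[f], fr$end[f] - 1L)
      p2[ii] <- runif_int(fr$start[f], fr$end[f] - 1L)
    }
    lo <- pmin(p1, p2); hi <- pmax(p1, p2)
    out$self <- data.frame(chrom1 = cn, pos1 = lo, strand1 = "+",
                           chrom2 = cn, pos2 = hi, strand2 = "-",
                           truth = "self_ligation", stringsAsFactors = FALSE)
  }
  if (n_rel > 0) {
    w <- pmax(nfrag - 1L, 0L)
    if (all(w == 0)) stop("no adjacent fragments available for re-ligation")
    ci <- sample.int(nrow(genome), n_rel, replace = TRUE, prob = w)
    cn <- genome$name[ci]
    p1 <- integer(n_rel); p2 <- integer(n_rel)
    for (c2 in unique(cn)) {
      ii <- which(cn == c2)
      fr <- fragments(fragmap, c2)
      f <- sample.int(nrow(fr) - 1L, length(ii), replace = TRUE)
      p1[ii] <- runif_int(fr$start[f], fr$end[f] - 1L)
      p2[ii] <- runif_int(fr$start[f + 1L], fr$end[f + 1L] - 1L)
    }
    out$rel <- data.frame(
      chrom1 = cn, pos1 = p1,
      strand1 = sample(c("+", "-"), n_rel, replace = TRUE),
      chrom2 = cn, pos2 = p2,
      strand2 = sample(c("+", "-"), n_rel, replace = TRUE),
      truth = "religation", stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
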