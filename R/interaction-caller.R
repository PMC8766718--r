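#' Upper-tail cumulative binomial p-value
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`, evaluated through the regularized
#' incomplete beta function (via [stats::pbinom()]), numerically stable for
#' library sizes up to at least 1e8.  Vectorized.
#'
#' @param k observed read count(s), `0 <= k <= n`.
#' @param n number of trials (total read pairs).
#' @param p per-trial success probability.
#' @return upper-tail probability; `1` when `k = 0`.
#' @export
binomial_pvalue <- function(k, n, p) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  if (any(k < 0) || any(k > n)) stop("k must satisfy 0 <= k <= n")
  stats::pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Caller configuration
#'
#' @param resolution bp resolution for interaction calling.
#' @param alpha p-value cutoff for significance.
#' @param min_observed minimum observed reads for a locus pair to be
#'   tested.
#' @param min_distance minimum cis anchor separation in bp; defaults to
#'   twice the resolution, excluding adjacent-bin artifacts.
#' @param fdr apply Benjamini-Hochberg correction across tested pairs
#'   before thresholding (off by default; the raw cutoff mirrors standard
#'   HOMER-style calling).
#' @export
caller_config <- function(resolution = 1000, alpha = 0.05, min_observed = 5,
                          min_distance = 2 * resolution, fdr = FALSE) {
  if (resolution <= 0) stop("resolution must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (min_observed < 0) stop("min_observed must be >= 0")
  structure(list(resolution = resolution, alpha = alpha,
                 min_observed = min_observed, min_distance = min_distance,
                 fdr = fdr),
            class = "caller_config")
}

# canonical anchor ordering: (chrom order in genome/bins, then start)
order_anchors <- function(df, chrom_levels) {
  ra <- match(df$chrom1, chrom_levels); rb <- match(df$chrom2, chrom_levels)
  swap <- rb < ra | (rb == ra & df$start2 < df$start1)
  if (any(swap)) {
    tmp <- df[swap, c("chrom1", "start1", "end1")]
    df[swap, c("chrom1", "start1", "end1")] <-
      df[swap, c("chrom2", "start2", "end2")]
    df[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  df
}

#' Construct an interaction set
#'
#' @param records data.frame with columns `chrom1,start1,end1,
#'   chrom2,start2,end2,observed,expected,p_value,class`.
#' @param condition condition label (e.g. `"NC"`).
#' @param config optional `caller_config` used to produce the records.
#' @param chrom_levels chromosome ordering for anchor normalization.
#' @return data.frame of class `interaction_set`.
#' @export
interaction_set <- function(records, condition = "condition",
                            config = NULL, chrom_levels = NULL) {
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "observed", "expected", "p_value", "class")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) &&
      (any(records$p_value < 0 | records$p_value > 1, na.rm = TRUE) ||
       any(records$observed < 0, na.rm = TRUE))) {
    stop("invalid p_value or observed count")
  }
  if (is.null(chrom_levels)) {
    chrom_levels <- sort(unique(c(records$chrom1, records$chrom2)))
  }
  records <- order_anchors(records, chrom_levels)
  rownames(records) <- NULL
  structure(records, class = c("interaction_set", "data.frame"),
            condition = condition, config = config,
            chrom_levels = chrom_levels)
}

#' @export
as.data.frame.interaction_set <- function(x, ...) {
  out <- x
  attr(out, "condition") <- NULL
  attr(out, "config") <- NULL
  attr(out, "chrom_levels") <- NULL
  attr(out, "n_tested") <- NULL
  attr(out, "model") <- NULL
  class(out) <- "data.frame"
  out
}

#' @export
print.interaction_set <- function(x, ...) {
  cc <- classify_cis_trans(x)
  cat(sprintf("Interaction set '%s': %d interactions (%d cis, %d trans)\n",
              attr(x, "condition"), nrow(x), cc$cis, cc$trans))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Call statistically significant chromatin interactions
#'
#' Bins the retained read pairs at the configured resolution, fits (or
#' reuses) the expected-count contact model, and tests every unordered
#' locus pair with at least `min_observed` reads by the upper-tail
#' cumulative binomial: with `e` the model-expected count and `N*` the
#' library total, the pair probability is `p = e / N*` and the p-value
#' `P(X >= observed)` for `X ~ Binomial(N*, p)`.  Pairs with p-value at or
#' below `alpha` are reported, classed cis or trans.
#'
#' @param pairs retained read-pair data.frame.
#' @param genome genome data.frame.
#' @param model optional `contact_model` fitted at `config$resolution`.
#' @param config `caller_config`.
#' @param condition condition label carried by the result.
#' @return `interaction_set`; attribute `n_tested` records how many pairs
#'   were tested.
#' @export
call_interactions <- function(pairs, genome, model = NULL,
                              config = caller_config(),
                              condition = "condition") {
  stopifnot(inherits(config, "caller_config"))
  mat <- bin_pairs(pairs, genome, config$resolution)
  if (is.null(model)) {
    model <- contact_model(mat)
  } else {
    if (!inherits(model, "contact_model")) stop("'model' must be a contact_model")
    if (model$bin_size != config$resolution) {
      stop("model resolution (", model$bin_size,
           ") does not match caller resolution (", config$resolution, ")")
    }
  }
  bins <- mat$bins
  nb <- nrow(bins)
  keep <- !mat$mask

  if (config$min_observed >= 1) {
    nz <- which(mat$observed >= config$min_observed & upper.tri(mat$observed,
                                                                diag = TRUE),
                arr.ind = TRUE)
    i <- nz[, 1]; j <- nz[, 2]
  } else {
    if (nb > 3000) stop("min_observed = 0 requires <= 3000 bins")
    ut <- which(upper.tri(matrix(0, nb, nb), diag = TRUE))
    i <- ((ut - 1L) %% nb) + 1L
    j <- ((ut - 1L) %/% nb) + 1L
  }
  ok <- keep[i] & keep[j]
  # minimum cis separation (midpoint distance); trans pairs always pass
  midd <- abs((bins$start[j] + bins$end[j]) - (bins$start[i] + bins$end[i])) / 2
  cis <- bins$chrom[i] == bins$chrom[j]
  ok <- ok & (!cis | midd >= config$min_distance)
  i <- i[ok]; j <- j[ok]; cis <- cis[ok]

  obs <- mat$observed[cbind(i, j)]
  e <- expected_count(i, j, model)
  p_pair <- pmin(pmax(e / model$N_star, 0), 1)
  pval <- binomial_pvalue(obs, model$N_star, p_pair)
  n_tested <- length(pval)
  pthr <- if (config$fdr) stats::p.adjust(pval, "BH") else pval
  sel <- pthr <= config$alpha

  records <- data.frame(
    chrom1 = bins$chrom[i][sel], start1 = bins$start[i][sel],
    end1 = bins$end[i][sel],
    chrom2 = bins$chrom[j][sel], start2 = bins$start[j][sel],
    end2 = bins$end[j][sel],
    observed = obs[sel], expected = e[sel], p_value = pval[sel],
    class = ifelse(cis[sel], "cis", "trans"),
    stringsAsFactors = FALSE
  )
  out <- interaction_set(records, condition = condition, config = config,
                         chrom_levels = genome$name)
  attr(out, "n_tested") <- n_tested
  attr(out, "model") <- model
  out
}

#' Cis/trans composition of an interaction set
#'
#' @param set `interaction_set` (or any data.frame with a `class` column).
#' @return list with `cis`, `trans` counts and `cis_pct`, `trans_pct`
#'   percentages rounded to one decimal (NA for an empty set, with a
#'   warning).
#' @export
classify_cis_trans <- function(set) {
  n <- nrow(set)
  cis <- sum(set$class == "cis")
  trans <- n - cis
  if (n == 0) {
    warning("empty interaction set: percentages undefined")
    return(list(cis = 0L, trans = 0L, cis_pct = NA_real_,
                trans_pct = NA_real_))
  }
  list(cis = cis, trans = trans,
       cis_pct = round(100 * cis / n, 1),
       trans_pct = round(100 * trans / n, 1))
}

#' Median genomic distance of cis interactions
#'
#' Median over cis records of the absolute difference of anchor midpoints.
#'
#' @param set `interaction_set`.
#' @return bp.
#' @export
median_cis_distance <- function(set) {
  cis <- set[set$class == "cis", , drop = FALSE]
  if (nrow(cis) == 0) stop("no cis interactions")
  midA <- (cis$start1 + cis$end1) / 2
  midB <- (cis$start2 + cis$end2) / 2
  stats::median(abs(midB - midA))
}

#' Contact-frequency decay profile
#'
#' Distributes cis contacts into log-spaced genomic-distance strata and
#' normalizes to unit total, the classic distance-decay summary.
#'
#' @param x an `interaction_set` (read counts by anchor distance) or a
#'   `contact_matrix` (binned cis counts by bin distance).
#' @param n_strata number of log-spaced strata.
#' @param ... unused.
#' @return data.frame with `dist_lo`, `dist_hi` (bp), `frequency`
#'   (sums to 1); attribute `monotone_decreasing` reports whether the
#'   profile decreases monotonically.
#' @export
decay_profile <- function(x, n_strata = 20, ...) UseMethod("decay_profile")

decay_profile_core <- function(dist, weight, n_strata) {
  if (!length(dist)) stop("no cis data")
  dmin <- max(min(dist), 1)
  dmax <- max(dist) + 1
  if (dmax <= dmin) dmax <- dmin * 2
  br <- unique(exp(seq(log(dmin), log(dmax), length.out = n_strata + 1)))
  br[1] <- dmin - 0.5; br[length(br)] <- dmax + 0.5
  stratum <- findInterval(dist, br, rightmost.closed = TRUE)
  tot <- tapply(weight, factor(stratum, levels = seq_len(length(br) - 1)),
                sum, default = 0)
  # contact probability is a per-bp density: log-spaced strata widen with
  # distance, so raw stratum totals would not reflect the decay
  dens <- as.numeric(tot) / diff(br)
  freq <- dens / sum(dens)
  out <- data.frame(dist_lo = br[-length(br)], dist_hi = br[-1],
                    frequency = freq)
  nz <- out$frequency[out$frequency > 0]
  attr(out, "monotone_decreasing") <- !is.unsorted(rev(nz), strictly = FALSE)
  out
}

#' @export
decay_profile.interaction_set <- function(x, n_strata = 20, ...) {
  cis <- x[x$class == "cis", , drop = FALSE]
  d <- abs((cis$start2 + cis$end2) - (cis$start1 + cis$end1)) / 2
  decay_profile_core(d, cis$observed, n_strata)
}

#' @export
decay_profile.contact_matrix <- function(x, n_strata = 20, ...) {
  bins <- x$bins
  keep <- !x$mask
  ds <- list(); ws <- list()
  for (cn in unique(bins$chrom)) {
    ii <- which(bins$chrom == cn & keep)
    if (length(ii) < 2) next
    sub <- x$observed[ii, ii, drop = FALSE]
    mid <- (bins$start[ii] + bins$end[ii]) / 2
    ut <- which(upper.tri(sub), arr.ind = TRUE)
    ds[[cn]] <- abs(mid[ut[, 2]] - mid[ut[, 1]])
    ws[[cn]] <- sub[ut]
  }
  decay_profile_core(unlist(ds), unlist(ws), n_strata)
}
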