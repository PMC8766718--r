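#' Fit the expected-count contact model
#'
#' Models the expected read count between bins i and j as
#' `e_ij = f(i - j) * n*_i * n*_j / N*` in cis and
#' `e_ij = t * n*_i * n*_j / N*` in trans, where `f` is the distance-decay
#' profile, `n*_i` are inferred per-bin read totals absorbing coverage and
#' accessibility bias, `N*` is the library total, and `t` is a constant
#' trans floor.  `f` is tabulated by [estimate_decay()]; `n*` is fitted by
#' damped multiplicative hill climbing on the per-bin marginals
#' ([infer_bin_totals()]); `t` is set so that the total expected trans mass
#' equals the observed trans mass.
#'
#' @param mat `contact_matrix` from [bin_pairs()].
#' @param decay optional precomputed `decay_estimate`; fitted from `mat`
#'   when `NULL`.
#' @param ... passed to [infer_bin_totals()].
#' @return object of class `contact_model` with components `f` (the decay
#'   estimate), `n_star`, `N_star`, `trans_floor`, `bins`, `bin_size`,
#'   `mask`, `convergence` and the fitting `matrix`.
#' @seealso [expected_count()], [normalized_matrix()], [correlation_matrix()]
#' @export
contact_model <- function(mat, decay = NULL, ...) {
  stopifnot(inherits(mat, "contact_matrix"))
  if (is.null(decay)) decay <- estimate_decay(mat)
  if (!inherits(decay, "decay_estimate")) stop("'decay' must come from estimate_decay()")
  if (decay$bin_size != mat$bin_size) stop("decay/matrix bin size mismatch")
  fit <- infer_bin_totals(mat, decay, ...)
  structure(list(f = decay, n_star = fit$n_star, N_star = fit$N_star,
                 trans_floor = fit$trans_floor, bins = mat$bins,
                 bin_size = mat$bin_size, mask = mat$mask,
                 convergence = fit$convergence, matrix = mat,
                 call = match.call()),
            class = "contact_model")
}

# distance (in bins) matrix for cis pairs, NA for trans; and cis indicator
cis_distance_matrix <- function(bins) {
  nb <- nrow(bins)
  idx <- seq_len(nb)
  D <- abs(outer(idx, idx, "-"))
  cis <- outer(bins$chrom, bins$chrom, "==")
  list(D = D, cis = cis)
}

#' Infer per-bin read totals by multiplicative hill climbing
#'
#' Minimizes the squared difference between observed and model-expected
#' per-bin marginals with the damped multiplicative update
#' `n*_i <- n*_i * (observed marginal_i / expected marginal_i)^damping`.
#' The trans floor is refreshed each iteration so trans mass stays
#' balanced.  The objective must descend; five consecutive increases abort
#' with diagnostics.
#'
#' @param mat `contact_matrix`.
#' @param decay `decay_estimate` for the same bin size.
#' @param max_iter iteration cap.
#' @param tol convergence when the maximum relative change of any `n*`
#'   falls below this.
#' @param damping exponent of the multiplicative update in (0, 1]; 0.5
#'   gives guaranteed-stable symmetric scaling.
#' @return list with `n_star`, `N_star`, `trans_floor`, `convergence`
#'   (iterations, objective trace, converged flag).
#' @export
infer_bin_totals <- function(mat, decay, max_iter = 200, tol = 1e-4,
                             damping = 0.5) {
  stopifnot(inherits(mat, "contact_matrix"))
  nb <- nrow(mat$bins)
  keep <- !mat$mask
  obs <- mat$observed
  N_star <- mat$n_pairs
  dc <- cis_distance_matrix(mat$bins)
  Fmat <- matrix(0, nb, nb)
  Fmat[dc$cis] <- decay_at(decay, dc$D[dc$cis])
  trans_mask <- !dc$cis
  # marginal = read ends per bin: within-bin pairs contribute both ends
  obs_marg <- rowSums(obs[, keep, drop = FALSE]) + diag(obs)
  obs_marg[!keep] <- 0
  obs_trans_total <- sum(obs[trans_mask & outer(keep, keep)]) / 2

  n <- obs_marg                      # initialization: observed marginals
  n[!keep] <- 0
  objective <- function(n, tf) {
    e_cis <- (Fmat * outer(n, n)) / N_star
    e_trans <- tf * outer(n, n) / N_star
    E <- ifelse(dc$cis, e_cis, e_trans)
    em <- rowSums(E[, keep, drop = FALSE]) + diag(E)
    sum((obs_marg[keep] - em[keep])^2)
  }
  trans_floor_of <- function(n) {
    denom <- sum(outer(n, n)[trans_mask]) / 2 / N_star
    if (denom > 0) obs_trans_total / denom else 0
  }

  tf <- trans_floor_of(n)
  obj <- numeric(0)
  bad_streak <- 0L
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    # expected marginal: cis part + trans part
    cisF <- Fmat; cisF[trans_mask] <- 0
    transF <- matrix(tf, nb, nb); transF[dc$cis] <- 0
    M <- cisF + transF
    em <- (n * (M[, keep, drop = FALSE] %*% n[keep])[, 1] +
             diag(M) * n^2) / N_star
    ratio <- rep(1, nb)
    pos <- keep & em > 0
    ratio[pos] <- (obs_marg[pos] / em[pos])^damping
    n_new <- n * ratio
    delta <- max(abs(n_new - n) / pmax(n, 1e-12), na.rm = TRUE)
    n <- n_new
    tf <- trans_floor_of(n)
    obj <- c(obj, objective(n, tf))
    if (it >= 2L) {
      if (obj[it] > obj[it - 1L] * (1 + 1e-12)) {
        bad_streak <- bad_streak + 1L
        if (bad_streak >= 5L) {
          stop(sprintf(paste0("hill climbing diverged: objective increased ",
                              "for 5 consecutive iterations (iteration %d, ",
                              "objective %.6g -> %.6g)"),
                       it, obj[it - 5L], obj[it]))
        }
      } else bad_streak <- 0L
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  list(n_star = as.numeric(n), N_star = N_star, trans_floor = tf,
       convergence = list(iterations = iters, converged = converged,
                          objective = obj))
}

#' Expected read count between two bins
#'
#' Evaluates `e_ij = f(|i - j|) n*_i n*_j / N*` for cis pairs and
#' `t n*_i n*_j / N*` for trans pairs.  Vectorized over `i`, `j`.
#'
#' @param i,j global bin indices (1-based, as in `model$bins`).
#' @param model `contact_model`.
#' @return expected read counts.
#' @export
expected_count <- function(i, j, model) {
  stopifnot(inherits(model, "contact_model"))
  bins <- model$bins
  cis <- bins$chrom[i] == bins$chrom[j]
  g <- model$n_star[i] * model$n_star[j] / model$N_star
  f <- ifelse(cis, decay_at(model$f, abs(i - j)), model$trans_floor)
  f * g
}

# dense expected matrix
expected_matrix <- function(model) {
  nb <- nrow(model$bins)
  dc <- cis_distance_matrix(model$bins)
  Fmat <- matrix(model$trans_floor, nb, nb)
  Fmat[dc$cis] <- decay_at(model$f, dc$D[dc$cis])
  E <- Fmat * outer(model$n_star, model$n_star) / model$N_star
  E[model$mask, ] <- NA; E[, model$mask] <- NA
  dimnames(E) <- dimnames(model$matrix$observed)
  E
}

#' Observed/expected normalized contact matrix
#'
#' @param mat `contact_matrix`; must be the matrix the model was fitted on
#'   (same bin structure).
#' @param model `contact_model`.
#' @return symmetric matrix of observed/expected ratios; entries with
#'   expected 0 and observed 0 are 1, entries with expected 0 but observed
#'   reads are masked (NA) with a warning; masked bins are NA.
#' @export
normalized_matrix <- function(mat, model) {
  stopifnot(inherits(mat, "contact_matrix"), inherits(model, "contact_model"))
  if (!identical(dim(mat$observed), dim(model$matrix$observed))) {
    stop("matrix/model shape mismatch")
  }
  E <- expected_matrix(model)
  R <- mat$observed / E
  both_zero <- !is.na(E) & E == 0 & mat$observed == 0
  R[both_zero] <- 1
  impossible <- !is.na(E) & E == 0 & mat$observed > 0
  if (any(impossible)) {
    warning(sum(impossible), " entries with observed reads but zero ",
            "expected count; masked")
    R[impossible] <- NA
  }
  R
}

#' Pearson correlation matrix of normalized contact profiles
#'
#' Entry (i, j) is the Pearson correlation between rows i and j of
#' `log2(obs/exp)`, computed over unmasked columns excluding columns i and
#' j themselves (so the bins' own mutual contacts do not drive their
#' correlation).  Bins with constant profiles are masked.
#'
#' @param norm normalized (obs/exp) matrix from [normalized_matrix()].
#' @return symmetric correlation matrix with unit diagonal for unmasked
#'   bins, entries in `[-1, 1]`, class `correlation_matrix`.
#' @export
correlation_matrix <- function(norm) {
  nb <- nrow(norm)
  L <- suppressWarnings(log2(norm))
  L[!is.finite(L)] <- NA
  usable <- colSums(!is.na(L)) > 0
  if (sum(usable) < 3L) stop("need at least 3 unmasked bins")
  C <- matrix(NA_real_, nb, nb, dimnames = dimnames(norm))
  for (i in seq_len(nb)) {
    if (!usable[i]) next
    C[i, i] <- 1
    for (j in seq_len(nb)) {
      if (j <= i || !usable[j]) next
      cols <- setdiff(which(usable), c(i, j))
      xi <- L[i, cols]; xj <- L[j, cols]
      ok <- !is.na(xi) & !is.na(xj)
      if (sum(ok) < 3L) next
      if (stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) next
      C[i, j] <- C[j, i] <- stats::cor(xi[ok], xj[ok])
    }
  }
  structure(C, class = c("correlation_matrix", class(C)))
}
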