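#' @export
print.contact_model <- function(x, ...) {
  cat("Expected-count contact model\n")
  cat("  bins:", nrow(x$bins), "of", fmt_count(x$bin_size), "bp (",
      sum(x$mask), "masked )\n")
  cat("  N* =", fmt_count(x$N_star), "read pairs; trans floor =",
      signif(x$trans_floor, 4), "\n")
  cat("  hill climbing:", x$convergence$iterations, "iterations,",
      if (x$convergence$converged) "converged" else "not converged", "\n")
  invisible(x)
}

#' @export
summary.contact_model <- function(object, ...) {
  n <- object$n_star[!object$mask]
  E <- expected_matrix(object)
  keep <- !object$mask
  obs <- object$matrix$observed
  tot_obs <- (sum(obs[keep, keep]) + sum(diag(obs)[keep])) / 2
  tot_exp <- (sum(E[keep, keep]) + sum(diag(E)[keep])) / 2
  out <- list(
    bins = nrow(object$bins), bin_size = object$bin_size,
    masked = sum(object$mask), N_star = object$N_star,
    n_star_range = range(n), trans_floor = object$trans_floor,
    total_observed = tot_obs, total_expected = tot_exp,
    conservation = tot_exp / tot_obs,
    convergence = object$convergence
  )
  class(out) <- "summary.contact_model"
  out
}

#' @export
print.summary.contact_model <- function(x, ...) {
  cat("Expected-count contact model\n")
  cat(sprintf("  %d bins of %s bp (%d masked), N* = %s\n", x$bins,
              fmt_count(x$bin_size), x$masked, fmt_count(x$N_star)))
  cat(sprintf("  n* range: %.1f .. %.1f; trans floor %.4g\n",
              x$n_star_range[1], x$n_star_range[2], x$trans_floor))
  cat(sprintf("  sum expected / sum observed = %.4f\n", x$conservation))
  cat(sprintf("  hill climbing: %d iterations (%s)\n",
              x$convergence$iterations,
              if (x$convergence$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.contact_model <- function(object, ...) {
  stats::setNames(object$n_star, bin_label(object$bins))
}

#' @export
fitted.contact_model <- function(object, ...) {
  expected_matrix(object)
}

#' Residuals of the contact model
#'
#' @param object `contact_model`.
#' @param type `"ratio"` (observed/expected, the normalized matrix),
#'   `"raw"` (observed - expected) or `"pearson"`
#'   ((obs - exp) / sqrt(exp), Poisson-scale).
#' @param ... unused.
#' @export
residuals.contact_model <- function(object,
                                    type = c("ratio", "raw", "pearson"),
                                    ...) {
  type <- match.arg(type)
  E <- expected_matrix(object)
  O <- object$matrix$observed
  switch(type,
         ratio = normalized_matrix(object$matrix, object),
         raw = O - E,
         pearson = (O - E) / sqrt(ifelse(E > 0, E, NA)))
}

#' Predict expected counts for bin pairs
#'
#' @param object `contact_model`.
#' @param i,j global bin indices; when omitted, the full expected matrix is
#'   returned.
#' @param ... unused.
#' @export
predict.contact_model <- function(object, i = NULL, j = NULL, ...) {
  if (is.null(i) && is.null(j)) return(expected_matrix(object))
  expected_count(i, j, object)
}

#' Plot the fitted distance-decay profile
#'
#' Log-log plot of expected reads per bin pair against genomic distance.
#'
#' @param x `contact_model` or `decay_estimate`.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.contact_model <- function(x, ...) {
  plot(x$f, ...)
}

#' @export
plot.decay_estimate <- function(x, ...) {
  s <- x$strata[x$strata$distance_bp > 0 & x$strata$f > 0, ]
  graphics::plot(s$distance_bp, s$f, log = "xy", type = "b",
                 xlab = "genomic distance (bp)",
                 ylab = "expected reads per bin pair", ...)
  invisible(x)
}

#' Simulate contact matrices from the fitted model
#'
#' Draws Poisson counts around the model-expected matrix; useful for
#' parametric-bootstrap checks of downstream statistics.
#'
#' @param object `contact_model`.
#' @param nsim number of matrices.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `contact_matrix` objects.
#' @export
simulate.contact_model <- function(object, nsim = 1, seed = 1, ...) {
  E <- expected_matrix(object)
  nb <- nrow(E)
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      up <- which(upper.tri(E, diag = TRUE) & !is.na(E))
      counts <- stats::rpois(length(up), E[up])
      M <- matrix(0, nb, nb, dimnames = dimnames(E))
      M[up] <- counts
      M <- M + t(M); diag(M) <- diag(M) / 2
      M[object$mask, ] <- 0; M[, object$mask] <- 0
      structure(list(bin_size = object$bin_size, bins = object$bins,
                     observed = M, mask = object$mask,
                     n_pairs = round(sum(M[upper.tri(M, diag = TRUE)]))),
                class = "contact_matrix")
    })
  })
}
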