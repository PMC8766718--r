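# Shared fixtures, built in code.  Moderate sizes keep the default run
# fast; the acceptance suite uses larger simulations.

toy_genome <- function(n_chrom = 3, chrom_length = 2e6, spacing = 4000,
                       seed = 7) {
  make_genome(n_chrom = n_chrom, chrom_length = chrom_length,
              site_spacing_mean = spacing, seed = seed)
}

# a tiny hand-built fragment map: sites at 100 and 200 on a 300 bp chrom
tiny_fragmap <- function() {
  structure(list(sites = list(chrA = c(100, 200)),
                 genome = data.frame(name = "chrA", length = 300,
                                     stringsAsFactors = FALSE)),
            class = "fragment_map")
}

# minimal contact model with prescribed parameters, for closed-form checks
manual_model <- function(f_values, n_star, N_star, trans_floor = 0,
                         bins = NULL) {
  if (is.null(bins)) {
    bins <- data.frame(chrom = "chr1",
                       start = (seq_along(n_star) - 1) * 1000,
                       end = seq_along(n_star) * 1000,
                       bin = seq_along(n_star))
  }
  decay <- structure(list(f = f_values, strata = NULL, bin_size = 1000),
                     class = "decay_estimate")
  structure(list(f = decay, n_star = n_star, N_star = N_star,
                 trans_floor = trans_floor, bins = bins,
                 bin_size = 1000, mask = rep(FALSE, nrow(bins)),
                 convergence = NULL, matrix = NULL),
            class = "contact_model")
}

# interaction records at given coordinates (1 kb anchors by default)
make_records <- function(chrom1, start1, chrom2, start2, width = 1000,
                         observed = 10, expected = 2, p = 0.01,
                         condition = "test") {
  n <- max(length(chrom1), length(start1), length(chrom2), length(start2))
  df <- data.frame(
    chrom1 = rep_len(chrom1, n), start1 = rep_len(start1, n),
    end1 = rep_len(start1, n) + width,
    chrom2 = rep_len(chrom2, n), start2 = rep_len(start2, n),
    end2 = rep_len(start2, n) + width,
    observed = rep_len(observed, n), expected = rep_len(expected, n),
    p_value = rep_len(p, n),
    stringsAsFactors = FALSE
  )
  df$class <- ifelse(df$chrom1 == df$chrom2, "cis", "trans")
  interaction_set(df, condition = condition)
}

# brute-force all-pairs overlap oracle using the scalar matcher
brute_overlap <- function(ref, other) {
  vapply(seq_len(nrow(ref)), function(i) {
    any(vapply(seq_len(nrow(other)), function(j) {
      interactions_match(as.data.frame(ref)[i, ], as.data.frame(other)[j, ])
    }, logical(1)))
  }, logical(1))
}
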