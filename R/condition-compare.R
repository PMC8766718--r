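# Cross-condition interaction dynamics and their relation to expression.

anchors_granges <- function(set, which = c("A", "B")) {
  which <- match.arg(which)
  cols <- if (which == "A") c("chrom1", "start1", "end1") else
    c("chrom2", "start2", "end2")
  df <- as.data.frame(set)[, cols]
  names(df) <- c("chrom", "start", "end")
  as_granges(df)
}

# For each record of a, TRUE if some record of b matches it (both anchors
# overlap by >= 1 bp, in either orientation).
match_in_set <- function(a, b) {
  if (nrow(a) == 0L) return(logical(0))
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  aA <- anchors_granges(a, "A"); aB <- anchors_granges(a, "B")
  bA <- anchors_granges(b, "A"); bB <- anchors_granges(b, "B")
  hitpairs <- function(x, y) {
    # sets on fully disjoint chromosomes are a legitimate comparison;
    # silence the seqlevel mismatch chatter
    h <- suppressWarnings(GenomicRanges::findOverlaps(x, y))
    paste(S4Vectors::queryHits(h), S4Vectors::subjectHits(h))
  }
  straight <- intersect(hitpairs(aA, bA), hitpairs(aB, bB))
  crossed <- intersect(hitpairs(aA, bB), hitpairs(aB, bA))
  qi <- as.integer(sub(" .*", "", c(straight, crossed)))
  out <- rep(FALSE, nrow(a))
  out[unique(qi)] <- TRUE
  out
}

#' Do two interaction records overlap?
#'
#' True when the anchors of `a` overlap the anchors of `b` (>= 1 bp, same
#' chromosome), in either pairing orientation; interactions are unordered
#' pairs of loci.
#'
#' @param a,b single interaction records (1-row data.frames with the
#'   `interaction_set` columns).
#' @return logical.
#' @export
interactions_match <- function(a, b) {
  ov <- function(c1, s1, e1, c2, s2, e2) c1 == c2 & s1 < e2 & s2 < e1
  straight <- ov(a$chrom1, a$start1, a$end1, b$chrom1, b$start1, b$end1) &
    ov(a$chrom2, a$start2, a$end2, b$chrom2, b$start2, b$end2)
  crossed <- ov(a$chrom1, a$start1, a$end1, b$chrom2, b$start2, b$end2) &
    ov(a$chrom2, a$start2, a$end2, b$chrom1, b$start1, b$end1)
  unname(straight | crossed)
}

#' Interaction overlap between conditions
#'
#' Counts, from the vantage of a reference condition, how many reference
#' interactions are shared with each other condition (match at least one
#' record there), how many are common to all conditions, and how many are
#' exclusive to the reference.  Counts are reported from every choice of
#' reference as well, since match multiplicity makes them asymmetric.
#'
#' @param sets named list of `interaction_set`s (>= 2).
#' @param reference name of the reference condition (must be in `sets`).
#' @return object of class `overlap_result`: `reference`, `total`,
#'   `shared` (named vector over other conditions), `common`, `exclusive`,
#'   `match_matrix` (logical records x conditions for the reference set),
#'   and `all_references` (per-reference common/exclusive table).
#' @export
overlap_counts <- function(sets, reference) {
  if (length(sets) < 2L) stop("need at least 2 interaction sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("'sets' must be a named list")
  }
  if (!reference %in% names(sets)) {
    stop("reference '", reference, "' not among sets")
  }
  count_for <- function(ref_name) {
    ref <- sets[[ref_name]]
    others <- setdiff(names(sets), ref_name)
    mm <- vapply(others, function(o) match_in_set(ref, sets[[o]]),
                 logical(nrow(ref)))
    if (nrow(ref) == 1L) mm <- matrix(mm, nrow = 1,
                                      dimnames = list(NULL, others))
    if (nrow(ref) == 0L) mm <- matrix(logical(0), nrow = 0, ncol =
                                        length(others),
                                      dimnames = list(NULL, others))
    shared <- colSums(mm)
    common <- sum(rowSums(mm) == length(others))
    exclusive <- sum(rowSums(mm) == 0)
    list(total = nrow(ref), shared = shared, common = common,
         exclusive = exclusive, match_matrix = mm)
  }
  main <- count_for(reference)
  all_ref <- do.call(rbind, lapply(names(sets), function(nm) {
    r <- count_for(nm)
    data.frame(reference = nm, total = r$total, common = r$common,
               exclusive = r$exclusive, stringsAsFactors = FALSE)
  }))
  structure(list(reference = reference, total = main$total,
                 shared = main$shared, common = main$common,
                 exclusive = main$exclusive,
                 match_matrix = main$match_matrix,
                 all_references = all_ref),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Interaction overlap (reference: %s, %d interactions)\n",
              x$reference, x$total))
  for (nm in names(x$shared)) {
    cat(sprintf("  shared with %s: %d\n", nm, x$shared[[nm]]))
  }
  cat(sprintf("  common to all: %d\n  exclusive: %d\n", x$common,
              x$exclusive))
  cat("  by reference:\n")
  print(x$all_references, row.names = FALSE)
  invisible(x)
}

#' Log2 fold change with pseudocount
#'
#' `log2((treated + pseudocount) / (control + pseudocount))`.
#'
#' @param fpkm_treated,fpkm_control non-negative FPKM values.
#' @param pseudocount positive FPKM pseudocount.
#' @export
log2fc <- function(fpkm_treated, fpkm_control, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (any(fpkm_treated < 0) || any(fpkm_control < 0)) {
    stop("FPKM values must be non-negative")
  }
  log2((fpkm_treated + pseudocount) / (fpkm_control + pseudocount))
}

#' Classify genes as up / down / unchanged between conditions
#'
#' @param genes character vector of gene ids to classify.
#' @param control,treated FPKM tables (`gene_id`, `fpkm`).
#' @param lfc_threshold log2 fold-change magnitude for the up/down calls.
#' @param pseudocount FPKM pseudocount for [log2fc()].
#' @return object of class `expression_comparison`: per-gene `log2fc` and
#'   `class`, tallies, percentages and ids of genes missing from either
#'   table (excluded).
#' @export
classify_expression <- function(genes, control, treated, lfc_threshold = 1,
                                pseudocount = 1) {
  mc <- control$fpkm[match(genes, control$gene_id)]
  mt <- treated$fpkm[match(genes, treated$gene_id)]
  missing <- genes[is.na(mc) | is.na(mt)]
  keep <- !(is.na(mc) | is.na(mt))
  lfc <- log2fc(mt[keep], mc[keep], pseudocount)
  cls <- ifelse(lfc >= lfc_threshold, "up",
                ifelse(lfc <= -lfc_threshold, "down", "unchanged"))
  tab <- c(up = sum(cls == "up"), down = sum(cls == "down"),
           unchanged = sum(cls == "unchanged"))
  structure(list(
    genes = genes[keep], log2fc = lfc, class = cls, tallies = tab,
    percentages = if (sum(tab) > 0) round(100 * tab / sum(tab), 1) else
      tab * NA_real_,
    missing = missing, lfc_threshold = lfc_threshold,
    pseudocount = pseudocount
  ), class = "expression_comparison")
}

#' @export
print.expression_comparison <- function(x, ...) {
  cat(sprintf("Expression classes (|log2FC| >= %g): ", x$lfc_threshold))
  cat(sprintf("up %d (%.1f%%), down %d (%.1f%%), unchanged %d (%.1f%%)\n",
              x$tallies["up"], x$percentages["up"],
              x$tallies["down"], x$percentages["down"],
              x$tallies["unchanged"], x$percentages["unchanged"]))
  if (length(x$missing)) cat(" ", length(x$missing),
                             "gene(s) missing from a table, excluded\n")
  invisible(x)
}

#' Genes overlapped by interaction anchors
#'
#' A gene counts as interacting when any interaction anchor overlaps its
#' gene body by at least 1 bp.
#'
#' @param set `interaction_set`.
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end`).
#' @return character vector of interacting gene ids.
#' @export
interacting_genes <- function(set, genes) {
  if (nrow(set) == 0 || nrow(genes) == 0) return(character(0))
  ag <- as_granges(set_anchor_df(set))
  gg <- as_granges(genes)
  hits <- suppressWarnings(IRanges::overlapsAny(gg, ag))
  unique(genes$gene_id[hits])
}

#' Seeded sample of control (non-interacting) genes
#'
#' @param genes gene table or character vector of all gene ids.
#' @param interacting ids of interacting genes to exclude.
#' @param n sample size (defaults to the number of interacting genes).
#' @param seed integer seed.
#' @return character vector of control gene ids.
#' @export
control_gene_sample <- function(genes, interacting,
                                n = length(interacting), seed = 1) {
  ids <- if (is.data.frame(genes)) genes$gene_id else as.character(genes)
  pool <- setdiff(ids, interacting)
  if (n > length(pool)) stop("not enough non-interacting genes to sample")
  with_seed(seed, sample(pool, n))
}

#' Rank-sum comparison of two expression distributions
#'
#' Two-sided Wilcoxon rank-sum test of interacting vs control gene
#' expression.
#'
#' @param expr_interacting,expr_control numeric FPKM vectors.
#' @return list with `statistic`, `p_value`, `n1`, `n2`; p_value is NA
#'   (flagged by a warning) when either group has fewer than 3 values.
#' @export
compare_groups <- function(expr_interacting, expr_control) {
  n1 <- length(expr_interacting); n2 <- length(expr_control)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  if (n1 < 3 || n2 < 3) {
    warning("group size < 3: p-value undefined")
    return(list(statistic = NA_real_, p_value = NA_real_, n1 = n1, n2 = n2))
  }
  wt <- suppressWarnings(stats::wilcox.test(expr_interacting, expr_control,
                                            alternative = "two.sided",
                                            exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n1 = n1, n2 = n2)
}

# 200-kb tile ids covered by the anchors of a set
block_tiles <- function(set, genome, block_size) {
  df <- as.data.frame(set)
  a <- rbind(stats::setNames(df[, c("chrom1", "start1", "end1")],
                             c("chrom", "start", "end")),
             stats::setNames(df[, c("chrom2", "start2", "end2")],
                             c("chrom", "start", "end")))
  if (nrow(a) == 0L) return(character(0))
  tiles <- unlist(lapply(seq_len(nrow(a)), function(k) {
    lo <- a$start[k] %/% block_size
    hi <- (a$end[k] - 1) %/% block_size
    paste(a$chrom[k], lo:hi, sep = ":")
  }))
  unique(tiles)
}

#' Cumulative block expression of common and unique interacting regions
#'
#' Tiles the genome at a coarse block size (default 200 kb), marks blocks
#' covered by interaction anchors of two conditions as common or unique,
#' sums the FPKM of all genes in each block per condition, and compares
#' cumulative expression of common vs unique blocks by rank-sum test.
#'
#' @param set_a,set_b `interaction_set`s of the two conditions.
#' @param genes gene table.
#' @param fpkm named list of FPKM tables (one per condition).
#' @param genome genome data.frame.
#' @param block_size bp (default 200 kb).
#' @return list with `blocks` (per-block group and cumulative expression
#'   per condition; blocks without genes are excluded and counted in
#'   `n_empty`) and `tests` (rank-sum common-vs-unique per condition).
#' @export
block_expression <- function(set_a, set_b, genes, fpkm, genome,
                             block_size = 2e5) {
  ta <- block_tiles(set_a, genome, block_size)
  tb <- block_tiles(set_b, genome, block_size)
  all_tiles <- union(ta, tb)
  group <- ifelse(all_tiles %in% ta & all_tiles %in% tb, "common",
                  ifelse(all_tiles %in% ta, "unique_a", "unique_b"))
  chrom <- sub(":.*", "", all_tiles)
  tile_i <- as.integer(sub(".*:", "", all_tiles))
  start <- tile_i * block_size
  end <- pmin(start + block_size, chrom_lengths(genome)[chrom])
  blocks <- data.frame(chrom = chrom, start = start, end = end,
                       group = group, stringsAsFactors = FALSE)
  bg <- as_granges(blocks)
  gg <- as_granges(genes)
  ov <- GenomicRanges::findOverlaps(bg, gg)
  cum <- matrix(0, nrow(blocks), length(fpkm),
                dimnames = list(NULL, names(fpkm)))
  for (cond in names(fpkm)) {
    v <- fpkm[[cond]]$fpkm[match(genes$gene_id, fpkm[[cond]]$gene_id)]
    v[is.na(v)] <- 0
    agg <- tapply(v[S4Vectors::subjectHits(ov)],
                  factor(S4Vectors::queryHits(ov),
                         levels = seq_len(nrow(blocks))),
                  sum, default = NA_real_)
    cum[, cond] <- as.numeric(agg)
  }
  has_genes <- !is.na(cum[, 1])
  n_empty <- sum(!has_genes)
  if (n_empty) message(n_empty, " block(s) without genes excluded")
  blocks <- cbind(blocks[has_genes, , drop = FALSE],
                  as.data.frame(cum[has_genes, , drop = FALSE]))
  tests <- lapply(names(fpkm), function(cond) {
    common <- blocks[blocks$group == "common", cond]
    unique_ <- blocks[blocks$group != "common", cond]
    if (length(common) >= 3 && length(unique_) >= 3) {
      compare_groups(common, unique_)
    } else list(statistic = NA_real_, p_value = NA_real_,
                n1 = length(common), n2 = length(unique_))
  })
  names(tests) <- names(fpkm)
  list(blocks = blocks, tests = tests, n_empty = n_empty)
}
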