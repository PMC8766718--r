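# Epigenetic-state assignment and preference testing, GWAS-SNP frequency
# analysis, and motif-region sequence export.

# numeric rank of state labels: embedded number when present ("state8" -> 8),
# otherwise alphabetical order.  Ties in overlap break toward the lower rank.
state_rank <- function(labels) {
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", labels)))
  if (any(is.na(num))) match(labels, sort(unique(labels))) else num
}

#' Primary epigenetic state of anchors
#'
#' Assigns each anchor the state with maximal overlap length; ties break
#' toward the lower state number.  States may overlap each other (the
#' published Arabidopsis states do), so the full set of overlapping states
#' is returned as well.
#'
#' @param anchors data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); a single anchor may be given as a 1-row data.frame.
#' @param es epigenetic-state annotation: data.frame with `chrom`,
#'   `start`, `end`, `label`.
#' @return character vector of primary states (`"unassigned"` where no
#'   state overlaps), with the per-anchor list of overlapping states as
#'   attribute `overlap_sets`.
#' @export
primary_state <- function(anchors, es) {
  n <- nrow(anchors)
  ag <- as_granges(anchors)
  eg <- as_granges(es)
  # anchors on chromosomes the annotation does not cover are legitimately
  # unassigned; silence the seqlevel mismatch chatter
  ov <- suppressWarnings(GenomicRanges::findOverlaps(ag, eg))
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  lab <- es$label[s]
  primary <- rep("unassigned", n)
  overlap_sets <- vector("list", n)
  if (length(q)) {
    w <- GenomicRanges::width(suppressWarnings(
      GenomicRanges::pintersect(ag[q], eg[s])))
    # per (anchor, state): total overlap; choose max, ties -> lower rank
    key <- paste(q, lab, sep = "\r")
    agg <- tapply(w, key, sum)
    kq <- as.integer(sub("\r.*", "", names(agg)))
    kl <- sub(".*\r", "", names(agg))
    rk <- state_rank(kl)
    ord <- order(kq, -as.numeric(agg), rk)
    first <- !duplicated(kq[ord])
    primary[kq[ord][first]] <- kl[ord][first]
    overlap_sets <- split(unique(data.frame(q = kq, lab = kl))$lab,
                          factor(unique(data.frame(q = kq, lab = kl))$q,
                                 levels = seq_len(n)))
  }
  attr(primary, "overlap_sets") <- overlap_sets
  primary
}

set_anchor_df <- function(set) {
  df <- as.data.frame(set)
  rbind(stats::setNames(df[, c("chrom1", "start1", "end1")],
                        c("chrom", "start", "end")),
        stats::setNames(df[, c("chrom2", "start2", "end2")],
                        c("chrom", "start", "end")))
}

#' Epigenetic-state distribution of interacting regions
#'
#' Each anchor contributes its primary state; percentages are over
#' assigned anchors and sum to 100.  In `multi = TRUE` mode every
#' overlapping state of an anchor contributes instead.
#'
#' @param set `interaction_set`.
#' @param es state annotation data.frame.
#' @param multi count every overlapping state rather than the primary one.
#' @return data.frame `state`, `count`, `percent`; attribute `unassigned`
#'   reports anchors overlapping no state.
#' @export
state_distribution <- function(set, es, multi = FALSE) {
  if (nrow(set) == 0) stop("empty interaction set")
  anchors <- set_anchor_df(set)
  ps <- primary_state(anchors, es)
  if (multi) {
    states <- unlist(attr(ps, "overlap_sets"))
  } else {
    states <- ps[ps != "unassigned"]
  }
  tab <- table(states)
  out <- data.frame(state = names(tab), count = as.integer(tab),
                    percent = round(100 * as.integer(tab) / sum(tab), 2),
                    stringsAsFactors = FALSE)
  out <- out[order(state_rank(out$state)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unassigned") <- sum(ps == "unassigned")
  out
}

#' Randomized control interactions
#'
#' Generates a control set with the same number of records, the same
#' anchor lengths and the same cis/trans split as the source set.  Cis
#' partners are placed at a distance resampled from the observed
#' cis-distance distribution; all placements are uniform over valid
#' positions.
#'
#' @param set source `interaction_set`.
#' @param genome genome data.frame.
#' @param seed integer seed.
#' @param max_retries placement retries per record before error.
#' @return `interaction_set` of control records.
#' @export
random_control_interactions <- function(set, genome, seed = 1,
                                        max_retries = 100) {
  stop_if_not_genome(genome)
  df <- as.data.frame(set)
  n <- nrow(df)
  if (n == 0) return(set)
  wA <- df$end1 - df$start1
  wB <- df$end2 - df$start2
  is_cis <- df$class == "cis"
  cis_d <- abs((df$start2 + df$end2) - (df$start1 + df$end1))[is_cis] / 2
  len <- chrom_lengths(genome)
  with_seed(seed, {
    out <- df
    # cis records: resample a distance, place the pair on a random
    # chromosome long enough to hold it; vectorized with retry rounds
    ci <- which(is_cis)
    if (length(ci)) {
      todo <- ci
      for (round in seq_len(max_retries)) {
        m <- length(todo)
        if (!m) break
        d <- sample(cis_d, m, replace = TRUE)
        span <- wA[todo] / 2 + d + wB[todo] / 2
        cn <- sample(genome$name, m, replace = TRUE, prob = genome$length)
        room <- len[cn] - span - 1
        sA <- floor(runif(m) * pmax(room, 1))
        midA <- sA + wA[todo] / 2
        sB <- round(midA + d - wB[todo] / 2)
        ok <- room > 0 & sB >= 0 & sB + wB[todo] <= len[cn]
        if (any(ok)) {
          k <- todo[ok]
          out$chrom1[k] <- cn[ok]
          out$start1[k] <- sA[ok]; out$end1[k] <- sA[ok] + wA[k]
          out$chrom2[k] <- cn[ok]
          out$start2[k] <- sB[ok]; out$end2[k] <- sB[ok] + wB[k]
        }
        todo <- todo[!ok]
      }
      if (length(todo)) stop("could not place a cis control record; ",
                             "genome too small for resampled distance")
    }
    # trans records: anchors uniform on two distinct chromosomes
    ti <- which(!is_cis)
    if (length(ti)) {
      if (nrow(genome) < 2) stop("trans control records need >= 2 chromosomes")
      m <- length(ti)
      c1 <- sample(genome$name, m, replace = TRUE, prob = genome$length)
      c2i <- vapply(c1, function(cn) {
        pool <- setdiff(genome$name, cn)
        sample(pool, 1, prob = len[pool])
      }, character(1))
      sA <- floor(runif(m) * (len[c1] - wA[ti]))
      sB <- floor(runif(m) * (len[c2i] - wB[ti]))
      out$chrom1[ti] <- c1
      out$start1[ti] <- sA; out$end1[ti] <- sA + wA[ti]
      out$chrom2[ti] <- c2i
      out$start2[ti] <- sB; out$end2[ti] <- sB + wB[ti]
    }
    interaction_set(out, condition = paste0(attr(set, "condition"),
                                            "_control"),
                    chrom_levels = genome$name)
  })
}

#' Same-state preference test for interacting partners
#'
#' Observed statistic: the fraction of interactions whose two anchors
#' share a primary epigenetic state.  Null distribution: the same
#' statistic on K independent randomized control sets
#' ([random_control_interactions()]).  The permutation p-value is
#' `(1 + #{null >= observed}) / (K + 1)`; a normal-approximation p-value
#' over the null replicates is reported alongside.
#'
#' @param set `interaction_set`.
#' @param es state annotation.
#' @param genome genome data.frame.
#' @param K number of null replicates.
#' @param seed integer seed.
#' @param same_mode `"primary"` (equal primary states) or `"any"` (any
#'   shared state among the overlap sets).
#' @return object of class `preference_test`: observed fraction, null
#'   fractions, null mean, permutation and normal-approximation p-values.
#' @export
es_preference_test <- function(set, es, genome, K = 1000, seed = 1,
                               same_mode = c("primary", "any")) {
  same_mode <- match.arg(same_mode)
  if (K < 1) stop("K must be >= 1")
  if (nrow(set) == 0) stop("empty interaction set")
  same_state_fraction <- function(s) {
    df <- as.data.frame(s)
    n <- nrow(df)
    anchors <- set_anchor_df(s)
    ps <- primary_state(anchors, es)
    pa <- ps[seq_len(n)]; pb <- ps[n + seq_len(n)]
    if (same_mode == "primary") {
      ok <- pa != "unassigned" & pb != "unassigned"
      if (!any(ok)) return(NA_real_)
      mean(pa[ok] == pb[ok])
    } else {
      os <- attr(ps, "overlap_sets")
      ok <- pa != "unassigned" & pb != "unassigned"
      if (!any(ok)) return(NA_real_)
      shared <- vapply(which(ok), function(k) {
        length(intersect(os[[k]], os[[n + k]])) > 0
      }, logical(1))
      mean(shared)
    }
  }
  observed <- same_state_fraction(set)
  null <- with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, K)
    vapply(seq_len(K), function(r) {
      ctrl <- random_control_interactions(set, genome, seed = sub_seeds[r])
      same_state_fraction(ctrl)
    }, numeric(1))
  })
  null <- null[!is.na(null)]
  p_perm <- (1 + sum(null >= observed)) / (length(null) + 1)
  z <- if (stats::sd(null) > 0) (observed - mean(null)) / stats::sd(null)
       else Inf
  p_norm <- stats::pnorm(z, lower.tail = FALSE)
  structure(list(observed = observed, null = null,
                 null_mean = mean(null), K = length(null),
                 p_permutation = p_perm, p_normal = p_norm,
                 same_mode = same_mode, seed = seed),
            class = "preference_test")
}

#' @export
print.preference_test <- function(x, ...) {
  cat(sprintf("Same-state preference (%s): observed %.3f, null mean %.3f\n",
              x$same_mode, x$observed, x$null_mean))
  cat(sprintf("  permutation p = %.4g (K = %d), normal-approx p = %.4g\n",
              x$p_permutation, x$K, x$p_normal))
  invisible(x)
}

#' Unique-SNP frequency per bp of a region set
#'
#' Number of unique SNP positions falling in the union of the regions,
#' divided by the union length.
#'
#' @param regions data.frame of intervals (`chrom`, `start`, `end`).
#' @param snps data.frame of SNP positions (`chrom`, `pos` 0-based) or
#'   intervals (`chrom`, `start`).
#' @return SNPs per bp.
#' @export
snp_frequency <- function(regions, snps) {
  if (nrow(regions) == 0) stop("empty region list")
  un <- GenomicRanges::reduce(as_granges(regions))
  total <- sum(GenomicRanges::width(un))
  if (total == 0) stop("zero-length region union")
  pos <- if ("pos" %in% names(snps)) snps$pos else snps$start
  up <- unique(data.frame(chrom = snps$chrom, pos = pos))
  sg <- GenomicRanges::GRanges(up$chrom,
                               IRanges::IRanges(up$pos + 1L, up$pos + 1L))
  hits <- sum(IRanges::overlapsAny(sg, un))
  hits / total
}

# sample a set of interval lengths into the complement of a region union
sample_into_complement <- function(piece_lens, comp, seed_stream_ok = TRUE,
                                   max_retries = 200) {
  placed <- GenomicRanges::GRanges()
  comp_w <- GenomicRanges::width(comp)
  for (L in sort(piece_lens, decreasing = TRUE)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      room <- comp_w - L + 1
      cand <- which(room > 0)
      if (!length(cand)) stop("complement too small for control intervals")
      g <- sample(cand, 1, prob = room[cand])
      off <- floor(runif(1) * room[g])
      iv <- GenomicRanges::GRanges(
        GenomeInfoDb::seqnames(comp)[g],
        IRanges::IRanges(GenomicRanges::start(comp)[g] + off, width = L))
      if (!any(IRanges::overlapsAny(iv, placed))) {
        placed <- c(placed, iv)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place control interval without overlap")
  }
  placed
}

#' GWAS-SNP frequency in interacting vs control vs background genome
#'
#' The interacting genome is the union of all interaction anchors.  The
#' control is a seeded random interval set of equal total length and
#' matched piece-length distribution drawn entirely from the
#' non-interacting complement.  Background is all unique SNPs divided by
#' genome length.  The depletion ratio is control frequency over
#' interacting frequency (> 1 means SNPs avoid interacting regions).
#'
#' @param set `interaction_set`.
#' @param snps SNP table (`chrom`, `pos`).
#' @param genome genome data.frame.
#' @param seed integer seed for control placement.
#' @return list `freq_interacting`, `freq_control`, `freq_background`,
#'   `ratio`.
#' @export
gwas_enrichment <- function(set, snps, genome, seed = 1) {
  stop_if_not_genome(genome)
  anchors <- set_anchor_df(set)
  un <- GenomicRanges::reduce(as_granges(anchors, genome))
  gg <- GenomicRanges::GRanges(genome$name,
                               IRanges::IRanges(1, genome$length))
  comp <- GenomicRanges::setdiff(gg, un)
  ctrl <- with_seed(seed, {
    sample_into_complement(GenomicRanges::width(un), comp)
  })
  freq_interacting <- snp_frequency(granges_to_df(un), snps)
  freq_control <- snp_frequency(granges_to_df(ctrl), snps)
  up <- unique(data.frame(chrom = snps$chrom, pos = snps$pos))
  freq_background <- nrow(up) / sum(genome$length)
  list(freq_interacting = freq_interacting, freq_control = freq_control,
       freq_background = freq_background,
       ratio = freq_control / freq_interacting)
}

#' Export motif-search regions around gene-associated anchors
#'
#' For every interaction with at least one anchor overlapping a
#' protein-coding gene, emits the `width`-bp window centered on each
#' qualifying anchor's midpoint (clipped to chromosome bounds),
#' deduplicated on coordinates.  Headers encode the 0-based half-open
#' window coordinates.
#'
#' @param set `interaction_set`.
#' @param genes gene table with `biotype`.
#' @param genome_fasta path to the genome FASTA.
#' @param width window width in bp (default 1000).
#' @param path optional output FASTA path.
#' @return `DNAStringSet` of the extracted sequences (written to `path`
#'   when given).
#' @export
export_motif_regions <- function(set, genes, genome_fasta, width = 1000,
                                 path = NULL) {
  if (!file.exists(genome_fasta)) stop("no such FASTA: ", genome_fasta)
  coding <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  df <- as.data.frame(set)
  if (nrow(df) == 0 || nrow(coding) == 0) {
    out <- Biostrings::DNAStringSet()
    if (!is.null(path)) Biostrings::writeXStringSet(out, path)
    return(out)
  }
  gg <- as_granges(coding)
  aA <- anchors_granges(df, "A"); aB <- anchors_granges(df, "B")
  hitA <- IRanges::overlapsAny(aA, gg)
  hitB <- IRanges::overlapsAny(aB, gg)
  qual <- rbind(
    set_anchor_df(df)[c(which(hitA), nrow(df) + which(hitB)), , drop = FALSE]
  )
  if (nrow(qual) == 0) {
    out <- Biostrings::DNAStringSet()
    if (!is.null(path)) Biostrings::writeXStringSet(out, path)
    return(out)
  }
  seqs <- Biostrings::readDNAStringSet(genome_fasta)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  mid <- round((qual$start + qual$end) / 2)
  # centered window, clipped at chromosome bounds (length <= width)
  s <- pmax(0, mid - floor(width / 2))
  e <- pmin(lens[qual$chrom], mid - floor(width / 2) + width)
  s <- pmax(0, pmin(s, e - 1))
  win <- unique(data.frame(chrom = qual$chrom, start = s, end = e))
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(win)), function(k) {
    as.character(Biostrings::subseq(seqs[[win$chrom[k]]],
                                    start = win$start[k] + 1L,
                                    end = win$end[k]))
  }, character(1)))
  names(out) <- sprintf("%s:%d-%d", win$chrom, win$start, win$end)
  if (!is.null(path)) Biostrings::writeXStringSet(out, path)
  out
}
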