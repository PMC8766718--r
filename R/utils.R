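# Internal helpers shared across modules.

# Run code with a private, seeded RNG stream, restoring the caller's RNG
# state afterwards.  Every generator and every randomized statistic uses
# this, so identical seeds give byte-identical output regardless of what the
# caller has done with .Random.seed.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_genome <- function(genome) {
  if (!is.data.frame(genome) || !all(c("name", "length") %in% names(genome))) {
    stop("'genome' must be a data.frame with columns 'name' and 'length'")
  }
  if (anyDuplicated(genome$name)) stop("chromosome names must be unique")
  if (any(genome$length <= 0)) stop("chromosome lengths must be positive")
  if (nrow(genome) < 1L) stop("genome has no chromosomes")
  invisible(genome)
}

chrom_lengths <- function(genome) {
  stats::setNames(genome$length, genome$name)
}

# 0-based half-open intervals -> GRanges (1-based closed).
as_granges <- function(df, genome = NULL) {
  seqinfo <- NULL
  if (!is.null(genome)) {
    seqinfo <- GenomeInfoDb::Seqinfo(seqnames = genome$name,
                                     seqlengths = genome$length)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  if (!is.null(seqinfo)) GenomeInfoDb::seqinfo(gr) <- seqinfo[as.character(
    unique(GenomeInfoDb::seqnames(gr))), ]
  gr
}

granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

check_intervals <- function(df, genome, what = "interval") {
  stop_if_not_genome(genome)
  len <- chrom_lengths(genome)
  if (!all(df$chrom %in% names(len))) {
    stop(sprintf("%s on unknown chromosome: %s", what,
                 paste(setdiff(unique(df$chrom), names(len)), collapse = ", ")))
  }
  bad <- df$start < 0 | df$end > len[df$chrom] | df$start >= df$end
  if (any(bad)) {
    stop(sprintf("%s out of chromosome bounds (first bad row %d)",
                 what, which(bad)[1L]))
  }
  invisible(df)
}

# Genome-wide bin tiling at a fixed bin size; last bin of each chromosome is
# truncated.  Returns one row per bin with a global 1-based index.
bin_table <- function(genome, bin_size) {
  stop_if_not_genome(genome)
  stopifnot(bin_size > 0)
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    n <- ceiling(genome$length[i] / bin_size)
    start <- (seq_len(n) - 1L) * bin_size
    data.frame(chrom = genome$name[i],
               start = start,
               end = pmin(start + bin_size, genome$length[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$bin <- seq_len(nrow(out))
  out
}

# Map (chrom, pos) to the global bin index of bin_table(genome, bin_size).
bin_index <- function(chrom, pos, genome, bin_size) {
  len <- chrom_lengths(genome)
  if (!all(chrom %in% names(len))) {
    stop("position on unknown chromosome: ",
         paste(setdiff(unique(chrom), names(len)), collapse = ", "))
  }
  if (any(pos < 0 | pos >= len[chrom])) {
    stop("position outside chromosome bounds")
  }
  nbin <- ceiling(len / bin_size)
  offset <- stats::setNames(cumsum(c(0, nbin[-length(nbin)])), names(nbin))
  as.integer(offset[chrom] + pos %/% bin_size + 1L)
}

bin_label <- function(bins) {
  sprintf("%s:%d-%d", bins$chrom, bins$start, bins$end)
}

fmt_count <- function(x) formatC(x, big.mark = ",", format = "d")
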