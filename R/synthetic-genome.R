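#' Generate a toy multi-chromosome genome with restriction sites
#'
#' Builds a stand-in reference genome together with a restriction-fragment
#' map.  Restriction sites are placed by exponential inter-site spacing
#' (Poisson process), emulating a 6-cutter such as HindIII whose mean
#' fragment size in the Arabidopsis genome is on the order of 4 kb.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_length length of every chromosome in bp.
#' @param site_spacing_mean mean distance between successive restriction
#'   sites in bp; must be smaller than `chrom_length` for any sites to be
#'   likely.
#' @param seed integer seed; identical seeds give identical output.
#' @return a list with components `genome` (data.frame with columns `name`
#'   and `length`) and `fragmap` (a `fragment_map`: per-chromosome ascending
#'   restriction-site positions, 0-based bp).
#' @examples
#' gf <- make_genome(n_chrom = 2, chrom_length = 1e5, site_spacing_mean = 4000,
#'                   seed = 1)
#' head(fragments(gf$fragmap, "chr1"))
#' @export
make_genome <- function(n_chrom = 3, chrom_length = 2e6,
                        site_spacing_mean = 4000, seed = 1) {
  if (n_chrom < 1) stop("n_chrom must be >= 1")
  if (chrom_length <= 0) stop("chrom_length must be positive")
  if (site_spacing_mean <= 0) stop("site_spacing_mean must be positive")
  genome <- data.frame(name = paste0("chr", seq_len(n_chrom)),
                       length = as.numeric(rep(chrom_length, n_chrom)),
                       stringsAsFactors = FALSE)
  sites <- with_seed(seed, {
    lapply(seq_len(n_chrom), function(i) {
      # oversample waiting times, keep sites inside the chromosome
      n_draw <- max(16L, ceiling(chrom_length / site_spacing_mean * 1.5) + 16L)
      pos <- cumsum(rexp(n_draw, rate = 1 / site_spacing_mean))
      while (length(pos) && pos[length(pos)] < chrom_length) {
        pos <- c(pos, pos[length(pos)] +
                   cumsum(rexp(n_draw, rate = 1 / site_spacing_mean)))
      }
      pos <- floor(pos[pos < chrom_length])
      sort(unique(pos[pos > 0]))
    })
  })
  names(sites) <- genome$name
  fragmap <- structure(list(sites = sites, genome = genome),
                       class = "fragment_map")
  list(genome = genome, fragmap = fragmap)
}

#' Restriction fragments of one chromosome
#'
#' @param fragmap a `fragment_map` from [make_genome()].
#' @param chrom chromosome name.
#' @return data.frame of half-open fragment intervals (`start`, `end`,
#'   0-based) that tile the chromosome exactly; fragment index `frag` is
#'   0-based to match [assign_fragment()].
#' @export
fragments <- function(fragmap, chrom) {
  stopifnot(inherits(fragmap, "fragment_map"))
  if (!chrom %in% names(fragmap$sites)) stop("unknown chromosome: ", chrom)
  len <- fragmap$genome$length[match(chrom, fragmap$genome$name)]
  b <- c(0, fragmap$sites[[chrom]], len)
  data.frame(frag = seq_len(length(b) - 1L) - 1L,
             start = b[-length(b)], end = b[-1L])
}

#' @export
print.fragment_map <- function(x, ...) {
  ns <- vapply(x$sites, length, integer(1))
  cat("Restriction fragment map:", length(ns), "chromosome(s),",
      fmt_count(sum(ns)), "sites,", fmt_count(sum(ns) + length(ns)),
      "fragments\n")
  invisible(x)
}

#' Generate synthetic gene models
#'
#' Draws genes of exponential length at uniform positions, a fixed
#' proportion annotated as protein coding (the remainder are labelled
#' transposable-element genes, mirroring the heterochromatin-rich gene
#' complement of a plant genome).
#'
#' @param genome genome data.frame.
#' @param n_genes number of genes.
#' @param mean_len mean gene length (bp).
#' @param prop_coding proportion of genes with biotype `protein_coding`.
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `biotype`, sorted by position.
#' @export
make_genes <- function(genome, n_genes = 300, mean_len = 2000,
                       prop_coding = 0.9, seed = 1) {
  stop_if_not_genome(genome)
  stopifnot(n_genes >= 1, mean_len > 0, prop_coding >= 0, prop_coding <= 1)
  with_seed(seed, {
    chrom <- sample(genome$name, n_genes, replace = TRUE,
                    prob = genome$length)
    len <- pmax(200, round(rexp(n_genes, 1 / mean_len)))
    maxstart <- pmax(0, chrom_lengths(genome)[chrom] - len)
    start <- floor(runif(n_genes) * maxstart)
    out <- data.frame(
      gene_id = sprintf("GENE%05d", seq_len(n_genes)),
      chrom = chrom,
      start = start,
      end = pmin(start + len, chrom_lengths(genome)[chrom]),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      biotype = ifelse(runif(n_genes) < prop_coding, "protein_coding",
                       "transposable_element_gene"),
      stringsAsFactors = FALSE
    )
    out <- out[order(match(out$chrom, genome$name), out$start), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write a random genome sequence consistent with the fragment map
#'
#' Emits a FASTA with uniform random nucleotides, then stamps the
#' restriction motif `AAGCTT` (HindIII) at every restriction-site position
#' of the fragment map so that sequence and fragment map agree.
#'
#' @param genome genome data.frame.
#' @param fragmap matching `fragment_map`.
#' @param path output FASTA path.
#' @param seed integer seed for the random sequence.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, fragmap, path, seed = 1) {
  stop_if_not_genome(genome)
  stopifnot(inherits(fragmap, "fragment_map"))
  seqs <- with_seed(seed, {
    lapply(seq_len(nrow(genome)), function(i) {
      len <- genome$length[i]
      s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      for (site in fragmap$sites[[genome$name[i]]]) {
        if (site + 6 <= len) s[(site + 1):(site + 6)] <-
            c("A", "A", "G", "C", "T", "T")
      }
      paste(s, collapse = "")
    })
  })
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  names(dna) <- genome$name
  Biostrings::writeXStringSet(dna, filepath = path, width = 70L)
  invisible(path)
}
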