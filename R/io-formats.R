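# Readers and writers for every external format the pipeline touches.
# Internal convention everywhere: 0-based half-open coordinates.  BED is
# native; GFF3 (1-based inclusive) is converted on read and write.

#' Read aligned Hi-C pair records
#'
#' Tab-separated, 7 columns: readname, chrom1, pos1, strand1, chrom2,
#' pos2, strand2.  Malformed lines (wrong column count, bad strand symbol,
#' negative position) raise an error naming the line.
#'
#' @param path input file.
#' @return read-pair data.frame.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    return(data.frame(name = character(), chrom1 = character(),
                      pos1 = integer(), strand1 = character(),
                      chrom2 = character(), pos2 = integer(),
                      strand2 = character(), stringsAsFactors = FALSE))
  }
  nf <- utils::count.fields(path, sep = "\t", quote = "",
                            comment.char = "")
  bad <- which(nf != 7L)
  if (length(bad)) {
    stop(sprintf("line %d: expected 7 tab-separated columns, found %d",
                 bad[1L], nf[bad[1L]]))
  }
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE,
                          col.names = c("name", "chrom1", "pos1", "strand1",
                                        "chrom2", "pos2", "strand2"),
                          colClasses = c("character", "character", "numeric",
                                         "character", "character", "numeric",
                                         "character"))
  bad_strand <- which(!(df$strand1 %in% c("+", "-")) |
                        !(df$strand2 %in% c("+", "-")))
  if (length(bad_strand)) {
    stop(sprintf("line %d: invalid strand symbol", bad_strand[1L]))
  }
  bad_pos <- which(df$pos1 < 0 | df$pos2 < 0 |
                     df$pos1 != floor(df$pos1) | df$pos2 != floor(df$pos2))
  if (length(bad_pos)) {
    stop(sprintf("line %d: invalid position", bad_pos[1L]))
  }
  df$pos1 <- as.integer(df$pos1); df$pos2 <- as.integer(df$pos2)
  df
}

#' Write aligned Hi-C pair records
#'
#' @param pairs read-pair data.frame; only the 7 standard columns are
#'   written (hidden truth labels are dropped).
#' @param path output file.
#' @export
write_pairs <- function(pairs, path) {
  cols <- c("name", "chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  if (!all(cols %in% names(pairs))) {
    stop("pairs must have columns ", paste(cols, collapse = ", "))
  }
  utils::write.table(pairs[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of labelled intervals
#'
#' @param path BED3+ file; column 4, when present, becomes `label`.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `label`; sorted by position (unsorted input is accepted).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- granges_to_df(gr)
  df$label <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write intervals as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional `label`.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  gr <- as_granges(df)
  if (!is.null(df$label)) gr$name <- df$label
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps `gene`-type features and converts 1-based inclusive GFF3
#' coordinates to the package's 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `biotype` (defaults to `protein_coding` when the file carries no
#'   biotype attribute).
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  df <- granges_to_df(gr)
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else
    sprintf("gene%05d", seq_along(gr))
  bio <- if (!is.null(gr$biotype)) as.character(gr$biotype) else
    rep("protein_coding", length(gr))
  bio[is.na(bio)] <- "protein_coding"
  out <- data.frame(gene_id = id, chrom = df$chrom, start = df$start,
                    end = df$end,
                    strand = as.character(BiocGenerics::strand(gr)),
                    biotype = bio, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write gene models as GFF3
#'
#' @param genes gene data.frame ([make_genes()] layout).
#' @param path output file.
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- as_granges(genes)
  BiocGenerics::strand(gr) <- genes$strand
  gr$source <- "hicstress"
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$biotype <- genes$biotype
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read / write per-gene FPKM tables
#'
#' Two-column TSV with header `gene_id`, `fpkm`.
#'
#' @param path file path.
#' @return data.frame `gene_id`, `fpkm`.
#' @export
read_fpkm <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "fpkm") %in% names(df))) {
    stop("FPKM table must have columns gene_id and fpkm")
  }
  if (any(df$fpkm < 0)) stop("negative FPKM value")
  df[, c("gene_id", "fpkm")]
}

#' @rdname read_fpkm
#' @param expr FPKM data.frame to write.
#' @export
write_fpkm <- function(expr, path) {
  utils::write.table(expr[, c("gene_id", "fpkm")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an interaction set as BEDPE
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, name,
#' score (= -log10 p, 3 decimals), strand1, strand2, then observed,
#' expected, p_value, class as extra columns.
#'
#' @param set `interaction_set`.
#' @param path output file.
#' @export
write_bedpe <- function(set, path) {
  df <- as.data.frame(set)
  out <- data.frame(
    chrom1 = df$chrom1, start1 = df$start1, end1 = df$end1,
    chrom2 = df$chrom2, start2 = df$start2, end2 = df$end2,
    name = sprintf("%s_%05d", attr(set, "condition") %||% "int",
                   seq_len(nrow(df))),
    score = round(-log10(pmax(df$p_value, 1e-300)), 3),
    strand1 = ".", strand2 = ".",
    observed = df$observed, expected = signif(df$expected, 10),
    p_value = signif(df$p_value, 10), class = df$class,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an interaction set from BEDPE
#'
#' Anchor pairs violating the canonical order are normalized with a
#' warning.
#'
#' @param path BEDPE file written by [write_bedpe()].
#' @param condition condition label for the resulting set.
#' @return `interaction_set`.
#' @export
read_bedpe <- function(path, condition = "condition") {
  if (file.size(path) == 0) {
    empty <- data.frame(chrom1 = character(), start1 = integer(),
                        end1 = integer(), chrom2 = character(),
                        start2 = integer(), end2 = integer(),
                        observed = numeric(), expected = numeric(),
                        p_value = numeric(), class = character(),
                        stringsAsFactors = FALSE)
    return(interaction_set(empty, condition = condition))
  }
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 14) stop("expected 14 BEDPE columns")
  names(df)[1:14] <- c("chrom1", "start1", "end1", "chrom2", "start2",
                       "end2", "name", "score", "strand1", "strand2",
                       "observed", "expected", "p_value", "class")
  lv <- sort(unique(c(df$chrom1, df$chrom2)))
  ra <- match(df$chrom1, lv); rb <- match(df$chrom2, lv)
  if (any(rb < ra | (rb == ra & df$start2 < df$start1))) {
    warning("unordered anchor pair(s) normalized on read")
  }
  interaction_set(df[, c("chrom1", "start1", "end1", "chrom2", "start2",
                         "end2", "observed", "expected", "p_value", "class")],
                  condition = condition, chrom_levels = lv)
}

#' Write / read a symmetric matrix as TSV
#'
#' Square matrix with bin coordinates as row and column headers; masked
#' entries serialized as `NA`.  Non-square or asymmetric files are
#' rejected on read.
#'
#' @param m matrix with dimnames.
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  df <- as.data.frame(signif(unclass(m), 10))
  utils::write.table(cbind(bin = rownames(m), df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  rn <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- rn
  if (nrow(m) != ncol(m)) stop("matrix file is not square")
  storage.mode(m) <- "double"
  asym <- !is.na(m) & !is.na(t(m)) & abs(m - t(m)) >
    1e-6 * pmax(abs(m), abs(t(m)), 1e-12)
  if (any(asym) || any(is.na(m) != is.na(t(m)))) {
    stop("matrix file is not symmetric")
  }
  m
}

#' Write / read the synthetic ground truth as JSON
#'
#' @param truth `truth_set`.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "truth_set"))
  obj <- unclass(truth)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("bins", "planted_pairs", "depleted_regions", "effect_genes")) {
    if (!is.null(obj[[nm]])) obj[[nm]] <- as.data.frame(obj[[nm]])
  }
  structure(obj, class = "truth_set")
}
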