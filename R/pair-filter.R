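#' Fragment assignment by binary search
#'
#' Maps a position to the 0-based index of the restriction fragment
#' containing it.  Fragments are half-open, so a position equal to a
#' restriction site belongs to the downstream fragment.
#'
#' @param chrom chromosome name (scalar or vector recycled with `pos`).
#' @param pos 0-based position(s).
#' @param fragmap `fragment_map` from [make_genome()].
#' @return integer 0-based fragment index, same length as `pos`.
#' @examples
#' fm <- structure(list(sites = list(chrA = c(100, 200)),
#'                      genome = data.frame(name = "chrA", length = 300)),
#'                 class = "fragment_map")
#' assign_fragment("chrA", c(0, 100, 150, 250), fm)  # 0 1 1 2
#' @export
assign_fragment <- function(chrom, pos, fragmap) {
  stopifnot(inherits(fragmap, "fragment_map"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  len <- chrom_lengths(fragmap$genome)
  if (!all(chrom %in% names(len))) {
    stop("unknown chromosome: ",
         paste(setdiff(unique(chrom), names(len)), collapse = ", "))
  }
  if (any(pos < 0 | pos >= len[chrom])) stop("position out of range")
  out <- integer(n)
  for (cn in unique(chrom)) {
    ii <- which(chrom == cn)
    out[ii] <- findInterval(pos[ii], fragmap$sites[[cn]])
  }
  out
}

# TRUE where the mate has a restriction site within `window` bp downstream
# of its 3' end: increasing coordinates for "+" reads, decreasing for "-".
has_downstream_site <- function(chrom, pos, strand, fragmap, window) {
  n <- length(pos)
  ok <- logical(n)
  for (cn in unique(chrom)) {
    ii <- which(chrom == cn)
    s <- fragmap$sites[[cn]]
    if (!length(s)) { ok[ii] <- FALSE; next }
    p <- pos[ii]; st <- strand[ii]
    res <- logical(length(ii))
    plus <- st == "+"
    if (any(plus)) {
      nxt <- findInterval(p[plus], s) + 1L     # first site strictly > pos
      has <- nxt <= length(s)
      res[plus] <- has & (s[pmin(nxt, length(s))] - p[plus]) <= window
    }
    if (any(!plus)) {
      prv <- findInterval(p[!plus] - 1L, s)    # last site strictly < pos
      has <- prv >= 1L
      res[!plus] <- has & (p[!plus] - s[pmax(prv, 1L)]) <= window
    }
    ok[ii] <- res
  }
  ok
}

#' Remove uninformative Hi-C read pairs
#'
#' Classifies and removes read pairs that do not represent true spatial
#' contacts, in a fixed precedence so that the QC report is a partition of
#' the input: (0) PCR duplicates (identical coordinates of both mates,
#' optional), (1) both mates in one restriction fragment
#' (self-ligation/dangling ends), (2) mates in adjacent fragments
#' (re-ligation), (3) same-chromosome inward-facing mates closer than the
#' insert window (continuous genomic fragments), (4) pairs in which neither
#' mate has a restriction site within the insert window downstream of its
#' 3' end.
#'
#' @param pairs read-pair data.frame (see [simulate_pairs()] /
#'   [read_pairs()]).
#' @param fragmap `fragment_map`.
#' @param insert_window bp; estimated sequencing insert length used for
#'   rules (3) and (4).
#' @param remove_duplicates collapse identical coordinate pairs to one
#'   before categorization.
#' @return list with `pairs` (retained records) and `report` (a
#'   `qc_report` whose counts sum to the input count).
#' @export
filter_pairs <- function(pairs, fragmap, insert_window = 500,
                         remove_duplicates = TRUE) {
  stopifnot(inherits(fragmap, "fragment_map"))
  if (insert_window <= 0) stop("insert_window must be positive")
  need <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  if (!all(need %in% names(pairs))) {
    stop("pairs must have columns ", paste(need, collapse = ", "))
  }
  n <- nrow(pairs)
  report <- list(input_pairs = n, removed_duplicate = 0L,
                 removed_same_fragment = 0L, removed_religation = 0L,
                 removed_continuous = 0L, removed_no_site = 0L,
                 retained = 0L)
  if (n == 0L) {
    return(list(pairs = pairs,
                report = structure(report, class = "qc_report")))
  }

  status <- rep("retained", n)

  if (remove_duplicates) {
    # canonical coordinate key, mate order ignored
    first <- ifelse(pairs$chrom1 < pairs$chrom2 |
                      (pairs$chrom1 == pairs$chrom2 &
                         pairs$pos1 <= pairs$pos2), 1L, 2L)
    key <- ifelse(first == 1L,
                  paste(pairs$chrom1, pairs$pos1, pairs$strand1,
                        pairs$chrom2, pairs$pos2, pairs$strand2),
                  paste(pairs$chrom2, pairs$pos2, pairs$strand2,
                        pairs$chrom1, pairs$pos1, pairs$strand1))
    status[duplicated(key)] <- "duplicate"
  }

  live <- status == "retained"
  f1 <- assign_fragment(pairs$chrom1[live], pairs$pos1[live], fragmap)
  f2 <- assign_fragment(pairs$chrom2[live], pairs$pos2[live], fragmap)
  same_chr <- pairs$chrom1[live] == pairs$chrom2[live]

  cat1 <- same_chr & f1 == f2
  cat2 <- same_chr & !cat1 & abs(f1 - f2) == 1L

  p1 <- pairs$pos1[live]; p2 <- pairs$pos2[live]
  s1 <- pairs$strand1[live]; s2 <- pairs$strand2[live]
  inward <- same_chr &
    ((p1 <= p2 & s1 == "+" & s2 == "-") |
       (p2 < p1 & s2 == "+" & s1 == "-"))
  cat3 <- !cat1 & !cat2 & inward & abs(p2 - p1) < insert_window

  ok1 <- has_downstream_site(pairs$chrom1[live], p1, s1, fragmap,
                             insert_window)
  ok2 <- has_downstream_site(pairs$chrom2[live], p2, s2, fragmap,
                             insert_window)
  cat4 <- !cat1 & !cat2 & !cat3 & !ok1 & !ok2

  st <- rep("retained", sum(live))
  st[cat4] <- "no_site"; st[cat3] <- "continuous"
  st[cat2] <- "religation"; st[cat1] <- "same_fragment"
  status[live] <- st

  report$removed_duplicate <- sum(status == "duplicate")
  report$removed_same_fragment <- sum(status == "same_fragment")
  report$removed_religation <- sum(status == "religation")
  report$removed_continuous <- sum(status == "continuous")
  report$removed_no_site <- sum(status == "no_site")
  report$retained <- sum(status == "retained")

  out <- pairs[status == "retained", , drop = FALSE]
  rownames(out) <- NULL
  rep_obj <- structure(report, class = "qc_report")
  attr(rep_obj, "status") <- status
  list(pairs = out, report = rep_obj)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Read-pair QC report\n")
  cat(sprintf("  input pairs:        %s\n", fmt_count(x$input_pairs)))
  cat(sprintf("  PCR duplicates:     %s\n", fmt_count(x$removed_duplicate)))
  cat(sprintf("  self-ligation:      %s\n",
              fmt_count(x$removed_same_fragment)))
  cat(sprintf("  re-ligation:        %s\n", fmt_count(x$removed_religation)))
  cat(sprintf("  continuous genomic: %s\n", fmt_count(x$removed_continuous)))
  cat(sprintf("  no 3' site:         %s\n", fmt_count(x$removed_no_site)))
  cat(sprintf("  retained:           %s (%.1f%%)\n", fmt_count(x$retained),
              if (x$input_pairs > 0) 100 * x$retained / x$input_pairs else 0))
  invisible(x)
}

#' @export
as.list.qc_report <- function(x, ...) {
  attributes(x) <- NULL
  names(x) <- c("input_pairs", "removed_duplicate", "removed_same_fragment",
                "removed_religation", "removed_continuous",
                "removed_no_site", "retained")
  x
}
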