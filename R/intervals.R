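#' Construct a set of genomic intervals
#'
#' An `IntervalSet` is the package's substrate for peaks, enhancer regions,
#' Hi-C anchors and promoter windows. Coordinates are 0-based, half-open
#' (`start` inclusive, `end` exclusive), the BED convention; intervals are
#' stored sorted by (chrom, start, end, name) so iteration order is
#' deterministic.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start,end Integer-like vectors, `0 <= start < end`.
#' @param name Optional identifiers; defaults to `"."`.
#' @param score Optional numeric scores; defaults to 0.
#' @param strand Optional strand (`"+"`, `"-"` or `"."`); defaults to `"."`.
#' @param label Optional track label (e.g. `"ATAC_naive"`), kept as an
#'   attribute.
#' @return A data frame of class `IntervalSet` with columns
#'   `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @examples
#' interval_set("chr1", c(100, 500), c(200, 900), label = "ATAC_naive")
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer(), name = NULL, score = NULL,
                         strand = NULL, label = NULL) {
  n <- max(length(chrom), length(start), length(end))
  if (!all(lengths(list(chrom, start, end)) %in% c(1L, n))) {
    stop("chrom, start and end must have equal length (or length 1)",
         call. = FALSE)
  }
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (n > 0) {
    if (anyNA(chrom) || any(!nzchar(chrom))) {
      stop("chrom must be non-empty", call. = FALSE)
    }
    if (anyNA(start) || anyNA(end)) stop("coordinates must not be NA", call. = FALSE)
    bad <- which(start < 0 | start >= end)
    if (length(bad) > 0) {
      stop(sprintf("invalid interval at position %d: start=%s end=%s (need 0 <= start < end)",
                   bad[1], format(start[bad[1]], scientific = FALSE),
                   format(end[bad[1]], scientific = FALSE)), call. = FALSE)
    }
  }
  name <- if (is.null(name)) rep(".", n) else as.character(name)
  score <- if (is.null(score)) rep(0, n) else as.numeric(score)
  strand <- if (is.null(strand)) rep(".", n) else as.character(strand)
  if (n > 0 && !all(strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   name = name, score = score, strand = strand,
                   stringsAsFactors = FALSE)
  if (n > 1) df <- df[order(df$chrom, df$start, df$end, df$name), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("IntervalSet", "data.frame"), label = label)
}

new_interval_set <- function(df, label = NULL) {
  interval_set(df$chrom, df$start, df$end,
               name = if ("name" %in% names(df)) df$name else NULL,
               score = if ("score" %in% names(df)) df$score else NULL,
               strand = if ("strand" %in% names(df)) df$strand else NULL,
               label = label)
}

#' @export
print.IntervalSet <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("IntervalSet%s with %d intervals\n",
              if (is.null(lab)) "" else paste0(" '", lab, "'"), nrow(x)))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Label of an interval set
#' @param x An `IntervalSet`.
#' @return The track label, or `NULL`.
#' @export
set_label <- function(x) attr(x, "label")

# 0-based half-open -> 1-based closed GRanges; strand deliberately dropped
# (strand never gates overlap eligibility).
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Pairwise interval overlap
#'
#' Two intervals overlap iff they are on the same chromosome and share at
#' least one base under half-open coordinates: `a$start < b$end` and
#' `b$start < a$end`. Adjacent intervals (`a$end == b$start`) do not overlap.
#'
#' @param a,b `IntervalSet`s of equal length, or length one (recycled).
#' @return Logical vector.
#' @examples
#' a <- interval_set("chr1", 100, 200)
#' overlaps(a, interval_set("chr1", 150, 250))  # TRUE
#' overlaps(a, interval_set("chr1", 200, 300))  # FALSE: adjacency
#' @export
overlaps <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na != nb && na != 1 && nb != 1) {
    stop("a and b must have equal length or length one", call. = FALSE)
  }
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Per-query overlap presence against a subject set
#'
#' The workhorse behind every `+`/`-` track-status call: element `i` is
#' `TRUE` iff query interval `i` overlaps at least one subject interval.
#'
#' @param query,subject `IntervalSet`s.
#' @return Logical vector, one element per query interval.
#' @export
intersect_presence <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  GenomicRanges::countOverlaps(as_granges(query), as_granges(subject)) > 0
}

#' Keep regions reproducible across two replicates
#'
#' Returns the `rep1` intervals that overlap at least one `rep2` interval;
#' `rep1` coordinates are kept unchanged, making it the coordinate
#' reference for the merged track. Peaks called in only one replicate are
#' discarded from downstream analysis.
#'
#' @param rep1,rep2 Replicate peak `IntervalSet`s for the same track.
#' @return An `IntervalSet` (subset of `rep1`).
#' @export
replicate_reproducible <- function(rep1, rep2) {
  keep <- intersect_presence(rep1, rep2)
  new_interval_set(as.data.frame(rep1)[keep, , drop = FALSE],
                   label = attr(rep1, "label"))
}

#' Construct a table of transcription start sites
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom Chromosome names.
#' @param tss 0-based TSS positions.
#' @param strand `"+"` or `"-"` per gene.
#' @return A data frame of class `TSSTable`.
#' @export
tss_table <- function(gene_id, chrom, tss, strand) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id in TSS table: ",
         gene_id[duplicated(gene_id)][1], call. = FALSE)
  }
  if (!all(strand %in% c("+", "-"))) {
    stop("TSS strand must be '+' or '-'", call. = FALSE)
  }
  if (any(tss < 0)) stop("tss positions must be >= 0", call. = FALSE)
  df <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                   tss = as.numeric(tss), strand = as.character(strand),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("TSSTable", "data.frame"))
}

#' Assign regions to their closest TSS
#'
#' Each region is assigned the gene whose TSS minimises the absolute
#' distance to the region midpoint (`floor((start + end) / 2)`). The
#' reported distance is the signed midpoint-to-TSS offset in the gene's
#' strand orientation: positive when the region midpoint lies downstream of
#' the TSS, negative when upstream. Ties are broken by the
#' lexicographically smaller `gene_id`. Strand never affects which gene is
#' chosen, only the sign.
#'
#' @param regions An `IntervalSet`.
#' @param tss A `TSSTable` (non-empty).
#' @return Data frame with one row per region: `gene_id`, `distance`.
#' @export
nearest_tss <- function(regions, tss) {
  if (nrow(tss) == 0) stop("TSS table is empty", call. = FALSE)
  n <- nrow(regions)
  gene_out <- character(n)
  dist_out <- numeric(n)
  mid <- floor((regions$start + regions$end) / 2)
  # order TSS rows so that which.min ties resolve to the smaller gene_id
  tss <- tss[order(tss$gene_id), , drop = FALSE]
  split_idx <- split(seq_len(nrow(tss)), tss$chrom)
  for (i in seq_len(n)) {
    idx <- split_idx[[regions$chrom[i]]]
    if (is.null(idx)) {
      stop(sprintf("no TSS on chromosome '%s' (region %s:%s-%s)",
                   regions$chrom[i], regions$chrom[i],
                   format(regions$start[i], scientific = FALSE),
                   format(regions$end[i], scientific = FALSE)),
           call. = FALSE)
    }
    d <- mid[i] - tss$tss[idx]
    j <- idx[which.min(abs(d))]
    gene_out[i] <- tss$gene_id[j]
    raw <- mid[i] - tss$tss[j]
    dist_out[i] <- if (tss$strand[j] == "-") -raw else raw
  }
  data.frame(gene_id = gene_out, distance = dist_out,
             stringsAsFactors = FALSE)
}

#' Symmetric window around an anchor position
#'
#' Builds the half-open interval
#' `[max(0, anchor_pos - half_width), anchor_pos + half_width)`, clipped at
#' the chromosome origin. Used for the +/- 2 kb promoter window around a
#' TSS and the +/- 10 kb window around a peak center.
#'
#' @param chrom Chromosome name(s).
#' @param anchor_pos Anchor position(s), 0-based.
#' @param half_width Window half-width in bp (> 0).
#' @return An `IntervalSet`, one interval per anchor.
#' @examples
#' window_around("chr1", 5000, 2000)  # chr1:3000-7000
#' window_around("chr1", 500, 10000)  # chr1:0-10500, clipped at 0
#' @export
window_around <- function(chrom, anchor_pos, half_width) {
  if (any(half_width <= 0)) stop("half_width must be > 0", call. = FALSE)
  interval_set(chrom, pmax(0, anchor_pos - half_width),
               anchor_pos + half_width)
}
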