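#' Normalize per-region tag counts as tags per 10 million (RP10M)
#'
#' Counts the tags overlapping each region and scales by
#' `scale / library_size` (default scale 1e7), the tags-per-10-million
#' normalization used for peak intensities. Linear in tag counts and
#' inversely proportional to library size.
#'
#' @param regions An `IntervalSet` of regions to quantify.
#' @param tags An `IntervalSet` of sequenced tags/fragments.
#' @param library_size Total tag count of the original library; defaults to
#'   `nrow(tags)`. Must be positive and at least the number of tags given.
#' @param scale Normalization constant (tags per `scale` reads).
#' @return A `SignalVector`: numeric vector of RP10M values named by region
#'   (`chrom:start-end` or the region name), with the library size as an
#'   attribute.
#' @examples
#' regions <- interval_set("chr1", 1000, 2000)
#' tags <- interval_set(rep("chr1", 100), 1400 + seq_len(100), 1401 + seq_len(100))
#' rp10m(regions, tags, library_size = 2e7)  # 100 * 1e7 / 2e7 = 50
#' @export
rp10m <- function(regions, tags, library_size = nrow(tags), scale = 1e7) {
  if (length(library_size) != 1 || is.na(library_size) || library_size <= 0) {
    stop("library_size must be a single positive count", call. = FALSE)
  }
  if (library_size < nrow(tags)) {
    stop("library_size is smaller than the number of tags provided",
         call. = FALSE)
  }
  counts <- if (nrow(regions) == 0) {
    numeric(0)
  } else if (nrow(tags) == 0) {
    rep(0, nrow(regions))
  } else {
    GenomicRanges::countOverlaps(as_granges(regions), as_granges(tags))
  }
  vals <- counts * scale / library_size
  ids <- ifelse(regions$name != ".", regions$name,
                paste0(regions$chrom, ":", format_coord(regions$start), "-",
                       format_coord(regions$end)))
  names(vals) <- ids
  structure(vals, library_size = library_size, class = c("SignalVector", "numeric"))
}

#' Binned signal profile matrix around anchor positions
#'
#' For each anchor, the window `[anchor - half_window, anchor + half_window)`
#' is divided into `n_bins` equal subdivisions and each cell holds the RP10M
#' of tags falling in that subdivision (bins truncated at the chromosome
#' origin count only their non-negative part). Column means give the
#' averaged profile; row sums equal [rp10m()] over the full windows.
#'
#' @param anchor_chrom,anchor_pos Anchor chromosomes and positions.
#' @param tags An `IntervalSet` of tags.
#' @param half_window Half-window in bp; `n_bins` must divide
#'   `2 * half_window`.
#' @param n_bins Number of equal bins across the window.
#' @param library_size Total library tag count.
#' @param scale Normalization constant.
#' @return Numeric anchors x bins matrix; bin columns are labelled by their
#'   offset from the anchor.
#' @export
profile_matrix <- function(anchor_chrom, anchor_pos, tags, half_window,
                           n_bins, library_size = nrow(tags), scale = 1e7) {
  if ((2 * half_window) %% n_bins != 0) {
    stop(sprintf("n_bins (%d) must divide the window width (%d)",
                 as.integer(n_bins), as.integer(2 * half_window)),
         call. = FALSE)
  }
  if (library_size <= 0) stop("library_size must be positive", call. = FALSE)
  n <- length(anchor_pos)
  bin_w <- 2 * half_window / n_bins
  offs <- -half_window + (seq_len(n_bins) - 1) * bin_w
  out <- matrix(0, nrow = n, ncol = n_bins,
                dimnames = list(NULL, paste0(format_coord(offs), ":",
                                             format_coord(offs + bin_w))))
  if (n == 0 || nrow(tags) == 0) return(out)
  starts <- rep(anchor_pos, each = n_bins) + rep(offs, n)
  ends <- starts + bin_w
  keep <- ends > 0
  starts <- pmax(0, starts)
  gr_bins <- GenomicRanges::GRanges(
    seqnames = rep(anchor_chrom, each = n_bins)[keep],
    ranges = IRanges::IRanges(start = starts[keep] + 1, end = ends[keep])
  )
  counts <- numeric(n * n_bins)
  counts[keep] <- GenomicRanges::countOverlaps(gr_bins, as_granges(tags))
  out[] <- matrix(counts, nrow = n, ncol = n_bins, byrow = TRUE)
  out * scale / library_size
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator` rounded half-up to `decimals`; `NA` when
#' the denominator is zero (never a division error).
#'
#' @param numerator,denominator Non-negative counts.
#' @param decimals Decimal places to keep.
#' @return A number, or `NA` if `denominator` is 0.
#' @examples
#' report_percent(1385, 2022)  # 68
#' report_percent(597, 1482)   # 40
#' @export
report_percent <- function(numerator, denominator, decimals = 0) {
  if (denominator == 0) return(NA_real_)
  round_half_up(100 * numerator / denominator, decimals)
}

#' Two-condition differential expression on a replicate RPKM matrix
#'
#' Per gene: condition means are computed on raw RPKM; genes with
#' `max(mean_a, mean_b) < min_expression` are labelled `low_expression` and
#' excluded from testing. Remaining genes get a Welch two-sample test on
#' `log2(RPKM + 1)` with Benjamini-Hochberg adjustment across tested genes.
#' Fold change is the ratio of raw condition means (`mean_b / mean_a`):
#' `up` requires `fold_change >= fc_threshold` and `p_adj < alpha`, `down`
#' is symmetric on `1 / fold_change`; everything else is `ns`. Genes whose
#' replicates have zero variance in both conditions cannot be tested and
#' fall back to p = 1 (count reported via a message).
#'
#' @param expr An `ExpressionTable`.
#' @param cond_a,cond_b Condition labels present in `expr$conditions`
#'   (a = reference/prior state, b = induced state).
#' @param config An `AnalysisConfig`.
#' @return Data frame with columns `gene_id`, `mean_a`, `mean_b`,
#'   `fold_change`, `log2fc`, `p_raw`, `p_adj`, `status`.
#' @export
differential_expression <- function(expr, cond_a, cond_b,
                                    config = analysis_config()) {
  for (cond in c(cond_a, cond_b)) {
    if (sum(expr$conditions == cond) < 2) {
      stop(sprintf("condition '%s' needs >= 2 replicate columns", cond),
           call. = FALSE)
    }
  }
  va <- expr$values[, expr$conditions == cond_a, drop = FALSE]
  vb <- expr$values[, expr$conditions == cond_b, drop = FALSE]
  mean_a <- rowMeans(va)
  mean_b <- rowMeans(vb)
  fold_change <- mean_b / mean_a
  log2fc <- log2(fold_change)

  # Welch t on log2(RPKM + 1), vectorized over genes
  la <- log2(va + 1); lb <- log2(vb + 1)
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  sa2 <- rowSums((la - ma)^2) / (na - 1)
  sb2 <- rowSums((lb - mb)^2) / (nb - 1)
  se2 <- sa2 / na + sb2 / nb
  tested <- pmax(mean_a, mean_b) >= config$min_expression
  degen <- tested & se2 == 0
  p_raw <- rep(NA_real_, length(mean_a))
  ok <- tested & !degen
  tt <- (mb[ok] - ma[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((sa2[ok] / na)^2 / (na - 1) + (sb2[ok] / nb)^2 / (nb - 1))
  p_raw[ok] <- 2 * stats::pt(-abs(tt), df)
  if (any(degen)) {
    message(sprintf("differential_expression: %d gene(s) with zero replicate variance; p set to 1",
                    sum(degen)))
    p_raw[degen] <- 1
  }
  p_adj <- rep(NA_real_, length(p_raw))
  p_adj[tested] <- stats::p.adjust(p_raw[tested], method = "BH")

  status <- rep("ns", length(mean_a))
  status[!tested] <- "low_expression"
  sig <- tested & !is.na(p_adj) & p_adj < config$alpha
  status[sig & fold_change >= config$fc_threshold] <- "up"
  status[sig & (1 / fold_change) >= config$fc_threshold] <- "down"
  data.frame(gene_id = expr$gene_ids, mean_a = mean_a, mean_b = mean_b,
             fold_change = fold_change, log2fc = log2fc,
             p_raw = p_raw, p_adj = p_adj, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write differential-expression results as TSV
#' @param de Data frame from [differential_expression()].
#' @param path Output path.
#' @export
write_de <- function(de, path) {
  data.table::fwrite(de, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
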