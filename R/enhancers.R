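MODALITY_LEVELS <- c("accessible", "poised", "unmarked", "de_novo")

# prior-state (ATAC, H3K4me1) -> modality; the 2x2 map
modality_from_flags <- function(atac_a, k4me1_a) {
  ifelse(atac_a & !k4me1_a, "accessible",
  ifelse(atac_a & k4me1_a, "poised",
  ifelse(!atac_a & !k4me1_a, "unmarked", "de_novo")))
}

# presence of >=1 subject interval within +/- half of each point, order kept
presence_at_points <- function(chrom, pos, half, subject) {
  if (length(pos) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, length(pos)))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pmax(0, pos - half) + 1,
                              end = pos + half)
  )
  GenomicRanges::countOverlaps(gr, as_granges(subject)) > 0
}

#' Call condition-B-specific enhancer regions
#'
#' An enhancer call is a condition-B H3K27ac peak that (i) overlaps a
#' condition-B H3K4me1 peak, (ii) overlaps a condition-B ATAC peak, and
#' (iii) overlaps no condition-A H3K27ac peak -- i.e. the full active
#' signature H3K4me1+/H3K27ac+/ATAC+ with H3K27ac newly acquired in B.
#' Region coordinates are the B H3K27ac peak spans. With
#' `config$distal_filter`, candidates lying within
#' `config$distal_min_tss_distance` of any TSS are dropped so that
#' promoters are excluded. Each call is annotated with its nearest TSS.
#'
#' Pass replicate-reproducible peak sets (see [replicate_reproducible()])
#' when replicates are available. An empty input track produces a warning,
#' not an error.
#'
#' @param atac_a,k4_a,k27_a Condition-A (prior state) peak `IntervalSet`s.
#' @param atac_b,k4_b,k27_b Condition-B (induced state) peak `IntervalSet`s.
#' @param tss A `TSSTable`.
#' @param config An `AnalysisConfig`.
#' @return Data frame of class `EnhancerCalls`: region columns (`chrom`,
#'   `start`, `end`, `name`, `score`, `strand`), condition-B flags
#'   (`atac_b`, `k4me1_b`, `k27ac_b`, all `TRUE`), `nearest_gene`,
#'   `tss_distance`, and `modality` (`NA` until [classify_modality()]).
#' @export
call_enhancers <- function(atac_a, k4_a, k27_a, atac_b, k4_b, k27_b,
                           tss, config = analysis_config()) {
  tracks <- list(atac_a = atac_a, k4_a = k4_a, k27_a = k27_a,
                 atac_b = atac_b, k4_b = k4_b, k27_b = k27_b)
  for (nm in names(tracks)) {
    if (nrow(tracks[[nm]]) == 0) {
      warning(sprintf("call_enhancers: input track '%s' is empty", nm),
              call. = FALSE)
    }
  }
  cand <- as.data.frame(k27_b)
  keep <- intersect_presence(k27_b, k4_b) &
    intersect_presence(k27_b, atac_b) &
    !intersect_presence(k27_b, k27_a)
  cand <- cand[keep, , drop = FALSE]
  if (isTRUE(config$distal_filter) && nrow(cand) > 0) {
    # a region counts as promoter-proximal when any TSS lies within
    # distal_min_tss_distance of its span
    d <- config$distal_min_tss_distance
    gr <- GenomicRanges::GRanges(
      seqnames = cand$chrom,
      ranges = IRanges::IRanges(start = pmax(0, cand$start - d) + 1,
                                end = cand$end + d)
    )
    tss_points <- interval_set(tss$chrom, tss$tss, tss$tss + 1)
    near <- GenomicRanges::countOverlaps(gr, as_granges(tss_points)) > 0
    cand <- cand[!near, , drop = FALSE]
  }
  if (nrow(cand) > 0) {
    nt <- nearest_tss(new_interval_set(cand), tss)
    # nearest_tss consumed the re-sorted set; cand rows are already sorted
    # identically because they came from a sorted IntervalSet subset
    cand <- as.data.frame(new_interval_set(cand))
    cand$nearest_gene <- nt$gene_id
    cand$tss_distance <- nt$distance
  } else {
    cand$nearest_gene <- character(0)
    cand$tss_distance <- numeric(0)
  }
  cand$atac_b <- rep(TRUE, nrow(cand))
  cand$k4me1_b <- rep(TRUE, nrow(cand))
  cand$k27ac_b <- rep(TRUE, nrow(cand))
  cand$modality <- rep(NA_character_, nrow(cand))
  rownames(cand) <- NULL
  structure(cand, class = c("EnhancerCalls", "data.frame"))
}

#' Classify the prior-state activation modality of enhancer calls
#'
#' The prior-state (condition A) ATAC and H3K4me1 status of each called
#' region resolves the four activation modalities: `accessible`
#' (ATAC+/H3K4me1-), `poised` (ATAC+/H3K4me1+), `unmarked`
#' (ATAC-/H3K4me1-) and `de_novo` (ATAC-/H3K4me1+). Presence/absence of a
#' peak is the class decision; an optional prior-state H3K4me1 RP10M value
#' can be attached as a descriptive signal tier but never influences the
#' class.
#'
#' @param calls An `EnhancerCalls` data frame from [call_enhancers()].
#' @param atac_a,k4_a Condition-A peak `IntervalSet`s.
#' @param k4_a_tags Optional condition-A H3K4me1 tag `IntervalSet`; if
#'   given, a `k4me1_a_rp10m` column is added.
#' @param k4_a_library_size Library size for the optional tag track.
#' @return The calls with `atac_a`, `k4me1_a`, `k27ac_a` (always `FALSE`)
#'   and `modality` filled in.
#' @export
classify_modality <- function(calls, atac_a, k4_a, k4_a_tags = NULL,
                              k4_a_library_size = NULL) {
  regions <- new_interval_set(as.data.frame(calls))
  calls$atac_a <- intersect_presence(regions, atac_a)
  calls$k4me1_a <- intersect_presence(regions, k4_a)
  calls$k27ac_a <- rep(FALSE, nrow(calls))
  calls$modality <- modality_from_flags(calls$atac_a, calls$k4me1_a)
  if (!is.null(k4_a_tags)) {
    ls <- if (is.null(k4_a_library_size)) nrow(k4_a_tags) else k4_a_library_size
    calls$k4me1_a_rp10m <- as.numeric(rp10m(regions, k4_a_tags, ls))
  }
  calls
}

#' Per-gene TSS accessibility change between two conditions
#'
#' For each differential-expression gene present in the TSS table, records
#' whether an ATAC peak falls in the promoter window
#' (`tss +/- config$tss_half_window`) in each condition, and classifies the
#' change: `gained` (closed in A, open in B), `lost` (open in A, closed in
#' B), `stable_open`, `stable_closed`. Genes absent from the TSS table are
#' skipped with a message reporting the count.
#'
#' @param de Data frame from [differential_expression()].
#' @param atac_a,atac_b Condition ATAC peak `IntervalSet`s.
#' @param tss A `TSSTable`.
#' @param config An `AnalysisConfig`.
#' @return Data frame with `gene_id`, `de_status`, `atac_a`, `atac_b`,
#'   `change`.
#' @export
tss_accessibility_table <- function(de, atac_a, atac_b, tss,
                                    config = analysis_config()) {
  if (nrow(de) == 0) stop("empty differential-expression table", call. = FALSE)
  idx <- match(de$gene_id, tss$gene_id)
  skipped <- sum(is.na(idx))
  if (skipped > 0) {
    message(sprintf("tss_accessibility_table: %d gene(s) absent from the TSS table; skipped",
                    skipped))
  }
  keep <- !is.na(idx)
  de <- de[keep, , drop = FALSE]
  idx <- idx[keep]
  half <- config$tss_half_window
  open_a <- presence_at_points(tss$chrom[idx], tss$tss[idx], half, atac_a)
  open_b <- presence_at_points(tss$chrom[idx], tss$tss[idx], half, atac_b)
  change <- ifelse(!open_a & open_b, "gained",
            ifelse(open_a & !open_b, "lost",
            ifelse(open_a & open_b, "stable_open", "stable_closed")))
  data.frame(gene_id = de$gene_id, de_status = de$status,
             atac_a = open_a, atac_b = open_b, change = change,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize the regulatory landscape of a run
#'
#' Aggregates enhancer calls, TSS accessibility changes and differential
#' expression into the headline counts and percentages: the four modality
#' counts and percentages, the share of upregulated genes gaining TSS
#' accessibility, the share of downregulated genes losing it, the share of
#' enhancers whose nearest gene is upregulated, and -- among upregulated
#' genes that are the nearest gene of at least one enhancer -- the share
#' associated with each modality. Percentages are rounded half-up
#' (`decimals` places) with raw counts always carried alongside; a zero
#' denominator yields `NA`, never an error.
#'
#' @param calls Classified `EnhancerCalls`.
#' @param changes TSS accessibility table from [tss_accessibility_table()].
#' @param de Differential-expression table.
#' @param decimals Report precision for percentages.
#' @return A list of class `LandscapeReport`.
#' @export
build_report <- function(calls, changes, de, decimals = 0) {
  n_enh <- nrow(calls)
  counts <- vapply(MODALITY_LEVELS, function(m) sum(calls$modality == m, na.rm = TRUE), 0L)
  pct <- vapply(counts, function(k) report_percent(k, n_enh, decimals), 0)
  up_genes <- de$gene_id[de$status == "up"]
  down_genes <- de$gene_id[de$status == "down"]
  up_ch <- changes[changes$gene_id %in% up_genes, , drop = FALSE]
  down_ch <- changes[changes$gene_id %in% down_genes, , drop = FALSE]
  pct_up_gain <- report_percent(sum(up_ch$change == "gained"), nrow(up_ch), decimals)
  pct_down_loss <- report_percent(sum(down_ch$change == "lost"), nrow(down_ch), decimals)
  near_up <- calls$nearest_gene %in% up_genes
  pct_near_up <- report_percent(sum(near_up), n_enh, decimals)
  assoc_up <- unique(calls$nearest_gene[near_up])
  pct_up_per_modality <- vapply(MODALITY_LEVELS, function(m) {
    report_percent(length(unique(calls$nearest_gene[near_up & calls$modality == m])),
                   length(assoc_up), decimals)
  }, 0)
  structure(list(
    n_enhancers = n_enh,
    modality_counts = counts,
    modality_percent = pct,
    n_up = length(up_genes),
    n_down = length(down_genes),
    n_up_gained = sum(up_ch$change == "gained"),
    n_down_lost = sum(down_ch$change == "lost"),
    pct_up_with_gain = pct_up_gain,
    pct_down_with_loss = pct_down_loss,
    n_enhancers_near_up = sum(near_up),
    pct_enhancers_near_upregulated = pct_near_up,
    n_up_genes_with_enhancer = length(assoc_up),
    pct_upregulated_per_modality = pct_up_per_modality,
    decimals = decimals
  ), class = "LandscapeReport")
}

#' @export
print.LandscapeReport <- function(x, ...) {
  cat("Regulatory landscape report\n")
  cat(sprintf("  enhancer calls: %d\n", x$n_enhancers))
  for (i in seq_along(MODALITY_LEVELS)) {
    cat(sprintf("    %-10s %5d  (%s%%)\n", MODALITY_LEVELS[i],
                x$modality_counts[i], format(x$modality_percent[i])))
  }
  cat(sprintf("  upregulated genes: %d; gained TSS accessibility: %d (%s%%)\n",
              x$n_up, x$n_up_gained, format(x$pct_up_with_gain)))
  cat(sprintf("  downregulated genes: %d; lost TSS accessibility: %d (%s%%)\n",
              x$n_down, x$n_down_lost, format(x$pct_down_with_loss)))
  cat(sprintf("  enhancers with upregulated nearest gene: %d (%s%%)\n",
              x$n_enhancers_near_up, format(x$pct_enhancers_near_upregulated)))
  cat(sprintf("  upregulated genes near an enhancer: %d; by modality: %s\n",
              x$n_up_genes_with_enhancer,
              paste(sprintf("%s %s%%", MODALITY_LEVELS,
                            format(x$pct_upregulated_per_modality)),
                    collapse = ", ")))
  invisible(x)
}

#' Tabular form of a landscape report
#' @param x A `LandscapeReport`.
#' @return Data frame with columns `metric`, `numerator`, `denominator`,
#'   `value`.
#' @export
report_as_table <- function(x) {
  rows <- list(
    c("n_enhancers", x$n_enhancers, NA, x$n_enhancers)
  )
  for (i in seq_along(MODALITY_LEVELS)) {
    rows[[length(rows) + 1]] <- c(paste0("pct_", MODALITY_LEVELS[i]),
                                  x$modality_counts[i], x$n_enhancers,
                                  x$modality_percent[i])
  }
  rows[[length(rows) + 1]] <- c("pct_up_with_gain", x$n_up_gained, x$n_up, x$pct_up_with_gain)
  rows[[length(rows) + 1]] <- c("pct_down_with_loss", x$n_down_lost, x$n_down, x$pct_down_with_loss)
  rows[[length(rows) + 1]] <- c("pct_enhancers_near_upregulated",
                                x$n_enhancers_near_up, x$n_enhancers,
                                x$pct_enhancers_near_upregulated)
  for (i in seq_along(MODALITY_LEVELS)) {
    rows[[length(rows) + 1]] <- c(paste0("pct_up_assoc_", MODALITY_LEVELS[i]),
                                  NA, x$n_up_genes_with_enhancer,
                                  x$pct_upregulated_per_modality[i])
  }
  df <- as.data.frame(do.call(rbind, lapply(rows, function(r) {
    data.frame(metric = r[[1]], numerator = as.numeric(r[[2]]),
               denominator = as.numeric(r[[3]]), value = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)
  })))
  rownames(df) <- NULL
  df
}
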