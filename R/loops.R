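anchor_set <- function(df, which = 1) {
  interval_set(df[[paste0("chrom", which)]], df[[paste0("start", which)]],
               df[[paste0("end", which)]])
}

# order-preserving overlap of anchor rows against a subject IntervalSet
anchor_presence <- function(df, which, subject) {
  n <- nrow(df)
  if (n == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, n))
  gr <- GenomicRanges::GRanges(
    seqnames = df[[paste0("chrom", which)]],
    ranges = IRanges::IRanges(start = df[[paste0("start", which)]] + 1,
                              end = df[[paste0("end", which)]])
  )
  GenomicRanges::countOverlaps(gr, as_granges(subject)) > 0
}

# comma-collapsed gene lists of promoter windows overlapping each anchor row
anchor_genes <- function(df, which, tss, half) {
  n <- nrow(df)
  if (n == 0) return(character(0))
  gr <- GenomicRanges::GRanges(
    seqnames = df[[paste0("chrom", which)]],
    ranges = IRanges::IRanges(start = df[[paste0("start", which)]] + 1,
                              end = df[[paste0("end", which)]])
  )
  prom <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = pmax(0, tss$tss - half) + 1,
                              end = tss$tss + half)
  )
  hits <- GenomicRanges::findOverlaps(gr, prom)
  out <- rep("", n)
  if (length(hits) > 0) {
    by_anchor <- split(tss$gene_id[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits))
    ids <- as.integer(names(by_anchor))
    out[ids] <- vapply(by_anchor, function(g) paste(sort(unique(g)), collapse = ","), "")
  }
  out
}

#' Annotate Hi-C interactions with open-chromatin and promoter status
#'
#' For each significant interaction, flags whether each anchor bin overlaps
#' an ATAC peak of the interaction's own condition, and lists the genes
#' whose promoter window (`tss +/- promoter_half_window`) overlaps each
#' anchor. Anchors are canonicalised (anchor1 before anchor2), so the
#' annotation is invariant to the input anchor order. Trans-chromosomal
#' interactions are annotated like any other.
#'
#' @param interactions An `InteractionTable` with a `condition` column.
#' @param atac_by_condition Named list of ATAC `IntervalSet`s, one per
#'   condition; every condition present in `interactions` must appear.
#' @param tss A `TSSTable`.
#' @param promoter_half_window Promoter half-window in bp.
#' @return The interactions with `anchor1_open`, `anchor2_open`,
#'   `anchor1_genes`, `anchor2_genes` (comma-separated, `""` if none).
#' @export
annotate_interactions <- function(interactions, atac_by_condition, tss,
                                  promoter_half_window = 2000) {
  df <- canonicalize_interactions(as.data.frame(interactions))
  if (!"condition" %in% names(df)) {
    stop("interactions must carry a 'condition' column", call. = FALSE)
  }
  missing_cond <- setdiff(unique(df$condition), names(atac_by_condition))
  if (length(missing_cond) > 0) {
    stop("unknown condition(s) in interactions: ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  df$anchor1_open <- rep(FALSE, nrow(df))
  df$anchor2_open <- rep(FALSE, nrow(df))
  for (cond in unique(df$condition)) {
    rows <- df$condition == cond
    df$anchor1_open[rows] <- anchor_presence(df[rows, , drop = FALSE], 1,
                                             atac_by_condition[[cond]])
    df$anchor2_open[rows] <- anchor_presence(df[rows, , drop = FALSE], 2,
                                             atac_by_condition[[cond]])
  }
  df$anchor1_genes <- anchor_genes(df, 1, tss, promoter_half_window)
  df$anchor2_genes <- anchor_genes(df, 2, tss, promoter_half_window)
  structure(df, class = c("InteractionTable", "data.frame"))
}

#' Nominate candidate enhancers for a gene from accessibility and loops
#'
#' The discovery logic that surfaces a distal regulatory element for a gene
#' of interest: a candidate element is `supported` when (i) it overlaps an
#' ATAC peak in at least `min_accessible` conditions, (ii) for every
#' required condition there is a cis interaction with one anchor bin
#' overlapping the element and the other overlapping the gene's promoter
#' window, and (iii) no forbidden condition carries such a loop ("loop
#' absent" means no qualifying interaction row in the table -- absence of
#' evidence by design). Trans-chromosomal interactions never qualify as
#' enhancer-promoter support. Candidates are ranked by number of accessible
#' conditions (descending), then number of required-condition loops
#' (descending), then genomic position; output order is independent of
#' input row order.
#'
#' @param gene_id Target gene; must be present in `tss`.
#' @param elements An `IntervalSet` of candidate elements.
#' @param atac_by_condition Named list of per-condition ATAC `IntervalSet`s.
#' @param interactions_by_condition Named list of per-condition
#'   `InteractionTable`s (anchors binned).
#' @param tss A `TSSTable`.
#' @param required_loop_conditions Conditions in which the element must
#'   loop to the promoter.
#' @param forbidden_loop_conditions Conditions in which such a loop
#'   disqualifies the element.
#' @param min_accessible Minimum number of accessible conditions.
#' @param promoter_half_window Promoter half-window in bp.
#' @return Data frame of class `CandidateTable`: element coordinates,
#'   `target_gene`, `accessible_conditions`, `looped_conditions`
#'   (comma-separated), `n_accessible`, `n_required_looped`, `supported`,
#'   `rank`.
#' @export
nominate_candidates <- function(gene_id, elements, atac_by_condition,
                                interactions_by_condition, tss,
                                required_loop_conditions,
                                forbidden_loop_conditions = character(),
                                min_accessible = 1,
                                promoter_half_window = 2000) {
  g <- tss[tss$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0) stop("gene not found in TSS table: ", gene_id, call. = FALSE)
  if (nrow(elements) == 0) stop("element set is empty", call. = FALSE)
  conds <- names(atac_by_condition)
  el <- as.data.frame(elements)
  n <- nrow(el)
  prom_lo <- max(0, g$tss - promoter_half_window)
  prom_hi <- g$tss + promoter_half_window

  acc <- matrix(FALSE, n, length(conds), dimnames = list(NULL, conds))
  for (cond in conds) {
    acc[, cond] <- intersect_presence(new_interval_set(el), atac_by_condition[[cond]])
  }
  loop_conds <- names(interactions_by_condition)
  looped <- matrix(FALSE, n, length(loop_conds), dimnames = list(NULL, loop_conds))
  for (cond in loop_conds) {
    ia <- as.data.frame(interactions_by_condition[[cond]])
    if (nrow(ia) == 0) next
    ia <- ia[ia$chrom1 == ia$chrom2, , drop = FALSE]  # cis only
    if (nrow(ia) == 0) next
    # anchor hits the promoter window?
    p1 <- ia$chrom1 == g$chrom & ia$start1 < prom_hi & prom_lo < ia$end1
    p2 <- ia$chrom2 == g$chrom & ia$start2 < prom_hi & prom_lo < ia$end2
    for (i in seq_len(n)) {
      e1 <- ia$chrom1 == el$chrom[i] & ia$start1 < el$end[i] & el$start[i] < ia$end1
      e2 <- ia$chrom2 == el$chrom[i] & ia$start2 < el$end[i] & el$start[i] < ia$end2
      looped[i, cond] <- any((e1 & p2) | (e2 & p1))
    }
  }
  collapse <- function(m, i) paste(colnames(m)[m[i, ]], collapse = ",")
  n_acc <- rowSums(acc)
  req <- intersect(required_loop_conditions, loop_conds)
  if (length(required_loop_conditions) > 0 && length(req) < length(required_loop_conditions)) {
    # a required condition with no interaction table can never be satisfied
    req_ok <- rep(FALSE, n)
  } else {
    req_ok <- if (length(req) == 0) rep(TRUE, n) else
      rowSums(looped[, req, drop = FALSE]) == length(req)
  }
  forb <- intersect(forbidden_loop_conditions, loop_conds)
  forb_ok <- if (length(forb) == 0) rep(TRUE, n) else
    rowSums(looped[, forb, drop = FALSE]) == 0
  n_req_looped <- if (length(req) == 0) rep(0, n) else
    rowSums(looped[, req, drop = FALSE])
  supported <- n_acc >= min_accessible & req_ok & forb_ok

  out <- data.frame(
    chrom = el$chrom, start = el$start, end = el$end, name = el$name,
    target_gene = gene_id,
    accessible_conditions = vapply(seq_len(n), function(i) collapse(acc, i), ""),
    looped_conditions = vapply(seq_len(n), function(i) collapse(looped, i), ""),
    n_accessible = n_acc, n_required_looped = n_req_looped,
    supported = supported, stringsAsFactors = FALSE
  )
  ord <- order(-out$n_accessible, -out$n_required_looped,
               out$chrom, out$start, out$end)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(n)
  rownames(out) <- NULL
  structure(out, class = c("CandidateTable", "data.frame"))
}

#' Write nominated candidates as TSV
#' @param x A `CandidateTable`.
#' @param path Output path.
#' @export
write_candidates <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE)
  invisible(path)
}
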