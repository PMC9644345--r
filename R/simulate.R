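# run expr under a seeded, restored RNG so generation is reproducible and
# never disturbs the caller's random stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Largest-remainder apportionment of counts
#'
#' Splits `n` into integer class counts proportional to `props`, summing
#' exactly to `n`. Quotas within 1e-9 of an integer are snapped to it
#' before flooring, so exact proportions yield exact counts. Leftover
#' units go to the largest fractional remainders; ties are broken toward
#' the smallest provisional count, then by class order (so a slight
#' proportion deficit tops up the smallest class).
#'
#' @param props Non-negative proportions summing to at most 1.
#' @param n Total count.
#' @return Integer vector of class counts summing to `n`.
#' @examples
#' largest_remainder(c(597, 386, 379, 120) / 1482, 1482)
#' @export
largest_remainder <- function(props, n) {
  if (sum(props) > 1 + 1e-9 || sum(props) <= 0) {
    stop("proportions must be positive and sum to at most 1", call. = FALSE)
  }
  if (any(props < 0)) stop("proportions must be non-negative", call. = FALSE)
  q <- props * n
  qr <- round(q)
  snap <- abs(q - qr) < 1e-9
  q[snap] <- qr[snap]
  base <- floor(q)
  rem <- q - base
  leftover <- as.integer(round(n - sum(base)))
  out <- as.integer(base)
  if (leftover > 0) {
    ord <- order(-rem, base, seq_along(props))
    add <- ord[seq_len(leftover)]
    out[add] <- out[add] + 1L
  }
  out
}

#' Parameters for the synthetic two-condition study generator
#'
#' Defaults are the study conditions the generator emulates: the observed
#' enhancer-class mix (597/386/379/120 of 1,482), a planted twofold
#' expression change with 10% replicate coefficient of variation over
#' four replicates, 68.5% of upregulated genes gaining and 37.2% of
#' downregulated genes losing TSS accessibility, and 25% of enhancers
#' targeting an upregulated gene.
#'
#' @param n_genes Number of genes on the toy genome.
#' @param n_enhancers Number of planted condition-B-specific enhancers.
#' @param class_proportions Length-4 proportions over
#'   (accessible, poised, unmarked, de_novo), summing to 1.
#' @param frac_up,frac_down Planted fractions of up/downregulated genes.
#' @param planted_log2fc Planted log2 fold change for DE genes.
#' @param replicate_cv Coefficient of variation of multiplicative
#'   log-normal replicate noise on RPKM.
#' @param n_replicates Replicates per condition in the expression matrix.
#' @param frac_up_gain Fraction of upregulated genes planted to gain TSS
#'   accessibility.
#' @param frac_down_loss Fraction of downregulated genes planted to lose
#'   TSS accessibility.
#' @param frac_enhancer_up Fraction of enhancers whose target gene is
#'   upregulated.
#' @param frac_ns_closed Fraction of non-DE genes with a closed promoter in
#'   both conditions.
#' @param peak_fdr_noise Probability that a true peak is dropped, and
#'   expected spurious peaks per true peak, per condition-track.
#' @param n_preexisting Number of decoy regions carrying the full
#'   condition-B signature but already H3K27ac+ in condition A (must never
#'   be called). Default 5% of `n_enhancers`.
#' @param n_loops Number of planted enhancer-promoter loops. Default 25%
#'   of `n_enhancers`.
#' @param loop_conditions Conditions in which planted loops are present: a
#'   character vector applied to every loop, or a list (one vector per
#'   loop, recycled).
#' @param conditions Length-2 character vector, condition A (prior state)
#'   then condition B (induced state).
#' @param chrom_sizes Optional named vector of chromosome sizes; by
#'   default a 4-chromosome toy genome is sized to hold one 40 kb gene
#'   slot per gene.
#' @param hic_resolution Hi-C bin size for emitted loops.
#' @param emit_tags Generate per-condition tag tracks?
#' @param tags_per_peak Tags emitted per present peak.
#' @param seed RNG seed; identical parameters and seed give byte-identical
#'   outputs.
#' @return A list of class `SimulationParams`.
#' @export
simulation_params <- function(n_genes = 400,
                              n_enhancers = 100,
                              class_proportions = c(accessible = 597, poised = 386,
                                                    unmarked = 379, de_novo = 120) / 1482,
                              frac_up = 0.20,
                              frac_down = 0.13,
                              planted_log2fc = 1,
                              replicate_cv = 0.1,
                              n_replicates = 4,
                              frac_up_gain = 1385 / 2022,
                              frac_down_loss = 479 / 1288,
                              frac_enhancer_up = 0.25,
                              frac_ns_closed = 0.10,
                              peak_fdr_noise = 0,
                              n_preexisting = NULL,
                              n_loops = NULL,
                              loop_conditions = NULL,
                              conditions = c("naive", "instructed"),
                              chrom_sizes = NULL,
                              hic_resolution = 10000,
                              emit_tags = TRUE,
                              tags_per_peak = 25,
                              seed = 1) {
  if (length(class_proportions) != 4 || abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must be 4 values summing to 1", call. = FALSE)
  }
  probs <- c(frac_up, frac_down, frac_up_gain, frac_down_loss,
             frac_enhancer_up, frac_ns_closed, peak_fdr_noise)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  if (frac_up + frac_down > 1) stop("frac_up + frac_down must be <= 1", call. = FALSE)
  if (length(conditions) != 2 || anyDuplicated(conditions)) {
    stop("conditions must be 2 distinct labels", call. = FALSE)
  }
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  if (is.null(n_preexisting)) n_preexisting <- ceiling(0.05 * n_enhancers)
  if (is.null(n_loops)) n_loops <- round(0.25 * n_enhancers)
  if (n_loops > n_enhancers) stop("n_loops must be <= n_enhancers", call. = FALSE)
  if (is.null(loop_conditions)) loop_conditions <- conditions[2]
  structure(list(
    n_genes = n_genes, n_enhancers = n_enhancers,
    class_proportions = class_proportions,
    frac_up = frac_up, frac_down = frac_down,
    planted_log2fc = planted_log2fc, replicate_cv = replicate_cv,
    n_replicates = n_replicates,
    frac_up_gain = frac_up_gain, frac_down_loss = frac_down_loss,
    frac_enhancer_up = frac_enhancer_up, frac_ns_closed = frac_ns_closed,
    peak_fdr_noise = peak_fdr_noise,
    n_preexisting = n_preexisting, n_loops = n_loops,
    loop_conditions = loop_conditions, conditions = conditions,
    chrom_sizes = chrom_sizes, hic_resolution = hic_resolution,
    emit_tags = emit_tags, tags_per_peak = tags_per_peak, seed = seed
  ), class = "SimulationParams")
}

GENE_SLOT <- 40000        # bp reserved per gene on the toy genome
TSS_SLOT_OFFSET <- 5000   # TSS position within its slot (plus jitter)
ENH_WIDTH <- 1000
PEAK_WIDTHS <- c(atac = 600, k4me1 = 900, k27ac = 1000)
PROMOTER_PEAK_HALF <- 300

# deterministic slot layout; errors if a supplied genome cannot host it
layout_genome <- function(params) {
  n_slots <- params$n_genes
  if (is.null(params$chrom_sizes)) {
    per_chrom <- ceiling(n_slots / 4)
    sizes <- rep((per_chrom + 1) * GENE_SLOT, 4)
    names(sizes) <- paste0("chrS", 1:4)
  } else {
    sizes <- params$chrom_sizes
    if (is.null(names(sizes))) stop("chrom_sizes must be named", call. = FALSE)
  }
  cap <- floor(sizes / GENE_SLOT)
  if (sum(cap) < n_slots) {
    stop(sprintf("infeasible layout: %d gene slots of %d bp do not fit in %s bp",
                 n_slots, GENE_SLOT, format(sum(sizes), scientific = FALSE)),
         call. = FALSE)
  }
  chrom <- rep(names(sizes), cap)[seq_len(n_slots)]
  slot_in_chrom <- unlist(lapply(cap, seq_len), use.names = FALSE)[seq_len(n_slots)] - 1
  list(chrom = chrom, slot_base = slot_in_chrom * GENE_SLOT, sizes = sizes)
}

peak_df <- function(chrom, center, width, name) {
  data.frame(chrom = chrom, start = pmax(0, round(center - width / 2)),
             end = round(center + width / 2), name = name,
             stringsAsFactors = FALSE)
}

# dropout + spurious peaks, shared by both replicates of a track
apply_peak_noise <- function(df, noise, sizes, track) {
  if (noise <= 0 || nrow(df) == 0) return(df)
  keep <- stats::runif(nrow(df)) >= noise
  n_spur <- stats::rbinom(1, nrow(df), noise)
  out <- df[keep, , drop = FALSE]
  if (n_spur > 0) {
    chrom <- sample(names(sizes), n_spur, replace = TRUE,
                    prob = sizes / sum(sizes))
    start <- floor(stats::runif(n_spur) * (sizes[chrom] - 500))
    out <- rbind(out, data.frame(chrom = chrom, start = start,
                                 end = start + 500,
                                 name = sprintf("spurious_%s_%03d", track, seq_len(n_spur)),
                                 stringsAsFactors = FALSE))
  }
  out
}

replicate_sets <- function(df, label) {
  rep1 <- interval_set(df$chrom, df$start, df$end, name = df$name,
                       label = paste0(label, "_rep1"))
  shift <- if (nrow(df) > 0) round(stats::runif(nrow(df), -50, 50)) else integer()
  rep2 <- interval_set(df$chrom, pmax(0, df$start + shift), df$end + shift,
                       name = df$name, label = paste0(label, "_rep2"))
  list(rep1 = rep1, rep2 = rep2)
}

make_tags <- function(df, per_peak, sizes, label) {
  if (nrow(df) == 0) {
    return(interval_set(label = label))
  }
  pos <- unlist(lapply(seq_len(nrow(df)), function(i) {
    floor(df$start[i] + stats::runif(per_peak) * (df$end[i] - df$start[i]))
  }), use.names = FALSE)
  chrom <- rep(df$chrom, each = per_peak)
  n_bg <- ceiling(0.1 * length(pos))
  bg_chrom <- sample(names(sizes), n_bg, replace = TRUE, prob = sizes / sum(sizes))
  bg_pos <- floor(stats::runif(n_bg) * (sizes[bg_chrom] - 1))
  interval_set(c(chrom, bg_chrom), c(pos, bg_pos), c(pos, bg_pos) + 1,
               label = label)
}

#' Simulate a two-condition multi-omic study with planted truth
#'
#' Generates, on a collision-free slotted toy genome: a stranded TSS
#' table; per-condition, per-replicate ATAC / H3K4me1 / H3K27ac peak sets
#' in which every planted enhancer carries the full condition-B signature
#' (H3K27ac acquired) and condition-A marks follow its planted class
#' (accessible: ATAC only; poised: ATAC and H3K4me1; unmarked: neither;
#' de_novo: H3K4me1 only); promoter ATAC peaks implementing the planted
#' TSS-accessibility changes; optional tag tracks with counts proportional
#' to peak presence; a replicate RPKM matrix with multiplicative
#' log-normal noise and planted fold changes; per-condition BEDPE loop
#' tables connecting planted enhancer bins to their target promoter bins;
#' and the ground-truth record. Decoy regions with a pre-existing
#' condition-A H3K27ac peak are planted to exercise the acquisition
#' filter. Identical `params` (including `seed`) give byte-identical
#' outputs.
#'
#' @param params A `SimulationParams`.
#' @param out_dir Optional directory; when given, all inputs are written
#'   as BED / BEDPE / TSV files whose paths are returned in `$files`.
#' @return A list of class `SyntheticStudy` with components `params`,
#'   `tss`, `peaks` (condition -> track -> rep1/rep2 `IntervalSet`s),
#'   `tags`, `expression`, `loops` (condition -> `InteractionTable`),
#'   `truth` (`genes`, `enhancers`, `loops` data frames) and `files`.
#' @export
simulate_study <- function(params = simulation_params(), out_dir = NULL) {
  stopifnot(inherits(params, "SimulationParams"))
  with_local_seed(params$seed, simulate_study_impl(params, out_dir))
}

simulate_study_impl <- function(params, out_dir) {
  cond_a <- params$conditions[1]
  cond_b <- params$conditions[2]
  n_genes <- params$n_genes

  ## genes on the slotted genome
  lay <- layout_genome(params)
  tss_pos <- lay$slot_base + TSS_SLOT_OFFSET + round(stats::runif(n_genes, -500, 500))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  tss <- tss_table(gene_id, lay$chrom, tss_pos, strand)

  ## planted DE statuses and TSS-accessibility changes
  de_counts <- largest_remainder(c(params$frac_up, params$frac_down,
                                   1 - params$frac_up - params$frac_down), n_genes)
  perm <- sample(n_genes)
  status <- rep("ns", n_genes)
  up_idx <- perm[seq_len(de_counts[1])]
  down_idx <- perm[de_counts[1] + seq_len(de_counts[2])]
  status[up_idx] <- "up"
  status[down_idx] <- "down"

  n_gain <- largest_remainder(c(params$frac_up_gain, 1 - params$frac_up_gain),
                              length(up_idx))[1]
  n_loss <- largest_remainder(c(params$frac_down_loss, 1 - params$frac_down_loss),
                              length(down_idx))[1]
  tss_change <- rep("stable_open", n_genes)
  tss_change[sample(up_idx, n_gain)] <- "gained"
  tss_change[sample(down_idx, n_loss)] <- "lost"
  ns_idx <- which(status == "ns")
  n_closed <- largest_remainder(c(params$frac_ns_closed, 1 - params$frac_ns_closed),
                                length(ns_idx))[1]
  if (n_closed > 0) tss_change[sample(ns_idx, n_closed)] <- "stable_closed"

  ## enhancer classes and target genes
  n_enh <- params$n_enhancers
  class_counts <- largest_remainder(params$class_proportions, n_enh)
  enh_class <- sample(rep(MODALITY_LEVELS, class_counts))
  n_up_target <- largest_remainder(c(params$frac_enhancer_up,
                                     1 - params$frac_enhancer_up), n_enh)[1]
  if (n_up_target > length(up_idx)) {
    stop("not enough upregulated genes to host frac_enhancer_up enhancer targets",
         call. = FALSE)
  }
  ns_open_idx <- which(status == "ns" & tss_change == "stable_open")
  n_ns_target <- n_enh - n_up_target + params$n_preexisting
  if (n_ns_target > length(ns_open_idx)) {
    stop("not enough non-DE genes to host enhancer and decoy targets", call. = FALSE)
  }
  up_targets <- sample(up_idx, n_up_target)
  ns_targets <- sample(ns_open_idx, n_ns_target)
  target_idx <- rep(NA_integer_, n_enh)
  which_up <- sample(n_enh, n_up_target)
  target_idx[which_up] <- up_targets
  target_idx[is.na(target_idx)] <- ns_targets[seq_len(n_enh - n_up_target)]
  decoy_target_idx <- ns_targets[n_enh - n_up_target + seq_len(params$n_preexisting)]

  ## element placement: inside the target gene's slot, >= 12 kb from its TSS
  place_elements <- function(idx) {
    offset <- 12000 + round(stats::runif(length(idx), 0, 3000))
    tss_pos[idx] + offset
  }
  enh_center <- place_elements(target_idx)
  enh_name <- sprintf("enh%05d", seq_len(n_enh))
  decoy_center <- place_elements(decoy_target_idx)
  decoy_name <- if (params$n_preexisting > 0) {
    sprintf("preexisting%03d", seq_len(params$n_preexisting))
  } else character(0)

  truth_enh <- data.frame(
    name = enh_name, chrom = lay$chrom[target_idx],
    start = enh_center - ENH_WIDTH / 2, end = enh_center + ENH_WIDTH / 2,
    class = enh_class, target_gene = gene_id[target_idx],
    stringsAsFactors = FALSE
  )

  ## peak tracks per condition
  prom_chrom <- lay$chrom
  tracks <- list()
  add <- function(lst, df) rbind(lst, df)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), stringsAsFactors = FALSE)
  for (cond in c(cond_a, cond_b)) tracks[[cond]] <- list(atac = empty, k4me1 = empty, k27ac = empty)

  # promoter accessibility
  open_in_a <- tss_change %in% c("lost", "stable_open")
  open_in_b <- tss_change %in% c("gained", "stable_open")
  tracks[[cond_a]]$atac <- add(tracks[[cond_a]]$atac,
    peak_df(prom_chrom[open_in_a], tss_pos[open_in_a], 2 * PROMOTER_PEAK_HALF,
            paste0("prom_", gene_id[open_in_a])))
  tracks[[cond_b]]$atac <- add(tracks[[cond_b]]$atac,
    peak_df(prom_chrom[open_in_b], tss_pos[open_in_b], 2 * PROMOTER_PEAK_HALF,
            paste0("prom_", gene_id[open_in_b])))

  # enhancer marks: full signature in B; class pattern in A
  for (track in names(PEAK_WIDTHS)) {
    tracks[[cond_b]][[track]] <- add(tracks[[cond_b]][[track]],
      peak_df(truth_enh$chrom, enh_center, PEAK_WIDTHS[[track]],
              paste0(enh_name, "_", track, "_b")))
  }
  a_atac <- enh_class %in% c("accessible", "poised")
  a_k4 <- enh_class %in% c("poised", "de_novo")
  tracks[[cond_a]]$atac <- add(tracks[[cond_a]]$atac,
    peak_df(truth_enh$chrom[a_atac], enh_center[a_atac], PEAK_WIDTHS[["atac"]],
            paste0(enh_name[a_atac], "_atac_a")))
  tracks[[cond_a]]$k4me1 <- add(tracks[[cond_a]]$k4me1,
    peak_df(truth_enh$chrom[a_k4], enh_center[a_k4], PEAK_WIDTHS[["k4me1"]],
            paste0(enh_name[a_k4], "_k4me1_a")))

  # pre-existing decoys: full B signature but H3K27ac already present in A
  if (params$n_preexisting > 0) {
    dchrom <- lay$chrom[decoy_target_idx]
    for (track in names(PEAK_WIDTHS)) {
      tracks[[cond_b]][[track]] <- add(tracks[[cond_b]][[track]],
        peak_df(dchrom, decoy_center, PEAK_WIDTHS[[track]],
                paste0(decoy_name, "_", track, "_b")))
    }
    tracks[[cond_a]]$k27ac <- add(tracks[[cond_a]]$k27ac,
      peak_df(dchrom, decoy_center, PEAK_WIDTHS[["k27ac"]],
              paste0(decoy_name, "_k27ac_a")))
    tracks[[cond_a]]$atac <- add(tracks[[cond_a]]$atac,
      peak_df(dchrom, decoy_center, PEAK_WIDTHS[["atac"]],
              paste0(decoy_name, "_atac_a")))
  }

  peaks <- list()
  tags <- list()
  for (cond in c(cond_a, cond_b)) {
    peaks[[cond]] <- list()
    tags[[cond]] <- list()
    for (track in names(PEAK_WIDTHS)) {
      df <- apply_peak_noise(tracks[[cond]][[track]], params$peak_fdr_noise,
                             lay$sizes, track)
      df <- df[order(df$chrom, df$start, df$end, df$name), , drop = FALSE]
      peaks[[cond]][[track]] <- replicate_sets(df, paste(track, cond, sep = "_"))
      if (params$emit_tags) {
        tags[[cond]][[track]] <- make_tags(df, params$tags_per_peak, lay$sizes,
                                           paste(track, cond, "tags", sep = "_"))
      }
    }
  }

  ## expression matrix
  base <- exp(stats::rnorm(n_genes, log(20), 0.8))
  base[status != "ns"] <- pmax(base[status != "ns"], 5)
  mean_a <- base
  mean_b <- base
  mean_b[status == "up"] <- base[status == "up"] * 2^params$planted_log2fc
  mean_b[status == "down"] <- base[status == "down"] / 2^params$planted_log2fc
  sdlog <- sqrt(log(1 + params$replicate_cv^2))
  nr <- params$n_replicates
  noise_mat <- function(mu) {
    vapply(seq_len(nr), function(r) mu * exp(stats::rnorm(n_genes, 0, sdlog)),
           numeric(n_genes))
  }
  vals <- cbind(noise_mat(mean_a), noise_mat(mean_b))
  colnames(vals) <- c(paste0(cond_a, "_", seq_len(nr)),
                      paste0(cond_b, "_", seq_len(nr)))
  expression <- expression_table(gene_id, vals)

  ## loops between enhancer bins and target-promoter bins
  res <- params$hic_resolution
  loop_enh <- sort(sample(n_enh, params$n_loops))
  loop_conds <- params$loop_conditions
  if (!is.list(loop_conds)) loop_conds <- list(loop_conds)
  loop_conds <- rep(loop_conds, length.out = max(1, params$n_loops))
  loop_rows <- list()
  for (k in seq_along(loop_enh)) {
    i <- loop_enh[k]
    eb <- floor(enh_center[i] / res) * res
    pb <- floor(tss_pos[target_idx[i]] / res) * res
    for (cond in loop_conds[[k]]) {
      loop_rows[[length(loop_rows) + 1]] <- data.frame(
        chrom1 = truth_enh$chrom[i], start1 = eb, end1 = eb + res,
        chrom2 = truth_enh$chrom[i], start2 = pb, end2 = pb + res,
        name = paste0("loop_", enh_name[i]), score = 10,
        condition = cond, stringsAsFactors = FALSE
      )
    }
  }
  loop_df <- if (length(loop_rows) > 0) do.call(rbind, loop_rows) else
    data.frame(chrom1 = character(), start1 = numeric(), end1 = numeric(),
               chrom2 = character(), start2 = numeric(), end2 = numeric(),
               name = character(), score = numeric(), condition = character(),
               stringsAsFactors = FALSE)
  loops <- list()
  for (cond in c(cond_a, cond_b)) {
    sub <- loop_df[loop_df$condition == cond, , drop = FALSE]
    sub <- canonicalize_interactions(sub)
    sub <- sub[order(sub$chrom1, sub$start1, sub$chrom2, sub$start2, sub$name), ,
               drop = FALSE]
    rownames(sub) <- NULL
    loops[[cond]] <- structure(sub, class = c("InteractionTable", "data.frame"))
  }
  truth_enh$looped <- seq_len(n_enh) %in% loop_enh

  truth <- list(
    genes = data.frame(gene_id = gene_id, status = status,
                       tss_change = tss_change, base_rpkm = base,
                       stringsAsFactors = FALSE),
    enhancers = truth_enh,
    preexisting = data.frame(name = decoy_name,
                             chrom = lay$chrom[decoy_target_idx],
                             start = decoy_center - ENH_WIDTH / 2,
                             end = decoy_center + ENH_WIDTH / 2,
                             target_gene = gene_id[decoy_target_idx],
                             stringsAsFactors = FALSE),
    loops = data.frame(enhancer = enh_name[loop_enh],
                       target_gene = gene_id[target_idx[loop_enh]],
                       conditions = vapply(seq_along(loop_enh), function(k)
                         paste(loop_conds[[k]], collapse = ","), ""),
                       stringsAsFactors = FALSE)
  )

  study <- structure(list(params = params, tss = tss, peaks = peaks,
                          tags = if (params$emit_tags) tags else NULL,
                          expression = expression, loops = loops,
                          truth = truth, files = NULL),
                     class = "SyntheticStudy")
  if (!is.null(out_dir)) study$files <- write_study(study, out_dir)
  study
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  p <- function(...) file.path(out_dir, paste0(...))
  files$tss <- write_tss(study$tss, p("tss.bed"))
  for (cond in names(study$peaks)) {
    for (track in names(study$peaks[[cond]])) {
      for (rep in c("rep1", "rep2")) {
        f <- p("peaks_", cond, "_", track, "_", rep, ".bed")
        write_bed(study$peaks[[cond]][[track]][[rep]], f)
        files[[paste("peaks", cond, track, rep, sep = "_")]] <- f
      }
      if (!is.null(study$tags)) {
        f <- p("tags_", cond, "_", track, ".bed")
        write_bed(study$tags[[cond]][[track]], f)
        files[[paste("tags", cond, track, sep = "_")]] <- f
      }
    }
  }
  files$expression <- write_expression(study$expression, p("expression.tsv"))
  for (cond in names(study$loops)) {
    f <- p("loops_", cond, ".bedpe")
    write_bedpe(study$loops[[cond]], f)
    files[[paste("loops", cond, sep = "_")]] <- f
  }
  for (tab in c("genes", "enhancers", "preexisting", "loops")) {
    f <- p("truth_", tab, ".tsv")
    data.table::fwrite(study$truth[[tab]], f, sep = "\t", quote = FALSE)
    files[[paste("truth", tab, sep = "_")]] <- f
  }
  files
}

#' @export
print.SyntheticStudy <- function(x, ...) {
  cat(sprintf("SyntheticStudy: %d genes, %d enhancers, %d loops, conditions %s (seed %s)\n",
              x$params$n_genes, x$params$n_enhancers,
              nrow(x$truth$loops), paste(x$params$conditions, collapse = " -> "),
              format(x$params$seed)))
  invisible(x)
}

#' Replicate-reproducible peak sets of a synthetic study
#'
#' Applies [replicate_reproducible()] to every condition/track pair.
#'
#' @param study A `SyntheticStudy`.
#' @return Nested list: condition -> track -> `IntervalSet`.
#' @export
reproducible_peaks <- function(study) {
  lapply(study$peaks, function(cond) {
    lapply(cond, function(track) replicate_reproducible(track$rep1, track$rep2))
  })
}

#' Five-condition fixture reproducing the En7 discovery logic
#'
#' A minimal multi-condition accessibility/loop fixture modelled on the
#' Pax7 locus: one target gene whose intronic element (the En7 analog) is
#' accessible in the four non-pluripotent conditions and loops to the
#' promoter in aPSM and HIFLR but not in ESC; two decoys accessible
#' everywhere but never looped (the -25 kb and -3.5 kb analogs); and one
#' decoy looped in aPSM/HIFLR but inaccessible everywhere. With the
#' recorded nomination arguments (loops required in aPSM and HIFLR,
#' forbidden in ESC, accessibility in at least 4 conditions), exactly the
#' En7 analog is supported.
#'
#' @param out_dir Optional directory to write the fixture files to.
#' @return A list of class `En7Fixture` with `tss`, `elements`,
#'   `atac_by_condition`, `interactions_by_condition`, `nominate_args`,
#'   `truth` (name of the one supported element) and `files`.
#' @export
make_en7_fixture <- function(out_dir = NULL) {
  conds <- c("ESC", "aPSM", "HIFLR", "MuSC", "somite")
  tss <- tss_table(c("Pax7", "CtrlGene"), c("chrP", "chrP"),
                   c(1000000, 2000000), c("+", "+"))
  res <- 10000
  elements <- interval_set(
    rep("chrP", 4),
    c(1014525, 974600, 996100, 959600),
    c(1015475, 975400, 996900, 960400),
    name = c("En7", "minus25kb", "minus3p5kb", "decoy_inaccessible")
  )
  prom_peak <- data.frame(chrom = "chrP", start = 999700, end = 1000300,
                          name = "Pax7_promoter", stringsAsFactors = FALSE)
  el <- as.data.frame(elements)
  el_peak <- function(nm) {
    r <- el[el$name == nm, , drop = FALSE]
    data.frame(chrom = r$chrom, start = r$start, end = r$end, name = nm,
               stringsAsFactors = FALSE)
  }
  atac <- list()
  for (cond in conds) {
    open <- prom_peak
    open <- rbind(open, el_peak("minus25kb"), el_peak("minus3p5kb"))
    if (cond != "ESC") open <- rbind(open, el_peak("En7"))
    atac[[cond]] <- interval_set(open$chrom, open$start, open$end,
                                 name = open$name,
                                 label = paste0("ATAC_", cond))
  }
  bin_of <- function(pos) floor(pos / res) * res
  prom_bin <- bin_of(1000000)
  loop_row <- function(element_pos, cond) {
    eb <- bin_of(element_pos)
    canonicalize_interactions(data.frame(
      chrom1 = "chrP", start1 = eb, end1 = eb + res,
      chrom2 = "chrP", start2 = prom_bin, end2 = prom_bin + res,
      name = "loop", score = 10, condition = cond, stringsAsFactors = FALSE))
  }
  empty_ia <- structure(
    data.frame(chrom1 = character(), start1 = numeric(), end1 = numeric(),
               chrom2 = character(), start2 = numeric(), end2 = numeric(),
               name = character(), score = numeric(), condition = character(),
               stringsAsFactors = FALSE),
    class = c("InteractionTable", "data.frame"))
  interactions <- list(ESC = empty_ia, MuSC = empty_ia, somite = empty_ia)
  for (cond in c("aPSM", "HIFLR")) {
    ia <- rbind(loop_row(1015000, cond), loop_row(960000, cond))
    interactions[[cond]] <- structure(ia, class = c("InteractionTable", "data.frame"))
  }
  fixture <- structure(list(
    tss = tss, elements = elements, atac_by_condition = atac,
    interactions_by_condition = interactions,
    nominate_args = list(gene_id = "Pax7",
                         required_loop_conditions = c("aPSM", "HIFLR"),
                         forbidden_loop_conditions = "ESC",
                         min_accessible = 4),
    truth = "En7", files = NULL
  ), class = "En7Fixture")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(tss = file.path(out_dir, "tss.bed"),
                  elements = file.path(out_dir, "elements.bed"))
    write_tss(tss, files$tss)
    write_bed(elements, files$elements)
    for (cond in conds) {
      f <- file.path(out_dir, paste0("atac_", cond, ".bed"))
      write_bed(atac[[cond]], f)
      files[[paste0("atac_", cond)]] <- f
      f <- file.path(out_dir, paste0("loops_", cond, ".bedpe"))
      write_bedpe(interactions[[cond]], f)
      files[[paste0("loops_", cond)]] <- f
    }
    fixture$files <- files
  }
  fixture
}
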