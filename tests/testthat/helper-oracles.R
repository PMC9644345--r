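# Brute-force all-pairs re-derivations, written against plain data frames
# with explicit loops so they stay independent of the package's interval
# engine.

ov1 <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 && s1 < e2 && s2 < e1
}

brute_presence <- function(query, subject) {
  q <- as.data.frame(query); s <- as.data.frame(subject)
  out <- logical(nrow(q))
  for (i in seq_len(nrow(q))) {
    hit <- FALSE
    for (j in seq_len(nrow(s))) {
      if (ov1(q$chrom[i], q$start[i], q$end[i], s$chrom[j], s$start[j], s$end[j])) {
        hit <- TRUE; break
      }
    }
    out[i] <- hit
  }
  out
}

brute_nearest_tss <- function(regions, tss) {
  r <- as.data.frame(regions)
  genes <- character(nrow(r)); dists <- numeric(nrow(r))
  for (i in seq_len(nrow(r))) {
    mid <- floor((r$start[i] + r$end[i]) / 2)
    on_chrom <- tss[tss$chrom == r$chrom[i], , drop = FALSE]
    best <- NULL
    for (j in seq_len(nrow(on_chrom))) {
      d <- abs(mid - on_chrom$tss[j])
      if (is.null(best) || d < best$d ||
          (d == best$d && on_chrom$gene_id[j] < best$g)) {
        best <- list(d = d, g = on_chrom$gene_id[j],
                     raw = mid - on_chrom$tss[j], strand = on_chrom$strand[j])
      }
    }
    genes[i] <- best$g
    dists[i] <- if (best$strand == "-") -best$raw else best$raw
  }
  data.frame(gene_id = genes, distance = dists, stringsAsFactors = FALSE)
}

# enhancer calling + classification re-derived with loops only
brute_enhancer_calls <- function(atac_a, k4_a, k27_a, atac_b, k4_b, k27_b,
                                 tss, config) {
  k27b <- as.data.frame(k27_b)
  keep <- logical(nrow(k27b))
  for (i in seq_len(nrow(k27b))) {
    keep[i] <- brute_presence(k27b[i, ], k4_b) &&
      brute_presence(k27b[i, ], atac_b) &&
      !brute_presence(k27b[i, ], k27_a)
  }
  cand <- k27b[keep, , drop = FALSE]
  if (isTRUE(config$distal_filter) && nrow(cand) > 0) {
    drop <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      for (j in seq_len(nrow(tss))) {
        if (tss$chrom[j] == cand$chrom[i] &&
            tss$tss[j] >= cand$start[i] - config$distal_min_tss_distance &&
            tss$tss[j] < cand$end[i] + config$distal_min_tss_distance) {
          drop[i] <- TRUE; break
        }
      }
    }
    cand <- cand[!drop, , drop = FALSE]
  }
  if (nrow(cand) == 0) return(cand)
  cand$atac_a <- brute_presence(cand, atac_a)
  cand$k4me1_a <- brute_presence(cand, k4_a)
  cand$modality <- ifelse(cand$atac_a & !cand$k4me1_a, "accessible",
                   ifelse(cand$atac_a & cand$k4me1_a, "poised",
                   ifelse(!cand$atac_a & !cand$k4me1_a, "unmarked", "de_novo")))
  nt <- brute_nearest_tss(cand, tss)
  cand$nearest_gene <- nt$gene_id
  cand$tss_distance <- nt$distance
  cand[order(cand$chrom, cand$start, cand$end, cand$name), , drop = FALSE]
}

brute_tss_changes <- function(de, atac_a, atac_b, tss, config) {
  half <- config$tss_half_window
  out <- list()
  for (i in seq_len(nrow(de))) {
    j <- which(tss$gene_id == de$gene_id[i])
    if (length(j) == 0) next
    win <- data.frame(chrom = tss$chrom[j],
                      start = max(0, tss$tss[j] - half),
                      end = tss$tss[j] + half)
    a <- brute_presence(win, atac_a)
    b <- brute_presence(win, atac_b)
    out[[length(out) + 1]] <- data.frame(
      gene_id = de$gene_id[i], de_status = de$status[i],
      atac_a = a, atac_b = b,
      change = if (!a && b) "gained" else if (a && !b) "lost"
               else if (a && b) "stable_open" else "stable_closed",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

brute_annotate <- function(interactions, atac_by_condition, tss, half) {
  df <- as.data.frame(interactions)
  a1o <- logical(nrow(df)); a2o <- logical(nrow(df))
  a1g <- character(nrow(df)); a2g <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    atac <- as.data.frame(atac_by_condition[[df$condition[i]]])
    a1o[i] <- brute_presence(df[i, c("chrom1", "start1", "end1")] |>
                               stats::setNames(c("chrom", "start", "end")), atac)
    a2o[i] <- brute_presence(df[i, c("chrom2", "start2", "end2")] |>
                               stats::setNames(c("chrom", "start", "end")), atac)
    g1 <- character(); g2 <- character()
    for (j in seq_len(nrow(tss))) {
      lo <- max(0, tss$tss[j] - half); hi <- tss$tss[j] + half
      if (ov1(df$chrom1[i], df$start1[i], df$end1[i], tss$chrom[j], lo, hi)) {
        g1 <- c(g1, tss$gene_id[j])
      }
      if (ov1(df$chrom2[i], df$start2[i], df$end2[i], tss$chrom[j], lo, hi)) {
        g2 <- c(g2, tss$gene_id[j])
      }
    }
    a1g[i] <- paste(sort(unique(g1)), collapse = ",")
    a2g[i] <- paste(sort(unique(g2)), collapse = ",")
  }
  df$anchor1_open <- a1o; df$anchor2_open <- a2o
  df$anchor1_genes <- a1g; df$anchor2_genes <- a2g
  df
}

brute_rp10m <- function(regions, tags, library_size, scale = 1e7) {
  r <- as.data.frame(regions); tg <- as.data.frame(tags)
  out <- numeric(nrow(r))
  for (i in seq_len(nrow(r))) {
    n <- 0
    for (j in seq_len(nrow(tg))) {
      if (ov1(r$chrom[i], r$start[i], r$end[i], tg$chrom[j], tg$start[j], tg$end[j])) {
        n <- n + 1
      }
    }
    out[i] <- n * scale / library_size
  }
  out
}

random_interval_set <- function(n, chroms = c("chrT1", "chrT2"),
                                size = 1e6, max_width = 5000, label = NULL) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- floor(runif(n, 0, size - max_width))
  width <- ceiling(runif(n, 1, max_width))
  interval_set(chrom, start, start + width,
               name = sprintf("iv%04d", seq_len(n)), label = label)
}

# standard two-condition analysis of a synthetic study, shared across tests
analyse_study <- function(st, config = analysis_config()) {
  rp <- reproducible_peaks(st)
  ca <- st$params$conditions[1]; cb <- st$params$conditions[2]
  de <- suppressMessages(differential_expression(st$expression, ca, cb, config))
  changes <- tss_accessibility_table(de, rp[[ca]]$atac, rp[[cb]]$atac,
                                     st$tss, config)
  calls <- suppressWarnings(
    call_enhancers(rp[[ca]]$atac, rp[[ca]]$k4me1, rp[[ca]]$k27ac,
                   rp[[cb]]$atac, rp[[cb]]$k4me1, rp[[cb]]$k27ac,
                   st$tss, config))
  calls <- classify_modality(calls, rp[[ca]]$atac, rp[[ca]]$k4me1)
  list(rp = rp, de = de, changes = changes, calls = calls,
       report = build_report(calls, changes, de))
}

# planted-class recovery of a study's enhancer calls: recall of planted
# regions among calls, and modality agreement among the recovered ones
recovery_stats <- function(st, calls) {
  truth <- st$truth$enhancers
  m <- match(calls$name, paste0(truth$name, "_k27ac_b"))
  ok <- !is.na(m)
  list(recall = mean(seq_len(nrow(truth)) %in% m),
       modality = mean(calls$modality[ok] == truth$class[m[ok]]),
       n_spurious = sum(!ok))
}
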