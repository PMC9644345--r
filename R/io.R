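#' Analysis configuration
#'
#' All thresholds used by the pipeline, with the study defaults: 1.5-fold
#' expression change, minimum expression 1 RPKM, adjusted p < 0.05, a
#' +/- 2 kb TSS window, a +/- 10 kb peak-center window, tags-per-10-million
#' signal scaling, and 10 kb Hi-C bins extracted with a 25 kb window.
#'
#' @param fc_threshold Fold-change cutoff (> 1).
#' @param min_expression Expression floor in RPKM.
#' @param alpha Adjusted-p cutoff, in (0, 1).
#' @param tss_half_window Promoter half-window in bp.
#' @param peak_half_window Peak-center half-window in bp.
#' @param rp10m_scale Signal normalization constant (tags per 10 million).
#' @param hic_resolution Hi-C bin size in bp.
#' @param hic_window Window used upstream when significant interactions were
#'   extracted; carried for provenance, not consumed downstream.
#' @param distal_filter Drop enhancer candidates near a TSS?
#' @param distal_min_tss_distance Minimum distance to any TSS (bp) for a
#'   region to count as distal.
#' @return A list of class `AnalysisConfig`.
#' @export
analysis_config <- function(fc_threshold = 1.5,
                            min_expression = 1.0,
                            alpha = 0.05,
                            tss_half_window = 2000,
                            peak_half_window = 10000,
                            rp10m_scale = 1e7,
                            hic_resolution = 10000,
                            hic_window = 25000,
                            distal_filter = TRUE,
                            distal_min_tss_distance = 2000) {
  cfg <- list(fc_threshold = fc_threshold, min_expression = min_expression,
              alpha = alpha, tss_half_window = tss_half_window,
              peak_half_window = peak_half_window, rp10m_scale = rp10m_scale,
              hic_resolution = hic_resolution, hic_window = hic_window,
              distal_filter = distal_filter,
              distal_min_tss_distance = distal_min_tss_distance)
  num <- setdiff(names(cfg), "distal_filter")
  for (k in num) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] <= 0) {
      stop(sprintf("config field '%s' must be a single positive number", k),
           call. = FALSE)
    }
  }
  if (cfg$alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (cfg$fc_threshold <= 1) stop("fc_threshold must be > 1", call. = FALSE)
  if (!is.logical(cfg$distal_filter) || length(cfg$distal_filter) != 1) {
    stop("distal_filter must be TRUE or FALSE", call. = FALSE)
  }
  structure(cfg, class = "AnalysisConfig")
}

#' Read a flat key-value configuration file
#'
#' A YAML-compatible flat mapping; keys must be fields of
#' [analysis_config()]. Unknown keys are an error, so a typo can never
#' silently fall back to a default threshold.
#'
#' @param path Path to the config file.
#' @return An `AnalysisConfig`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @param config An `AnalysisConfig` to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

parse_error <- function(path, line_no, msg) {
  stop(sprintf("%s: line %d: %s", path, line_no, msg), call. = FALSE)
}

read_table_lines <- function(path, min_cols, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines, keep = which(keep))
}

#' Read a BED3/BED6 file as an IntervalSet
#'
#' `track`, `browser` and `#` comment lines are skipped. A malformed line
#' (fewer than 3 columns, non-numeric or inverted coordinates) is an error
#' reporting the offending line number; records are rejected, never
#' silently repaired.
#'
#' @param path Path to a BED file (0-based half-open, tab-separated).
#' @param label Optional track label attached to the result.
#' @return An `IntervalSet`.
#' @export
read_bed <- function(path, label = NULL) {
  lr <- read_table_lines(path, 3, "BED")
  if (length(lr$keep) == 0) return(interval_set(label = label))
  fields <- strsplit(lr$lines[lr$keep], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3)) {
    parse_error(path, lr$keep[which(ncols < 3)[1]], "fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) parse_error(path, lr$keep[bad[1]], "non-numeric coordinates")
  bad <- which(start < 0 | start >= end)
  if (length(bad) > 0) {
    parse_error(path, lr$keep[bad[1]],
                sprintf("invalid span %s-%s (need 0 <= start < end)",
                        format(start[bad[1]], scientific = FALSE),
                        format(end[bad[1]], scientific = FALSE)))
  }
  getcol <- function(i, default) {
    ifelse(ncols >= i, vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, ""), default)
  }
  name <- getcol(4, ".")
  score <- suppressWarnings(as.numeric(getcol(5, "0")))
  score[is.na(score)] <- 0
  strand <- getcol(6, ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  interval_set(chrom, start, end, name = name, score = score,
               strand = strand, label = label)
}

#' Write an IntervalSet as BED6
#'
#' @param x An `IntervalSet`.
#' @param path Output path.
#' @param extra_cols Optional data frame of extra columns (BED6+).
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra_cols = NULL) {
  df <- as.data.frame(x)
  df$start <- format_coord(df$start)
  df$end <- format_coord(df$end)
  if (!is.null(extra_cols)) df <- cbind(df, extra_cols)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a BEDPE table of significant Hi-C interactions
#'
#' Anchors are snapped to resolution-aligned bins
#' (`floor(start / resolution) * resolution`, width one bin) and the anchor
#' pair is normalised so anchor1 sorts before anchor2 by (chrom, start). A
#' warning is issued once if input spans are not already bin-sized. A
#' missing score column yields score 0 with a note.
#'
#' @param path Path to a BEDPE file (>= 6 columns: chrom1, start1, end1,
#'   chrom2, start2, end2, then optional name and score).
#' @param resolution Hi-C bin size in bp.
#' @param condition Optional condition label stored in a `condition` column.
#' @return A data frame of class `InteractionTable` with columns `chrom1`,
#'   `start1`, `end1`, `chrom2`, `start2`, `end2`, `name`, `score` (and
#'   `condition` if given).
#' @export
read_bedpe <- function(path, resolution = 10000, condition = NULL) {
  lr <- read_table_lines(path, 6, "BEDPE")
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (length(lr$keep) == 0) {
    out <- data.frame(chrom1 = character(), start1 = numeric(),
                      end1 = numeric(), chrom2 = character(),
                      start2 = numeric(), end2 = numeric(),
                      name = character(), score = numeric(),
                      stringsAsFactors = FALSE)
    if (!is.null(condition)) out$condition <- character()
    return(structure(out, class = c("InteractionTable", "data.frame")))
  }
  fields <- strsplit(lr$lines[lr$keep], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 6)) {
    parse_error(path, lr$keep[which(ncols < 6)[1]], "fewer than 6 columns")
  }
  num <- function(i) suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
  chr1 <- vapply(fields, `[[`, "", 1); s1 <- num(2); e1 <- num(3)
  chr2 <- vapply(fields, `[[`, "", 4); s2 <- num(5); e2 <- num(6)
  bad <- which(is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2))
  if (length(bad) > 0) parse_error(path, lr$keep[bad[1]], "non-numeric anchor coordinates")
  bad <- which(s1 < 0 | s1 >= e1 | s2 < 0 | s2 >= e2)
  if (length(bad) > 0) parse_error(path, lr$keep[bad[1]], "invalid anchor span")
  name <- ifelse(ncols >= 7, vapply(fields, function(f) if (length(f) >= 7) f[[7]] else ".", ""), ".")
  if (any(ncols < 8)) message("read_bedpe: score column missing for some rows; using 0")
  score <- suppressWarnings(as.numeric(
    ifelse(ncols >= 8, vapply(fields, function(f) if (length(f) >= 8) f[[8]] else "0", ""), "0")))
  score[is.na(score)] <- 0
  if (any((s1 %% resolution) != 0 | (e1 - s1) != resolution |
          (s2 %% resolution) != 0 | (e2 - s2) != resolution)) {
    warning(sprintf("%s: anchor spans are not %d-bp bins; snapping to bins",
                    path, as.integer(resolution)), call. = FALSE)
  }
  b1 <- floor(s1 / resolution) * resolution
  b2 <- floor(s2 / resolution) * resolution
  out <- data.frame(chrom1 = chr1, start1 = b1, end1 = b1 + resolution,
                    chrom2 = chr2, start2 = b2, end2 = b2 + resolution,
                    name = name, score = score, stringsAsFactors = FALSE)
  out <- canonicalize_interactions(out)
  if (!is.null(condition)) out$condition <- condition
  structure(out, class = c("InteractionTable", "data.frame"))
}

# anchor1 must order before anchor2 by (chrom, start); swap rows violating it
canonicalize_interactions <- function(df) {
  swap <- df$chrom1 > df$chrom2 |
    (df$chrom1 == df$chrom2 & df$start1 > df$start2)
  if (any(swap)) {
    tmp <- df[swap, c("chrom1", "start1", "end1")]
    df[swap, c("chrom1", "start1", "end1")] <- df[swap, c("chrom2", "start2", "end2")]
    df[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  rownames(df) <- NULL
  df
}

#' Write an interaction table as BEDPE
#'
#' @param x An `InteractionTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(x, path) {
  df <- as.data.frame(x)[, c("chrom1", "start1", "end1",
                             "chrom2", "start2", "end2", "name", "score")]
  for (k in c("start1", "end1", "start2", "end2")) df[[k]] <- format_coord(df[[k]])
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a replicate RPKM expression matrix
#'
#' Tab-separated with a header; first column `gene_id`, remaining columns
#' named `<condition>_<replicate>` (condition parsed from everything before
#' the last underscore). Negative values, duplicate genes, and conditions
#' with fewer than two replicates are errors.
#'
#' @param path Path to the TSV file.
#' @return An `ExpressionTable`: list with `gene_ids`, `values` (gene x
#'   replicate matrix), `conditions` (per-column condition labels).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(dt) < 3) stop(path, ": need gene_id plus >= 2 replicate columns", call. = FALSE)
  gene_ids <- as.character(dt[[1]])
  vals <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  expression_table(gene_ids, vals)
}

#' Construct an expression table
#'
#' @param gene_ids Character vector of unique gene identifiers.
#' @param values Numeric gene x replicate matrix with `<condition>_<rep>`
#'   column names; all values must be non-negative.
#' @return An `ExpressionTable`.
#' @export
expression_table <- function(gene_ids, values) {
  gene_ids <- as.character(gene_ids)
  dup <- duplicated(gene_ids)
  if (any(dup)) stop("duplicate gene_id: ", gene_ids[dup][1], call. = FALSE)
  if (anyNA(values)) stop("expression values must not be NA", call. = FALSE)
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value for gene '%s' column '%s'",
                 gene_ids[bad[1]], colnames(values)[bad[2]]), call. = FALSE)
  }
  conds <- sub("_[^_]+$", "", colnames(values))
  tab <- table(conds)
  if (any(tab < 2)) {
    stop("condition(s) with fewer than 2 replicates: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  rownames(values) <- gene_ids
  structure(list(gene_ids = gene_ids, values = values, conditions = conds),
            class = "ExpressionTable")
}

#' @export
print.ExpressionTable <- function(x, ...) {
  cat(sprintf("ExpressionTable: %d genes x %d replicate columns (%s)\n",
              length(x$gene_ids), ncol(x$values),
              paste(unique(x$conditions), collapse = ", ")))
  invisible(x)
}

#' Write an expression table as TSV
#' @param x An `ExpressionTable`.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = x$gene_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a TSS table from BED6
#'
#' Expects one record per gene with `start = tss`, `end = tss + 1`,
#' `name = gene_id` and an explicit strand.
#'
#' @param path Path to the BED6 file.
#' @return A `TSSTable`.
#' @export
read_tss <- function(path) {
  x <- read_bed(path)
  if (nrow(x) == 0) stop(path, ": empty TSS table", call. = FALSE)
  if (any(x$end - x$start != 1)) {
    stop(path, ": TSS records must have width 1 (start = tss, end = tss + 1)",
         call. = FALSE)
  }
  tss_table(x$name, x$chrom, x$start, x$strand)
}

#' Write a TSS table as BED6
#' @param x A `TSSTable`.
#' @param path Output path.
#' @export
write_tss <- function(x, path) {
  write_bed(interval_set(x$chrom, x$tss, x$tss + 1, name = x$gene_id,
                         score = 0, strand = x$strand), path)
}
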