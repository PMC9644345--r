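log_line <- function(log_path, fmt, ...) {
  msg <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
  message(msg)
  if (!is.null(log_path)) cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  invisible(NULL)
}

#' Run the full regulatory-landscape pipeline
#'
#' Executes, in order: optional synthetic-study generation (or loading of
#' user-supplied input files), replicate merging, differential expression,
#' TSS accessibility change, enhancer calling and modality classification,
#' the landscape report, and (when loop tables and a target gene are
#' given) candidate-enhancer nomination. All analytic outputs plus a run
#' manifest (config snapshot, input checksums, seed, stage timings,
#' package version) are written to `out_dir`; re-running with identical
#' inputs, config and seed reproduces byte-identical analytic outputs.
#' Counts at every filter boundary are logged.
#'
#' @param out_dir Output directory (created if needed).
#' @param config An `AnalysisConfig`.
#' @param study A `SyntheticStudy` to analyse, or `NULL` to use `inputs`.
#' @param inputs Named list of file paths (used when `study` is `NULL`):
#'   `tss`, `expression`, per-condition/track peak BEDs as produced by
#'   [simulate_study()] (`peaks_<cond>_<track>_rep<k>`), and optional
#'   `loops_<cond>` BEDPE paths.
#' @param conditions Length-2 character vector (condition A, condition B);
#'   defaults to the study's conditions.
#' @param nominate_gene Optional gene for candidate nomination.
#' @param nominate_required,nominate_forbidden Loop conditions required /
#'   forbidden for support.
#' @param nominate_min_accessible Minimum accessible conditions.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed drives simulation only).
#' @return Invisibly, a list with the pipeline objects (`de`, `changes`,
#'   `calls`, `report`, `candidates`) and `out_dir`.
#' @export
run_pipeline <- function(out_dir,
                         config = analysis_config(),
                         study = NULL,
                         inputs = NULL,
                         conditions = NULL,
                         nominate_gene = NULL,
                         nominate_required = NULL,
                         nominate_forbidden = character(),
                         nominate_min_accessible = 1,
                         seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  if (file.exists(log_path)) unlink(log_path)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      log_line(log_path, "stage '%s' FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    res
  }
  checksums <- list()

  if (is.null(study)) {
    if (is.null(inputs)) stop("provide either a study or input file paths", call. = FALSE)
    if (is.null(conditions)) stop("conditions must be given with file inputs", call. = FALSE)
    needed <- c("tss", "expression")
    missing_in <- needed[!needed %in% names(inputs)]
    if (length(missing_in) > 0) {
      stop("missing required input(s): ", paste(missing_in, collapse = ", "),
           call. = FALSE)
    }
    loaded <- stage("load_inputs", {
      tss <- read_tss(inputs$tss)
      expr <- read_expression(inputs$expression)
      peaks <- list()
      for (cond in conditions) {
        peaks[[cond]] <- list()
        for (track in c("atac", "k4me1", "k27ac")) {
          k1 <- paste("peaks", cond, track, "rep1", sep = "_")
          k2 <- paste("peaks", cond, track, "rep2", sep = "_")
          if (!k1 %in% names(inputs)) {
            stop("missing peak input: ", k1, call. = FALSE)
          }
          rep1 <- read_bed(inputs[[k1]], label = k1)
          peaks[[cond]][[track]] <- if (k2 %in% names(inputs)) {
            list(rep1 = rep1, rep2 = read_bed(inputs[[k2]], label = k2))
          } else list(rep1 = rep1, rep2 = rep1)
        }
      }
      loops <- list()
      for (cond in conditions) {
        k <- paste("loops", cond, sep = "_")
        if (k %in% names(inputs)) {
          loops[[cond]] <- read_bedpe(inputs[[k]], config$hic_resolution,
                                      condition = cond)
        }
      }
      for (k in names(inputs)) checksums[[k]] <- unname(tools::md5sum(inputs[[k]]))
      list(tss = tss, expression = expr, peaks = peaks, loops = loops)
    })
    tss <- loaded$tss; expr <- loaded$expression
    peaks <- loaded$peaks; loops <- loaded$loops
  } else {
    if (is.null(conditions)) conditions <- study$params$conditions
    tss <- study$tss; expr <- study$expression
    peaks <- study$peaks; loops <- study$loops
    if (!is.null(study$files)) {
      for (k in names(study$files)) {
        checksums[[k]] <- unname(tools::md5sum(study$files[[k]]))
      }
    }
  }
  cond_a <- conditions[1]; cond_b <- conditions[2]
  if (!is.null(nominate_gene) && length(loops) == 0) {
    stop("candidate nomination requested but no loop (BEDPE) input was provided",
         call. = FALSE)
  }

  merged <- stage("replicate_merge", {
    lapply(peaks, function(cond) {
      lapply(cond, function(tr) replicate_reproducible(tr$rep1, tr$rep2))
    })
  })
  for (cond in conditions) {
    for (track in names(merged[[cond]])) {
      log_line(log_path, "replicate_merge: %s/%s %d -> %d regions", cond, track,
               nrow(peaks[[cond]][[track]]$rep1), nrow(merged[[cond]][[track]]))
    }
  }

  de <- stage("differential_expression",
              differential_expression(expr, cond_a, cond_b, config))
  log_line(log_path,
           "differential_expression: %d genes; %d up, %d down, %d ns, %d below %.3g RPKM",
           nrow(de), sum(de$status == "up"), sum(de$status == "down"),
           sum(de$status == "ns"), sum(de$status == "low_expression"),
           config$min_expression)
  write_de(de, file.path(out_dir, "de.tsv"))

  changes <- stage("tss_accessibility",
                   tss_accessibility_table(de, merged[[cond_a]]$atac,
                                           merged[[cond_b]]$atac, tss, config))
  log_line(log_path, "tss_accessibility: %d genes; gained %d, lost %d",
           nrow(changes), sum(changes$change == "gained"),
           sum(changes$change == "lost"))
  data.table::fwrite(changes, file.path(out_dir, "tss_changes.tsv"),
                     sep = "\t", quote = FALSE)

  calls <- stage("call_enhancers", {
    calls <- call_enhancers(merged[[cond_a]]$atac, merged[[cond_a]]$k4me1,
                            merged[[cond_a]]$k27ac, merged[[cond_b]]$atac,
                            merged[[cond_b]]$k4me1, merged[[cond_b]]$k27ac,
                            tss, config)
    classify_modality(calls, merged[[cond_a]]$atac, merged[[cond_a]]$k4me1)
  })
  log_line(log_path, "call_enhancers: %d calls from %d condition-B H3K27ac peaks",
           nrow(calls), nrow(merged[[cond_b]]$k27ac))
  de_status <- de$status[match(calls$nearest_gene, de$gene_id)]
  calls$nearest_gene_de_status <- ifelse(is.na(de_status), "ns", de_status)
  write_bed(new_interval_set(calls),
            file.path(out_dir, "enhancer_calls.bed"),
            extra_cols = as.data.frame(calls)[, c("modality", "atac_a", "k4me1_a",
                                                  "nearest_gene", "tss_distance",
                                                  "nearest_gene_de_status")])

  report <- stage("report", build_report(calls, changes, de))
  data.table::fwrite(report_as_table(report), file.path(out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, na = "NA")
  txt <- file.path(out_dir, "report.txt")
  sink(txt); print(report); sink()

  candidates <- NULL
  if (!is.null(nominate_gene)) {
    candidates <- stage("nominate", {
      atac_by_cond <- lapply(merged, function(x) x$atac)
      if (is.null(nominate_required)) nominate_required <- cond_b
      nominate_candidates(nominate_gene, new_interval_set(calls),
                          atac_by_cond, loops, tss,
                          required_loop_conditions = nominate_required,
                          forbidden_loop_conditions = nominate_forbidden,
                          min_accessible = nominate_min_accessible,
                          promoter_half_window = config$tss_half_window)
    })
    log_line(log_path, "nominate: %d candidates, %d supported",
             nrow(candidates), sum(candidates$supported))
    write_candidates(candidates, file.path(out_dir, "candidates.tsv"))
  }

  manifest <- list(
    tool = "enhancerscape",
    version = as.character(utils::packageVersion("enhancerscape")),
    config = unclass(config),
    conditions = conditions,
    seed = seed,
    input_checksums = checksums,
    stage_timings_s = timings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line(log_path, "done: outputs in %s", out_dir)
  invisible(list(de = de, changes = changes, calls = calls, report = report,
                 candidates = candidates, out_dir = out_dir))
}
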