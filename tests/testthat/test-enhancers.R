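# a hand-built locus: four candidate regions, one per prior-state pattern,
# plus regions failing each conjunct of the enhancer definition
toy_locus <- function() {
  tss <- tss_table(c("gUp", "gNs"), "chr1", c(5000, 95000), c("+", "-"))
  centers <- c(acc = 20000, poi = 30000, unm = 40000, den = 50000,
               oldk27 = 60000, nok4 = 70000, noatac = 80000)
  reg <- function(nms) {
    interval_set("chr1", centers[nms] - 500, centers[nms] + 500, name = nms)
  }
  list(
    tss = tss,
    atac_a = reg(c("acc", "poi")),
    k4_a = reg(c("poi", "den")),
    k27_a = reg("oldk27"),
    atac_b = reg(c("acc", "poi", "unm", "den", "oldk27", "nok4")),
    k4_b = reg(c("acc", "poi", "unm", "den", "oldk27", "noatac")),
    k27_b = reg(names(centers))
  )
}

test_that("enhancer calls require the full acquired signature", {
  L <- toy_locus()
  calls <- call_enhancers(L$atac_a, L$k4_a, L$k27_a, L$atac_b, L$k4_b, L$k27_b,
                          L$tss)
  # called: the four modality exemplars; rejected: pre-existing H3K27ac,
  # missing H3K4me1, missing ATAC
  expect_setequal(calls$name, c("acc", "poi", "unm", "den"))
  expect_true(all(calls$atac_b & calls$k4me1_b & calls$k27ac_b))
  expect_true(all(is.na(calls$modality)))
  classified <- classify_modality(calls, L$atac_a, L$k4_a)
  expect_equal(classified$modality[match(c("acc", "poi", "unm", "den"),
                                         classified$name)],
               c("accessible", "poised", "unmarked", "de_novo"))
  expect_false(any(classified$k27ac_a))
  # nearest-TSS annotation: midpoints 20-50 kb sit nearer gUp at 5 kb
  expect_equal(unique(calls$nearest_gene[calls$start < 45000]), "gUp")
})

test_that("the distal filter drops promoter-proximal candidates", {
  L <- toy_locus()
  # add a candidate straddling a promoter
  prox <- interval_set("chr1", 4600, 5600, name = "prox")
  grow <- function(s, extra) {
    df <- rbind(as.data.frame(s), as.data.frame(extra))
    interval_set(df$chrom, df$start, df$end, name = df$name)
  }
  with_prox <- lapply(L[c("atac_b", "k4_b", "k27_b")], grow, extra = prox)
  on_calls <- call_enhancers(L$atac_a, L$k4_a, L$k27_a, with_prox$atac_b,
                             with_prox$k4_b, with_prox$k27_b, L$tss)
  expect_false("prox" %in% on_calls$name)
  off <- analysis_config(distal_filter = FALSE)
  off_calls <- call_enhancers(L$atac_a, L$k4_a, L$k27_a, with_prox$atac_b,
                              with_prox$k4_b, with_prox$k27_b, L$tss, off)
  expect_true("prox" %in% off_calls$name)
  expect_warning(
    call_enhancers(interval_set(), L$k4_a, L$k27_a, L$atac_b, L$k4_b, L$k27_b,
                   L$tss),
    "empty")
})

test_that("TSS accessibility change classifies all four transitions", {
  tss <- tss_table(c("gGain", "gLoss", "gOpen", "gClosed"), "chr1",
                   c(10000, 30000, 50000, 70000), rep("+", 4))
  peak_at <- function(pos) interval_set("chr1", pos - 200, pos + 200)
  atac_a <- peak_at(c(30000, 50000))
  atac_b <- peak_at(c(10000, 50000))
  de <- data.frame(gene_id = c(tss$gene_id, "gMissing"),
                   status = c("up", "down", "ns", "ns", "up"),
                   stringsAsFactors = FALSE)
  expect_message(ch <- tss_accessibility_table(de, atac_a, atac_b, tss),
                 "absent from the TSS table")
  expect_equal(ch$change[match(c("gGain", "gLoss", "gOpen", "gClosed"),
                               ch$gene_id)],
               c("gained", "lost", "stable_open", "stable_closed"))
  # window edges: a peak just inside +/- 2 kb counts, just outside does not
  inside <- tss_accessibility_table(de[1, , drop = FALSE],
                                    interval_set(), peak_at(12100), tss)
  expect_equal(inside$change, "gained")
  outside <- tss_accessibility_table(de[1, , drop = FALSE],
                                     interval_set(), peak_at(12300), tss)
  expect_equal(outside$change, "stable_closed")
})

test_that("report percentages reproduce the worked count/percent pairs", {
  expect_equal(report_percent(1385, 2022), 68)
  expect_equal(report_percent(597, 1482), 40)
  expect_equal(report_percent(386, 1482), 26)
  expect_equal(report_percent(379, 1482), 26)
  expect_equal(report_percent(379, 1482, decimals = 1), 25.6)
  expect_equal(report_percent(120, 1482), 8)
  expect_equal(report_percent(479, 1288), 37)
  expect_equal(report_percent(0, 10), 0)
  expect_true(is.na(report_percent(5, 0)))
  # half-up, not banker's rounding
  expect_equal(report_percent(25, 200), 13)
  expect_equal(report_percent(35, 1000, decimals = 1), 3.5)
})

test_that("landscape report partitions calls and is order-invariant", {
  st <- simulate_study(simulation_params(n_genes = 300, n_enhancers = 80,
                                         seed = 23, emit_tags = FALSE))
  an <- analyse_study(st)
  rep1 <- an$report
  expect_equal(sum(rep1$modality_counts), rep1$n_enhancers)
  expect_equal(sum(rep1$modality_counts), nrow(an$calls))
  expect_true(all(!is.na(an$calls$modality)))
  # permuting input rows changes nothing
  withr::with_seed(5, {
    calls_p <- an$calls[sample(nrow(an$calls)), ]
    changes_p <- an$changes[sample(nrow(an$changes)), ]
    de_p <- an$de[sample(nrow(an$de)), ]
  })
  rep2 <- build_report(calls_p, changes_p, de_p)
  expect_equal(rep2, rep1)
  # degenerate empty run reports NA percentages, not errors
  rep0 <- build_report(an$calls[0, ], an$changes, an$de)
  expect_true(is.na(rep0$pct_enhancers_near_upregulated))
  expect_true(all(is.na(rep0$modality_percent)))
})

test_that("calls and classes equal the brute-force re-derivation", {
  cfg <- analysis_config()
  withr::with_seed(31, {
    for (rep in 1:3) {
      st <- simulate_study(simulation_params(
        n_genes = 80, n_enhancers = 25, peak_fdr_noise = 0.1,
        seed = sample(1e6, 1), emit_tags = FALSE))
      rp <- reproducible_peaks(st)
      got <- suppressWarnings(
        call_enhancers(rp$naive$atac, rp$naive$k4me1, rp$naive$k27ac,
                       rp$instructed$atac, rp$instructed$k4me1,
                       rp$instructed$k27ac, st$tss, cfg))
      got <- classify_modality(got, rp$naive$atac, rp$naive$k4me1)
      want <- brute_enhancer_calls(rp$naive$atac, rp$naive$k4me1,
                                   rp$naive$k27ac, rp$instructed$atac,
                                   rp$instructed$k4me1, rp$instructed$k27ac,
                                   st$tss, cfg)
      cols <- c("chrom", "start", "end", "name", "atac_a", "k4me1_a",
                "modality", "nearest_gene", "tss_distance")
      expect_equal(as.data.frame(got)[cols],
                   `rownames<-`(want[cols], NULL))
    }
  })
})
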