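test_that("largest-remainder apportionment sums exactly and breaks ties down", {
  expect_equal(largest_remainder(c(0.4, 0.26, 0.255, 0.08), 200),
               c(80L, 52L, 51L, 17L))
  expect_equal(largest_remainder(c(597, 386, 379, 120) / 1482, 1482),
               c(597L, 386L, 379L, 120L))
  withr::with_seed(707, {
    for (rep in 1:20) {
      p <- runif(4); p <- p / sum(p)
      n <- sample(10:2000, 1)
      counts <- largest_remainder(p, n)
      expect_equal(sum(counts), n)
      expect_true(all(abs(counts - p * n) < 1))
    }
  })
  expect_error(largest_remainder(c(0.9, 0.2), 10), "at most 1")
})

test_that("same parameters and seed give byte-identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p <- simulation_params(n_genes = 120, n_enhancers = 30, peak_fdr_noise = 0.05,
                         seed = 42)
  simulate_study(p, d1)
  simulate_study(p, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f2))))
})

test_that("at zero noise the emitted tracks are exactly consistent with truth", {
  st <- simulate_study(simulation_params(n_genes = 200, n_enhancers = 60,
                                         seed = 9, emit_tags = FALSE))
  truth <- st$truth$enhancers
  regions <- interval_set(truth$chrom, truth$start, truth$end, name = truth$name)
  rp <- reproducible_peaks(st)
  # condition-B signature on every planted enhancer
  for (track in c("atac", "k4me1", "k27ac")) {
    expect_true(all(intersect_presence(regions, rp$instructed[[track]])))
  }
  # condition-A marks re-derived from files match the planted class
  atac_a <- intersect_presence(regions, rp$naive$atac)
  k4_a <- intersect_presence(regions, rp$naive$k4me1)
  rederived <- ifelse(atac_a & !k4_a, "accessible",
               ifelse(atac_a & k4_a, "poised",
               ifelse(!atac_a & !k4_a, "unmarked", "de_novo")))
  truth_sorted <- truth[match(regions$name, truth$name), ]
  expect_equal(rederived, truth_sorted$class)
  # no planted enhancer carries a prior-state H3K27ac peak
  expect_false(any(intersect_presence(regions, rp$naive$k27ac)))
  # promoter accessibility matches the planted TSS change
  g <- st$truth$genes
  open_a <- intersect_presence(
    interval_set(st$tss$chrom, pmax(0, st$tss$tss - 2000), st$tss$tss + 2000,
                 name = st$tss$gene_id),
    rp$naive$atac)
  want_a <- g$tss_change[match(sort(g$gene_id), g$gene_id)] %in%
    c("lost", "stable_open")
  expect_equal(open_a, want_a)
})

test_that("planted class counts follow the apportioned proportions", {
  st <- simulate_study(simulation_params(n_genes = 500, n_enhancers = 200,
                                         seed = 3, emit_tags = FALSE))
  counts <- table(factor(st$truth$enhancers$class,
                         levels = c("accessible", "poised", "unmarked", "de_novo")))
  expect_equal(as.integer(counts),
               largest_remainder(st$params$class_proportions, 200))
})

test_that("infeasible chromosome sizes are rejected", {
  expect_error(
    simulate_study(simulation_params(n_genes = 1000,
                                     chrom_sizes = c(tiny = 1e6))),
    "infeasible")
})

test_that("the En7 fixture plants exactly one fully supported element", {
  fx <- make_en7_fixture()
  acc_counts <- vapply(fx$atac_by_condition, function(a)
    sum(intersect_presence(fx$elements, a)), 0)
  # the En7 analog is open in the 4 non-pluripotent conditions only
  el <- as.data.frame(fx$elements)
  en7 <- interval_set("chrP", el$start[el$name == "En7"], el$end[el$name == "En7"])
  expect_false(intersect_presence(en7, fx$atac_by_condition$ESC))
  for (cond in c("aPSM", "HIFLR", "MuSC", "somite")) {
    expect_true(intersect_presence(en7, fx$atac_by_condition[[cond]]))
  }
  expect_equal(nrow(fx$interactions_by_condition$ESC), 0)
  expect_equal(nrow(fx$interactions_by_condition$aPSM), 2)
  # by construction exactly one element meets all three conditions
  cand <- do.call(nominate_candidates,
                  c(list(elements = fx$elements,
                         atac_by_condition = fx$atac_by_condition,
                         interactions_by_condition = fx$interactions_by_condition,
                         tss = fx$tss),
                    fx$nominate_args))
  expect_equal(cand$name[cand$supported], "En7")
})

test_that("fixture files round-trip through the readers", {
  d <- withr::local_tempdir()
  st <- simulate_study(simulation_params(n_genes = 100, n_enhancers = 20,
                                         seed = 5), d)
  expect_equal(as.data.frame(read_bed(st$files$peaks_instructed_k27ac_rep1,
                                      label = "k27ac_instructed_rep1")),
               as.data.frame(st$peaks$instructed$k27ac$rep1))
  tss_back <- read_tss(st$files$tss)
  expect_equal(tss_back[order(tss_back$gene_id), ]$tss,
               st$tss[order(st$tss$gene_id), ]$tss)
  expr_back <- read_expression(st$files$expression)
  expect_equal(expr_back$values, st$expression$values, tolerance = 1e-12)
  loops_back <- read_bedpe(st$files$loops_instructed, 10000,
                           condition = "instructed")
  expect_equal(as.data.frame(loops_back),
               as.data.frame(st$loops$instructed))
})
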