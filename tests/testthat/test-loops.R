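test_that("interaction annotation flags open anchors and promoter genes", {
  tss <- tss_table(c("gA", "gB"), "chr1", c(15000, 250000), c("+", "-"))
  atac <- list(
    aPSM = interval_set("chr1", 52000, 52500),
    ESC = interval_set("chr1", 900000, 900100)
  )
  ia <- data.frame(chrom1 = "chr1", start1 = 50000, end1 = 60000,
                   chrom2 = "chr1", start2 = 10000, end2 = 20000,
                   name = "L1", score = 5, condition = "aPSM",
                   stringsAsFactors = FALSE)
  ann <- annotate_interactions(ia, atac, tss, promoter_half_window = 2000)
  # canonical order puts the 10 kb bin first; flags follow their condition
  expect_equal(ann$start1, 10000)
  expect_false(ann$anchor1_open)   # no aPSM peak in 10-20 kb
  expect_true(ann$anchor2_open)    # aPSM peak at 52 kb
  expect_equal(ann$anchor1_genes, "gA")
  expect_equal(ann$anchor2_genes, "")
  # same loop in ESC: the open flag derives from the ESC track only
  ia$condition <- "ESC"
  ann <- annotate_interactions(ia, atac, tss, 2000)
  expect_false(ann$anchor2_open)
  ia$condition <- "HIFLR"
  expect_error(annotate_interactions(ia, atac, tss, 2000), "unknown condition")
})

test_that("annotation is invariant to anchor order and matches brute force", {
  withr::with_seed(121, {
    tss <- tss_table(sprintf("g%02d", 1:20), sample(c("chrT1", "chrT2"), 20, TRUE),
                     floor(runif(20, 0, 1e6)), sample(c("+", "-"), 20, TRUE))
    atac <- list(condX = random_interval_set(100, size = 1e6),
                 condY = random_interval_set(100, size = 1e6))
    res <- 10000
    bins <- function(n) {
      b <- floor(runif(n, 0, 100)) * res
      list(start = b, end = b + res)
    }
    a1 <- bins(50); a2 <- bins(50)
    ia <- data.frame(chrom1 = sample(c("chrT1", "chrT2"), 50, TRUE),
                     start1 = a1$start, end1 = a1$end,
                     chrom2 = sample(c("chrT1", "chrT2"), 50, TRUE),
                     start2 = a2$start, end2 = a2$end,
                     name = sprintf("L%02d", 1:50), score = 1,
                     condition = sample(c("condX", "condY"), 50, TRUE),
                     stringsAsFactors = FALSE)
    ann <- annotate_interactions(ia, atac, tss, 2000)
    want <- brute_annotate(ann[, 1:9], atac, tss, 2000)
    expect_equal(as.data.frame(ann), want)
    # swapping the anchors of the input changes nothing
    swapped <- ia[, c("chrom2", "start2", "end2", "chrom1", "start1", "end1",
                      "name", "score", "condition")]
    names(swapped) <- names(ia)
    ann2 <- annotate_interactions(swapped, atac, tss, 2000)
    ord <- function(x) x[order(x$name), ]
    expect_equal(ord(as.data.frame(ann2)), ord(as.data.frame(ann)))
  })
})

test_that("candidate support needs accessibility plus the loop pattern", {
  fx <- make_en7_fixture()
  cand <- do.call(nominate_candidates,
                  c(list(elements = fx$elements,
                         atac_by_condition = fx$atac_by_condition,
                         interactions_by_condition = fx$interactions_by_condition,
                         tss = fx$tss),
                    fx$nominate_args))
  expect_equal(sum(cand$supported), 1)
  expect_equal(cand$name[cand$supported], "En7")
  # accessible-but-unlooped decoys fail the required-loop condition
  decoys <- cand[cand$name %in% c("minus25kb", "minus3p5kb"), ]
  expect_true(all(decoys$n_accessible == 5))
  expect_true(all(decoys$n_required_looped == 0))
  # the looped-but-inaccessible decoy fails the accessibility condition
  d4 <- cand[cand$name == "decoy_inaccessible", ]
  expect_equal(d4$n_required_looped, 2)
  expect_equal(d4$n_accessible, 0)
  # with no interaction evidence at all, nothing is supported
  empty <- lapply(fx$interactions_by_condition, function(x) x[0, ])
  none <- do.call(nominate_candidates,
                  c(list(elements = fx$elements,
                         atac_by_condition = fx$atac_by_condition,
                         interactions_by_condition = empty,
                         tss = fx$tss),
                    fx$nominate_args))
  expect_equal(sum(none$supported), 0)
  # a loop in the forbidden condition disqualifies the candidate
  withloop <- fx$interactions_by_condition
  esc_loop <- withloop$aPSM[1, ]
  esc_loop$condition <- "ESC"
  withloop$ESC <- esc_loop
  rejected <- do.call(nominate_candidates,
                      c(list(elements = fx$elements,
                             atac_by_condition = fx$atac_by_condition,
                             interactions_by_condition = withloop,
                             tss = fx$tss),
                        fx$nominate_args))
  expect_equal(sum(rejected$supported), 0)
  expect_error(
    do.call(nominate_candidates,
            c(list(elements = fx$elements,
                   atac_by_condition = fx$atac_by_condition,
                   interactions_by_condition = fx$interactions_by_condition,
                   tss = fx$tss),
              utils::modifyList(fx$nominate_args, list(gene_id = "Nope")))),
    "gene not found")
})

test_that("nomination is deterministic under input row permutation", {
  fx <- make_en7_fixture()
  run <- function(elements, ia) {
    do.call(nominate_candidates,
            c(list(elements = elements, atac_by_condition = fx$atac_by_condition,
                   interactions_by_condition = ia, tss = fx$tss),
              fx$nominate_args))
  }
  base <- run(fx$elements, fx$interactions_by_condition)
  withr::with_seed(77, {
    el <- as.data.frame(fx$elements)
    el <- el[sample(nrow(el)), ]
    shuffled_elements <- interval_set(el$chrom, el$start, el$end, name = el$name)
    ia <- lapply(fx$interactions_by_condition, function(x) {
      if (nrow(x) > 1) x[sample(nrow(x)), ] else x
    })
  })
  again <- run(shuffled_elements, ia)
  expect_equal(as.data.frame(again), as.data.frame(base))
})

test_that("trans-chromosomal interactions never support a candidate", {
  fx <- make_en7_fixture()
  ia <- fx$interactions_by_condition
  # rewrite the En7 loops as trans contacts
  for (cond in c("aPSM", "HIFLR")) {
    ia[[cond]]$chrom2 <- "chrQ"
  }
  cand <- do.call(nominate_candidates,
                  c(list(elements = fx$elements, atac_by_condition = fx$atac_by_condition,
                         interactions_by_condition = ia, tss = fx$tss),
                    fx$nominate_args))
  expect_equal(sum(cand$supported), 0)
})

test_that("planted loops are recovered as supported pairs at zero noise", {
  st <- simulate_study(simulation_params(n_genes = 200, n_enhancers = 60,
                                         n_loops = 20, seed = 13,
                                         emit_tags = FALSE))
  rp <- reproducible_peaks(st)
  atac <- list(naive = rp$naive$atac, instructed = rp$instructed$atac)
  truth <- st$truth$enhancers
  for (k in seq_len(nrow(st$truth$loops))) {
    enh <- st$truth$loops$enhancer[k]
    row <- truth[truth$name == enh, ]
    cand <- nominate_candidates(
      st$truth$loops$target_gene[k],
      interval_set(row$chrom, row$start, row$end, name = row$name),
      atac, st$loops, st$tss,
      required_loop_conditions = "instructed",
      min_accessible = 1)
    expect_true(cand$supported)
  }
})
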