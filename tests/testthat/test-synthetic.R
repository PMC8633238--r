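test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 9, n_patients = 3, n_blocks = 200,
                    n_donors = 20)
  p1 <- simulate_normal_panel(cfg)
  p2 <- simulate_normal_panel(cfg)
  expect_identical(p1, p2)
  t1 <- simulate_tumor_profile(cfg, 2)
  t2 <- simulate_tumor_profile(cfg, 2)
  expect_identical(t1, t2)
  # whole file set is byte-identical across runs
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # different seeds give different data
  p3 <- simulate_normal_panel(sim_config(seed = 10, n_patients = 3,
                                         n_blocks = 200, n_donors = 20))
  expect_false(identical(p1[, 1], p3[, 1]))
})

test_that("panel and tumor rates follow their beta distributions", {
  cfg <- sim_config(seed = 4, n_blocks = 2000, n_donors = 30)
  panel <- simulate_normal_panel(cfg)
  expect_equal(dim(panel), c(2000L, 30L))
  expect_true(all(panel >= 0 & panel <= 1))
  layout <- attr(panel, "layout")
  expect_equal(sum(layout$is_hyper), 100)  # 5% of 2000
  # hyper-block background mean ~ Beta(1,19) mean = 0.05
  expect_lt(abs(mean(panel[layout$is_hyper, ]) - 0.05), 0.01)
  # uninformative blocks sit near 0.5
  expect_equal(mean(panel[!layout$is_hyper, ]), 0.5, tolerance = 0.01)

  tumor <- simulate_tumor_profile(cfg, 1)
  expect_equal(mean(tumor$p_T[layout$is_hyper]), 0.9, tolerance = 0.05)
  purity <- attr(tumor, "tumor_purity")
  expect_true(purity >= 0.2 && purity <= 0.9)
})

test_that("plasma counts follow the spiked mixture", {
  cfg <- sim_config(seed = 6, n_blocks = 2000, n_donors = 30)
  panel <- simulate_normal_panel(cfg)
  tumor <- simulate_tumor_profile(cfg, 1)
  layout <- attr(panel, "layout")
  hy <- layout$is_hyper

  # alpha = 0: methylated fraction matches the panel background
  s0 <- simulate_plasma_sample(tumor, panel, 0, depth = 100, seed = 31)
  frac0 <- sum(s0$methylated_reads[hy]) / sum(s0$total_reads[hy])
  bg <- mean(panel[hy, ])
  se <- sqrt(bg * (1 - bg) / sum(s0$total_reads[hy]))
  expect_lt(abs(frac0 - bg), 4 * se + 0.002)

  # alpha = 1 on hyper blocks: pooled methylated fraction ~ 0.9
  s1 <- simulate_plasma_sample(tumor, panel, 1, depth = 100, seed = 32)
  frac1 <- sum(s1$methylated_reads[hy]) / sum(s1$total_reads[hy])
  expect_equal(frac1, mean(tumor$p_T[hy]), tolerance = 0.02)

  # depth is Poisson around the configured mean
  expect_equal(mean(s0$total_reads), 100, tolerance = 2)
  # output passes the cohort_io validator round trip
  tf <- tempfile(); write_block_table(s0, tf)
  expect_equal(nrow(read_block_table(tf)), 2000L)
})

test_that("the synthetic caller floor suppresses ultralow AFs", {
  cfg <- sim_config(seed = 12)
  catalog <- data.frame(gene = "EGFR", chrom = "chr7", pos = 1L,
                        ref = "T", alt = "G", tissue_af = 0.2,
                        stringsAsFactors = FALSE)
  # alpha = 0: no plasma signal, never called
  s <- simulate_mutations(cfg, catalog, purity = 0.5, true_alpha = 0,
                          sample_id = "S", seed = 1)
  expect_equal(nrow(s$calls), 0L)
  expect_equal(s$true_plasma_af, 0)

  # plasma AF 0.02 at 10,000x: called, observed near truth
  s2 <- simulate_mutations(cfg, catalog, purity = 0.5, true_alpha = 0.05,
                           sample_id = "S", seed = 2)
  expect_equal(s2$true_plasma_af, 0.02)
  expect_equal(nrow(s2$calls), 1L)
  se <- sqrt(0.02 * 0.98 / 10000)
  expect_lt(abs(s2$calls$af - 0.02), 3 * se)

  # plasma AF 1e-4 sits below the floor: emitted in <10% of replicates
  hits <- vapply(1:200, function(i) {
    nrow(simulate_mutations(cfg, catalog, purity = 0.5,
                            true_alpha = 2.5e-4, sample_id = "S",
                            seed = 1000 + i)$calls) > 0
  }, logical(1))
  expect_lt(mean(hits), 0.10)
})

test_that("cohort trajectories honour recurrence structure", {
  cfg <- sim_config(seed = 3, n_patients = 8, n_blocks = 300,
                    n_donors = 25, recurrence_fraction = 0.25)
  co <- simulate_cohort(cfg)
  expect_equal(sum(!is.na(co$clinical$recurrence_day)), 2L)
  gt <- co$ground_truth$alpha
  # non-recurring patients have alpha = 0 at every follow-up
  nonrec <- co$clinical$patient_id[is.na(co$clinical$recurrence_day)]
  post <- gt[gt$patient_id %in% nonrec & gt$timepoint_label != "baseline", ]
  expect_true(all(post$true_alpha == 0))
  # recurring patients ramp before their recurrence day
  for (pid in setdiff(co$clinical$patient_id, nonrec)) {
    rec <- co$clinical$recurrence_day[co$clinical$patient_id == pid]
    ramp <- gt[gt$patient_id == pid & gt$days_from_surgery > 0 &
                 gt$days_from_surgery <= rec, ]
    expect_true(any(ramp$true_alpha > 0), label = pid)
  }
  # recurrence_fraction = 0 shuts the ramp off entirely
  co0 <- simulate_cohort(sim_config(seed = 3, n_patients = 4,
                                    n_blocks = 100, n_donors = 20,
                                    recurrence_fraction = 0))
  gt0 <- co0$ground_truth$alpha
  expect_true(all(gt0$true_alpha[gt0$timepoint_label != "baseline"] == 0))
  # all emitted tables pass the io validators
  d <- tempfile(); write_cohort(co, d)
  m <- read_manifest(file.path(d, "manifest.tsv"),
                     file.path(d, "clinical.tsv"))
  expect_equal(sort(unique(m$samples$patient_id)),
               sort(co$clinical$patient_id))
  expect_gt(nrow(read_mutation_table(file.path(d, "mutations.tsv"))), 0)
})
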