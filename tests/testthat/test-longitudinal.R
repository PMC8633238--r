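tiny_cohort <- function() {
  samples <- data.frame(
    sample_id = c("P1_B", "P1_F1", "P1_F2", "P2_B", "P2_F1"),
    patient_id = c("P1", "P1", "P1", "P2", "P2"),
    material = "plasma",
    timepoint_label = c("baseline", "followup_1", "followup_2",
                        "baseline", "followup_1"),
    days_from_surgery = c(-7L, 100L, 200L, -5L, 90L),
    stringsAsFactors = FALSE)
  clinical <- data.frame(
    patient_id = c("P1", "P2"), histology = c("LUAD", "LUSC"),
    stage = c("IIIA", "IB"), tumor_purity = c(0.6, 0.5),
    recurrence_day = c(310L, NA), differentiation_grade = c(3L, 2L),
    stringsAsFactors = FALSE)
  list(samples = samples, clinical = clinical)
}

fake_call <- function(sid, wald, threshold = 1.96) {
  fit <- structure(list(alpha_hat = wald / 50, variance = 1e-4,
                        wald = wald, loglik = 0, n_blocks_used = 10L,
                        n_reads_used = 1000L, sample_id = sid,
                        blocks = NULL), class = "md_fit")
  call_mrd(sid, fit, threshold)
}

test_that("trajectories join assays and mark dropouts explicitly", {
  co <- tiny_cohort()
  mrd <- list(fake_call("P1_B", 5), fake_call("P1_F2", 2.5))
  mut <- list(summarize_plasma(make_calls("P1_B", "EGFR", 0.02)),
              summarize_plasma(make_calls("P2_B", "TP53", 0.01)))
  trs <- assemble_trajectories(co$samples, co$clinical, mrd, mut)
  expect_length(trs, 2)
  tp <- trs[[1]]$timepoints
  expect_equal(tp$timepoint_label,
               c("baseline", "followup_1", "followup_2"))
  # methylation assayed at 2 of 3 timepoints: one explicit dropout
  expect_equal(tp$mrd_assayed, c(TRUE, FALSE, TRUE))
  expect_true(is.na(tp$wald[2]))
  expect_equal(tp$mrd_positive, c(TRUE, NA, TRUE))
  expect_equal(tp$max_af, c(0.02, NA, NA))

  expect_length(assemble_trajectories(co$samples[0, ], co$clinical[0, ]),
                0)

  dup <- co$samples
  dup$timepoint_label[3] <- "followup_1"
  expect_error(assemble_trajectories(dup, co$clinical, list(), list()),
               "duplicate timepoint")
})

test_that("detection rates count only assayed patients", {
  co <- tiny_cohort()
  mrd <- list(fake_call("P1_B", 5), fake_call("P2_B", 1.0),
              fake_call("P1_F1", 0.2))
  mut <- list(summarize_plasma(make_calls("P1_B", "EGFR", 0.02)))
  trs <- assemble_trajectories(co$samples, co$clinical, mrd, mut)

  base_me <- detection_rate_table(trs, "methylation", "baseline")
  expect_equal(base_me$n_positive, 1L)
  expect_equal(base_me$n_assayed, 2L)
  expect_equal(base_me$rate, 50)
  # followup_1 methylation assayed only for P1
  f1 <- detection_rate_table(trs, "methylation", "followup_1")
  expect_equal(f1$n_assayed, 1L)
  expect_equal(f1$rate, 0)
  # nobody assayed for mutation at followup_2
  expect_error(detection_rate_table(trs, "mutation", "followup_2"),
               "no patient assayed")
  # rates are invariant to patient order
  f1_shuffled <- detection_rate_table(rev(trs), "methylation", "followup_1")
  expect_equal(f1_shuffled, f1)
})

test_that("fisher_exact_2x2 matches hand-derived and oracle values", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  # both extreme 5/5 splits: p = 2 / C(10,5)
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2)), 2 / 252,
               tolerance = 1e-9)
  # zero margin convention
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 7), 2)), 1)
  set.seed(14)
  for (i in 1:50) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    expect_equal(fisher_exact_2x2(tab), oracle_fisher_2x2(tab),
                 tolerance = 1e-9)
  }
  # the cohort-level wrapper reproduces the same p
  a <- data.frame(timepoint_label = "baseline", n_positive = 14,
                  n_assayed = 61)
  b <- data.frame(timepoint_label = "followup_1", n_positive = 7,
                  n_assayed = 31)
  cmp <- compare_detection_rates(a, b)
  expect_equal(cmp$p_value, oracle_fisher_2x2(cmp$table), tolerance = 1e-9)
  expect_equal(colSums(cmp$table), c(baseline = 61, followup_1 = 31))
})

test_that("wilcoxon_rank_sum agrees with rank enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 2 / 6,
               tolerance = 1e-12)
  # identical multisets are maximally null
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(21)
  for (i in 1:20) {
    x <- runif(4); y <- runif(4)
    expect_equal(wilcoxon_rank_sum(x, y), oracle_wilcoxon(x, y),
                 tolerance = 1e-12)
  }
})

test_that("maxAF/MD correlation is Spearman on detected pairs", {
  expect_equal(correlate_maxaf_md(1:6 / 100, (1:6)^2 / 50)$estimate, 1)
  expect_equal(correlate_maxaf_md(6:1 / 100, (1:6)^2 / 50)$estimate, -1)
  # hand-computed rho via the d^2 formula on 6 distinct pairs
  maf <- c(0.02, 0.001, 0.012, 0.3, 0.004, 0.05)
  md  <- c(0.010, 0.002, 0.009, 0.08, 0.001, 0.030)
  d <- rank(maf) - rank(md)
  rho_hand <- 1 - 6 * sum(d^2) / (6 * (36 - 1))
  expect_equal(correlate_maxaf_md(maf, md)$estimate, rho_hand)
  # undetected samples are excluded and counted
  res <- correlate_maxaf_md(c(maf, NA, NA), c(md, 0.01, 0.02))
  expect_equal(res$n_pairs, 6)
  expect_equal(res$n_excluded, 2)
  expect_error(correlate_maxaf_md(c(0.1, NA), c(0.2, 0.1)), "at least 3")
})

test_that("recurrence lead time uses the earliest postoperative positive", {
  co <- tiny_cohort()
  mrd <- list(fake_call("P1_B", 5), fake_call("P1_F1", 3),
              fake_call("P1_F2", 4))
  trs <- assemble_trajectories(co$samples, co$clinical, mrd, list())
  # earliest positive follow-up at day 100, recurrence day 310
  expect_equal(recurrence_lead_time(trs[[1]]), 6.9)

  # baseline positivity alone gives no postoperative signal
  mrd2 <- list(fake_call("P1_B", 5), fake_call("P1_F1", 0.5),
               fake_call("P1_F2", 1.0))
  trs2 <- assemble_trajectories(co$samples, co$clinical, mrd2, list())
  expect_true(is.na(recurrence_lead_time(trs2[[1]])))

  # positive exactly at recurrence day -> 0.0 months
  co3 <- tiny_cohort()
  co3$clinical$recurrence_day[1] <- 200L
  trs3 <- assemble_trajectories(co3$samples, co3$clinical,
                                list(fake_call("P1_F2", 3)), list())
  expect_equal(recurrence_lead_time(trs3[[1]]), 0.0)

  # no recurrence day / recurrence before surgery are errors
  expect_error(recurrence_lead_time(trs[[2]]), "no recurrence_day")
  co4 <- tiny_cohort()
  co4$clinical$recurrence_day[1] <- -10L
  trs4 <- assemble_trajectories(co4$samples, co4$clinical, mrd, list())
  expect_error(recurrence_lead_time(trs4[[1]]), "before surgery")
})
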