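# Seeded synthetic cohorts with the statistical structure the pipeline
# assumes: beta-distributed block methylation rates, Poisson/binomial
# read counts at the assay's depths, known spiked ctDNA fractions with
# recurrence ramps, and binomially sampled plasma mutation AFs behind a
# caller detection floor. Every table passes cohort_io validation, and
# the generating truth is emitted alongside so parameter-recovery and
# type-I experiments can score the pipeline against it.

#' Simulation configuration
#'
#' Defaults describe a desk-scale resected-NSCLC surveillance cohort:
#' a 2,000-block panel of which 5% are tumor-hypermethylated
#' (tumor rate ~ Beta(18,2), mean 0.9; healthy-plasma background ~
#' Beta(1,19), mean 0.05; uninformative blocks ~ Beta(5,5)), 30 healthy
#' donors, per-block plasma depth 100 (panel-wide sequencing at ~10,000x
#' spreads over many blocks; per-block coverage is what the likelihood
#' sees), tissue depth 1,000, baseline ctDNA fractions around 1%,
#' post-operative alpha 0 for non-recurring patients, and for recurring
#' patients a geometric ramp (start 0.002, doubling per follow-up)
#' beginning one to two follow-ups before the recurrence date. Plasma
#' mutations are re-observed at 10,000x behind a caller floor of AF >=
#' 0.05% and >= 3 alt reads.
#'
#' @param seed Integer master seed; every derived stream is a
#'   deterministic function of it.
#' @param n_patients Number of patients.
#' @param n_blocks Panel size in methylation blocks.
#' @param n_donors Healthy-donor panel size.
#' @param plasma_depth Mean per-block plasma read depth (Poisson).
#' @param tissue_depth Tissue read depth used to observe tumor rates.
#' @param tumor_hyper_fraction Fraction of blocks that are
#'   tumor-hypermethylated.
#' @param beta_tumor,beta_background,beta_uninformative Beta shape pairs
#'   for tumor-high, healthy-background (hyper blocks) and uninformative
#'   block rates.
#' @param baseline_alpha_meanlog,baseline_alpha_sdlog Log-normal
#'   parameters of the pre-surgery ctDNA fraction.
#' @param ramp_start,ramp_doubling Recurrence ramp: alpha at the first
#'   ramp follow-up and its per-follow-up multiplier.
#' @param recurrence_fraction Fraction of patients who recur.
#' @param followup_days Days from surgery of the follow-up draws.
#' @param purity_range Uniform range for tumor purity.
#' @param mutation_depth Plasma mutation sequencing depth.
#' @param n_mutations_range Range of tumor mutation counts per patient.
#' @param tissue_af_range Uniform range of clonal tissue AF before
#'   purity scaling.
#' @param caller_min_af,caller_min_alt Synthetic caller detection floor.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 12L,
                       n_blocks = 2000L,
                       n_donors = 30L,
                       plasma_depth = 100,
                       tissue_depth = 1000L,
                       tumor_hyper_fraction = 0.05,
                       beta_tumor = c(18, 2),
                       beta_background = c(1, 19),
                       beta_uninformative = c(5, 5),
                       baseline_alpha_meanlog = log(0.01),
                       baseline_alpha_sdlog = 0.5,
                       ramp_start = 0.002,
                       ramp_doubling = 2,
                       recurrence_fraction = 0.25,
                       followup_days = c(90L, 180L, 270L),
                       purity_range = c(0.2, 0.9),
                       mutation_depth = 10000L,
                       n_mutations_range = c(1L, 5L),
                       tissue_af_range = c(0.05, 0.4),
                       caller_min_af = 5e-4,
                       caller_min_alt = 3L) {
  cfg <- as.list(environment())
  stopifnot(cfg$seed == round(cfg$seed), cfg$n_patients >= 1,
            cfg$n_blocks >= 1, cfg$n_donors >= 1,
            cfg$tumor_hyper_fraction >= 0, cfg$tumor_hyper_fraction <= 1,
            cfg$recurrence_fraction >= 0, cfg$recurrence_fraction <= 1,
            cfg$ramp_start >= 0, cfg$ramp_start <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic sub-seed per named stream; keeps everything < 2^31.
sub_seed <- function(config, offset) {
  (abs(config$seed) * 131L + offset) %% 2147483647L
}

#' Panel block layout
#'
#' Deterministic block identities and BED coordinates for a
#' configuration; the first `round(n_blocks * tumor_hyper_fraction)`
#' blocks are the tumor-hypermethylated ones.
#'
#' @param config A [sim_config()].
#' @return Data frame `block_id`, `chrom`, `start`, `end`, `is_hyper`.
#' @export
block_layout <- function(config) {
  n <- config$n_blocks
  n_hyper <- round(n * config$tumor_hyper_fraction)
  data.frame(block_id = sprintf("MB%05d", seq_len(n)),
             chrom = paste0("chr", 1 + (seq_len(n) - 1) %% 22),
             start = as.integer((seq_len(n) - 1) * 1000L),
             end = as.integer((seq_len(n) - 1) * 1000L + 500L),
             is_hyper = seq_len(n) <= n_hyper,
             stringsAsFactors = FALSE)
}

#' Simulate a healthy-donor normal-plasma panel
#'
#' Per-block donor methylation rates: Beta(`beta_background`) on
#' tumor-hyper blocks (low background) and Beta(`beta_uninformative`) on
#' the rest.
#'
#' @param config A [sim_config()].
#' @return Matrix (blocks x donors) of rates with block-id rownames and
#'   a `layout` attribute ([block_layout()]).
#' @export
simulate_normal_panel <- function(config) {
  layout <- block_layout(config)
  set.seed(sub_seed(config, 1L))
  n <- config$n_blocks; d <- config$n_donors
  rates <- matrix(NA_real_, n, d,
                  dimnames = list(layout$block_id,
                                  sprintf("donor%02d", seq_len(d))))
  hy <- layout$is_hyper
  rates[hy, ]  <- stats::rbeta(sum(hy) * d, config$beta_background[1],
                               config$beta_background[2])
  rates[!hy, ] <- stats::rbeta(sum(!hy) * d, config$beta_uninformative[1],
                               config$beta_uninformative[2])
  attr(rates, "layout") <- layout
  rates
}

#' Simulate one patient's tumor methylation profile
#'
#' Tumor-hyper blocks draw underlying rates from Beta(`beta_tumor`); the
#' rest share the uninformative distribution. Observed `p_T` adds the
#' binomial sampling noise of tissue sequencing at `tissue_depth`.
#'
#' @param config A [sim_config()].
#' @param patient_index 1-based patient number (seeds the draw).
#' @param purity Tumor purity; drawn from `purity_range` when `NULL`.
#' @return Data frame `block_id`, `p_T` with attributes `patient_id`,
#'   `tumor_purity`, `true_p_T`.
#' @export
simulate_tumor_profile <- function(config, patient_index, purity = NULL) {
  layout <- block_layout(config)
  set.seed(sub_seed(config, 1000L + patient_index))
  if (is.null(purity)) {
    purity <- stats::runif(1, config$purity_range[1], config$purity_range[2])
  }
  true_p <- numeric(config$n_blocks)
  hy <- layout$is_hyper
  true_p[hy]  <- stats::rbeta(sum(hy), config$beta_tumor[1],
                              config$beta_tumor[2])
  true_p[!hy] <- stats::rbeta(sum(!hy), config$beta_uninformative[1],
                              config$beta_uninformative[2])
  obs <- stats::rbinom(config$n_blocks, config$tissue_depth, true_p) /
    config$tissue_depth
  out <- data.frame(block_id = layout$block_id, p_T = obs,
                    stringsAsFactors = FALSE)
  attr(out, "patient_id") <- sprintf("P%02d", patient_index)
  attr(out, "tumor_purity") <- purity
  attr(out, "true_p_T") <- true_p
  out
}

#' Simulate one plasma methylation sample
#'
#' Per block, total reads `n ~ Poisson(depth)` and methylated reads
#' `k ~ Binomial(n, theta)` with `theta = alpha * p_T + (1 - alpha) *
#' p_N`. The block's background rate `p_N` is the donor-panel mean —
#' the healthy-plasma consensus a tumor-free sample would express.
#'
#' @param tumor Tumor profile from [simulate_tumor_profile()].
#' @param panel Donor panel from [simulate_normal_panel()].
#' @param true_alpha Spiked ctDNA fraction in \[0,1\].
#' @param depth Mean per-block read depth.
#' @param seed Integer seed for this sample's draw.
#' @return A block count table (as [read_block_table()] returns) with a
#'   `true_alpha` attribute.
#' @export
simulate_plasma_sample <- function(tumor, panel, true_alpha,
                                   depth = 100, seed = 1L) {
  stopifnot(true_alpha >= 0, true_alpha <= 1)
  layout <- attr(panel, "layout")
  set.seed(seed)
  p_N <- clamp_rate(rowMeans(panel, na.rm = TRUE))
  p_T <- clamp_rate(tumor$p_T[match(rownames(panel), tumor$block_id)])
  theta <- mixture_rate(true_alpha, p_T, p_N)
  n <- stats::rpois(nrow(panel), depth)
  k <- stats::rbinom(nrow(panel), n, theta)
  out <- data.frame(chrom = layout$chrom, start = layout$start,
                    end = layout$end, block_id = layout$block_id,
                    methylated_reads = k, total_reads = n,
                    stringsAsFactors = FALSE)
  attr(out, "true_alpha") <- true_alpha
  out
}

#' Simulate plasma mutation calls for one sample
#'
#' Each tumor variant's expected plasma AF is `true_alpha * tissue_af /
#' purity` (tissue AF reflects purity dilution; dividing recovers the
#' clonal fraction), capped at 1. Observed alt reads are binomial at
#' `depth`; a call is emitted only past the caller floor (observed AF >=
#' `caller_min_af` and alt reads >= `caller_min_alt`).
#'
#' @param config A [sim_config()].
#' @param catalog Patient mutation catalog: data frame `gene`, `chrom`,
#'   `pos`, `ref`, `alt`, `tissue_af`.
#' @param purity Patient tumor purity.
#' @param true_alpha ctDNA fraction of the sample.
#' @param sample_id Sample label for the emitted calls.
#' @param seed Integer seed.
#' @return List with `calls` (a mutation table, possibly empty) and
#'   `true_plasma_af` (expected AF per catalog variant).
#' @export
simulate_mutations <- function(config, catalog, purity, true_alpha,
                               sample_id, seed = 1L) {
  set.seed(seed)
  plasma_af <- pmin(1, true_alpha * catalog$tissue_af / purity)
  alt <- stats::rbinom(nrow(catalog), config$mutation_depth, plasma_af)
  obs_af <- alt / config$mutation_depth
  keep <- obs_af >= config$caller_min_af & alt >= config$caller_min_alt
  calls <- data.frame(sample_id = rep(sample_id, sum(keep)),
                      gene = catalog$gene[keep],
                      chrom = catalog$chrom[keep],
                      pos = catalog$pos[keep],
                      ref = catalog$ref[keep],
                      alt = catalog$alt[keep],
                      af = obs_af[keep],
                      depth = rep(config$mutation_depth, sum(keep)),
                      chip_filtered = rep(TRUE, sum(keep)),
                      stringsAsFactors = FALSE)
  list(calls = calls, true_plasma_af = plasma_af)
}

PANEL_GENES <- data.frame(
  gene = c("EGFR", "KRAS", "TP53", "PIK3CA", "CTNNB1", "SOX2", "FGFR1",
           "BRAF", "MET", "STK11"),
  chrom = c("chr7", "chr12", "chr17", "chr3", "chr3", "chr3", "chr8",
            "chr7", "chr7", "chr19"),
  pos = c(55191822L, 25245350L, 7673802L, 179234297L, 41224610L,
          181711925L, 38428337L, 140753336L, 116771934L, 1207021L),
  stringsAsFactors = FALSE)

#' Simulate a full longitudinal cohort
#'
#' Orchestrates the per-stage simulators into a complete in-memory
#' cohort: donor panel, per-patient tumor profiles and mutation
#' catalogs, clinical records, a plasma manifest (baseline one week
#' before surgery plus the configured follow-ups), per-sample block
#' count tables and mutation calls, and the generating ground truth.
#' Recurring patients (the first `ceiling(n_patients *
#' recurrence_fraction)`) receive a recurrence day between the second
#' and third follow-up windows and an alpha ramp starting one to two
#' follow-ups before it; all other patients have alpha 0 after surgery.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort`: `samples`, `clinical`, `panel`,
#'   `tumor_profiles` (named list), `plasma_blocks` (named list by
#'   sample id), `mutations` (all calls, tissue and plasma),
#'   `ground_truth` (list `alpha`, `background`, `mutations`), `config`.
#' @export
simulate_cohort <- function(config) {
  panel <- simulate_normal_panel(config)
  p_N <- clamp_rate(rowMeans(panel, na.rm = TRUE))

  set.seed(sub_seed(config, 2L))
  np <- config$n_patients
  n_recur <- ceiling(np * config$recurrence_fraction)
  pids <- sprintf("P%02d", seq_len(np))
  histology <- sample(c("LUAD", "LUSC", "other"), np, replace = TRUE,
                      prob = c(0.75, 0.17, 0.08))
  stage <- sample(c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB"), np,
                  replace = TRUE, prob = c(.12, .06, .08, .22, .44, .08))
  grade <- sample(1:4, np, replace = TRUE)
  fu <- sort(config$followup_days)
  n_fu <- length(fu)
  recurrence_day <- rep(NA_integer_, np)
  if (n_recur > 0) {
    lo <- if (n_fu >= 2) fu[2] + 10L else fu[1] + 10L
    hi <- if (n_fu >= 3) fu[3] + 30L else lo + 120L
    recurrence_day[seq_len(n_recur)] <-
      as.integer(round(stats::runif(n_recur, lo, hi)))
  }
  baseline_alpha <- stats::rlnorm(np, config$baseline_alpha_meanlog,
                                  config$baseline_alpha_sdlog)
  baseline_alpha <- pmin(baseline_alpha, 0.5)
  n_mut <- sample(seq(config$n_mutations_range[1],
                      config$n_mutations_range[2]), np, replace = TRUE)
  ramp_lead <- sample(1:2, np, replace = TRUE)  # followups before recurrence

  tumor_profiles <- list(); catalogs <- list()
  samples <- list(); clinical <- list()
  plasma_blocks <- list(); mutations <- list()
  gt_alpha <- list(); gt_mut <- list()

  for (i in seq_len(np)) {
    pid <- pids[i]
    tumor <- simulate_tumor_profile(config, i)
    purity <- attr(tumor, "tumor_purity")
    tumor_profiles[[pid]] <- tumor

    set.seed(sub_seed(config, 3000L + i))
    gi <- sample(nrow(PANEL_GENES), n_mut[i])
    catalogs[[pid]] <- data.frame(
      gene = PANEL_GENES$gene[gi], chrom = PANEL_GENES$chrom[gi],
      pos = PANEL_GENES$pos[gi] + i,
      ref = sample(c("A", "C", "G", "T"), n_mut[i], replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n_mut[i], replace = TRUE),
      tissue_af = stats::runif(n_mut[i], config$tissue_af_range[1],
                               config$tissue_af_range[2]) * purity,
      stringsAsFactors = FALSE)

    clinical[[pid]] <- data.frame(
      patient_id = pid, histology = histology[i], stage = stage[i],
      tumor_purity = purity, recurrence_day = recurrence_day[i],
      differentiation_grade = grade[i], stringsAsFactors = FALSE)

    # tissue mutation calls (always detected, AF = tissue AF)
    tis_id <- paste0(pid, "_TIS")
    mutations[[tis_id]] <- data.frame(
      sample_id = tis_id, gene = catalogs[[pid]]$gene,
      chrom = catalogs[[pid]]$chrom, pos = catalogs[[pid]]$pos,
      ref = catalogs[[pid]]$ref, alt = catalogs[[pid]]$alt,
      af = catalogs[[pid]]$tissue_af, depth = config$tissue_depth,
      chip_filtered = TRUE, stringsAsFactors = FALSE)
    samples[[tis_id]] <- data.frame(
      sample_id = tis_id, patient_id = pid, material = "tumor_tissue",
      timepoint_label = "baseline", days_from_surgery = -7L,
      stringsAsFactors = FALSE)

    # alpha trajectory: baseline, then 0 or a pre-recurrence ramp
    tp_days <- c(-7L, as.integer(fu))
    tp_labels <- c("baseline", paste0("followup_", seq_len(n_fu)))
    alpha <- numeric(n_fu + 1)
    alpha[1] <- baseline_alpha[i]
    if (!is.na(recurrence_day[i])) {
      pre <- which(fu <= recurrence_day[i])
      ramp_from <- max(1L, if (length(pre)) max(pre) - ramp_lead[i] + 1L
                       else n_fu)
      for (j in seq_len(n_fu)) {
        if (j >= ramp_from) {
          alpha[j + 1] <- min(1, config$ramp_start *
                                config$ramp_doubling^(j - ramp_from))
        }
      }
    }

    for (j in seq_len(n_fu + 1)) {
      sid <- if (j == 1) paste0(pid, "_B") else paste0(pid, "_F", j - 1)
      samples[[sid]] <- data.frame(
        sample_id = sid, patient_id = pid, material = "plasma",
        timepoint_label = tp_labels[j], days_from_surgery = tp_days[j],
        stringsAsFactors = FALSE)
      plasma_blocks[[sid]] <- simulate_plasma_sample(
        tumor, panel, alpha[j], depth = config$plasma_depth,
        seed = sub_seed(config, 10000L + 100L * i + j))
      sim <- simulate_mutations(config, catalogs[[pid]], purity, alpha[j],
                                sid,
                                seed = sub_seed(config,
                                                50000L + 100L * i + j))
      if (nrow(sim$calls) > 0L) mutations[[sid]] <- sim$calls
      gt_alpha[[sid]] <- data.frame(
        sample_id = sid, patient_id = pid, timepoint_label = tp_labels[j],
        days_from_surgery = tp_days[j], true_alpha = alpha[j],
        stringsAsFactors = FALSE)
      gt_mut[[sid]] <- data.frame(
        sample_id = sid,
        key = paste(catalogs[[pid]]$chrom, catalogs[[pid]]$pos,
                    catalogs[[pid]]$ref, catalogs[[pid]]$alt, sep = ":"),
        true_plasma_af = sim$true_plasma_af, stringsAsFactors = FALSE)
    }
  }

  structure(list(
    samples = do.call(rbind, unname(samples)),
    clinical = do.call(rbind, unname(clinical)),
    panel = panel,
    tumor_profiles = tumor_profiles,
    catalogs = catalogs,
    plasma_blocks = plasma_blocks,
    mutations = do.call(rbind, c(unname(mutations),
                                 list(make.row.names = FALSE))),
    ground_truth = list(
      alpha = do.call(rbind, c(unname(gt_alpha),
                               list(make.row.names = FALSE))),
      background = data.frame(block_id = rownames(panel), p_N = p_N,
                              stringsAsFactors = FALSE),
      mutations = do.call(rbind, c(unname(gt_mut),
                                   list(make.row.names = FALSE)))),
    config = config), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic MRD cohort:", x$config$n_patients, "patients,",
      x$config$n_blocks, "blocks,", x$config$n_donors, "donors;",
      sum(!is.na(x$clinical$recurrence_day)), "recurring\n")
  invisible(x)
}

#' Write a simulated cohort as the pipeline's flat files
#'
#' Emits `manifest.tsv`, `clinical.tsv`, `panel.tsv` (block_id + one
#' column per donor), `tumor_<patient>.tsv`, `blocks_<sample>.tsv`,
#' `mutations.tsv` and `ground_truth_alpha.tsv` under `dir`. With a
#' fixed config seed the file set is byte-identical across runs.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(list(samples = cohort$samples, clinical = cohort$clinical),
                 file.path(dir, "manifest.tsv"),
                 file.path(dir, "clinical.tsv"))
  panel_df <- data.frame(block_id = rownames(cohort$panel),
                         cohort$panel, stringsAsFactors = FALSE,
                         check.names = FALSE)
  write_tsv(panel_df, file.path(dir, "panel.tsv"))
  for (pid in names(cohort$tumor_profiles)) {
    write_tsv(cohort$tumor_profiles[[pid]],
              file.path(dir, paste0("tumor_", pid, ".tsv")))
  }
  for (sid in names(cohort$plasma_blocks)) {
    write_block_table(cohort$plasma_blocks[[sid]],
                      file.path(dir, paste0("blocks_", sid, ".tsv")))
  }
  write_mutation_table(cohort$mutations, file.path(dir, "mutations.tsv"))
  write_tsv(cohort$ground_truth$alpha,
            file.path(dir, "ground_truth_alpha.tsv"))
  invisible(dir)
}
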