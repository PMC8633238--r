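# Cohort-level assembly and statistics: per-patient trajectories,
# per-timepoint detection-rate tables, exact 2x2 comparisons, rank
# correlation of maxAF vs MD ratio, and recurrence lead times.

#' Assemble per-patient longitudinal trajectories
#'
#' Joins the plasma sample manifest with per-sample MRD calls and
#' mutation profiles into one ordered trajectory per patient. Samples
#' with no result for an assay carry explicit `NA` markers (cfDNA
#' dropouts: some samples are sequenced for mutations only), so
#' downstream per-timepoint denominators count only assayed patients.
#'
#' @param samples,clinical Data frames as returned by [read_manifest()].
#' @param mrd_calls List of `mrd_call` objects (or `NULL`), keyed by
#'   their `sample_id`.
#' @param mutation_profiles List of `plasma_profile` objects keyed by
#'   `sample_id`.
#' @return A list of `patient_trajectory` objects. Each has
#'   `patient_id`, `clinical` (one-row data frame) and `timepoints`, a
#'   data frame ordered by `days_from_surgery` with columns `sample_id`,
#'   `timepoint_label`, `days_from_surgery`, `mrd_assayed`, `wald`,
#'   `mrd_positive`, `mut_assayed`, `mut_detected`, `max_af`.
#' @export
assemble_trajectories <- function(samples, clinical, mrd_calls = list(),
                                  mutation_profiles = list()) {
  pl <- samples[samples$material == "plasma", , drop = FALSE]
  mrd_ids <- vapply(mrd_calls, function(x) x$sample_id, character(1))
  mut_ids <- vapply(mutation_profiles, function(x) x$sample_id, character(1))
  lapply(unique(pl$patient_id), function(pid) {
    rows <- pl[pl$patient_id == pid, , drop = FALSE]
    if (anyDuplicated(rows$timepoint_label)) {
      stop("duplicate timepoint label for patient ", pid, call. = FALSE)
    }
    rows <- rows[order(rows$days_from_surgery), , drop = FALSE]
    if (rows$timepoint_label[1L] != "baseline" &&
        "baseline" %in% rows$timepoint_label) {
      stop("baseline of patient ", pid, " is not the earliest sample",
           call. = FALSE)
    }
    im <- match(rows$sample_id, mrd_ids)
    iv <- match(rows$sample_id, mut_ids)
    tp <- data.frame(
      sample_id = rows$sample_id,
      timepoint_label = rows$timepoint_label,
      days_from_surgery = rows$days_from_surgery,
      mrd_assayed = !is.na(im),
      wald = vapply(im, function(i)
        if (is.na(i)) NA_real_ else mrd_calls[[i]]$estimate$wald, numeric(1)),
      mrd_positive = vapply(im, function(i)
        if (is.na(i)) NA else mrd_calls[[i]]$positive, logical(1)),
      alpha_hat = vapply(im, function(i)
        if (is.na(i)) NA_real_ else mrd_calls[[i]]$estimate$alpha_hat,
        numeric(1)),
      mut_assayed = !is.na(iv),
      mut_detected = vapply(iv, function(i)
        if (is.na(i)) NA else mutation_profiles[[i]]$detected, logical(1)),
      max_af = vapply(iv, function(i)
        if (is.na(i)) NA_real_ else mutation_profiles[[i]]$max_af,
        numeric(1)),
      stringsAsFactors = FALSE)
    structure(list(patient_id = pid,
                   clinical = clinical[clinical$patient_id == pid, ,
                                       drop = FALSE],
                   timepoints = tp),
              class = "patient_trajectory")
  })
}

#' @export
print.patient_trajectory <- function(x, ...) {
  cat("Trajectory of patient", x$patient_id, "-",
      nrow(x$timepoints), "plasma timepoint(s)\n")
  print(x$timepoints[, c("timepoint_label", "days_from_surgery",
                         "wald", "mrd_positive", "max_af")], ...)
  invisible(x)
}

#' Per-timepoint detection-rate summary
#'
#' Counts, among patients assayed at `timepoint`, how many are positive:
#' mutation positivity is plasma detection; methylation positivity is a
#' Wald score above the MRD threshold. Patients not assayed at that
#' timepoint are excluded from the denominator, which is why cohort
#' denominators vary across timepoints.
#'
#' @param trajectories List from [assemble_trajectories()].
#' @param assay `"mutation"` or `"methylation"`.
#' @param timepoint Timepoint label, e.g. `"baseline"`, `"followup_1"`.
#' @return One-row data frame: `timepoint_label`, `assay`, `n_positive`,
#'   `n_assayed`, `rate` (percent).
#' @export
detection_rate_table <- function(trajectories,
                                 assay = c("mutation", "methylation"),
                                 timepoint) {
  assay <- match.arg(assay)
  pos <- vapply(trajectories, function(tr) {
    row <- tr$timepoints[tr$timepoints$timepoint_label == timepoint, ,
                         drop = FALSE]
    if (nrow(row) == 0L) return(NA)
    if (assay == "mutation") {
      if (!row$mut_assayed) NA else row$mut_detected
    } else {
      if (!row$mrd_assayed) NA else row$mrd_positive
    }
  }, logical(1))
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0L) {
    stop("no patient assayed for ", assay, " at ", timepoint, call. = FALSE)
  }
  data.frame(timepoint_label = timepoint, assay = assay,
             n_positive = sum(pos), n_assayed = length(pos),
             rate = 100 * sum(pos) / length(pos),
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact p-value summing, over all tables with the observed margins,
#' the hypergeometric probabilities not exceeding the observed table's
#' (with a 1e-7 relative tolerance for ties). A table with a zero margin
#' carries no information and returns `p = 1` by convention.
#'
#' @param table 2x2 matrix of non-negative integer counts, e.g.
#'   (positive, negative) x (timepoint A, timepoint B).
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Compare detection rates between two timepoints
#'
#' Builds the 2x2 (positive, negative) x (A, B) table from two
#' [detection_rate_table()] rows and applies [fisher_exact_2x2()].
#'
#' @param summary_a,summary_b One-row summaries for the two timepoints.
#' @return List with `table`, `p_value`, `test_name`.
#' @export
compare_detection_rates <- function(summary_a, summary_b) {
  tab <- matrix(c(summary_a$n_positive,
                  summary_a$n_assayed - summary_a$n_positive,
                  summary_b$n_positive,
                  summary_b$n_assayed - summary_b$n_positive),
                nrow = 2,
                dimnames = list(c("positive", "negative"),
                                c(summary_a$timepoint_label,
                                  summary_b$timepoint_label)))
  list(table = tab, p_value = fisher_exact_2x2(tab),
       test_name = "fisher_exact")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration p-value when the smaller group has at most 10
#' observations and there are no ties; otherwise the normal
#' approximation with tie correction (and continuity correction).
#'
#' @param x,y Non-empty numeric vectors (e.g. baseline maxAF by
#'   histology group).
#' @return The two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && min(length(x), length(y)) <= 10L
  suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value
  )
}

#' Spearman correlation of maxAF and MD ratio across samples
#'
#' Rank correlation between the plasma maxAF and the fitted MD ratio of
#' samples with both assays informative; samples without a detected
#' mutation (maxAF absent) are excluded and counted, since they carry no
#' AF rank.
#'
#' @param max_af Numeric vector of per-sample maxAF (NA = undetected).
#' @param alpha_hat Numeric vector of the same samples' MD ratios.
#' @return List with `estimate` (rho), `p_value`, `n_pairs`,
#'   `n_excluded`, `method`.
#' @export
correlate_maxaf_md <- function(max_af, alpha_hat) {
  stopifnot(length(max_af) == length(alpha_hat))
  ok <- !is.na(max_af) & !is.na(alpha_hat)
  if (sum(ok) < 3L) {
    stop("need at least 3 samples with both maxAF and an MD ratio",
         call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(max_af[ok], alpha_hat[ok], method = "spearman"))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n_pairs = sum(ok), n_excluded = sum(!ok), method = "spearman")
}

DAYS_PER_MONTH <- 30.4375  # calendar-average month

#' Lead time of methylation MRD over radiologic recurrence
#'
#' Months between the earliest postoperative MRD-positive methylation
#' call and the radiologic recurrence date, reported to 0.1 month
#' (days / 30.4375). `NA` when no positive postoperative call occurs at
#' or before recurrence.
#'
#' @param trajectory A `patient_trajectory` whose clinical record has a
#'   `recurrence_day`.
#' @param threshold Unused unless calls were made at a non-default
#'   threshold; kept for symmetry.
#' @return Lead time in months (>= 0), or `NA_real_`.
#' @export
recurrence_lead_time <- function(trajectory, threshold = 1.96) {
  rec <- trajectory$clinical$recurrence_day
  if (length(rec) != 1L || is.na(rec)) {
    stop("patient ", trajectory$patient_id, " has no recurrence_day",
         call. = FALSE)
  }
  if (rec <= 0) stop("recurrence before surgery for patient ",
                     trajectory$patient_id, call. = FALSE)
  tp <- trajectory$timepoints
  hits <- tp$days_from_surgery[tp$days_from_surgery > 0 &
                                 !is.na(tp$mrd_positive) &
                                 tp$mrd_positive &
                                 tp$days_from_surgery <= rec]
  if (length(hits) == 0L) return(NA_real_)
  round((rec - min(hits)) / DAYS_PER_MONTH, 1)
}
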