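# End-to-end convenience: run block selection, MD-ratio fitting and
# mutation summaries over a whole cohort and assemble trajectories.

#' Score every plasma sample of a cohort
#'
#' For each patient passing the tumor-content gate, selects methylation
#' blocks against the donor panel, fits the MD ratio of every plasma
#' sample, calls MRD positivity, summarises plasma mutations, and
#' assembles per-patient trajectories. Works on a [simulate_cohort()]
#' object or any list with the same shape (`samples`, `clinical`,
#' `panel`, `tumor_profiles`, `plasma_blocks`, `mutations`).
#'
#' @param cohort A `sim_cohort`-shaped list.
#' @param alpha_level,min_delta,direction Passed to
#'   [select_methylation_blocks()].
#' @param threshold Wald positivity cutoff for [call_mrd()].
#' @param purity_threshold Tumor-content gate for
#'   [check_tumor_content()].
#' @return List with `trajectories`, `mrd_calls`, `mutation_profiles`,
#'   `mb_sets` (per eligible patient), `excluded_patients`.
#' @export
score_cohort <- function(cohort, alpha_level = 0.05, min_delta = 0.1,
                         direction = "hyper", threshold = 1.96,
                         purity_threshold = 0.30) {
  clinical <- cohort$clinical
  mb_sets <- list(); mrd_calls <- list(); profiles <- list()
  excluded <- character(0)

  for (pid in clinical$patient_id) {
    clin <- clinical[clinical$patient_id == pid, , drop = FALSE]
    eligible <- check_tumor_content(clin, purity_threshold)
    if (eligible) {
      mb_sets[[pid]] <- select_methylation_blocks(
        cohort$tumor_profiles[[pid]], cohort$panel,
        alpha_level = alpha_level, min_delta = min_delta,
        direction = direction)
    } else {
      excluded <- c(excluded, pid)
    }
  }

  pl <- cohort$samples[cohort$samples$material == "plasma", , drop = FALSE]
  for (r in seq_len(nrow(pl))) {
    sid <- pl$sample_id[r]; pid <- pl$patient_id[r]
    blocks <- cohort$plasma_blocks[[sid]]
    if (!is.null(blocks) && !is.null(mb_sets[[pid]]) &&
        nrow(mb_sets[[pid]]) > 0L) {
      mix <- make_mixture_blocks(blocks, mb_sets[[pid]])
      fit <- fit_md_ratio(mix, sample_id = sid)
      mrd_calls[[sid]] <- call_mrd(sid, fit, threshold = threshold)
    }
    calls <- cohort$mutations[cohort$mutations$sample_id == sid, ,
                              drop = FALSE]
    profiles[[sid]] <- summarize_plasma(calls, sample_id = sid)
  }

  trajectories <- assemble_trajectories(cohort$samples, clinical,
                                        mrd_calls, profiles)
  list(trajectories = trajectories, mrd_calls = mrd_calls,
       mutation_profiles = profiles, mb_sets = mb_sets,
       excluded_patients = excluded)
}
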