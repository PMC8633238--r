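# Plasma somatic-mutation summaries: per-sample maxAF and detection
# status, tissue-plasma concordance classes, and ctDNA clearance.

# Variant identity for cross-material matching: coordinates + alleles
# when present, otherwise (gene, variant label) for coordinate-less
# events such as rearrangements.
variant_key <- function(calls) {
  has_coord <- !is.na(calls$pos) & nzchar(calls$ref) & !is.na(calls$ref)
  ifelse(has_coord,
         paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":"),
         paste(calls$gene, calls$alt, sep = ":"))
}

#' Summarise the plasma mutation profile of one sample
#'
#' Computes the detection flag and maxAF — the highest mutant allelic
#' fraction among the sample's calls. An undetected sample (no calls)
#' has `max_af = NA`, deliberately distinct from 0: non-detection and a
#' zero-AF call are different observations. All calls must already be
#' clonal-hematopoiesis filtered (`chip_filtered = TRUE`) unless
#' `allow_unfiltered = TRUE`.
#'
#' @param calls Mutation calls for a single sample (possibly zero rows),
#'   as from [read_mutation_table()].
#' @param sample_id Sample label; required when `calls` is empty,
#'   otherwise taken (and checked for uniqueness) from the calls.
#' @param allow_unfiltered Accept calls with `chip_filtered = FALSE`.
#' @return A list of class `plasma_profile`: `sample_id`, `detected`,
#'   `max_af` (`NA_real_` when undetected), `n_calls`, `calls`.
#' @export
summarize_plasma <- function(calls, sample_id = NULL,
                             allow_unfiltered = FALSE) {
  if (nrow(calls) > 0L) {
    ids <- unique(calls$sample_id)
    if (length(ids) != 1L) {
      stop("calls from multiple samples passed to summarize_plasma: ",
           paste(ids, collapse = ", "), call. = FALSE)
    }
    if (!is.null(sample_id) && !identical(sample_id, ids)) {
      stop("sample_id does not match the calls", call. = FALSE)
    }
    sample_id <- ids
    if (!allow_unfiltered && !all(calls$chip_filtered)) {
      stop("calls for ", sample_id, " are not clonal-hematopoiesis ",
           "filtered; run upstream filtering or set allow_unfiltered",
           call. = FALSE)
    }
  } else if (is.null(sample_id)) {
    stop("sample_id required for an empty call set", call. = FALSE)
  }
  detected <- nrow(calls) > 0L
  structure(list(sample_id = sample_id, detected = detected,
                 max_af = if (detected) max(calls$af) else NA_real_,
                 n_calls = nrow(calls), calls = calls),
            class = "plasma_profile")
}

#' @export
print.plasma_profile <- function(x, ...) {
  cat("Plasma mutation profile", x$sample_id, "-",
      if (x$detected) paste0(x$n_calls, " call(s), maxAF ",
                             format(x$max_af, digits = 3))
      else "no mutation detected", "\n")
  invisible(x)
}

#' Classify tissue-plasma variant concordance at baseline
#'
#' Every variant in the union of the baseline tissue and plasma call sets
#' receives exactly one class: `Match` (both materials), `Tis_only`
#' (tissue only) or `Pla_only` (plasma only). The patient-level
#' `concordant` flag is `TRUE` when plasma shares at least one tissue
#' variant — the per-patient basis of a cohort concordance rate.
#'
#' @param tissue_calls,plasma_calls Call tables for the same patient's
#'   baseline tissue and plasma samples.
#' @return List with `records` (data frame `key`, `gene`, `class`) and
#'   logical `concordant`.
#' @export
classify_concordance <- function(tissue_calls, plasma_calls) {
  tk <- unique(variant_key(tissue_calls))
  pk <- unique(variant_key(plasma_calls))
  all_keys <- union(tk, pk)
  cls <- ifelse(all_keys %in% tk & all_keys %in% pk, "Match",
                ifelse(all_keys %in% tk, "Tis_only", "Pla_only"))
  gene_of <- c(stats::setNames(tissue_calls$gene, variant_key(tissue_calls)),
               stats::setNames(plasma_calls$gene, variant_key(plasma_calls)))
  records <- data.frame(key = all_keys,
                        gene = unname(gene_of[all_keys]),
                        class = cls, stringsAsFactors = FALSE)
  list(records = records, concordant = any(cls == "Match"))
}

#' ctDNA clearance between baseline and a follow-up
#'
#' Clearance means the panel detects no mutation at follow-up in a
#' patient who was mutation-positive at baseline. Patients with no
#' baseline detection cannot clear and return `"not_applicable"`.
#'
#' @param baseline_profile,followup_profile `plasma_profile` objects for
#'   the same patient, follow-up later than baseline.
#' @return One of `"cleared"`, `"not_cleared"`, `"not_applicable"`.
#' @export
ctdna_clearance <- function(baseline_profile, followup_profile) {
  stopifnot(inherits(baseline_profile, "plasma_profile"),
            inherits(followup_profile, "plasma_profile"))
  if (!baseline_profile$detected) return("not_applicable")
  if (followup_profile$detected) "not_cleared" else "cleared"
}
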