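# Patient-specific selection of cancer methylation blocks: the resected
# tumor's per-block methylation rate is compared against a panel of
# healthy-donor plasma rates; blocks where the tumor is an outlier of the
# donor distribution (empirical rank p < 0.05) and the effect size is
# non-trivial become the patient's tumor-informed block set.

RATE_EPS <- 1e-6

clamp_rate <- function(p, eps = RATE_EPS) pmin(pmax(p, eps), 1 - eps)

#' Tumor-content eligibility gate
#'
#' Patients whose resected tissue has tumor content (purity) below 30%
#' are excluded from methylation MRD scoring: the tissue methylation
#' profile of a low-purity sample is dominated by normal cells and does
#' not define a usable tumor signature. The boundary is inclusive —
#' exactly 30% is eligible.
#'
#' @param clinical One clinical record (a one-row data frame or list with
#'   `patient_id` and `tumor_purity`).
#' @param threshold Minimum tumor purity, default 0.30.
#' @return `TRUE` if the patient is eligible for MRD scoring.
#' @export
check_tumor_content <- function(clinical, threshold = 0.30) {
  purity <- clinical$tumor_purity
  if (is.null(purity) || length(purity) != 1L || is.na(purity)) {
    stop("tumor_purity is missing for patient ",
         clinical$patient_id %||% "<unknown>",
         "; add it to the clinical table", call. = FALSE)
  }
  purity >= threshold
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-sided empirical rank p-value of a tumor rate against donor rates
#'
#' With a single tumor observation per patient no two-sample test applies;
#' instead the tumor rate is ranked within the healthy-donor panel. The
#' p-value is `(1 + m) / (N + 1)` where `m` counts donors at least as
#' extreme as the tumor in the tested direction (ties count as extreme),
#' so the smallest attainable p with N donors is `1/(N+1)`.
#'
#' @param tumor_rate Tumor methylation rate (beta value) in \[0,1\].
#' @param donor_rates Numeric vector of donor rates for the same block.
#' @param direction `"hyper"` (tumor more methylated than donors) or
#'   `"hypo"`.
#' @return The empirical p-value in (0, 1\].
#' @export
empirical_block_pvalue <- function(tumor_rate, donor_rates,
                                   direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  stopifnot(length(tumor_rate) == 1L, tumor_rate >= 0, tumor_rate <= 1,
            length(donor_rates) >= 1L,
            all(donor_rates >= 0 & donor_rates <= 1))
  m <- if (direction == "hyper") sum(donor_rates >= tumor_rate)
       else                      sum(donor_rates <= tumor_rate)
  (1 + m) / (length(donor_rates) + 1)
}

#' Select a patient's cancer methylation blocks
#'
#' For every block shared between the tumor profile and the donor panel,
#' computes the empirical rank p-value ([empirical_block_pvalue()]) and
#' the panel background rate `p_N` (donor mean, clamped away from 0/1).
#' A block is selected when `p < alpha_level` (strict) and the tumor rate
#' differs from the background by at least `min_delta` in the requested
#' direction. The result feeds [fit_md_ratio()] via [make_mixture_blocks()].
#'
#' @param tumor A tumor profile: data frame with columns `block_id` and
#'   `p_T` (tissue methylation rate); may carry attributes `patient_id`
#'   and `tumor_purity` (as produced by [simulate_tumor_profile()]).
#' @param panel Donor panel: numeric matrix of rates, blocks in rows
#'   (rownames are block ids), donors in columns. `NA` entries (missing
#'   donor/block measurements) are ignored per block.
#' @param alpha_level Significance cutoff, default 0.05 (strict `<`).
#' @param min_delta Minimum absolute tumor-background rate difference,
#'   default 0.1.
#' @param direction `"hyper"` (default) or `"hypo"`.
#' @return A data frame of class `mb_set` with columns `block_id`, `p_T`,
#'   `p_N`, `direction`, `p_value`, restricted to selected blocks.
#' @export
select_methylation_blocks <- function(tumor, panel, alpha_level = 0.05,
                                      min_delta = 0.1,
                                      direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(panel), !is.null(rownames(panel)),
            all(c("block_id", "p_T") %in% names(tumor)))
  shared <- intersect(tumor$block_id, rownames(panel))
  if (length(shared) == 0L) {
    stop("tumor profile and donor panel share no block_ids", call. = FALSE)
  }
  p_T <- tumor$p_T[match(shared, tumor$block_id)]
  sub <- panel[shared, , drop = FALSE]
  p_N <- clamp_rate(rowMeans(sub, na.rm = TRUE))
  pval <- vapply(seq_along(shared), function(i) {
    donors <- sub[i, ]
    empirical_block_pvalue(p_T[i], donors[!is.na(donors)], direction)
  }, numeric(1))
  delta <- if (direction == "hyper") p_T - p_N else p_N - p_T
  keep <- pval < alpha_level & delta >= min_delta
  out <- data.frame(block_id = shared[keep],
                    p_T = p_T[keep], p_N = p_N[keep],
                    direction = rep(direction, sum(keep)),
                    p_value = pval[keep],
                    stringsAsFactors = FALSE)
  attr(out, "patient_id") <- attr(tumor, "patient_id", exact = TRUE)
  attr(out, "alpha_level") <- alpha_level
  attr(out, "min_delta") <- min_delta
  class(out) <- c("mb_set", "data.frame")
  out
}

#' Join plasma block counts onto a selected block set
#'
#' Produces the mixture-model input for [fit_md_ratio()]: one row per
#' selected block present in the plasma table, with plasma counts `k`,
#' `n` and the tumor/background rates `p_T`, `p_N`.
#'
#' @param plasma_blocks Plasma count table as from [read_block_table()].
#' @param mb_set Selected blocks from [select_methylation_blocks()].
#' @return Data frame with columns `block_id`, `k`, `n`, `p_T`, `p_N`.
#' @export
make_mixture_blocks <- function(plasma_blocks, mb_set) {
  idx <- match(mb_set$block_id, plasma_blocks$block_id)
  found <- !is.na(idx)
  if (!any(found)) {
    stop("none of the selected blocks are present in the plasma table",
         call. = FALSE)
  }
  data.frame(block_id = mb_set$block_id[found],
             k = plasma_blocks$methylated_reads[idx[found]],
             n = plasma_blocks$total_reads[idx[found]],
             p_T = mb_set$p_T[found], p_N = mb_set$p_N[found],
             stringsAsFactors = FALSE)
}
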