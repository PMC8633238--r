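# Small programmatic fixtures shared across test files.

write_lines_tsv <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

block_table_file <- function(rows) {
  write_lines_tsv(c(
    "chrom\tstart\tend\tblock_id\tmethylated_reads\ttotal_reads", rows))
}

mutation_table_file <- function(rows) {
  write_lines_tsv(c(
    "sample_id\tgene\tchrom\tpos\tref\talt\taf\tdepth\tchip_filtered",
    rows))
}

manifest_files <- function(sample_rows, clinical_rows) {
  list(
    manifest = write_lines_tsv(c(
      "sample_id\tpatient_id\tmaterial\ttimepoint_label\tdays_from_surgery",
      sample_rows)),
    clinical = write_lines_tsv(c(
      paste("patient_id\thistology\tstage\ttumor_purity",
            "recurrence_day\tdifferentiation_grade", sep = "\t"),
      clinical_rows)))
}

# Mutation-call data frame constructor (chip-filtered by default).
make_calls <- function(sample_id, gene, af,
                       chrom = "chr1", pos = seq_along(gene),
                       ref = "A", alt = "T", depth = 10000L,
                       chip_filtered = TRUE) {
  k <- length(gene)
  data.frame(sample_id = rep_len(sample_id, k), gene = gene,
             chrom = rep_len(chrom, k), pos = rep_len(pos, k),
             ref = rep_len(ref, k), alt = rep_len(alt, k), af = af,
             depth = rep_len(depth, k),
             chip_filtered = rep_len(chip_filtered, k),
             stringsAsFactors = FALSE)
}

# A tiny synthetic trajectory whose per-timepoint positives/assayed are
# given directly: pos/assayed per label, one patient per assayed slot.
# Used to verify detection-rate arithmetic on known count fractions.
counts_trajectories <- function(counts, assay) {
  # counts: named list label -> c(pos, n)
  n_pat <- max(vapply(counts, `[`, numeric(1), 2))
  lapply(seq_len(n_pat), function(i) {
    tps <- lapply(names(counts), function(lab) {
      pos <- counts[[lab]][1]; n <- counts[[lab]][2]
      assayed <- i <= n
      positive <- i <= pos
      data.frame(
        sample_id = sprintf("P%03d_%s", i, lab),
        timepoint_label = lab,
        days_from_surgery = if (lab == "baseline") -7L
                            else 90L * match(lab, names(counts)),
        mrd_assayed = assay == "methylation" && assayed,
        wald = NA_real_,
        mrd_positive = if (assay == "methylation" && assayed) positive
                       else NA,
        alpha_hat = NA_real_,
        mut_assayed = assay == "mutation" && assayed,
        mut_detected = if (assay == "mutation" && assayed) positive
                       else NA,
        max_af = NA_real_, stringsAsFactors = FALSE)
    })
    structure(list(patient_id = sprintf("P%03d", i),
                   clinical = data.frame(patient_id = sprintf("P%03d", i)),
                   timepoints = do.call(rbind, tps)),
              class = "patient_trajectory")
  })
}
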