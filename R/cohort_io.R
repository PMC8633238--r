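# Table readers/writers for every flat file the pipeline touches.
# All tables are tab-separated UTF-8 with a header line; lines starting
# with '#' are comments. Block coordinates are BED-style 0-based
# half-open; point mutations are 1-based (VCF-style).

BLOCK_COLS    <- c("chrom", "start", "end", "block_id",
                   "methylated_reads", "total_reads")
MANIFEST_COLS <- c("sample_id", "patient_id", "material",
                   "timepoint_label", "days_from_surgery")
CLINICAL_COLS <- c("patient_id", "histology", "stage", "tumor_purity",
                   "recurrence_day", "differentiation_grade")
MUTATION_COLS <- c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                   "af", "depth", "chip_filtered")

MATERIALS  <- c("tumor_tissue", "plasma", "lymphocyte")

# "baseline" -> 0, "followup_k" -> k; unknown labels sort last.
timepoint_rank <- function(labels) {
  r <- rep(Inf, length(labels))
  r[labels == "baseline"] <- 0
  fu <- grepl("^followup_[0-9]+$", labels)
  r[fu] <- as.integer(sub("^followup_", "", labels[fu]))
  r
}

read_tsv_checked <- function(path, required_cols, what) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    stop(what, " table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df[required_cols]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a methylation-block count table
#'
#' Reads a BED-like TSV of per-block bisulfite read counts for one sample:
#' columns `chrom`, `start`, `end` (0-based half-open), `block_id`,
#' `methylated_reads` (k) and `total_reads` (n).
#'
#' @param path Path to a tab-separated file with the header above.
#' @return A data frame with one validated row per block, in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tstart\tend\tblock_id\tmethylated_reads\ttotal_reads",
#'              "chr1\t100\t200\tMB1\t5\t10"), tf)
#' read_block_table(tf)
#' @export
read_block_table <- function(path) {
  df <- read_tsv_checked(path, BLOCK_COLS, "block")
  if (nrow(df) == 0L) return(df)
  for (col in c("start", "end", "methylated_reads", "total_reads")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) | v != as.numeric(df[[col]]))
    if (length(bad) > 0L) {
      stop("block table ", path, ": non-integer ", col, " at data line ",
           bad[1L], call. = FALSE)
    }
    df[[col]] <- v
  }
  bad <- which(!nzchar(df$chrom) | is.na(df$chrom))
  if (length(bad)) stop("block table ", path, ": empty chrom at data line ",
                        bad[1L], call. = FALSE)
  bad <- which(df$start >= df$end)
  if (length(bad)) stop("block table ", path, ": start >= end at data line ",
                        bad[1L], call. = FALSE)
  bad <- which(df$methylated_reads < 0L | df$total_reads < 0L |
                 df$methylated_reads > df$total_reads)
  if (length(bad)) {
    stop("block table ", path,
         ": methylated_reads outside [0, total_reads] at data line ",
         bad[1L], call. = FALSE)
  }
  df
}

#' Write a methylation-block count table
#'
#' Inverse of [read_block_table()]; coordinates are written exactly as
#' stored (0-based half-open), so a read/write round trip is lossless.
#'
#' @param blocks Data frame as returned by [read_block_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_block_table <- function(blocks, path) {
  stopifnot(all(BLOCK_COLS %in% names(blocks)))
  write_tsv(blocks[BLOCK_COLS], path)
}

#' Read the sample manifest and clinical table
#'
#' The manifest lists every sequenced sample (`sample_id`, `patient_id`,
#' `material` in tumor_tissue/plasma/lymphocyte, `timepoint_label`,
#' `days_from_surgery`); the clinical table carries one row per patient
#' (`patient_id`, `histology`, `stage`, `tumor_purity`, optional
#' `recurrence_day`, optional `differentiation_grade`). The two are
#' cross-checked: every sample's patient must exist, sample ids must be
#' unique, baseline plasma must precede surgery, and within a patient the
#' plasma timepoint labels must be strictly ordered by day.
#'
#' @param manifest_path Path to the sample manifest TSV.
#' @param clinical_path Path to the clinical TSV.
#' @return A list with data frames `samples` and `clinical`.
#' @export
read_manifest <- function(manifest_path, clinical_path) {
  samples  <- read_tsv_checked(manifest_path, MANIFEST_COLS, "manifest")
  clinical <- read_tsv_checked(clinical_path, CLINICAL_COLS, "clinical")

  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup)) stop("duplicate sample_id in manifest: ",
                        paste(unique(dup), collapse = ", "), call. = FALSE)
  dup <- clinical$patient_id[duplicated(clinical$patient_id)]
  if (length(dup)) stop("duplicate patient_id in clinical table: ",
                        paste(unique(dup), collapse = ", "), call. = FALSE)

  bad <- setdiff(samples$material, MATERIALS)
  if (length(bad)) stop("unknown material in manifest: ",
                        paste(bad, collapse = ", "), call. = FALSE)

  orphan <- setdiff(samples$patient_id, clinical$patient_id)
  if (length(orphan)) {
    ids <- samples$sample_id[samples$patient_id %in% orphan]
    stop("manifest sample(s) reference unknown patient(s): ",
         paste(ids, collapse = ", "), call. = FALSE)
  }

  samples$days_from_surgery <- as.integer(samples$days_from_surgery)
  clinical$tumor_purity <- as.numeric(clinical$tumor_purity)
  bad <- which(!is.na(clinical$tumor_purity) &
                 (clinical$tumor_purity < 0 | clinical$tumor_purity > 1))
  if (length(bad)) stop("tumor_purity outside [0,1] for patient ",
                        clinical$patient_id[bad[1L]], call. = FALSE)
  clinical$recurrence_day <- suppressWarnings(as.integer(clinical$recurrence_day))
  bad <- which(!is.na(clinical$recurrence_day) & clinical$recurrence_day <= 0L)
  if (length(bad)) stop("recurrence_day must be > 0 (days from surgery); patient ",
                        clinical$patient_id[bad[1L]], call. = FALSE)

  pl <- samples[samples$material == "plasma", , drop = FALSE]
  bad <- which(pl$timepoint_label == "baseline" & pl$days_from_surgery > 0L)
  if (length(bad)) stop("baseline sample after surgery: ",
                        pl$sample_id[bad[1L]], call. = FALSE)
  for (pid in unique(pl$patient_id)) {
    d <- pl$days_from_surgery[pl$patient_id == pid]
    lab <- pl$timepoint_label[pl$patient_id == pid]
    if (anyDuplicated(lab)) {
      stop("duplicate timepoint label for patient ", pid, call. = FALSE)
    }
    if (is.unsorted(d[order(timepoint_rank(lab))], strictly = TRUE)) {
      stop("plasma timepoints of patient ", pid,
           " are not strictly ordered by days_from_surgery", call. = FALSE)
    }
  }

  list(samples = samples, clinical = clinical)
}

#' Write manifest and clinical tables
#' @param manifest List with `samples` and `clinical` as from [read_manifest()].
#' @param manifest_path,clinical_path Output paths.
#' @return `manifest_path`, invisibly.
#' @export
write_manifest <- function(manifest, manifest_path, clinical_path) {
  write_tsv(manifest$samples[MANIFEST_COLS], manifest_path)
  write_tsv(manifest$clinical[CLINICAL_COLS], clinical_path)
  invisible(manifest_path)
}

#' Read a somatic-mutation call table
#'
#' Calls are plasma or tissue variants with columns `sample_id`, `gene`,
#' `chrom`, `pos` (1-based; NA for coordinate-less events such as
#' rearrangements), `ref`, `alt`, `af` (allelic fraction in \[0,1\];
#' 0.012 means 1.2%), `depth` and `chip_filtered` (TRUE once
#' paired-lymphocyte clonal-hematopoiesis filtering has been applied
#' upstream).
#'
#' @param path Path to the TSV.
#' @return A data frame of validated calls.
#' @export
read_mutation_table <- function(path) {
  df <- read_tsv_checked(path, MUTATION_COLS, "mutation")
  if (nrow(df) == 0L) {
    df$chip_filtered <- logical(0)
    return(df)
  }
  df$af <- as.numeric(df$af)
  bad <- which(is.na(df$af) | df$af < 0 | df$af > 1)
  if (length(bad)) stop("mutation table ", path,
                        ": allelic fraction outside [0,1] at data line ",
                        bad[1L], call. = FALSE)
  df$pos <- suppressWarnings(as.integer(df$pos))
  df$depth <- as.integer(df$depth)
  bad <- which(is.na(df$depth) | df$depth <= 0L)
  if (length(bad)) stop("mutation table ", path,
                        ": non-positive depth at data line ", bad[1L],
                        call. = FALSE)
  cf <- tolower(as.character(df$chip_filtered))
  if (!all(cf %in% c("true", "false"))) {
    stop("mutation table ", path, ": chip_filtered must be true/false",
         call. = FALSE)
  }
  df$chip_filtered <- cf == "true"
  df
}

#' Write a somatic-mutation call table
#' @param calls Data frame as returned by [read_mutation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(calls, path) {
  stopifnot(all(MUTATION_COLS %in% names(calls)))
  out <- calls[MUTATION_COLS]
  out$chip_filtered <- tolower(as.character(out$chip_filtered))
  write_tsv(out, path)
}
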