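# Activity-data curation: select high-confidence direct-binding Ki
# measurements, aggregate per-compound potency as the geometric mean, and
# assemble target-based activity classes.

#' Read an activity table
#'
#' TSV/CSV with named columns `smiles`, `target_id`, `relationship`
#' (assay relationship type code), `confidence` (assay confidence score
#' 0-9) and `ki_nM` (Ki in nanomolar).
#'
#' @param path file path (delimiter sniffed by `data.table::fread`).
#' @return a `data.table` with the five canonical columns.
#' @export
read_activity_table <- function(path) {
  dt <- data.table::fread(path)
  need <- c("smiles", "target_id", "relationship", "confidence", "ki_nM")
  have <- tolower(names(dt))
  idx <- match(tolower(need), have)
  if (anyNA(idx)) {
    stop("activity table lacks column(s): ",
         paste(need[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- dt[, idx, with = FALSE]
  data.table::setnames(out, need)
  out
}

#' Read target sequences from FASTA
#'
#' @param path FASTA file keyed by target id (first word of each header).
#' @return named character vector `target_id -> residue string`.
#' @export
read_target_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(path)
    seqs <- as.character(aa)
    names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
    return(seqs)
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- sub("^>(\\S+).*", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  stats::setNames(toupper(seqs), id)
}

#' Filter raw activity rows
#'
#' Retains rows with assay relationship type `"D"` (direct interaction),
#' the highest assay confidence level (score 9), a present positive Ki
#' value, and a target sequence of at most 4000 residues. Rows lacking a
#' sequence are dropped with a warning; malformed rows are skipped with a
#' warning rather than failing the run. Idempotent.
#'
#' @param rows data.frame with columns `smiles`, `target_id`,
#'   `relationship`, `confidence`, `ki_nM`.
#' @param sequences named character vector `target_id -> sequence`.
#' @return filtered `data.table` with a `target_sequence` column attached.
#' @export
filter_rows <- function(rows, sequences) {
  dt <- data.table::as.data.table(rows)
  n0 <- nrow(dt)
  suppressWarnings({
    dt[, ki_nM := as.numeric(ki_nM)]
    dt[, confidence := as.integer(confidence)]
  })
  malformed <- is.na(dt$smiles) | !nzchar(trimws(dt$smiles)) |
    is.na(dt$confidence)
  if (any(malformed)) {
    warning(sum(malformed), " malformed row(s) skipped", call. = FALSE)
    dt <- dt[!malformed]
  }
  dt[, target_sequence := unname(sequences[target_id])]
  no_seq <- is.na(dt$target_sequence)
  if (any(no_seq)) {
    warning(sum(no_seq), " row(s) without a target sequence dropped",
            call. = FALSE)
    dt <- dt[!no_seq]
  }
  dt[relationship == "D" & confidence == 9L & !is.na(ki_nM) & ki_nM > 0 &
       nchar(target_sequence) <= 4000L]
}

#' Aggregate replicate Ki measurements into one pKi
#'
#' Multiple measurements for the same compound are combined as the
#' geometric mean of Ki -- equivalently the arithmetic mean of the
#' per-measurement pKi values -- provided all values fall within the same
#' order of magnitude (max/min ratio of at most 10, i.e. a pKi range of at
#' most 1 unit). Otherwise the compound is rejected and `NA` is returned.
#'
#' @param ki_nM numeric vector of positive Ki values in nanomolar.
#' @return aggregated pKi (`-log10` of Ki in molar units), or `NA_real_`
#'   when the measurements disagree by more than one order of magnitude.
#' @export
#' @examples
#' aggregate_potency(10)          # 8
#' aggregate_potency(c(10, 20))   # 7.8495
#' aggregate_potency(c(10, 200))  # NA: inconsistent measurements
aggregate_potency <- function(ki_nM) {
  stopifnot(length(ki_nM) >= 1L, is.numeric(ki_nM))
  if (anyNA(ki_nM) || any(ki_nM <= 0)) {
    stop("Ki values must be positive and non-missing", call. = FALSE)
  }
  if (max(ki_nM) / min(ki_nM) > 10 + 1e-9) return(NA_real_)
  mean(-log10(ki_nM * 1e-9))
}

#' Build target-based activity classes
#'
#' Canonicalizes SMILES once at ingestion, groups rows by target,
#' aggregates per-compound potency with [aggregate_potency()] (compounds
#' with inconsistent replicate measurements are excluded), and drops
#' classes left without compounds.
#'
#' @param rows filtered rows from [filter_rows()].
#' @return list of activity classes, each
#'   `list(target_id, target_sequence, records)` where `records` is a
#'   `data.table` with one row per unique compound (`canonical_smiles`,
#'   `pki`).
#' @export
build_classes <- function(rows) {
  dt <- data.table::as.data.table(rows)
  if (!nrow(dt)) return(list())
  dt[, canonical_smiles := canonicalize_smiles(smiles)]
  bad <- is.na(dt$canonical_smiles)
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable SMILES skipped",
            call. = FALSE)
    dt <- dt[!bad]
  }
  classes <- lapply(split(dt, by = "target_id", sorted = TRUE),
                    function(sub) {
    rec <- sub[, .(pki = aggregate_potency(ki_nM)),
               by = canonical_smiles]
    rec <- rec[!is.na(pki)]
    if (!nrow(rec)) return(NULL)
    list(target_id = sub$target_id[1L],
         target_sequence = sub$target_sequence[1L],
         records = rec[])
  })
  Filter(Negate(is.null), classes)
}

#' Run the full curation pipeline
#'
#' @param activities path to the activity table (see
#'   [read_activity_table()]).
#' @param sequences path to the target FASTA.
#' @param out output directory: one TSV per class
#'   (`<target_id>.tsv` with columns `canonical_smiles`, `pki`) plus a
#'   `manifest.json`.
#' @return the class list, invisibly.
#' @export
curate <- function(activities, sequences, out) {
  rows <- read_activity_table(activities)
  seqs <- read_target_fasta(sequences)
  classes <- build_classes(filter_rows(rows, seqs))
  write_classes(classes, out)
  invisible(classes)
}

#' Write / read activity-class files
#'
#' @param classes list from [build_classes()].
#' @param dir output directory.
#' @export
write_classes <- function(classes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(classes, function(cl) {
    f <- paste0(cl$target_id, ".tsv")
    data.table::fwrite(cl$records, file.path(dir, f), sep = "\t")
    list(target_id = cl$target_id, file = f,
         n_compounds = nrow(cl$records),
         sequence_length = nchar(cl$target_sequence),
         target_sequence = cl$target_sequence)
  })
  jsonlite::write_json(unname(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_classes
#' @param path a class TSV written by [write_classes()].
#' @export
read_class <- function(path) data.table::fread(path)
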