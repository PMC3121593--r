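# Versioned TSV/CSV dialects for feature maps, identification lists and
# growth curves, plus the KEGG pathway-coloring text format and FASTA
# export of (decoy-augmented) proteomes. Parsers validate and reject
# rather than repair; errors cite file line numbers (1-based, counting the
# version line).

DIALECT_VERSION <- "#version=1"

FEATURE_COLS <- c("run_id", "mz", "rt_start", "rt_apex", "rt_end",
                  "intensity", "charge")
ID_COLS <- c("run_id", "peptide", "protein_accessions", "charge",
             "mz_observed", "rt_observed", "ion_score", "is_decoy")
GROWTH_COLS <- c("time_min", "od600", "glucose_g_per_L", "lactose_g_per_L")

fail_row <- function(rows, what) {
  # rows are data rows; +2 accounts for the version and header lines
  abort(sprintf("%s (line %d)", what, rows[1] + 2L),
        class = "diauxielfq_validation_error")
}

check_version_line <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0 || first != DIALECT_VERSION) {
    abort(sprintf("'%s' does not start with '%s'", path, DIALECT_VERSION),
          class = "diauxielfq_parse_error")
  }
}

read_dialect <- function(path, cols, delim) {
  check_version_line(path)
  out <- tryCatch(
    readr::read_delim(path, delim = delim, skip = 1, col_types = readr::cols(),
                      show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("cannot parse '", path, "': ",
                                     conditionMessage(e)),
                              class = "diauxielfq_parse_error")
  )
  prob <- readr::problems(out)
  if (nrow(prob) > 0) {
    abort(sprintf("malformed row in '%s' (line %d): %s", path,
                  prob$row[1] + 2L, prob$expected[1]),
          class = "diauxielfq_parse_error")
  }
  if (!identical(names(out), cols)) {
    abort(sprintf("'%s': header must be exactly: %s", path,
                  paste(cols, collapse = ", ")),
          class = "diauxielfq_parse_error")
  }
  out
}

write_dialect <- function(x, path, delim) {
  readr::write_lines(DIALECT_VERSION, path)
  readr::write_delim(x, path, delim = delim, append = TRUE, col_names = TRUE)
  invisible(path)
}

validate_feature_map <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(!(x$rt_start <= x$rt_apex & x$rt_apex <= x$rt_end))
  if (length(bad)) fail_row(bad, "rt_start <= rt_apex <= rt_end violated")
  bad <- which(!(x$mz > 0))
  if (length(bad)) fail_row(bad, "mz must be positive")
  bad <- which(!(x$intensity > 0))
  if (length(bad)) fail_row(bad, "intensity must be positive")
  invisible(x)
}

validate_identifications <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(is.na(x$peptide) | nchar(x$peptide) == 0)
  if (length(bad)) fail_row(bad, "peptide must be non-empty")
  bad <- which(!is.finite(x$ion_score))
  if (length(bad)) fail_row(bad, "ion_score must be finite")
  acc <- strsplit(x$protein_accessions, ";", fixed = TRUE)
  all_decoy <- vapply(acc, function(a) all(startsWith(a, "DECOY_")),
                      logical(1))
  bad <- which(x$is_decoy != all_decoy)
  if (length(bad)) {
    fail_row(bad, "is_decoy must hold iff every accession has the DECOY_ prefix")
  }
  invisible(x)
}

validate_growth_curve <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(diff(x$time_min) <= 0) + 1L
  if (length(bad)) fail_row(bad, "time_min must be strictly increasing")
  bad <- which(x$od600 < 0)
  if (length(bad)) fail_row(bad, "od600 must be non-negative")
  bad <- which(diff(x$glucose_g_per_L) > 1e-9 | diff(x$lactose_g_per_L) > 1e-9) + 1L
  if (length(bad)) fail_row(bad, "sugar concentrations must be non-increasing")
  invisible(x)
}

#' Read / write LC-MS feature maps
#'
#' TSV dialect with a `#version=1` first line and fixed column order
#' `run_id, mz, rt_start, rt_apex, rt_end, intensity, charge`. `write` then
#' `read` is the identity on valid maps; invalid rows are rejected with the
#' offending file line number.
#'
#' @param path File path.
#' @return A feature-map tibble.
#' @export
read_feature_map <- function(path) {
  out <- read_dialect(path, FEATURE_COLS, "\t")
  validate_feature_map(out)
  out
}

#' @rdname read_feature_map
#' @param x Feature-map tibble (columns as above; extra columns dropped).
#' @export
write_feature_map <- function(x, path) {
  x <- dplyr::select(as.data.frame(x), dplyr::all_of(FEATURE_COLS))
  validate_feature_map(x)
  write_dialect(x, path, "\t")
}

#' Read / write peptide identification lists
#'
#' TSV dialect (`#version=1`) with columns `run_id, peptide,
#' protein_accessions, charge, mz_observed, rt_observed, ion_score,
#' is_decoy`. Multiple protein accessions are ";"-separated. A record is a
#' decoy iff every accession carries the `DECOY_` prefix; inconsistent
#' flags are a validation error.
#'
#' @param path File path.
#' @return An identification tibble.
#' @export
read_identifications <- function(path) {
  out <- read_dialect(path, ID_COLS, "\t")
  validate_identifications(out)
  out
}

#' @rdname read_identifications
#' @param x Identification tibble.
#' @export
write_identifications <- function(x, path) {
  x <- dplyr::select(as.data.frame(x), dplyr::all_of(ID_COLS))
  validate_identifications(x)
  write_dialect(x, path, "\t")
}

#' Read / write growth curves
#'
#' CSV dialect (`#version=1`) with columns `time_min, od600,
#' glucose_g_per_L, lactose_g_per_L`. Time must be strictly increasing and
#' sugars non-increasing.
#'
#' @param path File path.
#' @return A `growth_curve` tibble.
#' @export
read_growth_curve <- function(path) {
  out <- read_dialect(path, GROWTH_COLS, ",")
  validate_growth_curve(out)
  structure(out, class = c("growth_curve", class(out)))
}

#' @rdname read_growth_curve
#' @param x Growth-curve tibble.
#' @export
write_growth_curve <- function(x, path) {
  x <- dplyr::select(as.data.frame(x), dplyr::all_of(GROWTH_COLS))
  validate_growth_curve(x)
  write_dialect(x, path, ",")
}

#' Write a KEGG pathway-coloring file
#'
#' One line per entry in the format the KEGG pathway mapper accepts:
#' `entry_id bg_hex,fg_hex` (space-separated, background and foreground
#' colors comma-joined). Hex codes must match `#RRGGBB`.
#'
#' @param entries Tibble/data frame with columns `entry_id`, `bg_hex`,
#'   `fg_hex`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kegg_colors <- function(entries, path) {
  entries <- as.data.frame(entries)
  if (nrow(entries) == 0) {
    readr::write_lines(character(0), path)
    return(invisible(path))
  }
  ok <- grepl("^#[0-9A-F]{6}$", entries$bg_hex) &
    grepl("^#[0-9A-F]{6}$", entries$fg_hex)
  if (!all(ok)) {
    abort(sprintf("malformed hex color for entry '%s'",
                  entries$entry_id[which(!ok)[1]]),
          class = "diauxielfq_validation_error")
  }
  readr::write_lines(
    paste0(entries$entry_id, " ", entries$bg_hex, ",", entries$fg_hex),
    path)
  invisible(path)
}

#' Write a proteome (optionally with reversed decoys) as FASTA
#'
#' Decoy entries are reversed sequences under a `DECOY_`-prefixed
#' accession, the convention used for the target-decoy FDR estimate.
#'
#' @param proteome Tibble with `protein_id` and `sequence`.
#' @param path Output path.
#' @param decoys Append reversed-sequence decoys?
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path, decoys = TRUE) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required to write FASTA files")
  }
  seqs <- proteome$sequence
  ids <- proteome$protein_id
  if (decoys) {
    seqs <- c(seqs, str_reverse(proteome$sequence))
    ids <- c(ids, paste0("DECOY_", proteome$protein_id))
  }
  aa <- Biostrings::AAStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
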