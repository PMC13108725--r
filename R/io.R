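#' Read a long-format analyte measurement table
#'
#' Reads a CSV/TSV of secreted-analyte concentrations (one row per donor x
#' unit x analyte observation, pg/mL), validates it, and computes below-LLoQ
#' censoring flags from the supplied per-analyte lower limits of
#' quantification.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @param lloq_map named numeric vector, analyte -> LLoQ (pg/mL).
#' @param columns named character vector mapping the required names
#'   `donor`, `unit`, `analyte`, `concentration` to the file's header names.
#' @return tibble with columns `donor`, `unit`, `analyte`, `concentration`,
#'   `below_lloq`, plus any extra columns in the file.
#' @export
read_measurement_table <- function(path, lloq_map,
                                   columns = c(donor = "donor", unit = "unit",
                                               analyte = "analyte",
                                               concentration = "concentration")) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- read_delim_auto(path)
  if (nrow(df) == 0) abort(paste0("Empty measurement file: ", path))
  missing <- setdiff(unname(columns), names(df))
  if (length(missing) > 0) {
    abort(paste0("Measurement file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df <- dplyr::rename(df, dplyr::all_of(columns))
  validate_measurement_table(df, lloq_map)
}

#' Validate a measurement tibble and compute censoring flags
#'
#' Checks the invariants of the measurement-table contract: required columns,
#' non-negative concentrations, unique (donor, unit, analyte) triples, LLoQ
#' available for every analyte. `below_lloq` is (re)computed as
#' `concentration < lloq_map[analyte]`.
#'
#' @inheritParams read_measurement_table
#' @param df tibble with columns `donor`, `unit`, `analyte`, `concentration`.
#' @return the validated tibble with a `below_lloq` logical column.
#' @export
validate_measurement_table <- function(df, lloq_map) {
  check_columns(df, c("donor", "unit", "analyte", "concentration"),
                "measurement table")
  bad <- which(!is.finite(df$concentration) | df$concentration < 0)
  if (length(bad) > 0) {
    abort(paste0("Negative or non-finite concentration at row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  dup <- df |>
    dplyr::count(.data$donor, .data$unit, .data$analyte) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Duplicated (donor, unit, analyte) triple(s): ",
                 paste(paste(dup$donor, dup$unit, dup$analyte, sep = "/"),
                       collapse = "; ")))
  }
  missing_lloq <- setdiff(unique(df$analyte), names(lloq_map))
  if (length(missing_lloq) > 0) {
    abort(paste0("No LLoQ provided for analyte(s): ",
                 paste(missing_lloq, collapse = ", ")))
  }
  dplyr::mutate(df, below_lloq = .data$concentration <
                  unname(lloq_map[.data$analyte]))
}

#' Read a paired raw-count / normalized expression bundle
#'
#' Reads two gene x sample matrices (genes as rows, first column the gene
#' id) and aligns them on the intersection of their gene ids; sample sets
#' must overlap. Counts within 1e-6 of an integer are rounded; other
#' non-integer counts are rejected.
#'
#' @param counts_path path to the raw-count matrix (TSV/CSV).
#' @param normalized_path path to the normalized (TPM or control-gene
#'   normalized) matrix with the same layout.
#' @return list of class `expression_bundle`: `counts` and `normalized`
#'   numeric matrices (identical dimnames), `gene_ids`, `sample_ids`.
#' @export
read_expression_bundle <- function(counts_path, normalized_path) {
  counts <- read_matrix_file(counts_path)
  normalized <- read_matrix_file(normalized_path)
  samples <- intersect(colnames(counts), colnames(normalized))
  if (length(samples) == 0) {
    abort("Counts and normalized matrices share no sample ids.")
  }
  genes <- intersect(rownames(counts), rownames(normalized))
  dropped <- length(union(rownames(counts), rownames(normalized))) -
    length(genes)
  if (dropped > 0) {
    inform(paste0("Dropped ", dropped,
                  " gene(s) absent from one of the two matrices."))
  }
  if (length(genes) == 0) abort("Matrices share no gene ids.")
  counts <- counts[genes, samples, drop = FALSE]
  normalized <- normalized[genes, samples, drop = FALSE]
  off <- abs(counts - round(counts))
  if (any(off > 1e-6)) {
    abort("Counts matrix contains non-integer values.")
  }
  counts <- round(counts)
  if (any(counts < 0) || any(normalized < 0)) {
    abort("Expression matrices must be non-negative.")
  }
  new_expression_bundle(counts, normalized)
}

new_expression_bundle <- function(counts, normalized) {
  stopifnot(identical(dimnames(counts), dimnames(normalized)))
  if (anyDuplicated(colnames(counts))) abort("Sample ids must be unique.")
  structure(
    list(counts = counts, normalized = normalized,
         gene_ids = rownames(counts), sample_ids = colnames(counts)),
    class = "expression_bundle"
  )
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat("<expression_bundle> ", nrow(x$counts), " genes x ",
      ncol(x$counts), " samples\n", sep = "")
  invisible(x)
}

#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT dialect (set name, description, then member
#' gene ids). Malformed lines are reported with their line number; duplicate
#' set names and empty member lists are rejected.
#'
#' @param path GMT file path.
#' @return named list of character vectors (set -> members) with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("Empty GMT file: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad) > 0) {
    abort(paste0("GMT line ", bad[1], " has fewer than 3 fields."))
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    abort(paste0("Duplicated gene-set name(s): ",
                 paste(unique(names_[duplicated(names_)]), collapse = ", ")))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- which(vapply(sets, length, integer(1)) == 0)
  if (length(empty) > 0) {
    abort(paste0("Gene set '", names_[empty[1]], "' has no members."))
  }
  names(sets) <- names_
  attr(sets, "descriptions") <- setNames(
    vapply(fields, `[[`, character(1), 2), names_)
  sets
}

#' Write a results table deterministically
#'
#' Writes any tabular result as CSV with a `#`-prefixed header comment
#' carrying the run seed and a configuration hash, floats serialized at 10
#' significant digits. Writing the same result twice produces byte-identical
#' files.
#'
#' @param result non-empty data frame.
#' @param path output file path.
#' @param seed integer seed to record in the header (may be `NA`).
#' @param config list recorded (hashed) in the header.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(result, path, seed = NA_integer_,
                                config = list()) {
  result <- as.data.frame(result)
  if (nrow(result) == 0) abort("Refusing to write an empty results table.")
  hash <- config_hash(config)
  out <- result
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) formatC(v, digits = 10,
                                                   format = "g"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("# seed=", seed, " config_hash=", hash), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path file path.
#' @return tibble (the header comment is skipped).
#' @export
read_results_table <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

config_hash <- function(config) {
  # stable short hash of the serialized configuration; no digest dependency
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  sum_ <- 0
  for (ch in utf8ToInt(s)) sum_ <- (sum_ * 31 + ch) %% 2147483647
  sprintf("%08x", sum_)
}

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

read_matrix_file <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- read_delim_auto(path)
  if (nrow(df) == 0 || ncol(df) < 2) {
    abort(paste0("Not a gene x sample matrix: ", path))
  }
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    abort(paste0("Duplicated gene ids in ", path))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}
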