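#' Read a droplet amplitude CSV
#'
#' Reads one well's two-channel amplitude export: comma-separated, one
#' droplet per row, with a header containing "Ch1 Amplitude" and
#' "Ch2 Amplitude" (matched case-insensitively). Extra columns are ignored
#' with a warning; missing amplitude columns, non-numeric cells or an empty
#' file are errors, with the offending file line named.
#'
#' @param path CSV file path.
#' @param well_id,sample_id,assay_id Labels; `well_id` defaults to the file
#'   name without extension.
#' @return A `droplet_well`.
#' @seealso [write_amplitude_csv()]
#' @export
read_amplitude_csv <- function(path, well_id = NULL, sample_id = "sample",
                               assay_id = "assay") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    stop("empty amplitude file: ", path, call. = FALSE)
  }
  lc <- tolower(trimws(names(raw)))
  i1 <- which(lc == "ch1 amplitude")
  i2 <- which(lc == "ch2 amplitude")
  if (length(i1) != 1 || length(i2) != 1) {
    stop("amplitude file must have columns 'Ch1 Amplitude' and 'Ch2 Amplitude': ",
         path, call. = FALSE)
  }
  if (ncol(raw) > 2) {
    warning(sprintf("ignoring %d extra column(s) in %s", ncol(raw) - 2L, path),
            call. = FALSE)
  }
  parse_channel <- function(col, label) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric %s value(s) at file line(s) %s in %s",
                   label, paste(utils::head(bad + 1L, 5), collapse = ", "),
                   path), call. = FALSE)
    }
    v
  }
  ch1 <- parse_channel(raw[[i1]], "Ch1 Amplitude")
  ch2 <- parse_channel(raw[[i2]], "Ch2 Amplitude")
  droplet_well(ch1, ch2,
               well_id = well_id %||% sub("\\.[^.]*$", "", basename(path)),
               sample_id = sample_id, assay_id = assay_id)
}

#' Write a droplet amplitude CSV
#'
#' Writes the dialect [read_amplitude_csv()] reads, with amplitudes at full
#' double precision so a write-then-read round-trip is bit-exact.
#'
#' @param well A `droplet_well`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_amplitude_csv <- function(well, path) {
  if (!inherits(well, "droplet_well")) {
    stop("`well` must be a droplet_well", call. = FALSE)
  }
  lines <- c("Ch1 Amplitude,Ch2 Amplitude",
             paste(sprintf("%.17g", well$amplitudes$ch1),
                   sprintf("%.17g", well$amplitudes$ch2), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-SNP allele count table
#'
#' Tab-separated with header columns `snp_id`, `sample_id`, `wt_count`,
#' `mut_count`. Negative counts and duplicated (snp, sample) rows are
#' rejected.
#'
#' @param path TSV file path.
#' @return Validated data.frame.
#' @export
read_snp_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("snp_id", "sample_id", "wt_count", "mut_count")
  if (!all(req %in% names(tab))) {
    stop("SNP count file must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("wt_count", "mut_count")) {
    if (!is.numeric(tab[[col]])) {
      stop("column ", col, " must be numeric in ", path, call. = FALSE)
    }
  }
  validate_snp_table(tab[, req])
  tab[, req]
}

#' Write a per-SNP allele count table
#'
#' @param table SNP count table (validated).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_snp_counts <- function(table, path) {
  validate_snp_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results table deterministically
#'
#' Writes any result data.frame as TSV with a fixed column order (as given),
#' numeric columns formatted at 6 significant digits, and rows sorted by
#' `sample_id`, `assay_id` and `target` where those columns exist. Output is
#' byte-identical for identical input.
#'
#' @param results data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results)) stop("`results` must be a data.frame", call. = FALSE)
  keys <- intersect(c("sample_id", "assay_id", "target"), names(results))
  if (nrow(results) > 0 && length(keys)) {
    results <- results[do.call(order, results[keys]), , drop = FALSE]
  }
  out <- results
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- sprintf("%.6g", out[[col]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' One YAML file holds the run parameters, the plate metadata and the assay
#' definitions (see [run_pipeline()] for the recognized keys). rsIDs are
#' opaque labels; no external lookup is performed.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  cfg
}

#' Assay definition
#'
#' Maps the two fluorescence channels of an assay to targets. For a duplex
#' SNP assay channel 1 typically reads the WT probe and channel 2 the MUT
#' probe; single-channel assays (reference genes) map one channel and set
#' the other to `NA`.
#'
#' @param assay_id Assay label.
#' @param gene Gene label.
#' @param rs_id SNP identifier (opaque label).
#' @param ch1_allele,ch2_allele `"WT"`, `"MUT"`, `"total"`, `"reference"`,
#'   or `NA`.
#' @return An `assay_definition`.
#' @export
assay_definition <- function(assay_id, gene = NA_character_,
                             rs_id = NA_character_,
                             ch1_allele = "WT", ch2_allele = "MUT") {
  valid <- c("WT", "MUT", "total", "reference", NA_character_)
  if (!ch1_allele %in% valid || !ch2_allele %in% valid) {
    stop("channel alleles must be WT, MUT, total, reference or NA", call. = FALSE)
  }
  if (!is.na(ch1_allele) && !is.na(ch2_allele) && ch1_allele == ch2_allele) {
    stop("ch1_allele and ch2_allele must differ for a duplex assay", call. = FALSE)
  }
  structure(list(assay_id = assay_id, gene = gene, rs_id = rs_id,
                 ch1_allele = ch1_allele, ch2_allele = ch2_allele),
            class = "assay_definition")
}
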