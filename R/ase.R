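validate_snp_table <- function(table) {
  req <- c("snp_id", "sample_id", "wt_count", "mut_count")
  if (!is.data.frame(table) || !all(req %in% names(table))) {
    stop("SNP count table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(table$wt_count < 0) || any(table$mut_count < 0)) {
    stop("allele counts must be >= 0", call. = FALSE)
  }
  key <- paste(table$snp_id, table$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- table[duplicated(key), , drop = FALSE]
    stop("duplicated (snp_id, sample_id) rows: ",
         paste(unique(paste(dup$snp_id, dup$sample_id)), collapse = "; "),
         call. = FALSE)
  }
  invisible(table)
}

#' Per-SNP allele-specific expression fractions
#'
#' For each (SNP, sample) row computes the WT read fraction
#' `f = wt / (wt + mut)` with a 95% Wilson score interval. Zero-depth rows
#' are excluded with a warning.
#'
#' @param table data.frame with columns `snp_id`, `sample_id`, `wt_count`,
#'   `mut_count` (from [read_snp_counts()] or [simulate_snp_counts()]).
#' @return data.frame with `snp_id`, `sample_id`, `depth`, `f_wt`,
#'   `ci_low`, `ci_high`.
#' @examples
#' tab <- simulate_snp_counts(0.75, 1000, n_snps = 3, seed = 1)
#' per_snp_fraction(tab)
#' @export
per_snp_fraction <- function(table) {
  validate_snp_table(table)
  depth <- table$wt_count + table$mut_count
  if (any(depth == 0)) {
    warning(sprintf("excluding %d zero-depth row(s)", sum(depth == 0)),
            call. = FALSE)
    table <- table[depth > 0, , drop = FALSE]
    depth <- depth[depth > 0]
  }
  if (nrow(table) == 0) stop("no rows with positive depth", call. = FALSE)
  ci <- t(mapply(function(x, n) {
    stats::prop.test(x, n, correct = FALSE)$conf.int  # Wilson score interval
  }, table$wt_count, depth))
  data.frame(snp_id = table$snp_id, sample_id = table$sample_id,
             depth = depth, f_wt = table$wt_count / depth,
             ci_low = ci[, 1], ci_high = ci[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate allele fractions across SNPs per sample
#'
#' Two aggregation conventions: `mean_of_snps` (default) is the unweighted
#' mean of the per-SNP fractions, matching the practice of averaging over
#' SNP regions; `pooled_counts` sums reads across SNPs first. They differ
#' when depths differ across SNPs. Also reports the across-SNP SD -- the
#' dispersion that makes low-depth per-SNP RNA-seq estimates noisier than a
#' ddPCR measurement at comparable molecule counts.
#'
#' @param table SNP count table (see [per_snp_fraction()]).
#' @param method `"mean_of_snps"` or `"pooled_counts"`.
#' @return data.frame per sample: `sample_id`, `f_wt`, `sd_across_snps`,
#'   `n_snps`, `total_depth`, `method`.
#' @examples
#' tab <- simulate_snp_counts(0.747, 5000, n_snps = 3, seed = 2)
#' aggregate_fraction(tab)
#' @export
aggregate_fraction <- function(table, method = c("mean_of_snps", "pooled_counts")) {
  method <- match.arg(method)
  per <- per_snp_fraction(table)
  out <- do.call(rbind, lapply(split(per, per$sample_id), function(d) {
    f <- if (method == "mean_of_snps") {
      mean(d$f_wt)
    } else {
      sum(d$f_wt * d$depth) / sum(d$depth)
    }
    data.frame(sample_id = d$sample_id[1], f_wt = f,
               sd_across_snps = if (nrow(d) > 1) stats::sd(d$f_wt) else 0,
               n_snps = nrow(d), total_depth = sum(d$depth),
               method = method, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
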