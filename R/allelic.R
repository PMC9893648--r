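#' Allelic fractional abundance with propagated Poisson error
#'
#' Converts paired WT and MUT concentration measurements from the same
#' well(s) into fractional abundances: `f_wt = C_wt / (C_wt + C_mut)`,
#' `f_mut = 1 - f_wt` (exact). The standard error is first-order
#' propagation on the Poisson rates:
#' `SE(f) = f (1 - f) sqrt((SE_wt/lambda_wt)^2 + (SE_mut/lambda_mut)^2)`,
#' with `SE(f) = 0` when either rate is zero (the fraction is then pinned at
#' a boundary). The 95% CI is `f +/- 1.96 SE`, clipped to `[0, 1]`.
#'
#' @param m_wt,m_mut `target_measurement` objects for the WT and MUT targets.
#' @param sample_id,assay_id Labels carried into the result (defaults taken
#'   from nothing; pass them through when known).
#' @return An `allelic_result`: `f_wt`, `f_mut`, `se_f`, `ci_low`, `ci_high`
#'   (all proportions), plus labels and the pooled droplet count.
#' @examples
#' wt <- estimate_concentration(4000, 20000, target = "WT")
#' mut <- estimate_concentration(1500, 20000, target = "MUT")
#' allelic_fraction(wt, mut)
#' @export
allelic_fraction <- function(m_wt, m_mut, sample_id = "sample",
                             assay_id = "assay") {
  if (!inherits(m_wt, "target_measurement") ||
      !inherits(m_mut, "target_measurement")) {
    stop("inputs must be target_measurement objects", call. = FALSE)
  }
  lw <- m_wt$lambda_hat
  lm <- m_mut$lambda_hat
  if (lw + lm <= 0) {
    stop("no template detected: both concentrations are zero", call. = FALSE)
  }
  f <- lw / (lw + lm)
  se <- if (lw == 0 || lm == 0) {
    0
  } else {
    f * (1 - f) * sqrt((m_wt$se_lambda / lw)^2 + (m_mut$se_lambda / lm)^2)
  }
  structure(
    list(f_wt = f, f_mut = 1 - f, se_f = se,
         ci_low = max(0, f - 1.96 * se), ci_high = min(1, f + 1.96 * se),
         sample_id = sample_id, assay_id = assay_id,
         n_droplets = m_wt$n_total),
    class = "allelic_result"
  )
}

#' @export
print.allelic_result <- function(x, ...) {
  cat(sprintf("<allelic_result> %s/%s: %.1f%% WT / %.1f%% MUT (SE %.2f%%, 95%% CI %.1f-%.1f%%)\n",
              x$sample_id, x$assay_id, 100 * x$f_wt, 100 * x$f_mut,
              100 * x$se_f, 100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

#' @export
as.data.frame.allelic_result <- function(x, ...) {
  data.frame(sample_id = x$sample_id, assay_id = x$assay_id,
             f_wt = x$f_wt, f_mut = x$f_mut, se_f = x$se_f,
             ci_low = x$ci_low, ci_high = x$ci_high,
             n_droplets = x$n_droplets, stringsAsFactors = FALSE)
}

allelic_results_table <- function(results) {
  if (inherits(results, "allelic_result")) results <- list(results)
  if (is.data.frame(results)) return(results)
  do.call(rbind, lapply(results, as.data.frame))
}

#' Summarize allelic fractions over replicates and assays
#'
#' Per group and assay, the mean and SD of the replicate WT fractions; per
#' group, additionally a pooled row (`assay_id = "pooled"`): the unweighted
#' mean over all replicate values across assays, the convention used when a
#' sample's allele ratio is reported as the mean over its SNP assays.
#'
#' @param results List of `allelic_result` objects, or a data.frame as
#'   returned by `as.data.frame()` on them.
#' @param group Optional grouping vector (one per result); defaults to the
#'   results' `sample_id`.
#' @return data.frame with columns `group`, `assay_id`, `mean_f_wt`,
#'   `sd_f_wt`, `n`.
#' @examples
#' wt <- estimate_concentration(4000, 20000, target = "WT")
#' mut <- estimate_concentration(1500, 20000, target = "MUT")
#' r <- allelic_fraction(wt, mut)
#' summarize_replicates(list(r, r, r))
#' @export
summarize_replicates <- function(results, group = NULL) {
  tab <- allelic_results_table(results)
  if (is.null(tab) || nrow(tab) == 0) {
    stop("empty group: no allelic results to summarize", call. = FALSE)
  }
  tab$group <- if (is.null(group)) tab$sample_id else rep_len(group, nrow(tab))
  per_assay <- do.call(rbind, lapply(
    split(tab, list(tab$group, tab$assay_id), drop = TRUE),
    function(d) data.frame(group = d$group[1], assay_id = d$assay_id[1],
                           mean_f_wt = mean(d$f_wt),
                           sd_f_wt = if (nrow(d) > 1) stats::sd(d$f_wt) else 0,
                           n = nrow(d), stringsAsFactors = FALSE)))
  pooled <- do.call(rbind, lapply(
    split(tab, tab$group),
    function(d) data.frame(group = d$group[1], assay_id = "pooled",
                           mean_f_wt = mean(d$f_wt),
                           sd_f_wt = if (nrow(d) > 1) stats::sd(d$f_wt) else 0,
                           n = nrow(d), stringsAsFactors = FALSE)))
  out <- rbind(per_assay, pooled)
  out <- out[order(out$group, out$assay_id == "pooled", out$assay_id), ]
  rownames(out) <- NULL
  out
}
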