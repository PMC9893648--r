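#' Fit the Poisson quantification model to one ddPCR well
#'
#' The central estimator: classifies the droplets of one well and converts
#' the per-channel positive counts into absolute template concentrations via
#' the Poisson partitioning model. For a duplex WT/MUT SNP assay (the
#' default channel mapping: channel 1 = WT probe, channel 2 = MUT probe)
#' the fitted object also carries the allelic fractional abundance.
#'
#' @param well A `droplet_well` (from [simulate_well()] or
#'   [read_amplitude_csv()]).
#' @param thresholds `"auto"` or numeric `c(ch1, ch2)`; see [classify()].
#' @param droplet_volume Droplet volume in uL.
#' @param ch1_allele,ch2_allele Target labels for the channels; one of
#'   `"WT"`, `"MUT"`, `"total"`, `"reference"`, or `NA` to ignore a channel.
#' @param min_droplets QC flag threshold, see [classify()].
#' @param ci_method `"delta"` or `"exact"`, see [estimate_concentration()].
#' @return An object of class `ddpcr_fit` with components `classified`
#'   (the [classify()] result), `measurements` (named list of
#'   `target_measurement`), `allelic` (an `allelic_result`, when both WT and
#'   MUT are mapped and template was detected), and the call.
#' @examples
#' w <- simulate_well(simulation_spec(300, 100, seed = 11))
#' fit <- ddpcr_fit(w)
#' coef(fit)
#' summary(fit)
#' @export
ddpcr_fit <- function(well, thresholds = "auto", droplet_volume = 0.00085,
                      ch1_allele = "WT", ch2_allele = "MUT",
                      min_droplets = 10000,
                      ci_method = c("delta", "exact")) {
  ci_method <- match.arg(ci_method)
  cw <- classify(well, thresholds = thresholds, min_droplets = min_droplets)
  measurements <- list()
  if (!is.na(ch1_allele)) {
    measurements[[ch1_allele]] <- estimate_concentration(
      cw$k_ch1_pos, cw$n_total, droplet_volume,
      target = ch1_allele, ci_method = ci_method)
  }
  if (!is.na(ch2_allele)) {
    measurements[[ch2_allele]] <- estimate_concentration(
      cw$k_ch2_pos, cw$n_total, droplet_volume,
      target = ch2_allele, ci_method = ci_method)
  }
  allelic <- NULL
  if (all(c("WT", "MUT") %in% names(measurements))) {
    if (measurements$WT$lambda_hat + measurements$MUT$lambda_hat > 0) {
      allelic <- allelic_fraction(measurements$WT, measurements$MUT,
                                  sample_id = well$sample_id,
                                  assay_id = well$assay_id)
    }
  }
  structure(
    list(classified = cw, measurements = measurements, allelic = allelic,
         droplet_volume = droplet_volume, well = well,
         call = match.call()),
    class = "ddpcr_fit"
  )
}

#' @export
print.ddpcr_fit <- function(x, ...) {
  cat(sprintf("ddPCR Poisson fit: well %s (sample %s, assay %s)\n",
              x$classified$well_id, x$classified$sample_id,
              x$classified$assay_id))
  cat(sprintf("  %d droplets, thresholds ch1=%.5g ch2=%.5g%s\n",
              x$classified$n_total, x$classified$threshold_ch1,
              x$classified$threshold_ch2,
              if (x$classified$low_droplet_flag) "  [LOW DROPLETS]" else ""))
  for (m in x$measurements) {
    cat(sprintf("  %-9s %10.4g copies/uL  (95%% CI %.4g-%.4g)\n",
                m$target, m$concentration, m$ci_low, m$ci_high))
  }
  if (!is.null(x$allelic)) {
    cat(sprintf("  WT fraction: %.1f%% +/- %.1f%%\n",
                100 * x$allelic$f_wt, 100 * x$allelic$se_f))
  }
  invisible(x)
}

#' @export
coef.ddpcr_fit <- function(object, ...) {
  vapply(object$measurements, `[[`, numeric(1), "concentration")
}

#' @export
confint.ddpcr_fit <- function(object, parm, level = 0.95, ...) {
  ci <- t(vapply(object$measurements,
                 function(m) c(m$ci_low, m$ci_high), numeric(2)))
  colnames(ci) <- c("2.5 %", "97.5 %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.ddpcr_fit <- function(object, ...) {
  ms <- object$measurements
  tab <- data.frame(
    target = vapply(ms, `[[`, character(1), "target"),
    k_pos = vapply(ms, `[[`, integer(1), "k_pos"),
    n_total = vapply(ms, `[[`, integer(1), "n_total"),
    lambda_hat = vapply(ms, `[[`, numeric(1), "lambda_hat"),
    concentration = vapply(ms, `[[`, numeric(1), "concentration"),
    ci_low = vapply(ms, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(ms, `[[`, numeric(1), "ci_high"),
    row.names = NULL
  )
  out <- list(well_id = object$classified$well_id,
              sample_id = object$classified$sample_id,
              assay_id = object$classified$assay_id,
              table = tab, allelic = object$allelic,
              low_droplet_flag = object$classified$low_droplet_flag,
              saturated = object$classified$saturated)
  class(out) <- "summary.ddpcr_fit"
  out
}

#' @export
print.summary.ddpcr_fit <- function(x, ...) {
  cat(sprintf("ddPCR fit summary: well %s, sample %s, assay %s\n",
              x$well_id, x$sample_id, x$assay_id))
  print(x$table, row.names = FALSE)
  if (!is.null(x$allelic)) {
    cat(sprintf("allelic fraction: %.1f%% WT / %.1f%% MUT (SE %.2f%%)\n",
                100 * x$allelic$f_wt, 100 * x$allelic$f_mut,
                100 * x$allelic$se_f))
  }
  if (x$low_droplet_flag) cat("QC: low droplet count\n")
  if (any(x$saturated)) cat("QC: saturated channel\n")
  invisible(x)
}

#' Amplitude scatter plot of a fitted well
#'
#' Two-channel droplet amplitude scatter with the thresholds used by the
#' fit; the four quadrants correspond to the classification counts.
#'
#' @param x A `ddpcr_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ddpcr_fit <- function(x, ...) {
  amp <- x$well$amplitudes
  graphics::plot(amp$ch1, amp$ch2, pch = ".", cex = 2,
                 xlab = "Ch1 amplitude (a.u.)", ylab = "Ch2 amplitude (a.u.)",
                 main = sprintf("Well %s", x$classified$well_id), ...)
  graphics::abline(v = x$classified$threshold_ch1, col = "red", lty = 2)
  graphics::abline(h = x$classified$threshold_ch2, col = "red", lty = 2)
  invisible(x)
}

#' Simulate new wells from a fitted model
#'
#' Draws synthetic replicate wells at the fitted concentrations -- a
#' parametric-bootstrap style check of the estimator on its own output.
#'
#' @param object A `ddpcr_fit` whose channels map to WT/MUT.
#' @param nsim Number of wells.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of `droplet_well`.
#' @export
simulate.ddpcr_fit <- function(object, nsim = 1, seed = 1, ...) {
  conc <- coef(object)
  cw <- unname(conc["WT"] %||% conc[1])
  cm <- if ("MUT" %in% names(conc)) unname(conc["MUT"]) else 0
  cw <- if (is.na(cw)) 0 else cw
  lapply(seq_len(nsim), function(i) {
    simulate_well(simulation_spec(
      conc_wt = cw, conc_mut = cm,
      n_droplets = object$classified$n_total,
      droplet_volume = object$droplet_volume,
      seed = derive_seed(seed, i)
    ), well_id = sprintf("SIM%02d", i), sample_id = object$classified$sample_id,
       assay_id = object$classified$assay_id)
  })
}
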