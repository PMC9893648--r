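#' Automatic amplitude threshold for one channel
#'
#' Splits a channel's 1-D amplitude distribution into negative and positive
#' clusters by two-means: centers initialized at the 5th and 95th
#' percentiles, Lloyd updates for at most 100 iterations or until both
#' centers move less than 1e-6. The threshold is the midpoint of the final
#' centers.
#'
#' A channel without genuine two-cluster structure is rejected: if all
#' values are equal, or the final center gap is smaller than four times the
#' largest within-cluster standard deviation (a single Gaussian cloud split
#' in half fails this), the function errors with "no cluster structure".
#' Wells whose positive cluster is absent on one channel (e.g. a 100% WT
#' plasmid sample on the MUT channel) therefore cannot be auto-thresholded
#' per well; pool amplitudes across the plate with [plate_thresholds()] or
#' supply fixed thresholds instead.
#'
#' @param amplitudes Numeric vector of one channel's amplitudes (>= 100).
#' @param max_iter,tol Iteration cap and convergence tolerance.
#' @return Threshold in amplitude units (a.u.).
#' @examples
#' x <- c(rnorm(500, 2000, 300), rnorm(500, 8000, 300))
#' auto_threshold(x)
#' @export
auto_threshold <- function(amplitudes, max_iter = 100, tol = 1e-6) {
  x <- as.numeric(amplitudes)
  if (length(x) < 100) {
    stop("auto_threshold needs at least 100 droplets", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("amplitudes must be finite", call. = FALSE)
  centers <- unname(stats::quantile(x, c(0.05, 0.95)))
  if (diff(centers) == 0) stop("no cluster structure", call. = FALSE)
  for (iter in seq_len(max_iter)) {
    assign_hi <- abs(x - centers[2]) < abs(x - centers[1])
    if (!any(assign_hi) || all(assign_hi)) stop("no cluster structure", call. = FALSE)
    new_centers <- c(mean(x[!assign_hi]), mean(x[assign_hi]))
    if (max(abs(new_centers - centers)) < tol) {
      centers <- new_centers
      break
    }
    centers <- new_centers
  }
  assign_hi <- abs(x - centers[2]) < abs(x - centers[1])
  sds <- c(stats::sd(x[!assign_hi]), stats::sd(x[assign_hi]))
  sds[is.na(sds)] <- 0
  if (diff(centers) < 4 * max(sds, na.rm = TRUE) || diff(centers) == 0) {
    stop("no cluster structure", call. = FALSE)
  }
  mean(centers)
}

#' Per-channel thresholds pooled across a plate
#'
#' Concatenates the amplitudes of all wells and runs [auto_threshold()] per
#' channel. One threshold per assay across a plate is the usual practice
#' when individual wells lack one of the clusters (pure-WT or pure-MUT
#' samples in a dilution/mixture series).
#'
#' @param wells List of `droplet_well` objects.
#' @return Named numeric vector `c(ch1 = ..., ch2 = ...)`.
#' @export
plate_thresholds <- function(wells) {
  ch1 <- unlist(lapply(wells, function(w) w$amplitudes$ch1))
  ch2 <- unlist(lapply(wells, function(w) w$amplitudes$ch2))
  c(ch1 = auto_threshold(ch1), ch2 = auto_threshold(ch2))
}

#' Classify droplets into the four fluorescence quadrants
#'
#' A droplet is positive on a channel iff its amplitude is strictly greater
#' than that channel's threshold (droplets exactly at the threshold count as
#' negative -- a deterministic tie-break). Quadrant counts always sum to the
#' total droplet count.
#'
#' @param well A `droplet_well`.
#' @param thresholds `"auto"` (per-channel [auto_threshold()] on this well)
#'   or a numeric vector `c(ch1, ch2)`. Use `Inf` to force a channel
#'   all-negative (single-channel assays).
#' @param min_droplets Wells with fewer accepted droplets are flagged
#'   (`low_droplet_flag`), never dropped. Default 10000.
#' @return A `classified_well`: quadrant counts (`k_double_neg`,
#'   `k_ch1_only`, `k_ch2_only`, `k_double_pos`), per-channel positives
#'   (`k_ch1_pos`, `k_ch2_pos`), `n_total`, the thresholds used and QC flags.
#' @examples
#' w <- simulate_well(simulation_spec(300, 100, seed = 2))
#' classify(w, thresholds = c(5000, 5000))
#' @export
classify <- function(well, thresholds = "auto", min_droplets = 10000) {
  if (!inherits(well, "droplet_well")) {
    stop("`well` must be a droplet_well", call. = FALSE)
  }
  if (identical(thresholds, "auto")) {
    thresholds <- c(auto_threshold(well$amplitudes$ch1),
                    auto_threshold(well$amplitudes$ch2))
  }
  if (!is.numeric(thresholds) || length(thresholds) != 2L || any(is.na(thresholds))) {
    stop("`thresholds` must be \"auto\" or a numeric vector of length 2",
         call. = FALSE)
  }
  pos1 <- well$amplitudes$ch1 > thresholds[1]
  pos2 <- well$amplitudes$ch2 > thresholds[2]
  n <- well$accepted_count
  structure(
    list(well_id = well$well_id, sample_id = well$sample_id,
         assay_id = well$assay_id,
         n_total = n,
         k_ch1_pos = sum(pos1), k_ch2_pos = sum(pos2),
         k_double_pos = sum(pos1 & pos2),
         k_ch1_only = sum(pos1 & !pos2),
         k_ch2_only = sum(!pos1 & pos2),
         k_double_neg = sum(!pos1 & !pos2),
         threshold_ch1 = unname(thresholds[1]),
         threshold_ch2 = unname(thresholds[2]),
         low_droplet_flag = n < min_droplets,
         saturated = well$saturated),
    class = "classified_well"
  )
}

#' @export
print.classified_well <- function(x, ...) {
  cat(sprintf("<classified_well> %s  n=%d  ch1+=%d ch2+=%d double+=%d%s\n",
              x$well_id, x$n_total, x$k_ch1_pos, x$k_ch2_pos, x$k_double_pos,
              if (x$low_droplet_flag) "  [LOW DROPLETS]" else ""))
  invisible(x)
}

#' Poisson-corrected absolute concentration from droplet counts
#'
#' The core ddPCR estimator. With `k` positive droplets out of `n`, the
#' positive fraction is `p = k/n` and the mean template copies per droplet
#' is `lambda = -log(1 - p)` (the Poisson zero-truncation correction);
#' concentration is `lambda / droplet_volume` in copies/uL.
#'
#' The default 95% CI uses the delta method, `SE(lambda) =
#' sqrt(p / (n (1 - p)))`, with the interval floored at 0. With
#' `ci_method = "exact"` the Clopper-Pearson binomial interval on `p` is
#' transformed through `-log(1 - p)`. For `k = 0` the delta-method interval
#' degenerates, so the exact upper bound is used there in either mode.
#'
#' A fully positive well (`k = n`) carries no upper bound on lambda and is
#' an error ("saturated well").
#'
#' @param k_pos Positive droplet count (0 <= k <= n).
#' @param n_total Total accepted droplets (> 0).
#' @param droplet_volume Droplet volume in uL (default 0.00085).
#' @param target Label: one of `"WT"`, `"MUT"`, `"total"`, `"reference"`.
#' @param ci_method `"delta"` (default) or `"exact"`.
#' @return A `target_measurement`: `lambda_hat`, `se_lambda`,
#'   `concentration` (copies/uL), `ci_low`, `ci_high`, `k_pos`, `n_total`,
#'   `droplet_volume`, `target`.
#' @examples
#' estimate_concentration(10000, 20000)  # lambda = log(2), ~815.5 copies/uL
#' @export
estimate_concentration <- function(k_pos, n_total, droplet_volume = 0.00085,
                                   target = "total",
                                   ci_method = c("delta", "exact")) {
  ci_method <- match.arg(ci_method)
  stopifnot_scalar_number(n_total, "n_total", 0, strict_lower = TRUE)
  stopifnot_scalar_number(k_pos, "k_pos", 0)
  stopifnot_scalar_number(droplet_volume, "droplet_volume", 0, strict_lower = TRUE)
  if (k_pos > n_total) stop("`k_pos` cannot exceed `n_total`", call. = FALSE)
  if (k_pos == n_total) {
    stop("saturated well: concentration not estimable (all droplets positive)",
         call. = FALSE)
  }
  p <- k_pos / n_total
  lambda <- -log1p(-p)
  se <- sqrt(p / (n_total * (1 - p)))
  if (k_pos == 0) {
    p_up <- 1 - (0.025)^(1 / n_total)  # Clopper-Pearson upper bound at k = 0
    ci <- c(0, -log1p(-p_up))
  } else if (ci_method == "delta") {
    ci <- c(max(0, lambda - 1.96 * se), lambda + 1.96 * se)
  } else {
    bt <- stats::binom.test(k_pos, n_total)$conf.int
    ci <- -log1p(-bt)
  }
  structure(
    list(target = target,
         lambda_hat = lambda, se_lambda = se,
         concentration = lambda / droplet_volume,
         ci_low = ci[1] / droplet_volume, ci_high = ci[2] / droplet_volume,
         k_pos = as.integer(k_pos), n_total = as.integer(n_total),
         droplet_volume = droplet_volume),
    class = "target_measurement"
  )
}

#' @export
print.target_measurement <- function(x, digits = 4, ...) {
  cat(sprintf("<target_measurement> %s: %.6g copies/uL (95%% CI %.6g-%.6g), lambda=%.6g, k=%d/%d\n",
              x$target, x$concentration, x$ci_low, x$ci_high, x$lambda_hat,
              x$k_pos, x$n_total))
  invisible(x)
}

#' Pool replicate wells before Poisson correction
#'
#' Merging wells of the same sample and target sums the positive and total
#' droplet counts and applies [estimate_concentration()] to the pooled
#' counts. Pooling counts first is not the same as averaging per-well
#' concentrations when well sizes differ, and is the recommended way to
#' combine replicate wells.
#'
#' @param measurements List of `target_measurement` objects with identical
#'   `target` and `droplet_volume`.
#' @param ci_method Passed to [estimate_concentration()].
#' @return A pooled `target_measurement`.
#' @examples
#' a <- estimate_concentration(100, 10000)
#' b <- estimate_concentration(100, 10000)
#' merge_wells(list(a, b))  # identical to estimate_concentration(200, 20000)
#' @export
merge_wells <- function(measurements, ci_method = c("delta", "exact")) {
  if (inherits(measurements, "target_measurement")) {
    measurements <- list(measurements)
  }
  if (length(measurements) < 1) stop("need at least one well", call. = FALSE)
  ok <- vapply(measurements, inherits, logical(1), "target_measurement")
  if (!all(ok)) stop("all elements must be target_measurement", call. = FALSE)
  targets <- unique(vapply(measurements, `[[`, character(1), "target"))
  if (length(targets) != 1) {
    stop("cannot merge wells with mixed targets: ",
         paste(targets, collapse = ", "), call. = FALSE)
  }
  vols <- unique(vapply(measurements, `[[`, numeric(1), "droplet_volume"))
  if (length(vols) != 1) {
    stop("cannot merge wells with different droplet volumes", call. = FALSE)
  }
  k <- sum(vapply(measurements, `[[`, integer(1), "k_pos"))
  n <- sum(vapply(measurements, `[[`, integer(1), "n_total"))
  estimate_concentration(k, n, droplet_volume = vols, target = targets,
                         ci_method = match.arg(ci_method))
}
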