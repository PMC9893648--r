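# Accept either a target_measurement or a bare concentration; bare values
# carry zero sampling error (useful for worked examples and printed ratios).
as_measurement_like <- function(x, name) {
  if (inherits(x, "target_measurement")) {
    list(conc = x$concentration,
         rel_se = if (x$lambda_hat > 0) x$se_lambda / x$lambda_hat else 0)
  } else if (is.numeric(x) && length(x) == 1L && is.finite(x)) {
    list(conc = x, rel_se = 0)
  } else {
    stop(sprintf("`%s` must be a target_measurement or a single number", name),
         call. = FALSE)
  }
}

# Delta-method CI for a ratio of two independent concentration estimates.
ratio_ci <- function(value, rel_se_num, rel_se_den) {
  rel <- sqrt(rel_se_num^2 + rel_se_den^2)
  se <- value * rel
  c(low = max(0, value - 1.96 * se), high = value + 1.96 * se, se = se)
}

#' Transcripts per diploid genome
#'
#' Estimates the per-cell transcript count by dividing the total (WT + MUT)
#' cDNA concentration by the gDNA amplicon concentration from a paired,
#' same-assay measurement, scaled by the diploid factor: each diploid genome
#' contributes two amplicons to the gDNA assay, so with `diploid_factor = 2`
#' (the default) `transcripts = 2 x C_cDNA / C_gDNA`. `scaling` is a
#' user-supplied cDNA/gDNA recovery ratio for split-tube isolations
#' (default 1: both isolations recover comparable per-cell material).
#'
#' @param cdna,gdna Total-target `target_measurement`s (or bare
#'   concentrations in copies/uL) for the cDNA and gDNA aliquots.
#' @param diploid_factor Amplicons per diploid genome counted by the assay.
#' @param scaling cDNA/gDNA recovery ratio.
#' @return A `per_genome_result`: `transcripts_per_diploid_genome`, delta
#'   method `ci_low`/`ci_high`, the input concentrations and parameters.
#' @examples
#' copies_per_diploid_genome(540, 20)  # 54 transcripts per diploid genome
#' @export
copies_per_diploid_genome <- function(cdna, gdna, diploid_factor = 2,
                                      scaling = 1) {
  c_ <- as_measurement_like(cdna, "cdna")
  g_ <- as_measurement_like(gdna, "gdna")
  stopifnot_scalar_number(diploid_factor, "diploid_factor", 0, strict_lower = TRUE)
  stopifnot_scalar_number(scaling, "scaling", 0, strict_lower = TRUE)
  if (g_$conc <= 0) {
    stop("gDNA concentration must be > 0", call. = FALSE)
  }
  value <- diploid_factor * scaling * c_$conc / g_$conc
  ci <- ratio_ci(value, c_$rel_se, g_$rel_se)
  structure(
    list(transcripts_per_diploid_genome = value,
         ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
         se = unname(ci["se"]),
         cdna_conc = c_$conc, gdna_conc = g_$conc,
         diploid_factor = diploid_factor, scaling = scaling),
    class = "per_genome_result"
  )
}

#' @export
print.per_genome_result <- function(x, ...) {
  cat(sprintf("<per_genome_result> %.3g transcripts per diploid genome (95%% CI %.3g-%.3g)\n",
              x$transcripts_per_diploid_genome, x$ci_low, x$ci_high))
  invisible(x)
}

#' Copy number from a duplex CNV assay
#'
#' `cn_total = reference_copies x C_target / C_reference`, the standard
#' copy-number-variation read-out against a reference gene of known copy
#' number (e.g. Rpp30 at two copies per genome). The CI is the delta-method
#' interval for the ratio of independent Poisson-corrected estimates.
#' Homogeneous in the concentrations: scaling both by the same factor leaves
#' the copy number unchanged.
#'
#' @param target,reference `target_measurement`s (or bare concentrations).
#' @param reference_copies Copies of the reference gene per genome
#'   (default 2).
#' @return A `copy_number_result`: `cn_total` (continuous), `cn_total_int`
#'   (nearest integer, ties away from zero), CI; allele partitions are `NA`
#'   until [partition_cn()] is applied.
#' @examples
#' cnv(8.5, 1)          # ratio 8.5, 2-copy reference -> 17 copies
#' @export
cnv <- function(target, reference, reference_copies = 2) {
  t_ <- as_measurement_like(target, "target")
  r_ <- as_measurement_like(reference, "reference")
  stopifnot_scalar_number(reference_copies, "reference_copies", 0,
                          strict_lower = TRUE)
  if (r_$conc <= 0) stop("reference concentration must be > 0", call. = FALSE)
  value <- reference_copies * t_$conc / r_$conc
  ci <- ratio_ci(value, t_$rel_se, r_$rel_se)
  structure(
    list(cn_total = value,
         cn_total_int = round_half_away(value),
         ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
         cn_wt = NA_real_, cn_mut = NA_real_,
         cn_wt_int = NA_real_, cn_mut_int = NA_real_,
         reference_copies = reference_copies),
    class = "copy_number_result"
  )
}

#' @export
print.copy_number_result <- function(x, ...) {
  cat(sprintf("<copy_number_result> total %.4g copies (~%d; 95%% CI %.3g-%.3g)\n",
              x$cn_total, as.integer(x$cn_total_int), x$ci_low, x$ci_high))
  if (!is.na(x$cn_wt)) {
    cat(sprintf("  WT %.4g (~%d), MUT %.4g (~%d)\n",
                x$cn_wt, as.integer(x$cn_wt_int),
                x$cn_mut, as.integer(x$cn_mut_int)))
  }
  invisible(x)
}

#' Partition a total copy number into WT and MUT alleles
#'
#' Splits the total transgene copy number by the allelic fraction measured
#' on genomic DNA: `cn_wt = cn_total x f_wt`, `cn_mut = cn_total x f_mut`.
#' The continuous partitions always sum to the total; the integer report
#' rounds each partition to the nearest integer (ties away from zero).
#'
#' @param cn A `copy_number_result` from [cnv()], or a bare total copy
#'   number.
#' @param fractions An `allelic_result` measured on gDNA, or a bare WT
#'   fraction in `[0, 1]`.
#' @return The `copy_number_result` with `cn_wt`, `cn_mut` and their
#'   integer reports filled in.
#' @examples
#' partition_cn(cnv(8.5, 1), 0.645)  # ~11 WT and ~6 MUT copies
#' @export
partition_cn <- function(cn, fractions) {
  if (!inherits(cn, "copy_number_result")) {
    cn_val <- cn
    stopifnot_scalar_number(cn_val, "cn", 0)
    cn <- structure(
      list(cn_total = cn_val, cn_total_int = round_half_away(cn_val),
           ci_low = NA_real_, ci_high = NA_real_,
           cn_wt = NA_real_, cn_mut = NA_real_,
           cn_wt_int = NA_real_, cn_mut_int = NA_real_,
           reference_copies = NA_real_),
      class = "copy_number_result")
  }
  f_wt <- if (inherits(fractions, "allelic_result")) {
    fractions$f_wt
  } else {
    stopifnot_scalar_number(fractions, "fractions", 0, 1)
    fractions
  }
  cn$cn_wt <- cn$cn_total * f_wt
  cn$cn_mut <- cn$cn_total * (1 - f_wt)
  cn$cn_wt_int <- round_half_away(cn$cn_wt)
  cn$cn_mut_int <- round_half_away(cn$cn_mut)
  cn
}

#' Knockdown efficiency relative to a control group
#'
#' Normalizes target expression to a reference-gene assay within each group
#' (`norm = C_target / C_reference`), takes the treated/control ratio of the
#' normalized values for total, WT and MUT, and reports knockdown as
#' `100 x (1 - relative)` percent. This is the usual relative-expression
#' read-out for siRNA silencing with the control-transfected sample as
#' baseline.
#'
#' @param control,treated Named lists with `wt` and `mut`
#'   `target_measurement`s (or bare concentrations) for each group.
#' @param reference Named list with `control` and `treated` reference-gene
#'   measurements (or bare concentrations).
#' @return A `knockdown_result`: `relative` and `knockdown_pct`, each a
#'   named vector over `total`, `wt`, `mut`.
#' @examples
#' knockdown(control = list(wt = 200, mut = 110),
#'           treated = list(wt = 100, mut = 55),
#'           reference = list(control = 500, treated = 500))
#' @export
knockdown <- function(control, treated, reference) {
  conc <- function(x, name) as_measurement_like(x, name)$conc
  cw <- conc(control$wt, "control$wt"); cm <- conc(control$mut, "control$mut")
  tw <- conc(treated$wt, "treated$wt"); tm <- conc(treated$mut, "treated$mut")
  rc <- conc(reference$control, "reference$control")
  rt <- conc(reference$treated, "reference$treated")
  if (rc <= 0 || rt <= 0) {
    stop("reference-gene concentration must be > 0 in both groups", call. = FALSE)
  }
  ctrl_norm <- c(total = (cw + cm) / rc, wt = cw / rc, mut = cm / rc)
  trt_norm <- c(total = (tw + tm) / rt, wt = tw / rt, mut = tm / rt)
  if (ctrl_norm["total"] <= 0) {
    stop("control expression is zero: relative expression undefined",
         call. = FALSE)
  }
  relative <- trt_norm / ctrl_norm
  relative[ctrl_norm == 0] <- NA_real_  # allele absent in control
  structure(
    list(relative = relative,
         knockdown_pct = 100 * (1 - relative),
         control_norm = ctrl_norm, treated_norm = trt_norm),
    class = "knockdown_result"
  )
}

#' @export
print.knockdown_result <- function(x, ...) {
  cat("<knockdown_result>\n")
  for (t in names(x$relative)) {
    cat(sprintf("  %-6s relative %.3f  knockdown %.1f%%\n",
                t, x$relative[[t]], x$knockdown_pct[[t]]))
  }
  invisible(x)
}
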