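#' Amplitude model for synthetic droplet fluorescence
#'
#' Describes the two-cluster fluorescence distribution of negative and
#' positive droplets on each channel of a duplex ddPCR assay, plus two
#' nuisance features real wells show: "rain" (partially amplified positive
#' droplets with intermediate fluorescence between the clusters) and
#' cross-channel fluorescence shift.
#' All amplitude values are synthetic arbitrary units (a.u.); the defaults
#' (negative mean 2000, positive mean 8000, sd 300) are well-separated
#' stand-ins, not instrument calibrations.
#'
#' @param neg_mean_ch1,neg_mean_ch2 Mean fluorescence of negative droplets.
#' @param pos_mean_ch1,pos_mean_ch2 Mean fluorescence of positive droplets;
#'   must exceed the negative mean on the same channel.
#' @param neg_sd,pos_sd Within-cluster standard deviations (> 0).
#' @param rain_fraction Proportion (in `[0, 0.5)`) of each channel's
#'   template-occupied droplets whose amplitude on that channel is redrawn
#'   uniformly between the cluster means, emulating incomplete
#'   amplification. Rain scales with the positive population, so an empty
#'   well stays clean.
#' @param crosstalk_shift Fluorescence (a.u.) added to the off-channel of a
#'   droplet that is positive on the other channel. Default 0.
#' @return An object of class `amplitude_model`.
#' @examples
#' amplitude_model(rain_fraction = 0.02)
#' @export
amplitude_model <- function(neg_mean_ch1 = 2000, pos_mean_ch1 = 8000,
                            neg_mean_ch2 = 2000, pos_mean_ch2 = 8000,
                            neg_sd = 300, pos_sd = 300,
                            rain_fraction = 0.01, crosstalk_shift = 0) {
  stopifnot_scalar_number(neg_sd, "neg_sd", 0, strict_lower = TRUE)
  stopifnot_scalar_number(pos_sd, "pos_sd", 0, strict_lower = TRUE)
  stopifnot_scalar_number(rain_fraction, "rain_fraction", 0)
  if (rain_fraction >= 0.5) stop("`rain_fraction` must be < 0.5", call. = FALSE)
  stopifnot_scalar_number(crosstalk_shift, "crosstalk_shift")
  if (pos_mean_ch1 <= neg_mean_ch1 || pos_mean_ch2 <= neg_mean_ch2) {
    stop("positive cluster mean must exceed negative cluster mean on each channel",
         call. = FALSE)
  }
  structure(
    list(neg_mean_ch1 = neg_mean_ch1, pos_mean_ch1 = pos_mean_ch1,
         neg_mean_ch2 = neg_mean_ch2, pos_mean_ch2 = pos_mean_ch2,
         neg_sd = neg_sd, pos_sd = pos_sd,
         rain_fraction = rain_fraction, crosstalk_shift = crosstalk_shift),
    class = "amplitude_model"
  )
}

#' Simulation specification for one synthetic ddPCR well
#'
#' Ground truth for the generator: the wild-type and mutant template
#' concentrations, the droplet count and volume, the amplitude model, and
#' the seed. Channel 1 carries the WT probe signal and channel 2 the MUT
#' probe signal, mirroring a duplex SNP-discrimination assay.
#'
#' @param conc_wt,conc_mut True template concentrations in copies/uL (>= 0).
#' @param n_droplets Number of accepted droplets (default 20000, a typical
#'   accepted-droplet count per well).
#' @param droplet_volume Volume of one droplet in uL. Default 0.00085 uL
#'   (0.85 nL, the QX200 convention).
#' @param amplitude_model An [amplitude_model()].
#' @param seed Integer seed; every draw in [simulate_well()] derives from it.
#' @return An object of class `sim_spec`.
#' @examples
#' simulation_spec(conc_wt = 300, conc_mut = 100, seed = 1)
#' @export
simulation_spec <- function(conc_wt, conc_mut, n_droplets = 20000,
                            droplet_volume = 0.00085,
                            amplitude_model = dropquant::amplitude_model(),
                            seed = 1) {
  stopifnot_scalar_number(conc_wt, "conc_wt", 0)
  stopifnot_scalar_number(conc_mut, "conc_mut", 0)
  stopifnot_scalar_number(n_droplets, "n_droplets", 0, strict_lower = TRUE)
  stopifnot_scalar_number(droplet_volume, "droplet_volume", 0, strict_lower = TRUE)
  if (!inherits(amplitude_model, "amplitude_model")) {
    stop("`amplitude_model` must be created by amplitude_model()", call. = FALSE)
  }
  structure(
    list(conc_wt = conc_wt, conc_mut = conc_mut,
         n_droplets = as.integer(n_droplets),
         droplet_volume = droplet_volume,
         amplitude_model = amplitude_model, seed = seed),
    class = "sim_spec"
  )
}

#' Simulate one ddPCR well
#'
#' Inverts the Poisson quantification model: each droplet independently
#' receives WT copies ~ Poisson(conc_wt x droplet_volume) and MUT copies ~
#' Poisson(conc_mut x droplet_volume). A droplet occupied by a target emits
#' in that channel's positive amplitude cluster (both targets -> double
#' positive); unoccupied droplets emit in the negative cluster. Per channel,
#' a `rain_fraction` subset of the occupied droplets is then redrawn
#' uniformly between the two cluster means (partial amplification). The true
#' occupancy and rain labels are kept on the returned well so classification
#' can be audited against ground truth.
#'
#' If the expected positive fraction `1 - exp(-lambda)` exceeds 0.999 on a
#' channel the well is flagged as saturated (not an error): such wells carry
#' almost no quantitative information.
#'
#' @param spec A [simulation_spec()].
#' @param well_id,sample_id,assay_id Labels attached to the well.
#' @return A `droplet_well`: list with `amplitudes` (data.frame of `ch1`,
#'   `ch2`), `accepted_count`, identifying labels, `saturated` flags per
#'   channel, and a `labels` data.frame (`occ_wt`, `occ_mut`, `rain_ch1`,
#'   `rain_ch2`).
#' @examples
#' w <- simulate_well(simulation_spec(300, 100, seed = 7))
#' w$accepted_count
#' @seealso [classify()], [ddpcr_fit()]
#' @export
simulate_well <- function(spec, well_id = "A01", sample_id = "sample",
                          assay_id = "assay") {
  if (!inherits(spec, "sim_spec")) {
    stop("`spec` must be created by simulation_spec()", call. = FALSE)
  }
  n <- spec$n_droplets
  am <- spec$amplitude_model
  lambda_wt <- spec$conc_wt * spec$droplet_volume
  lambda_mut <- spec$conc_mut * spec$droplet_volume

  draws <- with_local_seed(spec$seed, {
    occ_wt <- stats::rpois(n, lambda_wt) > 0L
    occ_mut <- stats::rpois(n, lambda_mut) > 0L
    ch1 <- stats::rnorm(n,
                        mean = ifelse(occ_wt, am$pos_mean_ch1, am$neg_mean_ch1),
                        sd = ifelse(occ_wt, am$pos_sd, am$neg_sd))
    ch2 <- stats::rnorm(n,
                        mean = ifelse(occ_mut, am$pos_mean_ch2, am$neg_mean_ch2),
                        sd = ifelse(occ_mut, am$pos_sd, am$neg_sd))
    if (am$crosstalk_shift != 0) {
      ch1 <- ch1 + am$crosstalk_shift * (occ_mut & !occ_wt)
      ch2 <- ch2 + am$crosstalk_shift * (occ_wt & !occ_mut)
    }
    make_rain <- function(occ) {
      rain <- rep(FALSE, n)
      idx <- which(occ)
      n_rain <- round(am$rain_fraction * length(idx))
      if (n_rain > 0) {
        rain[if (length(idx) == 1) idx else sample(idx, n_rain)] <- TRUE
      }
      rain
    }
    rain1 <- make_rain(occ_wt)
    rain2 <- make_rain(occ_mut)
    ch1[rain1] <- stats::runif(sum(rain1), am$neg_mean_ch1, am$pos_mean_ch1)
    ch2[rain2] <- stats::runif(sum(rain2), am$neg_mean_ch2, am$pos_mean_ch2)
    list(occ_wt = occ_wt, occ_mut = occ_mut, ch1 = ch1, ch2 = ch2,
         rain_ch1 = rain1, rain_ch2 = rain2)
  })

  structure(
    list(well_id = well_id, sample_id = sample_id, assay_id = assay_id,
         amplitudes = data.frame(ch1 = draws$ch1, ch2 = draws$ch2),
         accepted_count = n,
         saturated = c(ch1 = 1 - exp(-lambda_wt) > 0.999,
                       ch2 = 1 - exp(-lambda_mut) > 0.999),
         labels = data.frame(occ_wt = draws$occ_wt, occ_mut = draws$occ_mut,
                             rain_ch1 = draws$rain_ch1,
                             rain_ch2 = draws$rain_ch2)),
    class = "droplet_well"
  )
}

#' @export
print.droplet_well <- function(x, ...) {
  cat(sprintf("<droplet_well> %s  sample=%s assay=%s  %d droplets%s\n",
              x$well_id, x$sample_id, x$assay_id, x$accepted_count,
              if (any(x$saturated)) "  [SATURATED]" else ""))
  invisible(x)
}

#' Construct a droplet well from raw amplitudes
#'
#' Used by the readers and available for wrapping externally produced
#' amplitude tables. No ground-truth labels are attached.
#'
#' @param ch1,ch2 Numeric amplitude vectors of equal length, finite.
#' @param well_id,sample_id,assay_id Labels.
#' @return A `droplet_well`.
#' @export
droplet_well <- function(ch1, ch2, well_id = "A01", sample_id = "sample",
                         assay_id = "assay") {
  if (length(ch1) != length(ch2)) {
    stop("channel amplitude vectors must have equal length", call. = FALSE)
  }
  if (!all(is.finite(ch1)) || !all(is.finite(ch2))) {
    stop("amplitudes must be finite", call. = FALSE)
  }
  structure(
    list(well_id = well_id, sample_id = sample_id, assay_id = assay_id,
         amplitudes = data.frame(ch1 = as.numeric(ch1), ch2 = as.numeric(ch2)),
         accepted_count = length(ch1),
         saturated = c(ch1 = FALSE, ch2 = FALSE),
         labels = NULL),
    class = "droplet_well"
  )
}

#' Simulate a named experimental design
#'
#' Builds the multi-well designs the analysis functions consume:
#' \describe{
#'   \item{`mixture_series`}{Seven plasmid mixtures I-VII at a fixed total
#'     concentration with WT fractions 1.0, 0.9, 0.75, 0.5, 0.25, 0.1, 0.0 --
#'     the assay-specificity validation series.}
#'   \item{`het_gdna`}{Replicate genomic-DNA wells with equal WT and MUT
#'     concentrations -- the heterozygous 50:50 control.}
#'   \item{`paired_cdna_gdna`}{Replicate pairs of cDNA and gDNA wells from
#'     the same notional cells, for transcripts-per-diploid-genome.}
#'   \item{`knockdown`}{Control and treated duplex wells plus single-channel
#'     reference-gene wells in both groups, for silencing efficiency.}
#' }
#'
#' @param design Design name (see above).
#' @param seed Base integer seed; each well gets a seed derived from it.
#' @param ... Design parameters overriding the defaults below.
#'
#' @section Design parameters:
#' `mixture_series`: `total_conc` (400), `wt_fractions`
#' (`c(1, .9, .75, .5, .25, .1, 0)`), `n_replicates` (1).
#' `het_gdna`: `conc` (100, per allele), `n_replicates` (3).
#' `paired_cdna_gdna`: `cdna_total` (540), `gdna_total` (20), `wt_fraction`
#' (0.5), `n_replicates` (3).
#' `knockdown`: `control` (`c(200, 110)`), `treated` (`c(100, 55)`),
#' `reference_conc` (500), `n_replicates` (3).
#' All designs accept `n_droplets`, `droplet_volume`, `amplitude_model`.
#'
#' @return List with `wells` (list of `droplet_well`) and `metadata`
#'   (data.frame: `well_id`, `sample_id`, `assay_id`, `material`, `group`,
#'   `replicate`).
#' @examples
#' ex <- simulate_experiment("het_gdna", seed = 3)
#' ex$metadata
#' @export
simulate_experiment <- function(design, seed = 1, ...) {
  opts <- list(...)
  common <- list(
    n_droplets = opts$n_droplets %||% 20000,
    droplet_volume = opts$droplet_volume %||% 0.00085,
    amplitude_model = opts$amplitude_model %||% amplitude_model()
  )
  builder <- switch(design,
    mixture_series = build_mixture_series,
    het_gdna = build_het_gdna,
    paired_cdna_gdna = build_paired_cdna_gdna,
    knockdown = build_knockdown,
    stop(sprintf("unknown design '%s'", design), call. = FALSE)
  )
  plan <- builder(opts)
  wells <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    spec <- simulation_spec(conc_wt = plan$conc_wt[i], conc_mut = plan$conc_mut[i],
                            n_droplets = common$n_droplets,
                            droplet_volume = common$droplet_volume,
                            amplitude_model = common$amplitude_model,
                            seed = derive_seed(seed, i))
    wells[[i]] <- simulate_well(spec, well_id = plan$well_id[i],
                                sample_id = plan$sample_id[i],
                                assay_id = plan$assay_id[i])
  }
  metadata <- plan[, c("well_id", "sample_id", "assay_id", "material",
                       "group", "replicate")]
  rownames(metadata) <- NULL
  list(wells = wells, metadata = metadata,
       truth = plan[, c("well_id", "conc_wt", "conc_mut")])
}

well_ids <- function(n) sprintf("%s%02d", LETTERS[(seq_len(n) - 1) %/% 12 + 1],
                                (seq_len(n) - 1) %% 12 + 1)

build_mixture_series <- function(opts) {
  total <- opts$total_conc %||% 400
  fr <- opts$wt_fractions %||% c(1, 0.9, 0.75, 0.5, 0.25, 0.1, 0)
  reps <- opts$n_replicates %||% 1
  samples <- as.character(utils::as.roman(seq_along(fr)))
  plan <- expand.grid(replicate = seq_len(reps), i = seq_along(fr))
  data.frame(
    well_id = well_ids(nrow(plan)),
    sample_id = samples[plan$i],
    assay_id = "duplex_snp",
    material = "plasmid",
    group = "mixture_series",
    replicate = plan$replicate,
    conc_wt = total * fr[plan$i],
    conc_mut = total * (1 - fr[plan$i]),
    stringsAsFactors = FALSE
  )
}

build_het_gdna <- function(opts) {
  conc <- opts$conc %||% 100
  reps <- opts$n_replicates %||% 3
  data.frame(
    well_id = well_ids(reps),
    sample_id = "het_gdna",
    assay_id = "duplex_snp",
    material = "gDNA",
    group = "het_gdna",
    replicate = seq_len(reps),
    conc_wt = conc, conc_mut = conc,
    stringsAsFactors = FALSE
  )
}

build_paired_cdna_gdna <- function(opts) {
  cdna <- opts$cdna_total %||% 540
  gdna <- opts$gdna_total %||% 20
  f <- opts$wt_fraction %||% 0.5
  reps <- opts$n_replicates %||% 3
  plan <- expand.grid(replicate = seq_len(reps),
                      material = c("cDNA", "gDNA"),
                      stringsAsFactors = FALSE)
  total <- ifelse(plan$material == "cDNA", cdna, gdna)
  data.frame(
    well_id = well_ids(nrow(plan)),
    sample_id = paste0(tolower(plan$material), "_rep", plan$replicate),
    assay_id = "duplex_snp",
    material = plan$material,
    group = "paired",
    replicate = plan$replicate,
    conc_wt = total * f,
    conc_mut = total * (1 - f),
    stringsAsFactors = FALSE
  )
}

build_knockdown <- function(opts) {
  control <- opts$control %||% c(200, 110)
  treated <- opts$treated %||% c(100, 55)
  ref <- opts$reference_conc %||% 500
  reps <- opts$n_replicates %||% 3
  plan <- expand.grid(replicate = seq_len(reps),
                      assay = c("target", "reference"),
                      group = c("control", "treated"),
                      stringsAsFactors = FALSE)
  conc_wt <- ifelse(plan$assay == "reference", ref,
                    ifelse(plan$group == "control", control[1], treated[1]))
  conc_mut <- ifelse(plan$assay == "reference", 0,
                     ifelse(plan$group == "control", control[2], treated[2]))
  data.frame(
    well_id = well_ids(nrow(plan)),
    sample_id = paste0(plan$group, "_", plan$assay, "_rep", plan$replicate),
    assay_id = ifelse(plan$assay == "reference", "reference", "duplex_snp"),
    material = "cDNA",
    group = plan$group,
    replicate = plan$replicate,
    conc_wt = conc_wt, conc_mut = conc_mut,
    stringsAsFactors = FALSE
  )
}

#' Simulate per-SNP allele read counts
#'
#' Generates the RNA-seq cross-check input: for each SNP, the WT read count
#' is Binomial(depth, true_fraction) and the MUT count is the remainder.
#'
#' @param true_fraction True WT allele fraction in `[0, 1]`.
#' @param depth_per_snp Read depth per SNP (single value or one per SNP, > 0).
#' @param n_snps Number of SNPs.
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @param snp_ids Optional SNP labels (default `snp1..snpN`).
#' @return data.frame with columns `snp_id`, `sample_id`, `wt_count`,
#'   `mut_count`.
#' @examples
#' simulate_snp_counts(0.747, depth_per_snp = 5000, n_snps = 3, seed = 1)
#' @export
simulate_snp_counts <- function(true_fraction, depth_per_snp, n_snps, seed,
                                sample_id = "sample",
                                snp_ids = paste0("snp", seq_len(n_snps))) {
  stopifnot_scalar_number(true_fraction, "true_fraction", 0, 1)
  if (any(depth_per_snp <= 0)) stop("depths must be > 0", call. = FALSE)
  depth <- rep_len(as.integer(depth_per_snp), n_snps)
  wt <- with_local_seed(seed, stats::rbinom(n_snps, depth, true_fraction))
  data.frame(snp_id = snp_ids, sample_id = sample_id,
             wt_count = wt, mut_count = depth - wt,
             stringsAsFactors = FALSE)
}
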