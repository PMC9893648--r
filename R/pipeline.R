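config_error <- function(msgs) {
  stop(structure(class = c("dropquant_config_error", "error", "condition"),
                 list(message = paste(msgs, collapse = "\n"), call = NULL)))
}

required_config <- function(config, keys, subcommand) {
  missing <- setdiff(keys, names(config))
  if (length(missing)) {
    config_error(sprintf("config for '%s' is missing key '%s'",
                         subcommand, missing))
  }
}

resolve_assays <- function(config) {
  defs <- config$assays
  if (is.null(defs)) {
    defs <- list(list(assay_id = "duplex_snp", ch1_allele = "WT",
                      ch2_allele = "MUT"),
                 list(assay_id = "reference", ch1_allele = "reference",
                      ch2_allele = NA_character_))
  }
  out <- list()
  for (d in defs) {
    a <- assay_definition(d$assay_id, gene = d$gene %||% NA_character_,
                          rs_id = d$rs_id %||% NA_character_,
                          ch1_allele = d$ch1_allele %||% "WT",
                          ch2_allele = d$ch2_allele %||% "MUT")
    out[[a$assay_id]] <- a
  }
  out
}

load_wells <- function(config) {
  required_config(config, c("amplitude_dir", "metadata"), "quantify")
  meta <- if (is.character(config$metadata)) {
    utils::read.delim(config$metadata, stringsAsFactors = FALSE)
  } else {
    as.data.frame(config$metadata, stringsAsFactors = FALSE)
  }
  req <- c("well_id", "sample_id", "assay_id", "file")
  if (!all(req %in% names(meta))) {
    config_error(paste("plate metadata needs columns:",
                       paste(req, collapse = ", ")))
  }
  if (anyDuplicated(meta$well_id)) {
    config_error("plate metadata has duplicated well_ids")
  }
  wells <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    f <- file.path(config$amplitude_dir, meta$file[i])
    if (!file.exists(f)) {
      stop("amplitude file not found: ", f, call. = FALSE)
    }
    wells[[i]] <- read_amplitude_csv(f, well_id = meta$well_id[i],
                                     sample_id = meta$sample_id[i],
                                     assay_id = meta$assay_id[i])
  }
  list(wells = wells, metadata = meta)
}

# Per-assay thresholds under the configured mode: "auto" (per well, resolved
# later), "plate" (pooled across wells of the same assay), or fixed numeric.
resolve_thresholds <- function(mode, wells, metadata, assays) {
  if (identical(mode, "auto") || is.null(mode)) return("auto")
  if (is.numeric(mode) && length(mode) == 2) {
    return(stats::setNames(rep(list(mode), length(assays)), names(assays)))
  }
  if (identical(mode, "plate")) {
    out <- list()
    for (aid in unique(metadata$assay_id)) {
      sel <- wells[metadata$assay_id == aid]
      a <- assays[[aid]]
      th <- c(ch1 = Inf, ch2 = Inf)
      if (is.null(a) || !is.na(a$ch1_allele)) {
        th["ch1"] <- auto_threshold(unlist(lapply(sel, function(w) w$amplitudes$ch1)))
      }
      if (is.null(a) || !is.na(a$ch2_allele)) {
        th["ch2"] <- auto_threshold(unlist(lapply(sel, function(w) w$amplitudes$ch2)))
      }
      out[[aid]] <- unname(th)
    }
    return(out)
  }
  config_error("`thresholds` must be \"auto\", \"plate\" or a numeric pair")
}

well_thresholds <- function(thresholds, well, assay) {
  if (identical(thresholds, "auto")) {
    th <- c(Inf, Inf)
    if (is.null(assay) || !is.na(assay$ch1_allele)) {
      th[1] <- auto_threshold(well$amplitudes$ch1)
    }
    if (is.null(assay) || !is.na(assay$ch2_allele)) {
      th[2] <- auto_threshold(well$amplitudes$ch2)
    }
    return(th)
  }
  thresholds[[well$assay_id]] %||% config_error(
    sprintf("no thresholds for assay '%s'", well$assay_id))
}

# Fit every well against its assay definition; returns per-target rows plus
# the fitted objects keyed by well_id.
quantify_wells <- function(wells, metadata, config, log) {
  assays <- resolve_assays(config)
  vol <- config$droplet_volume %||% 0.00085
  mind <- config$min_droplets %||% 10000
  cim <- config$ci_method %||% "delta"
  thresholds <- resolve_thresholds(config$thresholds %||% "plate",
                                   wells, metadata, assays)
  fits <- list()
  rows <- list()
  for (i in seq_along(wells)) {
    w <- wells[[i]]
    a <- assays[[w$assay_id]] %||% assay_definition(w$assay_id)
    th <- well_thresholds(thresholds, w, a)
    fit <- ddpcr_fit(w, thresholds = th, droplet_volume = vol,
                     ch1_allele = a$ch1_allele, ch2_allele = a$ch2_allele,
                     min_droplets = mind, ci_method = cim)
    if (fit$classified$low_droplet_flag) {
      log(sprintf("QC: well %s has fewer than %d droplets", w$well_id, mind))
    }
    if (any(w$saturated)) {
      log(sprintf("QC: well %s flagged saturated", w$well_id))
    }
    fits[[w$well_id]] <- fit
    for (m in fit$measurements) {
      rows[[length(rows) + 1L]] <- data.frame(
        well_id = w$well_id, sample_id = w$sample_id, assay_id = w$assay_id,
        target = m$target, k_pos = m$k_pos, n_total = m$n_total,
        lambda_hat = m$lambda_hat, concentration = m$concentration,
        ci_low = m$ci_low, ci_high = m$ci_high,
        threshold_ch1 = fit$classified$threshold_ch1,
        threshold_ch2 = fit$classified$threshold_ch2,
        low_droplet_flag = fit$classified$low_droplet_flag,
        stringsAsFactors = FALSE)
    }
  }
  list(fits = fits, table = do.call(rbind, rows), metadata = metadata)
}

# Pool replicate wells for one target of one selection of the metadata.
pooled_measurement <- function(fits, metadata, select, target, ci_method = "delta") {
  ids <- metadata$well_id[select]
  if (!length(ids)) stop("no wells matched the selection", call. = FALSE)
  ms <- lapply(ids, function(id) fits[[id]]$measurements[[target]])
  ms <- Filter(Negate(is.null), ms)
  if (!length(ms)) {
    stop(sprintf("target '%s' not measured in the selected wells", target),
         call. = FALSE)
  }
  merge_wells(ms, ci_method = ci_method)
}

#' Total (WT + MUT) concentration from a duplex measurement
#'
#' Sums the WT and MUT Poisson rates of one well (or pooled wells) into a
#' single total-target measurement; standard errors add in quadrature since
#' the two rates are estimated from independent channel counts.
#'
#' @param m_wt,m_mut `target_measurement`s with the same droplet volume.
#' @return A `target_measurement` with `target = "total"`.
#' @export
total_concentration <- function(m_wt, m_mut) {
  if (!inherits(m_wt, "target_measurement") ||
      !inherits(m_mut, "target_measurement")) {
    stop("inputs must be target_measurement objects", call. = FALSE)
  }
  if (m_wt$droplet_volume != m_mut$droplet_volume) {
    stop("droplet volumes differ", call. = FALSE)
  }
  lambda <- m_wt$lambda_hat + m_mut$lambda_hat
  se <- sqrt(m_wt$se_lambda^2 + m_mut$se_lambda^2)
  vol <- m_wt$droplet_volume
  structure(
    list(target = "total", lambda_hat = lambda, se_lambda = se,
         concentration = lambda / vol,
         ci_low = max(0, lambda - 1.96 * se) / vol,
         ci_high = (lambda + 1.96 * se) / vol,
         k_pos = NA_integer_, n_total = m_wt$n_total,
         droplet_volume = vol),
    class = "target_measurement"
  )
}

#' Run one pipeline subcommand
#'
#' End-to-end orchestration over the module functions. All inputs come from
#' one configuration (a YAML file path or an equivalent named list); outputs
#' are TSV files written to `output_dir`, together with the resolved
#' configuration (`resolved_config.yaml`) and a run log (`run.log`) for
#' provenance. Identical config and seed give byte-identical outputs.
#'
#' @section Subcommands and their config keys:
#' \describe{
#'   \item{`simulate`}{`design`, `seed`, optional design parameters (see
#'     [simulate_experiment()]). Writes one amplitude CSV per well,
#'     `metadata.tsv` (with a `file` column) and `truth.tsv`.}
#'   \item{`quantify`}{`amplitude_dir`, `metadata`, optional `assays`,
#'     `droplet_volume`, `thresholds` (`"auto"`, `"plate"` (default) or a
#'     numeric pair), `min_droplets`, `ci_method`. Writes
#'     `concentrations.tsv`.}
#'   \item{`allelic`}{As `quantify`; additionally writes `allelic.tsv`
#'     (per well) and `allelic_summary.tsv` (replicate/assay summaries).}
#'   \item{`pergenome`}{As `quantify` plus `diploid_factor` (default 2) and
#'     `scaling` (default 1); metadata must carry `material` with `cDNA`
#'     and `gDNA` wells. Writes `pergenome.tsv`.}
#'   \item{`cnv`}{As `quantify` plus `target_assay_id`,
#'     `reference_assay_id`, `reference_copies` (default 2), optional
#'     `gdna_wt_fraction` to partition alleles. Writes `cnv.tsv`.}
#'   \item{`knockdown`}{As `quantify` plus `target_assay_id`,
#'     `reference_assay_id`; metadata must carry `group` with `control` and
#'     `treated` wells. Writes `knockdown.tsv`.}
#'   \item{`ase`}{`snp_counts` (TSV path), optional `method`. Writes
#'     `ase_per_snp.tsv` and `ase_aggregate.tsv`.}
#' }
#'
#' @param subcommand One of `"simulate"`, `"quantify"`, `"allelic"`,
#'   `"pergenome"`, `"cnv"`, `"knockdown"`, `"ase"`.
#' @param config YAML file path or named list.
#' @param output_dir Output directory (created if needed).
#' @param quiet Suppress progress messages (they always go to the log file).
#' @return Invisibly, a named list of the result data.frames written.
#' @examples
#' \donttest{
#' dir <- tempfile(); dir.create(dir)
#' run_pipeline("simulate", list(design = "het_gdna", seed = 1), dir)
#' run_pipeline("allelic",
#'              list(amplitude_dir = dir,
#'                   metadata = file.path(dir, "metadata.tsv")), dir)
#' }
#' @export
run_pipeline <- function(subcommand, config, output_dir, quiet = FALSE) {
  subcommands <- c("simulate", "quantify", "allelic", "pergenome", "cnv",
                   "knockdown", "ase")
  if (!subcommand %in% subcommands) {
    config_error(sprintf("unknown subcommand '%s' (expected one of: %s)",
                         subcommand, paste(subcommands, collapse = ", ")))
  }
  if (is.character(config)) config <- read_run_config(config)
  if (!is.list(config)) config_error("`config` must be a list or a YAML path")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  log_lines <- character()
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  log(sprintf("dropquant %s | subcommand: %s",
              as.character(utils::packageVersion("dropquant")), subcommand))

  results <- switch(subcommand,
    simulate = pipeline_simulate(config, output_dir, log),
    ase = pipeline_ase(config, output_dir, log),
    pipeline_analysis(subcommand, config, output_dir, log)
  )

  yaml::write_yaml(config, file.path(output_dir, "resolved_config.yaml"))
  writeLines(log_lines, file.path(output_dir, "run.log"))
  invisible(results)
}

pipeline_simulate <- function(config, output_dir, log) {
  required_config(config, c("design", "seed"), "simulate")
  params <- config[setdiff(names(config), c("design", "seed", "amplitude"))]
  if (is.list(config$amplitude)) {
    params$amplitude_model <- do.call(amplitude_model, config$amplitude)
  }
  ex <- do.call(simulate_experiment,
                c(list(design = config$design, seed = config$seed), params))
  meta <- ex$metadata
  meta$file <- paste0(meta$well_id, ".csv")
  for (i in seq_along(ex$wells)) {
    write_amplitude_csv(ex$wells[[i]], file.path(output_dir, meta$file[i]))
  }
  utils::write.table(meta, file.path(output_dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_results(ex$truth, file.path(output_dir, "truth.tsv"))
  log(sprintf("simulated %d wells for design '%s' (seed %s)",
              nrow(meta), config$design, config$seed))
  list(metadata = meta, truth = ex$truth)
}

pipeline_ase <- function(config, output_dir, log) {
  required_config(config, "snp_counts", "ase")
  tab <- read_snp_counts(config$snp_counts)
  per <- per_snp_fraction(tab)
  agg <- aggregate_fraction(tab, method = config$method %||% "mean_of_snps")
  write_results(per, file.path(output_dir, "ase_per_snp.tsv"))
  write_results(agg, file.path(output_dir, "ase_aggregate.tsv"))
  log(sprintf("ase: %d SNP rows, %d sample(s)", nrow(per), nrow(agg)))
  list(per_snp = per, aggregate = agg)
}

pipeline_analysis <- function(subcommand, config, output_dir, log) {
  loaded <- load_wells(config)
  q <- quantify_wells(loaded$wells, loaded$metadata, config, log)
  write_results(q$table, file.path(output_dir, "concentrations.tsv"))
  out <- list(concentrations = q$table)
  meta <- loaded$metadata
  cim <- config$ci_method %||% "delta"

  if (subcommand == "allelic") {
    fr <- Filter(Negate(is.null), lapply(q$fits, `[[`, "allelic"))
    if (!length(fr)) stop("no duplex WT/MUT wells to analyze", call. = FALSE)
    tab <- allelic_results_table(unname(fr))
    export <- data.frame(
      sample_id = tab$sample_id, assay_id = tab$assay_id,
      f_wt_pct = round(100 * tab$f_wt, 1),
      f_mut_pct = round(100 * tab$f_mut, 1),
      se_pct = round(100 * tab$se_f, 2),
      ci_low_pct = round(100 * tab$ci_low, 1),
      ci_high_pct = round(100 * tab$ci_high, 1),
      n_droplets = tab$n_droplets, stringsAsFactors = FALSE)
    write_results(export, file.path(output_dir, "allelic.tsv"))
    summ <- summarize_replicates(unname(fr))
    write_results(summ, file.path(output_dir, "allelic_summary.tsv"))
    out$allelic <- tab
    out$summary <- summ
  } else if (subcommand == "pergenome") {
    if (!"material" %in% names(meta)) {
      config_error("pergenome needs a `material` column in the metadata")
    }
    total_for <- function(material) {
      sel <- meta$material == material
      wt <- pooled_measurement(q$fits, meta, sel, "WT", cim)
      mut <- pooled_measurement(q$fits, meta, sel, "MUT", cim)
      total_concentration(wt, mut)
    }
    pg <- copies_per_diploid_genome(total_for("cDNA"), total_for("gDNA"),
                                    diploid_factor = config$diploid_factor %||% 2,
                                    scaling = config$scaling %||% 1)
    tab <- data.frame(transcripts_per_diploid_genome = pg$transcripts_per_diploid_genome,
                      ci_low = pg$ci_low, ci_high = pg$ci_high,
                      cdna_conc = pg$cdna_conc, gdna_conc = pg$gdna_conc,
                      diploid_factor = pg$diploid_factor, scaling = pg$scaling)
    write_results(tab, file.path(output_dir, "pergenome.tsv"))
    log(sprintf("pergenome: %.3g transcripts per diploid genome",
                pg$transcripts_per_diploid_genome))
    out$pergenome <- tab
  } else if (subcommand == "cnv") {
    required_config(config, c("target_assay_id", "reference_assay_id"), "cnv")
    pool_total <- function(aid) {
      sel <- meta$assay_id == aid
      fit1 <- q$fits[[meta$well_id[which(sel)[1]]]]
      targets <- names(fit1$measurements)
      if (all(c("WT", "MUT") %in% targets)) {
        total_concentration(pooled_measurement(q$fits, meta, sel, "WT", cim),
                            pooled_measurement(q$fits, meta, sel, "MUT", cim))
      } else {
        pooled_measurement(q$fits, meta, sel, targets[1], cim)
      }
    }
    cn <- cnv(pool_total(config$target_assay_id),
              pool_total(config$reference_assay_id),
              reference_copies = config$reference_copies %||% 2)
    if (!is.null(config$gdna_wt_fraction)) {
      cn <- partition_cn(cn, config$gdna_wt_fraction)
    }
    tab <- data.frame(cn_total = cn$cn_total, cn_total_int = cn$cn_total_int,
                      ci_low = cn$ci_low, ci_high = cn$ci_high,
                      cn_wt = cn$cn_wt, cn_wt_int = cn$cn_wt_int,
                      cn_mut = cn$cn_mut, cn_mut_int = cn$cn_mut_int)
    write_results(tab, file.path(output_dir, "cnv.tsv"))
    log(sprintf("cnv: %.3g total copies", cn$cn_total))
    out$cnv <- tab
  } else if (subcommand == "knockdown") {
    required_config(config, c("target_assay_id", "reference_assay_id"),
                    "knockdown")
    if (!"group" %in% names(meta)) {
      config_error("knockdown needs a `group` column in the metadata")
    }
    grab <- function(group, assay, target) {
      pooled_measurement(q$fits, meta,
                         meta$group == group & meta$assay_id == assay,
                         target, cim)
    }
    kd <- knockdown(
      control = list(wt = grab("control", config$target_assay_id, "WT"),
                     mut = grab("control", config$target_assay_id, "MUT")),
      treated = list(wt = grab("treated", config$target_assay_id, "WT"),
                     mut = grab("treated", config$target_assay_id, "MUT")),
      reference = list(
        control = grab("control", config$reference_assay_id, "reference"),
        treated = grab("treated", config$reference_assay_id, "reference"))
    )
    tab <- data.frame(target = names(kd$relative),
                      relative = unname(kd$relative),
                      knockdown_pct = unname(kd$knockdown_pct))
    write_results(tab, file.path(output_dir, "knockdown.tsv"))
    log(sprintf("knockdown: total %.1f%%", kd$knockdown_pct[["total"]]))
    out$knockdown <- tab
  }
  out
}
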