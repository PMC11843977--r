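#' Read a tidy observed-concentration dataset
#'
#' Expected columns: `tissue`, `time_h`, `conc_nM` and optionally
#' `replicate`. Units must already be h and nmol/L.
#'
#' @param path CSV path.
#' @return data.frame suitable for [fit_mrt_parameters()] and [nca_table()].
#' @export
read_observed_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue", "time_h", "conc_nM")
  if (!all(need %in% names(df))) {
    stop("dataset must have columns: ", paste(need, collapse = ", "))
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (any(!is.finite(df$time_h)) || any(df$time_h < 0)) stop("invalid times")
  if (any(!is.finite(df$conc_nM)) || any(df$conc_nM < 0)) {
    stop("concentrations must be finite and non-negative")
  }
  df
}

#' Write a dataset or tissue table as CSV
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load the packaged printed AUC table
#'
#' The per-tissue predicted and observed AUC pairs (h*nmol/L) reported for
#' the mouse study, shipped as a plain-text input for the worked-example
#' metrics.
#'
#' @return data.frame with columns `tissue`, `auc_pred`, `auc_obs`.
#' @export
load_printed_auc <- function() {
  read.csv(.extdata("mouse_auc_printed.csv"), stringsAsFactors = FALSE)
}

#' Run a complete workflow from a configuration
#'
#' A thin driver over the package functions, used by the command-line
#' script. `config` is a list (or path to a JSON file) with elements
#' `species`, `body_weight`, `dose` (mg/kg), `times`, `seed`, `out_dir`,
#' plus command-specific fields. Every run writes a provenance JSON next to
#' its outputs recording the resolved configuration and package version, so
#' a deterministic run can be reproduced bit-for-bit from its dump.
#'
#' @param command one of `"simulate"`, `"nca"`, `"fit"`, `"sensitivity"`,
#'   `"synth"`, `"translate"`, `"physiology"`.
#' @param config list or JSON path.
#' @return list of result objects (also written to `out_dir` when set).
#' @export
run_workflow <- function(command = c("simulate", "nca", "fit", "sensitivity",
                                     "synth", "translate", "physiology"),
                         config = list()) {
  command <- match.arg(command)
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(
    list(species = "mouse", body_weight = NULL, dose = 10, times = study_times(),
         seed = 1, out_dir = NULL, perfused = TRUE, perturb = 0.2,
         to = "human", data = NULL, parameters = NULL),
    config
  )
  if (!cfg$species %in% .SPECIES) {
    stop("schema error: unknown species '", cfg$species, "'")
  }
  sp <- load_species_physiology(cfg$species, body_weight = cfg$body_weight)
  bw <- sp$body_weight
  ctx <- model_context(sp, dose = dose_event(dose_mg_per_kg = cfg$dose,
                                             body_weight = bw))
  emit <- function(obj, file) {
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_dataset(obj, file.path(cfg$out_dir, file))
      prov <- list(package = "mrtpbpk",
                   version = as.character(utils::packageVersion("mrtpbpk")),
                   command = command, seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), "out_dir")])
      jsonlite::write_json(prov, file.path(cfg$out_dir, paste0(command, "_provenance.json")),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    obj
  }

  switch(command,
    simulate = {
      sim <- simulate_pbpk(system = build_pbpk_system(sp, ctx$gk, ctx$mrt),
                           doses = ctx$dose, times = cfg$times)
      emit(tissue_concentrations(sim, perfused = cfg$perfused), "simulation.csv")
    },
    nca = {
      if (is.null(cfg$data)) stop("schema error: nca requires 'data'")
      pred <- read_observed_dataset(cfg$data)
      obs <- if (!is.null(cfg$observed)) read_observed_dataset(cfg$observed) else NULL
      emit(nca_table(pred, obs), "nca.csv")
    },
    fit = {
      if (is.null(cfg$data)) stop("schema error: fit requires 'data'")
      ds <- read_observed_dataset(cfg$data)
      pars <- if (is.null(cfg$parameters)) c("Q_ep", "Q_vd", "Q_sv", "Q_pg", "CLup_BTB") else cfg$parameters
      fit <- fit_mrt_parameters(ds, fit_spec(pars), error_model(), ctx)
      emit(data.frame(parameter = fit$parameters, estimate = fit$estimates,
                      se = fit$se, cv_percent = fit$cv_percent), "fit.csv")
    },
    sensitivity = {
      sens <- local_sensitivity(ctx, perturbation = cfg$perturb)
      emit(as.data.frame(sens), "sensitivity.csv")
    },
    synth = {
      ds <- generate_dataset(ctx, study_design(dose = ctx$dose), seed = cfg$seed)
      emit(ds, "obs_synth.csv")
    },
    translate = {
      tsp <- translate_physiology("mouse", cfg$to)
      emit(tsp$organs, paste0("physiology_", cfg$to, ".csv"))
    },
    physiology = {
      emit(sp$organs, paste0("physiology_", cfg$species, ".csv"))
    }
  )
}
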