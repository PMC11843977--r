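#' Destructive-sampling study design
#'
#' The biodistribution design emulated by the generator: plasma sampled at
#' 5 min and 6, 24, 96, 168 h; the five MRT tissues at 6, 24, 96, 168 h
#' after whole-body perfusion; three animals per time point; a single
#' 10 mg/kg IV bolus.
#'
#' @param plasma_times plasma sampling times (h), positive increasing.
#' @param tissue_times tissue sampling times (h).
#' @param replicates animals per time point (>= 1).
#' @param dose a `dose_event`.
#' @param perfused whether tissues are collected after perfusion.
#' @param tissues tissue labels sampled besides plasma.
#' @return object of class `study_design`.
#' @export
study_design <- function(plasma_times = c(5 / 60, 6, 24, 96, 168),
                         tissue_times = c(6, 24, 96, 168),
                         replicates = 3,
                         dose = dose_event(),
                         perfused = TRUE,
                         tissues = MRT_ORGANS) {
  stopifnot(all(plasma_times > 0), !is.unsorted(plasma_times, strictly = TRUE),
            all(tissue_times > 0), !is.unsorted(tissue_times, strictly = TRUE),
            replicates >= 1)
  structure(list(plasma_times = plasma_times, tissue_times = tissue_times,
                 replicates = replicates, dose = dose, perfused = perfused,
                 tissues = tissues),
            class = "study_design")
}

# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic observed dataset
#'
#' Simulates the model under a study design and perturbs each record with
#' independent Gaussian noise from the combined error model,
#' `conc = max(0, Y + e)`, `e ~ N(0, (delta_intercept +
#' delta_slope * Y)^2)`. Negative draws are truncated at zero (not
#' resampled), which introduces a slight positive bias at concentrations
#' near the noise floor; the fraction of truncated records is attached as
#' attribute `truncated_fraction`. The same seed always reproduces the same
#' dataset, and the caller's RNG state is left untouched.
#'
#' @param ctx a `model_context` (its `dose` is overridden by the design's).
#' @param design a `study_design`.
#' @param em an `error_model`; the defaults are test settings chosen for
#'   this package, not reported study values.
#' @param seed integer seed recorded in the output attributes.
#' @return data.frame with columns `tissue`, `time_h`, `conc_nM`,
#'   `replicate`, plus attributes `seed` and `truncated_fraction`.
#' @export
generate_dataset <- function(ctx, design = study_design(),
                             em = error_model(), seed = 1) {
  stopifnot(inherits(ctx, "model_context"), inherits(design, "study_design"))
  times <- sort(unique(c(design$plasma_times, design$tissue_times)))
  sys <- build_pbpk_system(ctx$sp, ctx$gk, ctx$mrt, ctx$muscular_transit)
  sim <- simulate_pbpk(system = sys, doses = design$dose, times = times,
                       method = ctx$method)
  tc <- tissue_concentrations(sim, tissues = c("plasma", design$tissues),
                              perfused = design$perfused)
  key <- paste(tc$tissue, signif(tc$time_h, 12))
  pred <- setNames(tc$conc_nM, key)

  grid <- rbind(
    expand.grid(tissue = "plasma", time_h = design$plasma_times,
                replicate = seq_len(design$replicates),
                stringsAsFactors = FALSE),
    expand.grid(tissue = design$tissues, time_h = design$tissue_times,
                replicate = seq_len(design$replicates),
                stringsAsFactors = FALSE)
  )
  grid <- grid[order(grid$tissue, grid$time_h, grid$replicate), ]
  y <- unname(pred[paste(grid$tissue, signif(grid$time_h, 12))])
  sd <- em$delta_intercept + em$delta_slope * y
  noisy <- .with_seed(seed, y + stats::rnorm(length(y), 0, sd))
  truncated <- noisy < 0
  noisy[truncated] <- 0

  out <- data.frame(tissue = grid$tissue, time_h = grid$time_h,
                    conc_nM = noisy, replicate = grid$replicate)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "truncated_fraction") <- mean(truncated)
  out
}
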