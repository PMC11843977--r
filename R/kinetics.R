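#' Global antibody / FcRn kinetic parameters
#'
#' Rate constants shared across organs: endosomal pinocytosis (`CLup`,
#' expressed per litre of endosomal volume), FcRn association/dissociation,
#' lysosomal degradation of unbound antibody, the recycling fraction `FR`
#' (fraction of FcRn-bound antibody returned to the originating side of the
#' cell; `1 - FR` is transcytosed onward), and the vascular, interstitial
#' (lymphatic) and epithelial reflection coefficients. Free FcRn is treated
#' as a fixed concentration, so the whole system is linear; the
#' blood-testis-barrier FcRn defaults to one tenth of the endothelial value.
#'
#' @param kon_FcRn association rate constant, 1/(M*h).
#' @param koff_FcRn dissociation rate constant, 1/h.
#' @param kdeg degradation rate of unbound endosomal antibody, 1/h.
#' @param FR recycling fraction in `[0, 1]`.
#' @param CLup_endothelium pinocytosis rate, L/h per L endosomal volume.
#' @param FcRn_endothelium free FcRn concentration in endothelial endosomes, M.
#' @param FcRn_BTB free FcRn concentration behind the blood-testis barrier, M.
#' @param sigma_vascular,sigma_interstitial,sigma_epithelial default
#'   reflection coefficients (dimensionless, in `[0, 1]`); per-organ values
#'   can be supplied as named vectors in `sigma_overrides`.
#' @param sigma_overrides named list with optional elements `vascular`,
#'   `interstitial`, `epithelial`, each a named numeric vector keyed by organ.
#' @return an object of class `global_kinetics`.
#' @export
global_kinetics <- function(kon_FcRn = 8.06e7, koff_FcRn = 6.55, kdeg = 26.6,
                            FR = 0.715, CLup_endothelium = 0.55,
                            FcRn_endothelium = 4.98e-5,
                            FcRn_BTB = FcRn_endothelium / 10,
                            sigma_vascular = 0.95,
                            sigma_interstitial = 0.2,
                            sigma_epithelial = 0.95,
                            sigma_overrides = list(vascular = c(brain = 0.99))) {
  stopifnot(
    kon_FcRn >= 0, koff_FcRn >= 0, kdeg >= 0, CLup_endothelium >= 0,
    FcRn_endothelium >= 0, FcRn_BTB >= 0,
    FR >= 0, FR <= 1,
    sigma_vascular >= 0, sigma_vascular <= 1,
    sigma_interstitial >= 0, sigma_interstitial <= 1,
    sigma_epithelial >= 0, sigma_epithelial <= 1
  )
  structure(
    list(kon_FcRn = kon_FcRn, koff_FcRn = koff_FcRn, kdeg = kdeg, FR = FR,
         CLup_endothelium = CLup_endothelium,
         FcRn_endothelium = FcRn_endothelium, FcRn_BTB = FcRn_BTB,
         sigma_vascular = sigma_vascular,
         sigma_interstitial = sigma_interstitial,
         sigma_epithelial = sigma_epithelial,
         sigma_overrides = sigma_overrides),
    class = "global_kinetics"
  )
}

#' Load global kinetic parameters from a parameter file
#'
#' Reads the packaged (or a user-supplied) CSV of platform kinetic constants.
#' The packaged file is a representative IgG parameter set assembled for this
#' package (see the vignette); the FcRn concentrations are anchored at
#' 4.98e-5 M endothelial / 4.98e-6 M blood-testis barrier.
#'
#' @param path optional CSV path (columns parameter, value, unit); defaults
#'   to the packaged file.
#' @return a `global_kinetics` object.
#' @export
load_global_kinetics <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("global_kinetics_platform_synthetic.csv")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  val <- setNames(tab$value, tab$parameter)
  gk <- global_kinetics(
    kon_FcRn = val[["kon_FcRn"]], koff_FcRn = val[["koff_FcRn"]],
    kdeg = val[["kdeg"]], FR = val[["FR"]],
    CLup_endothelium = val[["CLup_endothelium"]],
    FcRn_endothelium = val[["FcRn_endothelium"]],
    FcRn_BTB = val[["FcRn_BTB"]],
    sigma_vascular = val[["sigma_vascular_default"]],
    sigma_interstitial = val[["sigma_interstitial_default"]],
    sigma_epithelial = val[["sigma_epithelial_default"]],
    sigma_overrides = list(vascular = c(brain = val[["sigma_vascular_brain"]]))
  )
  gk
}

#' MRT-specific model parameters
#'
#' The eight parameters specific to the male reproductive tract: pinocytosis
#' rates across the blood-testis barrier and in the testis endothelium,
#' luminal (seminal-fluid) flows of the five organs, and the estimated
#' blood-epididymal-barrier (BEB) volume. Defaults are the packaged final
#' estimates.
#'
#' @param CLup_BTB blood-testis-barrier pinocytosis rate, L/h/L.
#' @param CLup_E_testis testis endothelial pinocytosis rate, L/h/L.
#' @param Q_retetestis,Q_ep,Q_vd,Q_sv,Q_pg luminal flows, L/h.
#' @param BEB_volume epididymis epithelial (BEB) volume, L.
#' @return an object of class `mrt_parameters` (a named numeric vector).
#' @export
mrt_parameters <- function(CLup_BTB = 6.78e-2, CLup_E_testis = 1.27e2,
                           Q_retetestis = 1.20e-8, Q_ep = 1.60e-4,
                           Q_vd = 2.00e-5, Q_sv = 9.40e-5, Q_pg = 1.60e-5,
                           BEB_volume = 2.80e-4) {
  v <- c(CLup_BTB = CLup_BTB, CLup_E_testis = CLup_E_testis,
         Q_retetestis = Q_retetestis, Q_ep = Q_ep, Q_vd = Q_vd,
         Q_sv = Q_sv, Q_pg = Q_pg, BEB_volume = BEB_volume)
  if (any(v < 0)) stop("MRT parameters must be non-negative")
  structure(v, class = "mrt_parameters")
}

#' Load the packaged MRT parameter estimates
#'
#' @param path optional CSV path (columns parameter, estimate, se,
#'   cv_percent, unit); defaults to the packaged estimates.
#' @return an `mrt_parameters` vector with the reported standard errors and
#'   CV% attached as attributes `se` and `cv_percent`.
#' @export
load_mrt_parameters <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("mrt_parameters_mouse.csv")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  est <- setNames(tab$estimate, tab$parameter)
  out <- do.call(mrt_parameters, as.list(est))
  attr(out, "se") <- setNames(tab$se, tab$parameter)
  attr(out, "cv_percent") <- setNames(tab$cv_percent, tab$parameter)
  out
}

# update an mrt_parameters / global_kinetics pair from a named vector of
# parameter values (used by estimation and sensitivity); names must be MRT
# parameter names or global kinetic scalars
.update_parameters <- function(mrt, gk, values) {
  for (nm in names(values)) {
    if (nm %in% names(mrt)) {
      mrt[[nm]] <- values[[nm]]
    } else if (nm %in% names(gk) && is.numeric(gk[[nm]])) {
      gk[[nm]] <- values[[nm]]
    } else {
      stop("unknown model parameter: ", nm)
    }
  }
  list(mrt = mrt, gk = gk)
}
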