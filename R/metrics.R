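#' Concentration-time curve container
#'
#' @param times strictly increasing times (h), length >= 2.
#' @param conc concentrations (nmol/L), same length, non-negative, no NaN.
#' @param tissue optional tissue label.
#' @return object of class `pk_curve`.
#' @export
pk_curve <- function(times, conc, tissue = NA_character_) {
  if (length(times) != length(conc) || length(times) < 2) {
    stop("times and conc must have equal length >= 2")
  }
  if (any(!is.finite(times)) || any(!is.finite(conc))) stop("NaN/Inf in curve")
  if (any(diff(times) <= 0)) stop("input error: times must be strictly increasing")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  structure(list(times = times, conc = conc, tissue = tissue), class = "pk_curve")
}

#' Area under the curve by the trapezoidal rule
#'
#' AUC from the first to the last observed time point; no terminal
#' extrapolation. The default is the linear trapezoidal rule; `log = TRUE`
#' uses the log-trapezoidal rule on strictly positive declining segments
#' (falling back to linear where either endpoint is zero or the segment is
#' not declining).
#'
#' @param curve a `pk_curve`, or a numeric vector of times if `conc` given.
#' @param conc concentrations when `curve` is a plain time vector.
#' @param log use the log-trapezoidal variant (not the default).
#' @return AUC in h*nmol/L.
#' @examples
#' auc_linear_trapezoid(pk_curve(c(0, 1), c(1, 1)))  # 1
#' @export
auc_linear_trapezoid <- function(curve, conc = NULL, log = FALSE) {
  if (!inherits(curve, "pk_curve")) curve <- pk_curve(curve, conc)
  t <- curve$times
  y <- curve$conc
  dt <- diff(t)
  y1 <- y[-length(y)]
  y2 <- y[-1]
  seg <- (y1 + y2) / 2 * dt
  if (log) {
    use <- y1 > 0 & y2 > 0 & y2 < y1
    seg[use] <- (y1[use] - y2[use]) / log(y1[use] / y2[use]) * dt[use]
  }
  sum(seg)
}

#' Antibody biodistribution coefficient (percent)
#'
#' The tissue-to-plasma AUC ratio expressed as a percentage,
#' `100 * AUC_tissue / AUC_plasma`.
#'
#' @param auc_tissue,auc_plasma AUCs in the same units; `auc_plasma` > 0.
#' @return ABC in percent.
#' @examples
#' abc_percent(2253, 87505)  # 2.57
#' @export
abc_percent <- function(auc_tissue, auc_plasma) {
  if (any(auc_plasma <= 0)) stop("plasma AUC must be positive")
  100 * auc_tissue / auc_plasma
}

#' Percentage prediction error
#'
#' `100 * (AUC_pred / AUC_obs - 1)`; positive iff the prediction exceeds the
#' observation.
#'
#' @param auc_pred,auc_obs predicted and observed AUC; `auc_obs` > 0.
#' @param absolute return `|%PE|` (the tabulated form).
#' @return percent.
#' @examples
#' percent_prediction_error(87505, 70799)  # 23.6
#' @export
percent_prediction_error <- function(auc_pred, auc_obs, absolute = FALSE) {
  if (any(auc_obs <= 0)) stop("observed AUC must be positive")
  pe <- 100 * (auc_pred / auc_obs - 1)
  if (absolute) abs(pe) else pe
}

#' Per-tissue NCA summary table
#'
#' Computes trapezoidal AUC per tissue from a tidy concentration table,
#' the ABC relative to the plasma AUC, and (when a paired observed table is
#' supplied) the percentage prediction error, tabulated as `|%PE|` rounded
#' to one decimal.
#'
#' @param pred data.frame with columns `tissue`, `time_h`, `conc_nM`
#'   (replicates are averaged per time point).
#' @param observed optional data.frame in the same format.
#' @return data.frame with columns `tissue`, `auc`, `abc_percent`, and when
#'   observed data are given `auc_obs`, `pe_percent`, `abs_pe_percent`.
#' @export
nca_table <- function(pred, observed = NULL) {
  auc_of <- function(df) {
    sapply(split(df, df$tissue), function(d) {
      m <- tapply(d$conc_nM, d$time_h, mean)
      auc_linear_trapezoid(as.numeric(names(m)), as.numeric(m))
    })
  }
  auc <- auc_of(pred)
  if (!"plasma" %in% names(auc)) stop("prediction table must include plasma")
  out <- data.frame(tissue = names(auc), auc = as.numeric(auc))
  out$abc_percent <- abc_percent(out$auc, auc[["plasma"]])
  if (!is.null(observed)) {
    aobs <- auc_of(observed)
    out$auc_obs <- as.numeric(aobs[out$tissue])
    out$pe_percent <- percent_prediction_error(out$auc, out$auc_obs)
    out$abs_pe_percent <- round(abs(out$pe_percent), 1)
  }
  rownames(out) <- NULL
  out
}
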