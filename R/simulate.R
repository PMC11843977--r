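#' Intravenous bolus dose event
#'
#' Converts a mg/kg dose to the administered amount in nmol:
#' `dose_mg_per_kg * body_weight / molecular_weight * 1e6`
#' (for 10 mg/kg, 0.028 kg and a 150 kDa antibody this is 1.8667 nmol).
#'
#' @param time dose time (h).
#' @param dose_mg_per_kg dose in mg/kg (>= 0).
#' @param body_weight body weight (kg).
#' @param molecular_weight antibody molecular weight (g/mol); default 150 kDa.
#' @return object of class `dose_event` with the computed `amount_nmol`.
#' @export
dose_event <- function(time = 0, dose_mg_per_kg = 10, body_weight = 0.028,
                       molecular_weight = 1.5e5) {
  stopifnot(time >= 0, dose_mg_per_kg >= 0, body_weight > 0, molecular_weight > 0)
  structure(
    list(time = time, dose_mg_per_kg = dose_mg_per_kg,
         body_weight = body_weight, molecular_weight = molecular_weight,
         amount_nmol = dose_mg_per_kg * body_weight / molecular_weight * 1e6),
    class = "dose_event"
  )
}

#' Default study sampling schedule (h)
#' @return numeric vector: 5 min and 6, 24, 96, 168 h.
#' @export
study_times <- function() c(5 / 60, 6, 24, 96, 168)

# propagate the linear system dx/dt = A x through sorted non-negative times
# (starting from x0 at t = 0) with matrix exponentials. When all steps are
# integer multiples of the smallest one, a single expm of the base step is
# squared dyadically and each step is applied as a few matrix-vector
# products; otherwise one expm per unique step size.
.propagate_expm <- function(A, x0, times) {
  steps <- diff(c(0, times))
  out <- matrix(0, length(times), length(x0))
  x <- x0
  pos <- steps[steps > 0]
  h <- if (length(pos)) min(pos) else 1
  k <- steps / h
  dyadic <- length(pos) > 0 && all(abs(k - round(k)) < 1e-8 * pmax(k, 1)) &&
    max(k) < 2^24
  if (dyadic) {
    k <- round(k)
    nb <- max(1, ceiling(log2(max(k) + 1)))
    pows <- vector("list", nb)  # pows[[j]] advances 2^(j-1) base steps
    pows[[1]] <- as.matrix(Matrix::expm(Matrix::Matrix(A * h)))
    if (nb > 1) for (j in 2:nb) pows[[j]] <- pows[[j - 1]] %*% pows[[j - 1]]
    for (i in seq_along(steps)) {
      ki <- as.integer(k[i])
      j <- 1
      while (ki > 0) {
        if (bitwAnd(ki, 1L) == 1L) x <- as.vector(pows[[j]] %*% x)
        ki <- bitwShiftR(ki, 1L)
        j <- j + 1
      }
      out[i, ] <- x
    }
  } else {
    keys <- sprintf("%.15g", steps)
    cache <- new.env(parent = emptyenv())
    for (i in seq_along(steps)) {
      if (steps[i] > 0) {
        E <- cache[[keys[i]]]
        if (is.null(E)) {
          E <- as.matrix(Matrix::expm(Matrix::Matrix(A * steps[i])))
          cache[[keys[i]]] <- E
        }
        x <- as.vector(E %*% x)
      }
      out[i, ] <- x
    }
  }
  out
}

.integrate_lsoda <- function(A, x0, times, rtol, atol) {
  func <- function(t, y, p) list(as.vector(A %*% y))
  jac <- function(t, y, p) A
  sol <- deSolve::ode(y = x0, times = c(0, times), func = func, parms = NULL,
                      jacfunc = jac, jactype = "fullusr", method = "lsoda",
                      rtol = rtol, atol = atol)
  diag <- attr(sol, "istate")
  if (!is.null(diag) && diag[1] < 0) {
    stop(sprintf("solver failure (istate %d); last successful time %.4g h",
                 diag[1], max(sol[, "time"])))
  }
  unname(as.matrix(sol[-1, -1, drop = FALSE]))
}

#' Simulate the whole-body PBPK model
#'
#' Integrates the linear system for one or more IV bolus doses and returns
#' amounts in every sub-compartment at the requested report times. Dose
#' discontinuities are handled by restarting the integration at each dose
#' time (the bolus is added to the plasma pool), never by smoothing.
#'
#' Two integration back-ends are available: `"lsoda"` (stiff-capable
#' adaptive solver from deSolve, with the analytic constant Jacobian;
#' default tolerances rtol 1e-8 / atol 1e-10) and `"expm"` (exact
#' propagation of the constant-coefficient linear system by matrix
#' exponential; used internally by estimation and sensitivity for speed).
#' The two agree to solver tolerance and are cross-checked in the test
#' suite.
#'
#' @param sp a `species_physiology`, or `NULL` if `system` is given.
#' @param gk,mrt kinetic parameter objects (defaults used when omitted).
#' @param doses a `dose_event` or list of them.
#' @param times strictly increasing report times (h); defaults to
#'   [study_times()].
#' @param method `"lsoda"` or `"expm"`.
#' @param rtol,atol solver tolerances for `"lsoda"`.
#' @param muscular_transit passed to [build_pbpk_system()].
#' @param system optionally a prebuilt `pbpk_system` (skips assembly).
#' @return object of class `simulation_result`: list with `times`, `amounts`
#'   (times x states, nmol), the `system`, and `dose_nmol`.
#' @examples
#' \donttest{
#' mouse <- load_species_physiology("mouse")
#' sim <- simulate_pbpk(mouse, doses = dose_event(dose_mg_per_kg = 10))
#' tissue_concentrations(sim)
#' }
#' @export
simulate_pbpk <- function(sp = NULL, gk = global_kinetics(), mrt = mrt_parameters(),
                          doses = dose_event(), times = study_times(),
                          method = c("lsoda", "expm"),
                          rtol = 1e-8, atol = 1e-10,
                          muscular_transit = TRUE, system = NULL) {
  method <- match.arg(method)
  if (is.null(system)) system <- build_pbpk_system(sp, gk, mrt, muscular_transit)
  if (inherits(doses, "dose_event")) doses <- list(doses)
  stopifnot(length(doses) >= 1, all(vapply(doses, inherits, TRUE, "dose_event")))
  if (any(diff(times) <= 0) || any(times < 0)) {
    stop("report times must be strictly increasing and non-negative")
  }
  dose_times <- vapply(doses, `[[`, 0, "time")
  if (max(dose_times) > max(times)) stop("time grid must cover all dose times")

  A <- system$A
  n <- nrow(A)
  ip <- system$index[["plasma"]]
  x <- numeric(n)
  total_dose <- 0

  # breakpoints: segment the integration at each dose time
  breaks <- sort(unique(dose_times))
  grid <- sort(unique(c(times, breaks)))
  out <- matrix(0, length(grid), n, dimnames = list(NULL, system$states$state))
  done <- rep(FALSE, length(grid))
  applied <- rep(FALSE, length(doses))
  t0 <- 0
  for (b in c(breaks, Inf)) {
    for (j in seq_along(doses)) {
      if (!applied[j] && doses[[j]]$time <= t0) {
        x[ip] <- x[ip] + doses[[j]]$amount_nmol
        total_dose <- total_dose + doses[[j]]$amount_nmol
        applied[j] <- TRUE
      }
    }
    seg <- which(!done & grid >= t0 & grid <= b)
    if (length(seg) > 0) {
      tt <- grid[seg] - t0
      pos <- tt > 0
      if (any(pos)) {
        res <- if (method == "expm") {
          .propagate_expm(A, x, tt[pos])
        } else {
          .integrate_lsoda(A, x, tt[pos], rtol, atol)
        }
        out[seg[pos], ] <- res
        x <- res[nrow(res), ]
      }
      if (any(!pos)) out[seg[!pos], ] <- matrix(x, sum(!pos), n, byrow = TRUE)
      done[seg] <- TRUE
    }
    t0 <- b
  }

  keep <- grid %in% times
  amounts <- out[keep, , drop = FALSE]
  scale <- max(total_dose, 1)
  if (min(amounts) < -1e-6 * scale) {
    stop(sprintf("integration error: negative state beyond tolerance (min %.3g nmol)",
                 min(amounts)))
  }
  amounts[amounts < 0] <- 0

  structure(
    list(times = times, amounts = amounts, system = system,
         dose_nmol = total_dose, method = method),
    class = "simulation_result"
  )
}

#' @method print simulation_result
#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %s, dose %.4g nmol, %d report times (%.3g..%.3g h), method %s\n",
              x$system$species, x$dose_nmol, length(x$times),
              min(x$times), max(x$times), x$method))
  invisible(x)
}

#' Concentrations of every kinetic state
#'
#' @param result a `simulation_result`.
#' @return matrix (times x states) in nmol/L; sink states are omitted.
#' @export
state_concentrations <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  v <- result$system$volumes
  keep <- !is.na(v)
  sweep(result$amounts[, keep, drop = FALSE], 2, v[keep], "/")
}

#' Volume-weighted observed tissue concentration
#'
#' The whole-tissue concentration reconstructed from sub-compartment
#' concentrations as `sum(C_k V_k) / sum(V_k)`.
#'
#' @param conc sub-compartment concentrations (nmol/L).
#' @param volumes matching sub-compartment volumes (L); total must be > 0.
#' @return scalar nmol/L.
#' @examples
#' observed_tissue_concentration(c(0, 2), c(1, 1))  # 1
#' @export
observed_tissue_concentration <- function(conc, volumes) {
  if (length(conc) != length(volumes)) stop("conc and volumes must match")
  tot <- sum(volumes)
  if (!is.finite(tot) || tot <= 0) stop("total volume must be positive")
  sum(conc * volumes) / tot
}

# reconstruction table for one organ: sub-compartment labels, the states
# aggregated into each, and the weighting volume
.reconstruction_parts <- function(system, organ) {
  comps <- .state_compartments(organ)
  v <- system$volumes
  org <- system$physiology$organs
  parts <- list(
    vascular = list(states = paste0(organ, ".V"), volume = v[[paste0(organ, ".V")]]),
    blood_cell = list(states = paste0(organ, ".BC"), volume = v[[paste0(organ, ".BC")]]),
    endosomal = list(states = paste0(organ, c(".EU", ".EB")),
                     volume = v[[paste0(organ, ".EU")]]),
    interstitial = list(states = paste0(organ, ".IS"), volume = v[[paste0(organ, ".IS")]])
  )
  if ("PU" %in% comps) {
    # the homogenate denominator carries the full anatomical barrier layer
    # (the epididymis's layer is its estimated barrier volume); the
    # numerator is the antibody amount held in the layer's endosomes
    vep_anat <- if (organ == "epididymis") v[[paste0(organ, ".PU")]]
                else org$epithelial_volume[org$organ == organ]
    parts$epithelial <- list(states = paste0(organ, c(".PU", ".PB")),
                             volume = vep_anat)
  }
  if ("MU" %in% comps) {
    parts$muscular <- list(states = paste0(organ, ".MU"), volume = v[[paste0(organ, ".MU")]])
  }
  if ("LU" %in% comps) {
    parts$luminal <- list(states = paste0(organ, ".LU"), volume = v[[paste0(organ, ".LU")]])
  }
  parts
}

#' Reconstructed tissue concentration-time profiles
#'
#' Whole-tissue concentrations as the study would measure them: the
#' volume-weighted mean over vascular, blood-cell, endosomal, interstitial,
#' epithelial, muscular (where present) and luminal sub-compartments; for
#' the testis and epididymis there is no muscular term. The rete testis is
#' not part of the reconstruction. Plasma is reported directly as the
#' plasma-pool concentration.
#'
#' With `perfused = TRUE` (default, matching tissue collection after whole
#' body perfusion) the vascular and blood-cell contributions are zeroed
#' while their volumes stay in the denominator, so reported concentrations
#' are lower than the residual-blood reconstruction at every time point.
#'
#' @param result a `simulation_result`.
#' @param tissues tissue labels; `"plasma"` and any organ name.
#' @param perfused emulate vascular washout (default `TRUE`).
#' @return data.frame with columns `tissue`, `time_h`, `conc_nM`.
#' @export
tissue_concentrations <- function(result, tissues = c("plasma", MRT_ORGANS),
                                  perfused = TRUE) {
  stopifnot(inherits(result, "simulation_result"))
  sys <- result$system
  out <- list()
  for (tis in tissues) {
    if (tis == "plasma") {
      conc <- result$amounts[, "plasma"] / sys$volumes[["plasma"]]
    } else {
      if (!tis %in% sys$states$organ) stop("unknown tissue: ", tis)
      parts <- .reconstruction_parts(sys, tis)
      if (perfused) parts$vascular$zero <- parts$blood_cell$zero <- TRUE
      pc <- vapply(parts, function(p) {
        if (isTRUE(p$zero)) return(rep(0, length(result$times)))
        rowSums(result$amounts[, p$states, drop = FALSE]) / p$volume
      }, numeric(length(result$times)))
      if (is.null(dim(pc))) pc <- matrix(pc, nrow = 1, dimnames = list(NULL, names(parts)))
      pv <- vapply(parts, `[[`, 0, "volume")
      conc <- apply(pc, 1, observed_tissue_concentration, volumes = pv)
    }
    out[[tis]] <- data.frame(tissue = tis, time_h = result$times, conc_nM = unname(conc))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
as.data.frame.simulation_result <- function(x, row.names = NULL, optional = FALSE, ...) {
  conc <- state_concentrations(x)
  df <- data.frame(
    time_h = rep(x$times, ncol(conc)),
    state = rep(colnames(conc), each = nrow(conc)),
    conc_nM = as.vector(conc)
  )
  df
}
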