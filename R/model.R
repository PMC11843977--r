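#' Whole-body PBPK system assembly
#'
#' The model tracks antibody amounts (nmol) in every sub-compartment of the
#' 15 platform organs (vascular plasma, vascular blood cells, endosomal
#' unbound/FcRn-bound, interstitial), in the plasma, blood-cell and
#' lymph-node pools, and in the five MRT organs, which add an
#' epithelial/barrier endosome (unbound/bound), a luminal space, a muscular
#' transit layer (vas deferens, seminal vesicle, prostate gland) and the
#' rete-testis transit compartment. Two auxiliary states accumulate the
#' degradation and luminal-excretion sinks so mass balance can be audited.
#'
#' Because free FcRn is a fixed concentration, the full system is linear and
#' is represented by a constant matrix `A` with `dx/dt = A x`. `A` is
#' Metzler (non-negative off-diagonal), so trajectories from non-negative
#' states remain non-negative.
#'
#' @name pbpk_system
NULL

.state_compartments <- function(organ) {
  base <- c("V", "BC", "EU", "EB", "IS")
  if (organ == "testis") c(base, "PU", "PB", "LU", "RT")
  else if (organ == "epididymis") c(base, "PU", "PB", "LU")
  else if (organ %in% MUSCULAR_ORGANS) c(base, "MU", "PU", "PB", "LU")
  else base
}

.HEMATOCRIT <- 0.45

# per-organ sigma lookup honouring overrides
.sigma_for <- function(gk, which, organ) {
  ov <- gk$sigma_overrides[[which]]
  if (!is.null(ov) && organ %in% names(ov)) return(unname(ov[[organ]]))
  switch(which,
         vascular = gk$sigma_vascular,
         interstitial = gk$sigma_interstitial,
         epithelial = gk$sigma_epithelial)
}

#' Build the state table for a physiology
#'
#' One row per model state with its organ, compartment code
#' (V vascular plasma, BC blood cells, EU/EB endosomal unbound/bound,
#' IS interstitial, MU muscular, PU/PB epithelial endosome unbound/bound,
#' LU luminal, RT rete testis) and the volume used to convert amounts to
#' concentrations. The epididymis epithelial volume is the estimated
#' blood-epididymal-barrier volume from `mrt`.
#'
#' @param sp a `species_physiology`.
#' @param mrt an `mrt_parameters` vector.
#' @return data.frame with columns `state`, `organ`, `compartment`, `volume`.
#' @export
model_state_index <- function(sp, mrt = mrt_parameters()) {
  org <- sp$organs
  rows <- list(
    data.frame(state = "plasma", organ = "plasma", compartment = "POOL",
               volume = unname(sp$pools[["plasma"]])),
    data.frame(state = "blood_cell_pool", organ = "blood_cell", compartment = "POOL",
               volume = unname(sp$pools[["blood_cell"]])),
    data.frame(state = "lymph_node", organ = "lymph_node", compartment = "POOL",
               volume = unname(sp$pools[["lymph_node"]]))
  )
  for (i in seq_len(nrow(org))) {
    o <- org$organ[i]
    comps <- .state_compartments(o)
    # the epithelial barrier compartment is the endosomal space of the
    # barrier cells: pinocytosis and FcRn binding are endosomal processes,
    # so the platform's 0.5%-endosome rule is applied to the barrier layer.
    # The epididymis is the exception: its effective barrier volume was an
    # estimated model parameter and is used as supplied.
    vep <- if (o == "epididymis") unname(mrt[["BEB_volume"]])
           else 0.005 * org$epithelial_volume[i]
    vols <- c(
      V = org$vascular_volume[i] * (1 - .HEMATOCRIT),
      BC = org$vascular_volume[i] * .HEMATOCRIT,
      EU = org$endosomal_volume[i], EB = org$endosomal_volume[i],
      IS = org$interstitial_volume[i],
      MU = org$muscular_volume[i],
      PU = vep, PB = vep,
      LU = org$luminal_volume[i],
      RT = org$rete_testis_volume[i]
    )
    rows[[length(rows) + 1L]] <- data.frame(
      state = paste(o, comps, sep = "."), organ = o, compartment = comps,
      volume = unname(vols[comps])
    )
  }
  rows[[length(rows) + 1L]] <- data.frame(
    state = c("degraded", "excreted"), organ = "sink",
    compartment = c("DEG", "EXC"), volume = NA_real_
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the PBPK system matrix
#'
#' Builds the constant state matrix `A` (1/h) of the linear whole-body
#' system, wiring: the circulatory loop (plasma to lung, lung to organs in
#' parallel, splanchnic organs draining through the liver), transcapillary
#' convection `(1 - sigma_v) L C_V`, pinocytotic endosomal uptake from both
#' vascular and interstitial sides, linear FcRn binding at fixed free-FcRn
#' concentration, degradation of unbound endosomal antibody, the FR /
#' (1 - FR) recycling split, lymph return through the lymph-node pool, the
#' MRT epithelial barriers (blood-testis barrier with its own pinocytosis
#' rate and ten-fold lower FcRn; estimated BEB volume in the epididymis) and
#' the luminal chain testis lumen -> rete testis -> epididymis -> vas
#' deferens -> seminal vesicle -> prostate -> excretion.
#'
#' @param sp a `species_physiology` (validated).
#' @param gk a `global_kinetics`.
#' @param mrt an `mrt_parameters`.
#' @param muscular_transit if `TRUE` (default) the muscular layer of the vas
#'   deferens, seminal vesicle and prostate gland is a well-mixed transit
#'   compartment between interstitium and epithelium; if `FALSE` it is
#'   collapsed to a pass-through and the epithelium exchanges with the
#'   interstitium directly.
#' @return an object of class `pbpk_system`: list with the matrix `A`,
#'   the `states` table, `volumes`, and bookkeeping indices.
#' @export
build_pbpk_system <- function(sp, gk = global_kinetics(), mrt = mrt_parameters(),
                              muscular_transit = TRUE) {
  stopifnot(inherits(sp, "species_physiology"), inherits(gk, "global_kinetics"))
  states <- model_state_index(sp, mrt)
  n <- nrow(states)
  idx <- setNames(seq_len(n), states$state)
  vol <- setNames(states$volume, states$state)
  org <- sp$organs
  rownames(org) <- org$organ

  kinetic <- states$compartment %in% c("V", "BC", "EU", "EB", "IS", "MU",
                                       "PU", "PB", "LU", "RT", "POOL")
  bad <- kinetic & (!is.finite(states$volume) | states$volume <= 0)
  if (any(bad)) {
    stop("structural error: zero or missing volume for state(s): ",
         paste(states$state[bad], collapse = ", "))
  }

  A <- matrix(0, n, n, dimnames = list(states$state, states$state))
  # clearance-driven flux CL (L/h) acting on the source concentration
  flux <- function(from, to, CL) {
    k <- CL / vol[[from]]
    A[idx[[from]], idx[[from]]] <<- A[idx[[from]], idx[[from]]] - k
    if (!is.null(to)) A[idx[[to]], idx[[from]]] <<- A[idx[[to]], idx[[from]]] + k
    invisible(NULL)
  }
  # first-order rate k (1/h) acting on the source amount
  rate <- function(from, to, k) {
    A[idx[[from]], idx[[from]]] <<- A[idx[[from]], idx[[from]]] - k
    if (!is.null(to)) A[idx[[to]], idx[[from]]] <<- A[idx[[to]], idx[[from]]] + k
    invisible(NULL)
  }

  PQ <- setNames(org$plasma_flow, org$organ)
  BQ <- setNames(org$blood_cell_flow, org$organ)
  L  <- setNames(org$lymph_flow, org$organ)
  nonlung <- setdiff(org$organ, "lung")
  direct <- setdiff(nonlung, c(SPLANCHNIC_ORGANS, "liver"))

  # --- circulatory loop, plasma side ---
  flux("plasma", "lung.V", PQ[["lung"]])
  for (o in nonlung) flux("lung.V", paste0(o, ".V"), PQ[[o]])
  for (o in direct) flux(paste0(o, ".V"), "plasma", PQ[[o]] - L[[o]])
  for (o in SPLANCHNIC_ORGANS) flux(paste0(o, ".V"), "liver.V", PQ[[o]] - L[[o]])
  liver_out <- PQ[["liver"]] + sum(PQ[SPLANCHNIC_ORGANS] - L[SPLANCHNIC_ORGANS]) - L[["liver"]]
  flux("liver.V", "plasma", liver_out)

  # --- circulatory loop, blood-cell side ---
  flux("blood_cell_pool", "lung.BC", BQ[["lung"]])
  for (o in nonlung) flux("lung.BC", paste0(o, ".BC"), BQ[[o]])
  for (o in direct) flux(paste0(o, ".BC"), "blood_cell_pool", BQ[[o]])
  for (o in SPLANCHNIC_ORGANS) flux(paste0(o, ".BC"), "liver.BC", BQ[[o]])
  flux("liver.BC", "blood_cell_pool", BQ[["liver"]] + sum(BQ[SPLANCHNIC_ORGANS]))

  # --- per-organ endosomal handling and lymph ---
  for (o in org$organ) {
    sv <- .sigma_for(gk, "vascular", o)
    si <- .sigma_for(gk, "interstitial", o)
    clup_rate <- if (o == "testis") unname(mrt[["CLup_E_testis"]]) else gk$CLup_endothelium
    VE <- org[o, "endosomal_volume"]
    CLE <- clup_rate * VE
    sV <- paste0(o, ".V"); sIS <- paste0(o, ".IS")
    sEU <- paste0(o, ".EU"); sEB <- paste0(o, ".EB")

    flux(sV, sIS, (1 - sv) * L[[o]])
    flux(sV, sEU, CLE)
    flux(sIS, sEU, CLE)
    konF <- gk$kon_FcRn * gk$FcRn_endothelium
    rate(sEU, sEB, konF)
    rate(sEB, sEU, gk$koff_FcRn)
    rate(sEU, "degraded", gk$kdeg)
    rate(sEB, sV, clup_rate * gk$FR)
    rate(sEB, sIS, clup_rate * (1 - gk$FR))
    flux(sIS, "lymph_node", (1 - si) * L[[o]])
  }
  flux("lymph_node", "plasma", sum(L))

  # --- MRT epithelial barriers and luminal chain ---
  for (o in MRT_ORGANS) {
    se <- .sigma_for(gk, "epithelial", o)
    clup_ep <- if (o == "testis") unname(mrt[["CLup_BTB"]]) else gk$CLup_endothelium
    FcRn_ep <- if (o == "testis") gk$FcRn_BTB else gk$FcRn_endothelium
    Vep <- vol[[paste0(o, ".PU")]]
    CLP <- clup_ep * Vep
    sIS <- paste0(o, ".IS"); sPU <- paste0(o, ".PU")
    sPB <- paste0(o, ".PB"); sLU <- paste0(o, ".LU")

    if (o %in% MUSCULAR_ORGANS && muscular_transit) {
      sMU <- paste0(o, ".MU")
      CLMU <- gk$CLup_endothelium * vol[[sMU]]
      flux(sIS, sMU, CLMU)
      flux(sMU, sIS, CLMU)
      flux(sMU, sPU, CLP)
      ret <- sMU
    } else {
      flux(sIS, sPU, CLP)
      ret <- sIS
    }
    konFp <- gk$kon_FcRn * FcRn_ep
    rate(sPU, sPB, konFp)
    rate(sPB, sPU, gk$koff_FcRn)
    rate(sPU, "degraded", gk$kdeg)
    rate(sPB, ret, clup_ep * gk$FR)
    rate(sPB, sLU, clup_ep * (1 - gk$FR))
    # paracellular lymph-like leak into the lumen, driven by the epithelial
    # concentration (unbound + bound): a leak driven by the interstitial
    # concentration would bypass the barrier the epithelium represents
    flux(sPU, sLU, (1 - se) * L[[o]])
    flux(sPB, sLU, (1 - se) * L[[o]])
  }
  flux("testis.LU", "testis.RT", unname(mrt[["Q_retetestis"]]))
  flux("testis.RT", "epididymis.LU", unname(mrt[["Q_retetestis"]]))
  flux("epididymis.LU", "vas_deferens.LU", unname(mrt[["Q_ep"]]))
  flux("vas_deferens.LU", "seminal_vesicle.LU", unname(mrt[["Q_vd"]]))
  flux("seminal_vesicle.LU", "prostate_gland.LU", unname(mrt[["Q_sv"]]))
  flux("prostate_gland.LU", "excreted", unname(mrt[["Q_pg"]]))

  if (any(!is.finite(A))) stop("non-finite entry in system matrix")

  structure(
    list(A = A, states = states, volumes = vol, index = idx,
         species = sp$species, physiology = sp, kinetics = gk,
         mrt = mrt, muscular_transit = muscular_transit),
    class = "pbpk_system"
  )
}

#' State-derivative function of the assembled system
#'
#' Returns `f(t, state)` giving `dstate/dt` in nmol/h; the system is
#' autonomous so `t` is ignored.
#'
#' @param sp,gk,mrt,... passed to [build_pbpk_system()].
#' @return a function `(t, state) -> dstate/dt`.
#' @export
build_rhs <- function(sp, gk = global_kinetics(), mrt = mrt_parameters(), ...) {
  sys <- build_pbpk_system(sp, gk, mrt, ...)
  function(t, state) as.vector(sys$A %*% state)
}

#' @method print pbpk_system
#' @export
print.pbpk_system <- function(x, ...) {
  cat(sprintf("<pbpk_system> %s: %d states (%d organs), linear Metzler matrix\n",
              x$species, nrow(x$states), nrow(x$physiology$organs)))
  invisible(x)
}

#' Mass-balance audit of a simulation
#'
#' Checks dose = amount remaining + amount degraded + amount excreted at the
#' final time of a simulation, using the auxiliary sink states accumulated
#' during integration.
#'
#' @param result a `simulation_result`.
#' @param dose total administered amount (nmol); defaults to the dose
#'   recorded in `result`.
#' @return list with `remaining`, `degraded`, `excreted`, `imbalance` (nmol)
#'   and `relative` (imbalance / dose; 0 for a zero dose).
#' @export
mass_balance <- function(result, dose = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  if (is.null(dose)) dose <- result$dose_nmol
  amounts <- result$amounts
  if (!all(c("degraded", "excreted") %in% colnames(amounts))) {
    stop("contract error: simulation lacks the auxiliary sink states")
  }
  last <- nrow(amounts)
  sinks <- c("degraded", "excreted")
  remaining <- sum(amounts[last, setdiff(colnames(amounts), sinks)])
  degraded <- amounts[last, "degraded"]
  excreted <- amounts[last, "excreted"]
  imbalance <- dose - (remaining + degraded + excreted)
  list(remaining = unname(remaining), degraded = unname(degraded),
       excreted = unname(excreted), imbalance = unname(imbalance),
       relative = if (dose > 0) unname(abs(imbalance) / dose) else 0)
}
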