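test_that("the assembled system is linear with the origin as fixed point", {
  sys <- mouse_system()
  rhs <- build_rhs(mouse_physiology())
  n <- nrow(sys$states)
  expect_equal(rhs(0, numeric(n)), numeric(n))
  # Metzler structure: all off-diagonal entries non-negative
  offdiag <- sys$A - diag(diag(sys$A))
  expect_true(min(offdiag) >= 0)
})

test_that("every efflux is an influx exactly once (flux-consistent RHS)", {
  # with the sinks included, the sum over all state derivatives must be zero
  # for any state: columns of A sum to zero to machine precision
  sys <- mouse_system()
  expect_lt(max(abs(colSums(sys$A))), 1e-9 * max(abs(sys$A)))

  # with degradation and luminal exit active, the total-system derivative
  # (excluding sinks) equals the sink fluxes, term by term
  set.seed(42)
  x <- runif(nrow(sys$states))
  names(x) <- sys$states$state
  dx <- as.vector(sys$A %*% x)
  names(dx) <- sys$states$state
  sinks <- c("degraded", "excreted")
  live <- setdiff(sys$states$state, sinks)
  gk <- global_kinetics()
  unbound <- grep("\\.(EU|PU)$", live, value = TRUE)
  deg_flux <- gk$kdeg * sum(x[unbound])
  exc_flux <- unname(mrt_parameters()[["Q_pg"]]) *
    x[["prostate_gland.LU"]] / sys$volumes[["prostate_gland.LU"]]
  expect_equal(sum(dx[live]), -(deg_flux + exc_flux), tolerance = 1e-10)
  expect_equal(dx[["degraded"]], deg_flux, tolerance = 1e-12)
  expect_equal(dx[["excreted"]], exc_flux, tolerance = 1e-12)
})

test_that("mass balance closes for a full mouse simulation", {
  sim <- simulate_pbpk(system = mouse_system(), method = "lsoda")
  mb <- mass_balance(sim)
  expect_lt(mb$relative, 1e-6)
  # exact propagation closes to near machine precision
  mbe <- mass_balance(mouse_sim())
  expect_lt(mbe$relative, 1e-8)
  # zero dose: everything zero
  sim0 <- simulate_pbpk(system = mouse_system(),
                        doses = dose_event(dose_mg_per_kg = 0))
  expect_equal(max(abs(sim0$amounts)), 0)
  expect_equal(mass_balance(sim0, dose = 0)$relative, 0)
})

test_that("with no degradation and a sealed prostate outflow the system is closed", {
  gk0 <- global_kinetics(kdeg = 0)
  mrt0 <- mrt_parameters(Q_pg = 0)
  sys <- build_pbpk_system(mouse_physiology(), gk0, mrt0)
  sim <- simulate_pbpk(system = sys, times = c(24, 168), method = "lsoda")
  d <- sim$dose_nmol
  remaining <- rowSums(sim$amounts[, setdiff(colnames(sim$amounts),
                                             c("degraded", "excreted"))])
  expect_equal(remaining / d, c(1, 1), tolerance = 1e-9)
  expect_equal(max(sim$amounts[, c("degraded", "excreted")]), 0)
})

test_that("doubling the dose exactly doubles every trajectory", {
  sys <- mouse_system()
  s1 <- simulate_pbpk(system = sys, doses = dose_event(dose_mg_per_kg = 10),
                      method = "lsoda")
  s2 <- simulate_pbpk(system = sys, doses = dose_event(dose_mg_per_kg = 20),
                      method = "lsoda")
  expect_equal(s2$amounts, 2 * s1$amounts, tolerance = 1e-8)
})

test_that("zeroing MRT exchange decouples the reproductive organs", {
  sp <- mouse_physiology()
  idx <- sp$organs$organ %in% MRT_ORGANS
  sp$organs$lymph_flow[idx] <- 0
  mrt0 <- mrt_parameters(CLup_BTB = 0, CLup_E_testis = 0, Q_retetestis = 0,
                         Q_ep = 0, Q_vd = 0, Q_sv = 0, Q_pg = 0)
  gk <- global_kinetics()
  gk$sigma_overrides$vascular <- c(gk$sigma_overrides$vascular,
                                   setNames(rep(1, 5), MRT_ORGANS))
  sys <- build_pbpk_system(sp, gk, mrt0)
  # suppress the shared endothelial pinocytosis in the MRT organs only, by
  # zeroing their endosomal volumes
  for (o in setdiff(MRT_ORGANS, "testis")) {
    for (cmp in c("EU", "EB")) {
      s <- paste0(o, ".", cmp)
      sys$A[, s] <- 0
      sys$A[s, ] <- 0
    }
  }
  sim <- simulate_pbpk(system = sys, method = "expm")
  mrt_states <- sys$states$state[sys$states$organ %in% MRT_ORGANS &
                                   !sys$states$compartment %in% c("V", "BC")]
  expect_equal(max(abs(sim$amounts[, mrt_states])), 0)
})

test_that("the isolated FcRn binding sub-system reaches the closed-form ratio", {
  gk <- global_kinetics()
  konF <- gk$kon_FcRn * gk$FcRn_endothelium
  A <- matrix(c(-konF, konF, gk$koff_FcRn, -gk$koff_FcRn), 2, 2)
  x <- mrtpbpk:::.propagate_expm(A, c(1, 0), times = 10)  # ~6e4 half-lives
  ratio <- x[1, 2] / x[1, 1]
  expect_equal(ratio, konF / gk$koff_FcRn, tolerance = 1e-3)
  # also at the lower FcRn concentration behind the blood-testis barrier
  konF_btb <- gk$kon_FcRn * gk$FcRn_BTB
  A2 <- matrix(c(-konF_btb, konF_btb, gk$koff_FcRn, -gk$koff_FcRn), 2, 2)
  x2 <- mrtpbpk:::.propagate_expm(A2, c(1, 0), times = 10)
  expect_equal(x2[1, 2] / x2[1, 1], konF_btb / gk$koff_FcRn, tolerance = 1e-3)
})

test_that("structural errors are raised for broken topologies", {
  sp <- mouse_physiology()
  sp$organs$vascular_volume[sp$organs$organ == "heart"] <- 0
  expect_error(build_pbpk_system(sp), "structural error")
  sim <- mouse_sim()
  sim$amounts <- sim$amounts[, setdiff(colnames(sim$amounts), "degraded")]
  expect_error(mass_balance(sim), "contract error")
})

test_that("the muscular layer can be collapsed to a pass-through", {
  sys <- build_pbpk_system(mouse_physiology(), muscular_transit = FALSE)
  sim <- simulate_pbpk(system = sys, method = "expm")
  mu <- paste0(c("vas_deferens", "seminal_vesicle", "prostate_gland"), ".MU")
  expect_equal(max(abs(sim$amounts[, mu])), 0)
  # epithelium still fills via the direct interstitial route
  expect_gt(sim$amounts[3, "vas_deferens.PB"], 0)
})
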