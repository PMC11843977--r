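test_that("the pooled NLL implements the combined error model density", {
  ctx <- mouse_context()
  ds <- generate_dataset(ctx, study_design(), error_model(1e-12, 1e-12), seed = 3)
  n <- nrow(ds)
  # zero residuals with unit additive SD: NLL = n/2 log(2 pi)
  expect_equal(negative_log_likelihood(NULL, ds, error_model(1, 0), ctx),
               n / 2 * log(2 * pi), tolerance = 1e-6)
  # hand-computed Gaussian terms for perturbed records
  em <- error_model(0.5, 0.5)
  ds2 <- ds
  set.seed(11)
  r <- rnorm(n, 0, 5)
  ds2$conc_nM <- pmax(0, ds$conc_nM + r)
  pred <- mrtpbpk:::.predict_records(ctx, ds2)
  sd <- em$delta_intercept + em$delta_slope * pred
  manual <- sum(0.5 * log(2 * pi * sd^2) + 0.5 * ((ds2$conc_nM - pred) / sd)^2)
  expect_equal(negative_log_likelihood(NULL, ds2, em, ctx), manual,
               tolerance = 1e-10)
  # scale equivariance: scaling concentrations, predictions and the additive
  # SD by c leaves the quadratic term unchanged; test via a purely additive
  # model where the whole NLL shifts by n log(c)
  em1 <- error_model(1, 0)
  emc <- error_model(10, 0)
  ds10 <- ds2
  ds10$conc_nM <- ds2$conc_nM  # same data; sigma scaling only
  nll1 <- negative_log_likelihood(NULL, ds2, em1, ctx)
  quad1 <- nll1 - n / 2 * log(2 * pi)
  nll10 <- negative_log_likelihood(NULL, ds2, emc, ctx)
  quad10 <- nll10 - n / 2 * log(2 * pi * 100)
  expect_equal(quad10, quad1 / 100, tolerance = 1e-8)
  expect_error(negative_log_likelihood(NULL, ds[0, ], em, ctx), "empty")
})

test_that("CV% follows the reported SE/estimate relationship", {
  expect_equal(cv_percent(2.0e-5, 1.9e-6), 9.5)
  expect_equal(round(cv_percent(1.6e-5, 8.6e-7), 2), 5.38)
  expect_equal(cv_percent(3, 0), 0)
  expect_true(is.na(cv_percent(0, 1)))
})

test_that("noise-free data are recovered to within 0.1%", {
  ctx <- mouse_context()
  # self-consistency at a sharp optimum: data generated at the packaged
  # estimates with (numerically) no noise, fitted under a matching
  # tight error model
  ds <- generate_dataset(ctx, study_design(), error_model(1e-12, 1e-12), seed = 5)
  em <- error_model(1e-6, 1e-3)
  pars <- c("Q_vd", "Q_sv", "CLup_BTB")
  truth <- unlist(as.list(ctx$mrt)[pars])
  fit <- fit_mrt_parameters(ds, fit_spec(pars, init = truth * 1.6), em, ctx)
  expect_equal(unname(fit$estimates / truth), rep(1, 3), tolerance = 1e-3)
  expect_lte(fit$objective, fit$objective_init)
  expect_equal(fit$convergence, 0)
  # CV% field is consistent with SE and estimates
  expect_equal(fit$cv_percent, 100 * fit$se / abs(fit$estimates))
})

test_that("staged fitting fixes earlier stages and matches the joint optimum", {
  ctx <- mouse_context()
  ds <- generate_dataset(ctx, study_design(), error_model(1e-12, 1e-12), seed = 6)
  em <- error_model(1e-6, 1e-3)
  pars <- c("CLup_BTB", "Q_vd")
  truth <- unlist(as.list(ctx$mrt)[pars])
  staged <- fit_mrt_parameters(
    ds, fit_spec(pars, init = truth * 1.5,
                 stages = list("CLup_BTB", "Q_vd")), em, ctx)
  expect_equal(unname(staged$estimates / truth), c(1, 1), tolerance = 2e-3)
  # profile sanity: fixing one parameter at its estimate and refitting the
  # other cannot lower the NLL appreciably
  prof <- fit_mrt_parameters(
    ds, fit_spec("Q_vd", init = c(Q_vd = unname(staged$estimates[["Q_vd"]]) * 1.3)),
    em, model_context(ctx$sp,
                      mrt = do.call(mrt_parameters,
                                    as.list(replace(ctx$mrt, "CLup_BTB",
                                                    staged$estimates[["CLup_BTB"]])))))
  expect_gte(prof$objective, staged$objective - 1e-2)
})

test_that("log-space and linear-space optimization find the same optimum", {
  ctx <- mouse_context()
  ds <- generate_dataset(ctx, study_design(), error_model(1e-12, 1e-12), seed = 8)
  em <- error_model(1e-6, 1e-3)
  truth <- unname(ctx$mrt[["Q_sv"]])
  fit <- fit_mrt_parameters(ds, fit_spec("Q_sv", init = c(Q_sv = truth * 2)),
                            em, ctx)
  lin <- optim(truth * 2,
               function(p) negative_log_likelihood(c(Q_sv = p), ds, em, ctx),
               method = "Brent", lower = truth / 10, upper = truth * 10)
  expect_equal(unname(fit$estimates[["Q_sv"]]), lin$par, tolerance = 1e-4)
})

test_that("degenerate fits are reported, not hidden", {
  ctx <- mouse_context()
  ds <- generate_dataset(ctx, study_design(), error_model(0.1, 0.2), seed = 9)
  em <- error_model(0.1, 0.2)
  expect_error(fit_mrt_parameters(ds[0, ], fit_spec("Q_vd"), em, ctx), "empty")
  w <- capture_warnings(
    fit_mrt_parameters(ds, fit_spec("Q_retetestis"), em, ctx,
                       control = list(maxit = 2)))
  expect_true(any(grepl("poorly identified", w)))
  expect_error(fit_spec(c("Q_vd", "Q_sv"), stages = list("Q_vd")), "partition")
  expect_error(error_model(0, 0), "degenerate")
})
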