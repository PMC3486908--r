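# Deterministic least-squares calibration and local sensitivity.

test_that("a single free parameter is recovered exactly from model output", {
  truth <- one_compartment_model(k = 0.02, production = 0.5)
  target <- steady_state(truth, tol = 1e-9)$concentrations$concentration_uM
  start <- one_compartment_model(k = 0.05, production = 0.5)
  cal <- calibrate(start, "process/cl/k",
                   targets = list(list(
                     name = "ss",
                     observable = function(m) {
                       steady_state(m, tol = 1e-9)$concentrations$
                         concentration_uM
                     },
                     value = target)))
  expect_true(cal$convergence)
  expect_equal(unname(cal$par), 0.02, tolerance = 1e-4)
  expect_lt(abs(cal$residuals$rel_residual), 1e-6)
})

test_that("two parameters are recovered within 5% from 1%-noisy kinetics", {
  k_true <- 0.015; p_true <- 0.3
  truth <- one_compartment_model(k = k_true, production = p_true)
  tr <- simulate_pbpk(truth, duration = 240)
  t_obs <- c(31, 91, 151, 241)      # rise-to-plateau sampling
  set.seed(99)
  obs <- tr$amounts[t_obs, 1, 1] * (1 + 0.01 * rnorm(length(t_obs)))
  targets <- purrr::map(seq_along(t_obs), function(i) {
    list(name = paste0("t", t_obs[i]),
         observable = function(m) {
           simulate_pbpk(m, duration = 240)$amounts[t_obs[i], 1, 1]
         },
         value = obs[i])
  })
  start <- one_compartment_model(k = 0.04, production = 0.1)
  cal <- calibrate(start, c("process/cl/k", "process/prod/rate"),
                   targets, lower = 1e-5, upper = 10)
  expect_lt(abs(cal$par[["process/cl/k"]] - k_true) / k_true, 0.05)
  expect_lt(abs(cal$par[["process/prod/rate"]] - p_true) / p_true, 0.05)
})

test_that("a parameter with no influence triggers the flat-objective warning", {
  m <- one_compartment_model(k = 0.02, production = 0.5)
  # volume does not change the steady-state concentration p/k
  expect_warning(
    calibrate(m, "volume/body",
              targets = list(list(
                observable = function(mm) {
                  steady_state(mm, tol = 1e-9)$concentrations$
                    concentration_uM
                },
                value = 25))),
    "flat objective")
})

test_that("local sensitivity reproduces closed-form coefficients", {
  m <- one_compartment_model(k = 0.02, production = 0.5)
  ss_conc <- function(mm) {
    steady_state(mm, tol = 1e-10)$concentrations$concentration_uM
  }
  # C = p/k: sensitivity +1 to production, -1 to the elimination rate
  expect_equal(local_sensitivity(m, "process/prod/rate", ss_conc), 1,
               tolerance = 1e-3)
  expect_equal(local_sensitivity(m, "process/cl/k", ss_conc), -1,
               tolerance = 1e-3)
  # an observable independent of the parameter
  expect_equal(local_sensitivity(m, "process/prod/rate",
                                 function(mm) 42), 0)
  expect_warning(s0 <- local_sensitivity(m, "process/prod/rate",
                                         function(mm) 0), "zero")
  expect_true(is.na(s0))
})

test_that("metabolite linking conserves parent-to-metabolite mass", {
  comp <- tibble::tibble(name = "body", volume = 10)
  noflow <- tibble::tibble(source = character(), target = character(),
                           rate = numeric())
  parent <- pbpk_model(comp, noflow, tibble::tibble(name = "p"),
                       list(process_first_order("cl", "body", "p",
                                                k = 0.02)))
  metab <- pbpk_model(comp, noflow, tibble::tibble(name = "m"),
                      list())
  linked <- link_metabolite(parent, metab, "cl",
                            stoichiometric_yield = 1)
  tr <- simulate_pbpk(linked, duration = 400,
                      init = matrix(c(100, 0), 1, 2,
                                    dimnames = list("body",
                                                    c("p", "m"))))
  cleared <- 100 - tr$amounts[401, 1, "p"]
  formed <- tr$amounts[401, 1, "m"]
  expect_equal(formed, cleared, tolerance = 1e-9)
  # yield 0 keeps the metabolite identically zero
  linked0 <- link_metabolite(parent, metab, "cl",
                             stoichiometric_yield = 0)
  tr0 <- simulate_pbpk(linked0, duration = 100,
                       init = matrix(c(100, 0), 1, 2,
                                     dimnames = list("body",
                                                     c("p", "m"))))
  expect_true(all(tr0$amounts[, 1, "m"] == 0))
})
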