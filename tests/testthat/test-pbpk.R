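# Whole-body ODE engine: closed forms, conservation, convergence and an
# independent stiff-solver oracle.

test_that("first-order decay matches the closed form", {
  m <- one_compartment_model(k = 0.01)
  tr <- simulate_pbpk(m, duration = 100, init = init_one(100, m))
  expect_length(tr$times, 101)
  expect_equal(tr$amounts[101, 1, 1], 100 * exp(-1), tolerance = 1e-8)
})

test_that("an empty system stays identically zero", {
  m <- one_compartment_model(k = 0.01)
  tr <- simulate_pbpk(m, duration = 50)
  expect_true(all(tr$amounts == 0))
})

test_that("mass is conserved when eliminations are absent", {
  m <- pbpk_model(
    compartments = tibble::tibble(name = c("ven", "liv", "rest"),
                                  volume = c(3, 2, 30)),
    flows = tibble::tibble(
      source = c("ven", "liv", "ven", "rest"),
      target = c("liv", "ven", "rest", "ven"),
      rate = c(1.5, 1.5, 3, 3)),
    species = tibble::tibble(name = "d"),
    partition = tibble::tibble(species = "d", compartment = "liv",
                               k = 0.8))
  tr <- simulate_pbpk(m, duration = 1440,
                      init = matrix(c(50, 0, 0), 3, 1,
                                    dimnames = list(c("ven", "liv",
                                                      "rest"), "d")))
  total <- apply(tr$amounts[, , 1], 1, sum)
  expect_lt(max(abs(total - 50)) / 50, 1e-6)
})

test_that("a closed two-compartment system equilibrates concentrations", {
  m <- pbpk_model(
    compartments = tibble::tibble(name = c("a", "b"), volume = c(2, 5)),
    flows = tibble::tibble(source = c("a", "b"), target = c("b", "a"),
                           rate = c(1, 1)),
    species = tibble::tibble(name = "x"))
  tr <- simulate_pbpk(m, duration = 300,
                      init = matrix(c(70, 0), 2, 1,
                                    dimnames = list(c("a", "b"), "x")))
  ca <- concentration(tr, "a", "x")
  cb <- concentration(tr, "b", "x")
  expect_equal(tail(ca, 1), tail(cb, 1), tolerance = 1e-9)
  expect_equal(tail(ca, 1), 10, tolerance = 1e-6)   # 70 umol / 7 L
})

test_that("halving the step changes concentrations by far less than 0.5%", {
  m <- ammonia_pbpk_model()
  tr1 <- simulate_pbpk(m, duration = 720, dt = 1)
  tr2 <- simulate_pbpk(m, duration = 720, dt = 0.5)
  c1 <- concentration(tr1, "venous_blood", "nh3")
  c2 <- concentration(tr2, "venous_blood", "nh3")[seq(1, 1441, by = 2)]
  expect_lt(max(abs(c1[-1] - c2[-1]) / pmax(c2[-1], 1e-9)), 0.005)
})

test_that("trajectories agree with an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  m <- pbpk_model(
    compartments = tibble::tibble(name = c("ven", "liv", "rest"),
                                  volume = c(3, 2, 30)),
    flows = tibble::tibble(
      source = c("ven", "liv", "ven", "rest"),
      target = c("liv", "ven", "rest", "ven"),
      rate = c(1.5, 1.5, 3, 3)),
    species = tibble::tibble(name = "d"),
    processes = list(
      process_michaelis_menten("cl", "liv", "d", vmax = 5, km = 20),
      process_zero_order("prod", "rest", "d", rate = 0.1)),
    partition = tibble::tibble(species = "d", compartment = "liv",
                               k = 0.8))
  tr <- simulate_pbpk(m, duration = 500,
                      init = matrix(c(50, 0, 0), 3, 1,
                                    dimnames = list(c("ven", "liv",
                                                      "rest"), "d")))
  rhs <- function(t, y, p) {
    cv <- y[1] / 3; cl <- y[2] / 2 / 0.8; cr <- y[3] / 30
    mm <- 5 * 2 * (y[2] / 2) / (20 + y[2] / 2)
    list(c(1.5 * cl + 3 * cr - 4.5 * cv,
           1.5 * cv - 1.5 * cl - mm,
           3 * cv - 3 * cr + 0.1 * 30))
  }
  o <- deSolve::ode(c(50, 0, 0), seq(0, 500, 1), rhs, NULL,
                    method = "lsoda", rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(o[, 2:4] - tr$amounts[, , 1])), 0.05)
})

test_that("dose events inject amounts on the coupling grid", {
  m <- one_compartment_model(k = 0)
  m$doses <- tibble::tibble(species = "drug", amount = 10,
                            route = "intravenous", time = c(0, 30))
  tr <- simulate_pbpk(m, duration = 60)
  expect_equal(tr$amounts[2, 1, 1], 10)
  expect_equal(tr$amounts[61, 1, 1], 20)
})

test_that("configuration errors name the offending reference", {
  expect_error(pbpk_model(
    compartments = tibble::tibble(name = "a", volume = 1),
    flows = tibble::tibble(source = "a", target = "b", rate = 1),
    species = tibble::tibble(name = "x")), "unknown compartment: b|b")
  expect_error(pbpk_model(
    compartments = tibble::tibble(name = "a", volume = -1),
    flows = tibble::tibble(source = character(), target = character(),
                           rate = numeric()),
    species = tibble::tibble(name = "x")), "volume")
  m <- one_compartment_model()
  expect_error(process_rate(m, "nope", tr <- NULL), "unknown process")
})

test_that("steady state honours closed forms and reports convergence", {
  # zero production -> zero steady state
  m0 <- one_compartment_model(k = 0.01)
  ss0 <- steady_state(m0, tol = 1e-8, max_time = 600)
  expect_true(ss0$converged)
  expect_equal(max(abs(ss0$state)), 0)
  # production p with first-order k: C = p / k
  m <- one_compartment_model(k = 0.02, production = 0.5)
  ss <- steady_state(m, tol = 1e-9)
  expect_equal(ss$concentrations$concentration_uM, 0.5 / 0.02,
               tolerance = 1e-6)
  # at steady state production flux equals elimination flux
  prod_flux <- process_rate(m, "prod", ss$state)
  elim_flux <- process_rate(m, "cl", ss$state)
  expect_equal(prod_flux, elim_flux, tolerance = 1e-6)
  # dose events are rejected
  m$doses <- tibble::tibble(species = "drug", amount = 1,
                            route = "intravenous", time = 0)
  expect_error(steady_state(m), "dose")
})
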