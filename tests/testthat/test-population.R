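# Virtual-population sampling and the biomarker KS statistics.

test_that("cv = 0 yields identical copies and sampling is seed-deterministic", {
  base <- c(production = 0.694, liver_k = 0.14, kidney_k = 0.8)
  spec0 <- population_spec(n = 5, cv = 0, seed = 4)
  pop0 <- sample_population(spec0, base)
  expect_true(all(pop0$production == 0.694))
  expect_true(all(pop0$kidney_k == 0.8))
  spec <- population_spec(n = 50, cv = 0.1, seed = 4)
  expect_identical(sample_population(spec, base),
                   sample_population(spec, base))
  # a different seed gives a different draw
  expect_false(identical(
    sample_population(population_spec(n = 50, cv = 0.1, seed = 5), base),
    sample_population(spec, base)))
})

test_that("large-sample moments match the requested relative spread", {
  base <- c(production = 0.694, liver_k = 0.14, kidney_k = 0.8)
  pop <- sample_population(population_spec(n = 10000, cv = 0.1,
                                           seed = 12), base)
  for (p in names(base)) {
    expect_equal(mean(pop[[p]]), base[[p]], tolerance = 0.01)
    expect_lt(abs(sd(pop[[p]]) / mean(pop[[p]]) - 0.1), 0.005)
  }
  expect_true(all(pop$production > 0))
})

test_that("KS statistic and p-value satisfy the defining cases", {
  a <- c(1, 2, 3, 4, 5)
  same <- ks_two_sample(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  disjoint <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(disjoint$statistic, 1)
  expect_error(ks_two_sample(1, a), "at least 2")
})

test_that("D is invariant under common monotone transformations", {
  set.seed(8)
  a <- rnorm(40); b <- rnorm(40, 0.5)
  d0 <- ks_two_sample(a, b)$statistic
  expect_equal(ks_two_sample(exp(a), exp(b))$statistic, d0)
  expect_equal(ks_two_sample(a^3, b^3)$statistic, d0)
})

test_that("asymptotic p agrees with a permutation estimate within 0.005", {
  set.seed(7)
  ks_D <- function(a, b) {
    w <- c(a, b)
    z <- cumsum(ifelse(order(w) <= length(a), 1 / length(a),
                       -1 / length(b)))
    max(abs(z))
  }
  a <- rnorm(100); b <- rnorm(100, 0.3)
  D <- ks_D(a, b)
  p_asym <- ks_two_sample(a, b)$p_value
  pool <- c(a, b)
  perm <- replicate(10000, {
    i <- sample(200, 100)
    ks_D(pool[i], pool[-i])
  })
  p_perm <- mean(perm >= D - 1e-12)
  expect_lt(abs(p_asym - p_perm), 0.005)
})

test_that("diseased endpoints exceed healthy endpoints individual by individual", {
  cal <- cached_ammonia_calibration()
  base <- c(production = 0.694,
            liver_k = cal$model$processes$liver_clearance$params$k,
            kidney_k = cal$model$processes$kidney_clearance$params$k)
  pop <- sample_population(population_spec(n = 6, cv = 0.1, seed = 2),
                           base)
  cohort <- run_cohort(pop)
  expect_true(all(cohort$converged))
  expect_true(all(cohort$diseased_uM > cohort$healthy_uM))
  expect_gt(mean(cohort$diseased_uM), mean(cohort$healthy_uM))
  # identical individuals give constant endpoints
  pop0 <- sample_population(population_spec(n = 2, cv = 0, seed = 2),
                            base)
  c0 <- run_cohort(pop0)
  expect_equal(c0$healthy_uM[1], c0$healthy_uM[2], tolerance = 1e-12)
  expect_equal(c0$diseased_uM[1], c0$diseased_uM[2], tolerance = 1e-12)
  # the mean patient's endpoint is close to the cohort mean at 10% CV
  expect_equal(c0$healthy_uM[1], mean(cohort$healthy_uM),
               tolerance = 0.02)
})
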