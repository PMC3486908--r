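# Case-study drivers: dose-response logic and PK properties at reduced
# horizons (the full-length protocols run in the acceptance suite).

test_that("paracetamol dose zero leaves every activity and objective untouched", {
  r0 <- run_paracetamol(dose_g = 0, duration = 360)
  expect_true(all(r0$relE[, -1] == 1))
  expect_equal(sum(r0$panel_report$affected), 0)
})

test_that("paracetamol dose raises NAPQI and deepens inhibition pointwise", {
  r1 <- run_paracetamol(1)
  r15 <- run_paracetamol(15)
  n1 <- concentration(r1$pk, "liver", "NAPQI")
  n15 <- concentration(r15$pk, "liver", "NAPQI")
  expect_true(all(n15 >= n1 - 1e-12))
  for (tag in c("THFDH", "GDH", "ATPS", "GSH")) {
    expect_true(all(r15$relE[[tag]] <= r1$relE[[tag]] + 1e-12))
  }
  # saturation of conjugation pushes the overdose disproportionately
  # into the toxic pathway
  expect_gt(max(n15) / max(n1), 15)
  # affected objectives: the toxic dose affects a superset
  a1 <- r1$panel_report |>
    dplyr::filter(.data$time_point == "t_max_napqi", .data$affected)
  a15 <- r15$panel_report |>
    dplyr::filter(.data$time_point == "t_max_napqi", .data$affected)
  expect_true(all(a1$objective %in% a15$objective))
  # the calibration anchor: peak 15 g concentration produces the stated
  # maximal inhibitions
  i15 <- which.max(n15)
  expect_equal(r15$relE$GSH[i15], 0.2, tolerance = 1e-6)
  expect_equal(r15$relE$ATPS[i15], 0.4, tolerance = 1e-6)
})

test_that("objectives recover at 24 h after 1 g but stay depressed after 15 g", {
  r1 <- run_paracetamol(1)
  r15 <- run_paracetamol(15)
  dec24 <- function(r) {
    max(r$panel_report$decrease[r$panel_report$time_point == "t_24h"])
  }
  expect_lt(dec24(r1), 0.05)
  expect_gt(dec24(r15), 0.3)
})

test_that("the alternative inhibition reading flips the activity floors", {
  r <- run_paracetamol(15, inhibition_reading = "remaining")
  n15 <- concentration(r$pk, "liver", "NAPQI")
  i15 <- which.max(n15)
  # "reduced TO 25%": THFDH floor is 0.25 instead of 0.75
  expect_equal(r$relE$THFDH[i15], 0.25, tolerance = 1e-6)
})

test_that("allopurinol therapy shows the expected PK and uric-acid response", {
  r <- run_allopurinol(n_doses = 6, record_every = 10)
  s <- stats::setNames(r$summary$value, r$summary$metric)
  expect_equal(s[["pre_treatment_uric_uM"]], 476, tolerance = 0.01)
  tr <- r$trajectory
  cv_al <- concentration(tr, "venous_blood", "allopurinol")
  cv_oxy <- concentration(tr, "venous_blood", "oxypurinol")
  cv_ua <- concentration(tr, "venous_blood", "uric_acid")
  t <- tr$times
  # parent does not accumulate: trough below 1% of peak before redosing
  for (d in 1:5) {
    win <- t > d * 1440 - 60 & t <= d * 1440
    expect_lt(min(cv_al[win]), 0.01 * max(cv_al[t <= d * 1440]))
  }
  # oxypurinol accumulates: successive troughs increase
  troughs <- vapply(1:5, function(d) {
    min(cv_oxy[t > d * 1440 - 30 & t <= d * 1440])
  }, numeric(1))
  expect_true(all(diff(troughs) > 0))
  # uric acid declines below the hyperuricemia threshold under therapy
  expect_lt(min(cv_ua), 470)
  expect_lt(tail(cv_ua, 1), cv_ua[1])
  # xanthine-oxidase activity is strongly reduced at steady dosing
  expect_lt(s[["mean_relE_last_interval"]], 0.6)
})

test_that("therapy interruption lets uric acid rebound toward the gouty state", {
  r <- run_allopurinol(n_doses = 1, follow_up = 10 * 1440,
                       record_every = 60)
  cv_ua <- concentration(r$trajectory, "venous_blood", "uric_acid")
  t <- r$trajectory$times
  expect_lt(min(cv_ua), 470)                       # initial dip
  expect_gt(tail(cv_ua, 1), 0.97 * cv_ua[1])       # near-complete rebound
})

test_that("a zero-depth disease ramp leaves the steady state unchanged", {
  cal <- cached_ammonia_calibration()
  ss <- cached_ammonia_base_ss()
  ms <- ammonia_multiscale_model(cal$model)
  act <- list(urea_cycle = function(t) 1)          # no disease
  tr <- simulate_coupled(ms, duration = 1440, init = ss$state,
                         activity = act, record_every = 1440)
  v <- concentration(tr, "venous_blood", "nh3")
  expect_equal(tail(v, 1), v[1], tolerance = 1e-3)
})

test_that("scenario results are tidy-able and self-consistent", {
  r <- run_paracetamol(1, duration = 360)
  expect_s3_class(generics::tidy(r), "tbl_df")
  expect_true(all(c("metric", "value") %in% names(generics::tidy(r))))
})
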