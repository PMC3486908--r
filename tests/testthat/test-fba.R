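# Flux balance analysis: hand-solved optima, properties, and the
# enumeration oracle.

test_that("toy ammonia network reproduces the hand-solved baseline optimum", {
  net <- make_ammonia_network()
  sol <- fba(net, "EX_nh3")
  expect_equal(sol$status, "optimal")
  # nitrogen balance: uptake = 2 urea + 2 gln + ala; caps bind
  expect_equal(unname(flux_of(sol, "EX_nh3")), 0.163)
  expect_equal(unname(flux_of(sol, "EX_gln")), 0.008)
  expect_equal(unname(flux_of(sol, "EX_ala")), 0.002)
  expect_equal(unname(flux_of(sol, "EX_urea")), (0.163 - 0.018) / 2)
})

test_that("urea-cycle block with fourfold caps gives the disease-state optimum", {
  net <- make_ammonia_network()
  ov <- tibble::tibble(reaction = c("urea_cycle", "EX_gln", "EX_ala"),
                       lb = c(0, 0, 0), ub = c(0, 0.032, 0.008))
  sol <- fba(net, "EX_nh3", overrides = ov)
  expect_equal(unname(flux_of(sol, "EX_nh3")), 2 * 0.032 + 0.008)
  expect_equal(unname(flux_of(sol, "EX_gln")), 0.032)
})

test_that("all-zero bounds give a zero optimum and infeasibility is reported", {
  net <- make_ammonia_network(glutamine_cap = 0, alanine_cap = 0,
                              uptake_ub = 0)
  sol <- fba(net, "EX_nh3")
  expect_equal(sol$objective_value, 0)
  # secretion demand above the offered uptake is infeasible
  ov <- tibble::tibble(reaction = "EX_nh3", lb = NA, ub = 0.001)
  sol2 <- fba(make_ammonia_network(), "EX_nh3", overrides = ov)
  expect_equal(sol2$status, "infeasible")
  expect_null(sol2$fluxes)
})

test_that("optimum scales with bounds and never decreases when relaxed", {
  base <- make_ammonia_network()
  f0 <- fba(base, "EX_nh3")$objective_value
  for (c_scale in c(0.5, 2, 7)) {
    net_s <- make_ammonia_network(0.008 * c_scale, 0.002 * c_scale,
                                  0.163 * c_scale)
    expect_equal(fba(net_s, "EX_nh3")$objective_value, c_scale * f0,
                 tolerance = 1e-9)
  }
  relaxed <- fba(base, "EX_nh3",
                 overrides = tibble::tibble(reaction = "EX_nh3",
                                            lb = NA, ub = 0.4))
  expect_gte(relaxed$objective_value, f0 - 1e-12)
})

test_that("LP optima equal exhaustive vertex enumeration on small networks", {
  # randomised <=6-reaction chains with caps
  set.seed(11)
  for (i in 1:20) {
    caps <- round(runif(3, 0.1, 2), 2)
    net <- metabolic_network(tibble::tibble(
      reaction_id = c("in1", "in2", "conv", "out"),
      equation = c("-> a[c]", "-> b[c]", "a[c] + b[c] -> c[c]",
                   "c[c] ->"),
      lb = 0, ub = c(caps, Inf)))
    sol <- fba(net, "out")
    expect_equal(sol$objective_value, enum_fba_max(net, "out"),
                 tolerance = 1e-8)
  }
  net <- make_purine_network(supply_ub = 1.7)
  expect_equal(fba(net, "EX_ua")$objective_value,
               enum_fba_max(net, "EX_ua"), tolerance = 1e-8)
})

test_that("parsimonious selection is reproducible under reaction reordering", {
  gp <- make_gsh_panel()
  tab <- tibble::tibble(
    reaction_id = gp$network$reactions$id,
    equation = purrr::map_chr(seq_len(ncol(gp$network$S)), function(j) {
      dfbalink:::format_equation(gp$network$S[, j])
    }),
    lb = gp$network$reactions$lb, ub = gp$network$reactions$ub,
    notes = gp$network$reactions$notes)
  set.seed(3)
  v_ref <- flux_of(fba(gp$network, "EX_gsh"))
  for (i in 1:3) {
    perm <- sample(nrow(tab))
    net_p <- metabolic_network(tab[perm, ])
    v_p <- flux_of(fba(net_p, "EX_gsh"))
    expect_equal(v_p[names(v_ref)], v_ref, tolerance = 1e-9)
  }
})

test_that("check_balance accepts optima and flags perturbed fluxes", {
  net <- make_ammonia_network()
  sol <- fba(net, "EX_nh3")
  expect_true(check_balance(net, sol)$pass)
  v <- flux_of(sol)
  expect_equal(check_balance(net, stats::setNames(rep(0, length(v)),
                                                  names(v)))$residual, 0)
  v["GDH"] <- v["GDH"] + 0.01        # internal perturbation imbalances S v
  cb <- check_balance(net, v)
  expect_false(cb$pass)
  expect_gte(cb$residual, 0.01 * min(abs(net$S[net$S != 0])))
})
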