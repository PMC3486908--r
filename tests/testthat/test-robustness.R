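# Objective-panel scans and flux-change classification.

test_that("panel counts partition the compared set and respect tightening", {
  gp <- make_gsh_panel()
  inh <- stats::setNames(rep(0.2, 2),
                         reactions_by_tag(gp$network, "GSH"))
  rep <- evaluate_panel(gp$network, gp$panel, inh)
  expect_true(all(rep$perturbed <= rep$reference + 1e-9))
  expect_true(all(rep$decrease >= 0 & rep$decrease <= 1))
  # glutathione-dependent objectives drop to relE of their reference
  expect_equal(rep$decrease[rep$objective == "EX_gsh"], 0.8,
               tolerance = 1e-8)
})

test_that("stronger inhibition never shrinks the affected set", {
  gp <- make_gsh_panel()
  tags <- c("THFDH", "GDH", "ATPS", "GSH")
  state_at <- function(relEs) {
    out <- numeric(0)
    for (i in seq_along(tags)) {
      r <- reactions_by_tag(gp$network, tags[i])
      out[r] <- relEs[i]
    }
    out
  }
  weak <- evaluate_panel(gp$network, gp$panel,
                         state_at(c(0.9, 0.9, 0.8, 0.6)))
  strong <- evaluate_panel(gp$network, gp$panel,
                           state_at(c(0.75, 0.75, 0.4, 0.2)))
  expect_true(all(weak$objective[weak$affected] %in%
                    strong$objective[strong$affected]))
  expect_gte(sum(strong$affected), sum(weak$affected))
})

test_that("flux classification partitions and detects the trivial case", {
  net <- make_purine_network(supply_ub = 1)
  ref <- fba(net, "EX_ua")
  self <- classify_flux_changes(ref, ref)
  expect_equal(self$fraction_unchanged, 1)
  expect_equal(sum(self$counts$n), self$n_compared)
  # halving a linear chain: every active flux becomes smaller, none new
  v0 <- flux_of(ref)
  ov <- dplyr::bind_rows(constrain_flux(net, "XO1", 0.5, v0[["XO1"]]),
                         constrain_flux(net, "XO2", 0.5, v0[["XO2"]]))
  half <- fba(net, "EX_ua", overrides = ov)
  cls <- classify_flux_changes(ref, half)
  expect_equal(cls$counts$n[cls$counts$class == "smaller"],
               cls$n_compared)
  expect_equal(cls$counts$n[cls$counts$class == "new"], 0L)
  expect_equal(sum(cls$counts$n), cls$n_compared)
})

test_that("blocking the primary route activates rerouting fluxes", {
  # two routes to the same product; the parsimonious reference uses the
  # short one, blocking it reroutes through the long one ("new" fluxes)
  net <- metabolic_network(tibble::tibble(
    reaction_id = c("S_a", "direct", "det1", "det2", "EX_p"),
    equation = c("-> a[c]", "a[c] -> p[c]", "a[c] -> i[c]",
                 "i[c] -> p[c]", "p[c] ->"),
    lb = 0, ub = c(1, Inf, Inf, Inf, Inf)))
  ref <- fba(net, "EX_p")
  expect_equal(unname(flux_of(ref, "direct")), 1)   # short route wins
  blocked <- fba(net, "EX_p",
                 overrides = tibble::tibble(reaction = "direct",
                                            lb = 0, ub = 0))
  expect_equal(blocked$objective_value, 1)          # optimum preserved
  cls <- classify_flux_changes(ref, blocked)
  expect_equal(sort(cls$detail$reaction[cls$detail$class == "new"]),
               c("det1", "det2"))
})

test_that("mismatched reaction sets are rejected", {
  net <- make_purine_network(supply_ub = 1)
  gp <- make_gsh_panel()
  expect_error(classify_flux_changes(fba(net, "EX_ua"),
                                     fba(gp$network, "EX_gsh")),
               "different reaction sets")
})

test_that("affected sets are invariant to reaction ordering", {
  gp <- make_gsh_panel()
  inh <- stats::setNames(c(0.3, 0.3),
                         reactions_by_tag(gp$network, "GSH"))
  rep1 <- evaluate_panel(gp$network, gp$panel, inh)
  tab <- tibble::tibble(
    reaction_id = gp$network$reactions$id,
    equation = purrr::map_chr(seq_len(ncol(gp$network$S)), function(j) {
      dfbalink:::format_equation(gp$network$S[, j])
    }),
    lb = gp$network$reactions$lb, ub = gp$network$reactions$ub,
    notes = gp$network$reactions$notes)
  set.seed(5)
  net2 <- metabolic_network(tab[sample(nrow(tab)), ])
  rep2 <- evaluate_panel(net2, gp$panel, inh)
  expect_equal(rep2$affected[match(rep1$objective, rep2$objective)],
               rep1$affected)
  expect_equal(rep2$decrease[match(rep1$objective, rep2$objective)],
               rep1$decrease, tolerance = 1e-9)
})
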