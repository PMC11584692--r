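test_that("cohort generation respects range, determinism and limits", {
  m <- defaultModel()
  cohort <- generateCohort(m$params, nCells = 100, seed = 5)
  expect_length(cohort@cells, 100)
  allm <- do.call(rbind, lapply(cohort@cells, `[[`, "multipliers"))
  expect_true(all(allm >= 0.5 & allm <= 2))
  cohort2 <- generateCohort(m$params, nCells = 100, seed = 5)
  expect_identical(lapply(cohort@cells, `[[`, "multipliers"),
                   lapply(cohort2@cells, `[[`, "multipliers"))
  # sd -> 0 degenerates to the baseline cell
  c0 <- generateCohort(m$params, nCells = 5, seed = 1, sd = 1e-12)
  expect_equal(max(abs(do.call(c, lapply(c0@cells, `[[`,
                                         "multipliers")) - 1)), 0,
               tolerance = 1e-9)
  expect_error(generateCohort(m$params, nCells = 0), ">= 1")
  expect_error(generateCohort(m$params, character(0)), "nonempty")
})

test_that("heterogeneity multipliers center on 1 (law of large numbers)", {
  m <- defaultModel()
  big <- generateCohort(m$params, c("kt_Succinate", "kd_ROS"),
                        nCells = 10000, seed = 8)
  allm <- do.call(rbind, lapply(big@cells, `[[`, "multipliers"))
  expect_lt(max(abs(colMeans(allm) - 1)), 0.02)
})

test_that("interventions compose multiplicatively and are seeded", {
  m <- defaultModel()
  cohort <- generateCohort(m$params, nCells = 50, seed = 2)
  # identity intervention leaves multipliers unchanged
  same <- applyIntervention(cohort, "succinate", low = 1, high = 1)
  expect_equal(lapply(same@cells, `[[`, "multipliers"),
               lapply(lapply(cohort@cells, `[[`, "multipliers"),
                      function(x) x))
  treat <- applyIntervention(cohort, "succinate", 0.5, 0.8, seed = 4)
  for (i in seq_along(treat@cells)) {
    mt <- treat@cells[[i]]$multipliers["kt_Succinate"]
    expect_gte(mt, 0.5 * 0.5 - 1e-9)
    expect_lte(mt, 2 * 0.8 + 1e-9)
  }
  treat2 <- applyIntervention(cohort, "succinate", 0.5, 0.8, seed = 4)
  expect_identical(lapply(treat@cells, `[[`, "multipliers"),
                   lapply(treat2@cells, `[[`, "multipliers"))
  # enhancement uses the reciprocal range
  enh <- applyIntervention(cohort, "IkB", 0.5, 0.8, seed = 4,
                           mode = "enhance")
  eff <- vapply(enh@cells, function(cell)
    cell$provenance$intervention$efficacy, numeric(1))
  expect_true(all(eff >= 1.25 - 1e-9 & eff <= 2 + 1e-9))
  expect_error(applyIntervention(cohort, "nope"), "unknown target")
})

test_that("identical baseline cells show zero between-cell variance", {
  m <- defaultModel()
  c0 <- generateCohort(m$params, nCells = 3, seed = 1, sd = 1e-12)
  res <- simulateCohort(m$network, m$params, c0,
                        protocol = makeOGDRProtocol(6, 2,
                                                    preEquilibration = 1),
                        state = m$state)
  cf <- vapply(res@cells, function(x) x$endpoint["cell_function"],
               numeric(1))
  expect_lt(stats::sd(cf) / mean(cf), 1e-6)
  expect_length(res@failures, 0)
})

test_that("cohort summaries reduce hand-built pairs correctly", {
  mk <- function(ids, cfs) {
    cells <- Map(function(id, cf)
      list(cellId = id, endpoint = c(cell_function = cf)), ids, cfs)
    names(cells) <- ids
    new("CohortResult", cells = cells, summary = list(),
        failures = character(0))
  }
  treated <- mk(c("a", "b", "c"), c(2, 1, 3))
  control <- mk(c("a", "b", "c"), c(1, 2, 1))
  s <- summarizeCohort(treated, control)
  expect_equal(sort(unname(s$fold_changes)), c(0.5, 2, 3))
  expect_equal(s$median, 2)
  expect_equal(s$fraction_improved, 2 / 3)
  # treated == control: all fold changes 1, none strictly improved
  s0 <- summarizeCohort(control, control)
  expect_true(all(s0$fold_changes == 1))
  expect_equal(s0$fraction_improved, 0)
  expect_error(summarizeCohort(treated, mk("z", 1)), "id mismatch")
})

test_that("target modulation is monotone in intervention strength", {
  m <- defaultModel()
  cfs <- vapply(c(1, 0.8, 0.6, 0.4), function(s)
    endpointCF(simulateTargetModulation(m$network, m$params, "succinate",
                                        s)$treated), numeric(1))
  # strength 1 equals control; stronger inhibition raises endpoint CF
  ctrl <- endpointCF(simulateTargetModulation(m$network, m$params,
                                              "succinate", 1)$control)
  expect_equal(cfs[1], ctrl, tolerance = 1e-9)
  expect_true(all(diff(cfs) > 0))
})
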