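# One full protocol simulation is reused across the blocks below.
jak_model <- jakstat_model()
jak_sim <- simulate_jakstat(jak_model, dt_out = 30)

test_that("the model has the documented structure", {
  expect_length(jak_model$species, 36)
  expect_length(jak_model$params, 50)
  expect_setequal(names(jak_model$conservation),
                  c("Jak", "receptor", "SHP2", "PPX", "PPN"))
  expect_error(jakstat_model(jakstat_params()[-1]), "missing parameter")
  p <- c(jakstat_params(), extra = 1)
  expect_error(jakstat_model(p), "unknown parameter")
})

test_that("stoichiometry conserves what it should and balances synthesis", {
  set.seed(55)
  p <- as.list(jakstat_params())
  for (i in 1:5) {
    y <- runif(36, 0, 50)
    names(y) <- jak_model$species
    d <- unlist(jak_model$rhs(0, y, NULL))
    names(d) <- jak_model$species
    for (nm in names(jak_model$conservation))
      expect_equal(sum(d * jak_model$conservation[[nm]]), 0, tolerance = 1e-9)
    # total STAT1 changes only through translation minus degradation
    w <- jakstat_readout_weights(jak_model)
    expect_equal(sum(d * w$STAT1_total),
                 p$k_stat1_tl * y[["stat1_mRNAc"]] - p$k_stat1_deg * y[["STAT1c"]],
                 tolerance = 1e-9)
    expect_equal(sum(d * w$SOCS1_total),
                 p$k_socs1_tl * y[["socs1_mRNAc"]] - p$k_socs1_deg * y[["SOCS1"]],
                 tolerance = 1e-9)
  }
})

test_that("the zero-signal steady state is a fixed point and untreated arms stay flat", {
  y0 <- primingscreen:::jakstat_steady_state(jak_model)
  expect_lt(max(abs(unlist(jak_model$rhs(0, y0, NULL)))), 1e-8)
  flat <- jak_sim$untreated
  rel_drift <- apply(flat$values, 2, function(v)
    if (max(abs(v)) < 1e-12) 0 else diff(range(v)) / max(abs(v)))
  expect_lt(max(rel_drift), 1e-4)
})

test_that("conserved moieties drift by less than 1e-6 over the full protocol", {
  for (arm in c("HD", "LD_HD")) {
    tc <- jak_sim[[arm]]
    for (nm in names(jak_model$conservation)) {
      tot <- as.numeric(tc$values %*% jak_model$conservation[[nm]])
      expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6,
                label = paste(arm, nm, "drift"))
    }
  }
})

test_that("species never go negative under the tested protocols", {
  for (arm in names(jak_sim))
    expect_gte(min(jak_sim[[arm]]$values), -1e-8)
})

test_that("low-dose priming raises total STAT1 but not SOCS1", {
  base <- jakstat_readout_course(jak_sim, "untreated")
  ld <- jakstat_readout_course(jak_sim, "LD")
  end_prime <- attr(jak_sim, "ld_period")[2]
  stat1_base <- primingscreen:::tc_at(base, "STAT1_total", end_prime)
  stat1_ld <- primingscreen:::tc_at(ld, "STAT1_total", end_prime)
  expect_gt(stat1_ld / stat1_base, 2)
  socs1_ld <- max(ld$values[, "SOCS1_total"])
  socs1_hd <- max(jakstat_readout_course(jak_sim, "HD")$values[, "SOCS1_total"])
  expect_lt(socs1_ld, 0.1 * socs1_hd)
})

test_that("priming amplifies the phosphorylated STAT1 dimer and IRF-1 peaks", {
  r_sd <- priming_readout_report(jak_sim, "STAT1sD")
  expect_gte(r_sd$peak_ratio, 1.5)
  expect_true(r_sd$verdict$primed)
  r_irf <- priming_readout_report(jak_sim, "IRF1")
  expect_gt(r_irf$peak_ratio, 1)
})

test_that("removing the IFN-to-stat1 coupling abolishes the priming advantage", {
  p <- jakstat_params()
  p["k_x_prod"] <- 0
  m0 <- jakstat_model(p)
  sim0 <- simulate_jakstat(m0, dt_out = 30)
  base <- jakstat_readout_course(sim0, "untreated")
  ld <- jakstat_readout_course(sim0, "LD")
  end_prime <- attr(sim0, "ld_period")[2]
  rise <- primingscreen:::tc_at(ld, "STAT1_total", end_prime) /
    primingscreen:::tc_at(base, "STAT1_total", end_prime)
  expect_lt(rise, 1.05)
  r0 <- priming_readout_report(sim0, "STAT1sD")
  r1 <- priming_readout_report(jak_sim, "STAT1sD")
  expect_lt(r0$peak_ratio, r1$peak_ratio)
  # without the coupling the 50% excess is lost (ratio falls toward 1)
  expect_lt(r0$peak_ratio, 1.5)
  expect_false(r0$verdict$primed)
})
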