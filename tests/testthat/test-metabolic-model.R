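test_that("Arrhenius correction matches direct evaluation", {
  expect_equal(arrhenius_correct(0.7, 1.08, 20), 0.7)
  expect_equal(arrhenius_correct(0.7, 1, 28), 0.7)
  expect_equal(arrhenius_correct(1, 1.05, 30), 1.05^10)
  expect_equal(arrhenius_correct(1, 1.05, 30), 1.6289, tolerance = 1e-4)
  expect_error(arrhenius_correct(1, -0.5, 20), "positive")
})

test_that("pH acts on transport energy and P release but not on the
           acetate glycogen stoichiometry", {
  y6 <- ph_yields(6, "HAc")
  y75 <- ph_yields(7.5, "HAc")
  expect_false(isTRUE(all.equal(y6$p_release, y75$p_release)))
  expect_identical(y6$y_gly, y75$y_gly)  # pH-independent for acetate
  p6 <- ph_yields(6, "HPr")
  p75 <- ph_yields(7.5, "HPr")
  expect_false(isTRUE(all.equal(p6$p_release, p75$p_release)))
  expect_false(isTRUE(all.equal(p6$y_gly, p75$y_gly)))
  # continuity in pH
  for (src in c("HAc", "HPr")) {
    a <- ph_yields(7, src)
    b <- ph_yields(7 + 1e-6, src)
    expect_lt(abs(a$p_release - b$p_release), 1e-4)
    expect_lt(abs(a$y_pha_total - b$y_pha_total), 1e-4)
  }
  expect_error(ph_yields(5.5, "HAc"), "range")
  expect_error(ph_yields(8, "HPr"), "range")
})

test_that("every process column balances carbon over the validated pH
           range", {
  for (ph in c(6, 6.7, 7.5)) {
    for (src in c("HAc", "HPr")) {
      y <- ph_yields(ph, src)
      expect_equal(1 + y$y_gly, y$y_pha_total + y$co2, tolerance = 1e-9)
      expect_equal(sum(y$pha_split), 1, tolerance = 1e-9)
    }
  }
})

test_that("anaerobic rate laws: biomass proportionality, Monod gating and
           sequential maintenance", {
  row <- paper_scenario()
  rp <- resolve_parameters(row)
  r <- anaerobic_rates(rp$init, rp$parms)
  expect_true(all(r >= 0))
  expect_gt(r[["uptake_HAc"]], 0)
  # no biomass, no activity
  s0 <- rp$init
  s0["X_PAO"] <- 0
  s0[c("X_PHB", "X_PHV", "X_PH2MV", "X_Gly", "X_PP")] <- 0
  expect_true(all(anaerobic_rates(s0, rp$parms) == 0))
  # no substrate: uptake stops, maintenance continues on reserves
  s1 <- rp$init
  s1[c("S_HAc", "S_HPr")] <- 0
  r1 <- anaerobic_rates(s1, rp$parms)
  expect_identical(unname(r1[c("uptake_HAc", "uptake_HPr")]), c(0, 0))
  expect_gt(r1[["maint_PP"]], 0)
  # doubling biomass at fixed intra-cellular fractions doubles uptake
  s2 <- rp$init
  s2[c("X_PAO", "X_PHB", "X_PHV", "X_PH2MV", "X_Gly", "X_PP")] <-
    2 * s2[c("X_PAO", "X_PHB", "X_PHV", "X_PH2MV", "X_Gly", "X_PP")]
  r2 <- anaerobic_rates(s2, rp$parms)
  expect_equal(r2[["uptake_HAc"]], 2 * r[["uptake_HAc"]], tolerance = 1e-9)
  expect_equal(r2[["uptake_HPr"]], 2 * r[["uptake_HPr"]], tolerance = 1e-9)
  # poly-P priority: with poly-P present, glycogen maintenance is inactive
  expect_lt(r[["maint_Gly"]] / r[["maint_PP"]], 1e-3)
  s3 <- rp$init
  s3["X_PP"] <- 0
  r3 <- anaerobic_rates(s3, rp$parms)
  expect_gt(r3[["maint_Gly"]], 0)
  expect_error(anaerobic_rates(replace(rp$init, 2, -1), rp$parms),
               "negative")
})

test_that("aerobic rate laws: substrate limits, storage caps and the VFA
           gate", {
  row <- paper_scenario()
  rp <- resolve_parameters(row)
  st <- rp$init
  st["S_O2"] <- 0.25
  # no PHA: no degradation, no growth
  s0 <- st
  s0[c("X_PHB", "X_PHV", "X_PH2MV")] <- 0
  r0 <- aerobic_rates(s0, rp$parms)
  expect_identical(r0[["pha_degradation"]], 0)
  expect_identical(r0[["growth"]], 0)
  # poly-P at its cap shuts down poly-P formation
  s1 <- st
  s1["X_PP"] <- rp$parms[["f_PP_max"]] * s1[["X_PAO"]]
  expect_identical(aerobic_rates(s1, rp$parms)[["pp_formation"]], 0)
  # glycogen at its cap shuts down glycogen formation
  s2 <- st
  s2["X_Gly"] <- rp$parms[["f_Gly_max"]] * s2[["X_PAO"]]
  expect_identical(aerobic_rates(s2, rp$parms)[["gly_formation"]], 0)
  # the gate suppresses aerobic VFA uptake even with residual acetate
  s3 <- st
  s3["S_HAc"] <- 0.8
  expect_identical(aerobic_rates(s3, rp$parms,
                                 vfa_gate = FALSE)[["uptake_HAc"]], 0)
  expect_gt(aerobic_rates(s3, rp$parms, vfa_gate = TRUE)[["uptake_HAc"]], 0)
})

test_that("compiled and reference derivatives agree to 1e-12 on random
           states", {
  pm <- draw_rows(25, seed = 21)
  set.seed(22)
  worst <- 0
  for (i in 1:25) {
    rp <- resolve_parameters(full_row(pm, i))
    for (phase in c(1, 2)) {
      for (rep in 1:20) {
        st <- rp$init
        st[] <- runif(11, 0, 3)
        st["S_O2"] <- runif(1, 0, 0.25)
        p <- rp$parms
        p[["phase"]] <- phase
        p[["vfa_gate"]] <- sample(0:1, 1)
        d_c <- .Call("pao_eval_deriv", as.numeric(st), as.numeric(p),
                     PACKAGE = "paosens")
        d_r <- paosens:::.pao_deriv_r(st, p)
        d_o <- oracle_deriv(st, p)
        scale <- max(1, max(abs(d_o)))
        worst <- max(worst, max(abs(d_c - unname(d_o))) / scale,
                     max(abs(unname(d_r) - unname(d_o))) / scale)
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("a zero-biomass cycle is the identity trajectory", {
  row <- paper_scenario()
  row["X_PAO_i"] <- 0
  rp <- resolve_parameters(row)
  traj <- simulate_cycle(rp$init, rp$parms)
  for (comp in c("S_HAc", "S_HPr", "S_PO4", "X_PHB", "X_Gly", "X_PP")) {
    expect_equal(traj[[comp]], rep(rp$init[[comp]], nrow(traj)),
                 tolerance = 1e-12)
  }
})

test_that("the reference scenario reproduces the qualitative cycle
           profile", {
  rp <- resolve_parameters(paper_scenario())
  traj <- simulate_cycle(rp$init, rp$parms)
  an <- traj$phase == "anaerobic"
  expect_identical(sum(diff(an) != 0), 1L)  # one phase switch
  expect_equal(traj$time[max(which(an))], 2.5)
  # anaerobically: VFA falls, phosphate rises, biomass exactly constant
  expect_lt(traj$S_HAc[sum(an)], traj$S_HAc[1])
  expect_lt(traj$S_HPr[sum(an)], traj$S_HPr[1])
  expect_gt(traj$S_PO4[sum(an)], traj$S_PO4[1])
  expect_identical(max(abs(traj$X_PAO[an] - traj$X_PAO[1])), 0)
  # aerobically: phosphate is taken up again and biomass grows
  expect_lt(traj$S_PO4[nrow(traj)], traj$S_PO4[sum(an)])
  expect_gt(traj$X_PAO[nrow(traj)], traj$X_PAO[sum(an)])
})

test_that("solver failures carry the offending parameters", {
  rp <- resolve_parameters(paper_scenario())
  p <- rp$parms
  p[["qHAc_T"]] <- NaN
  expect_error(simulate_cycle(rp$init, p), "non-finite|parameters")
})
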