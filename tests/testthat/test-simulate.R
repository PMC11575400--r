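test_that("batch growth obeys the degenerate and conservation limits", {
  # no uptake: OD stays at P0
  g0 <- genotype("null", Y = 1, V = 0, K = 0.06, resource = "benzoate")
  cv <- simulate_batch_growth(g0, R0 = 0.6, P0 = 0.01, t_grid = t_grid_24h)
  expect_equal(cv$od, rep(0.01, length(t_grid_24h)), tolerance = 1e-9)

  # total conversion: final OD -> P0 + Y * R0
  g1 <- genotype("conv", Y = 1, V = 10, K = 0.06, resource = "benzoate")
  cv1 <- simulate_batch_growth(g1, R0 = 0.6, P0 = 0.01,
                               t_grid = seq(0, 48, by = 0.5))
  expect_equal(max(cv1$od), 0.61, tolerance = 1e-4)

  # resource-biomass conservation at all output times
  cv2 <- noiseless_curve()
  resid <- cv2$od - 0.005 - 0.05 * (0.6 - cv2$resource)
  expect_lt(max(abs(resid)), 1e-7)
  expect_true(all(cv2$od >= 0 & cv2$resource >= 0))
  expect_true(all(diff(cv2$resource) <= 1e-12))

  expect_error(simulate_batch_growth(g1, R0 = -1, P0 = 0.01, t_grid = 0:2),
               "R0")
  expect_error(simulate_batch_growth(g1, R0 = 0.6, P0 = 0, t_grid = 0:2),
               "P0")
  expect_error(simulate_batch_growth(g1, R0 = 0.6, P0 = 0.01,
                                     t_grid = c(0, 2, 1)), "t_grid")
})

test_that("cross-feeding cycle routes resource through the producer", {
  aj <- genotype("Aj", Y = 0.04, V = 8, K = 0.05,
                 resource = "benzyl_alcohol", produces = "benzoate",
                 leak_fraction = 1)
  pp <- genotype("Pp", Y = 0.05, V = 7, K = 0.06, resource = "benzoate")

  # leak 0: consumer starves at its starting density
  aj0 <- genotype("Aj", Y = 0.04, V = 8, K = 0.05,
                  resource = "benzyl_alcohol", produces = "benzoate",
                  leak_fraction = 0)
  st <- community_state(c(benzyl_alcohol = 0.6, benzoate = 0),
                        c(Aj = 1e-3, Pp = 1e-3))
  tr0 <- simulate_crossfeed_cycle(st, list(aj0, pp))
  expect_equal(tr0$Pp[nrow(tr0)], 1e-3, tolerance = 1e-8)

  # full leak: benzoate produced never exceeds benzyl alcohol consumed,
  # benzyl alcohol is monotone non-increasing, everything non-negative
  tr1 <- simulate_crossfeed_cycle(st, list(aj, pp))
  consumed <- 0.6 - tr1$benzyl_alcohol
  supplied <- tr1$benzoate + (tr1$Pp - 1e-3) / pp$Y
  expect_true(all(supplied <= consumed + 1e-7))
  expect_true(all(diff(tr1$benzyl_alcohol) <= 1e-12))
  expect_true(all(as.matrix(tr1[-1]) >= 0))
  expect_gt(tr1$Pp[nrow(tr1)], 10 * 1e-3)   # the consumer actually grew

  # no producer: reduces to single-species batch growth on the shared pool
  st2 <- community_state(c(benzoate = 0.6), c(Pp = 0.005))
  tr2 <- simulate_crossfeed_cycle(st2, list(pp))
  ref <- simulate_batch_growth(mk_genotype(label = "Pp"), R0 = 0.6,
                               P0 = 0.005, t_grid = t_grid_24h)
  expect_equal(tr2$Pp, ref$od, tolerance = 1e-8)

  # symmetry: identical genotypes started 50:50 stay 50:50
  ppb <- genotype("Pp2", Y = 0.05, V = 7, K = 0.06, resource = "benzoate")
  st3 <- community_state(c(benzoate = 0.6), c(Pp = 0.002, Pp2 = 0.002))
  tr3 <- simulate_crossfeed_cycle(st3, list(pp, ppb))
  expect_equal(tr3$Pp, tr3$Pp2, tolerance = 1e-10)

  expect_error(simulate_crossfeed_cycle(st, list(pp, pp)), "duplicated")
})

test_that("serial transfers dilute 1:100, keep neutral frequencies, fix the faster genotype", {
  a <- genotype("a", Y = 0.02, V = 25, K = 0.06, resource = "benzoate")
  b <- genotype("b", Y = 0.02, V = 25, K = 0.06, resource = "benzoate")
  st <- community_state(c(benzoate = 0.6), c(a = 6e-5, b = 6e-5))
  proto <- transfer_protocol(days = 3)
  ser <- run_serial_transfers(st, list(a, b), proto)

  # dilution arithmetic: with the resource exhausted daily the cycle is
  # (nearly) periodic, so end-of-day densities repeat: each day's start is
  # 1/100 of the previous end and regrowth is resource-limited
  d1 <- ser$cfu_per_ml[ser$day == 1 & ser$label == "a"]
  d2 <- ser$cfu_per_ml[ser$day == 2 & ser$label == "a"]
  expect_equal(d1, d2, tolerance = 0.02)

  # neutrality: equal params, equal start -> frequency constant
  fr <- ser |>
    dplyr::group_by(day) |>
    dplyr::summarise(f = cfu_per_ml[label == "a"] / sum(cfu_per_ml))
  expect_true(all(abs(fr$f - 0.5) < 1e-10))

  # 2x mu_max (same Y): winner fixes, loser censored at 1e2 CFU/mL in
  # finite time
  fast <- genotype("fast", Y = 0.02, V = 50, K = 0.06, resource = "benzoate")
  st2 <- community_state(c(benzoate = 0.6), c(a = 6e-5, fast = 6e-5))
  ser2 <- run_serial_transfers(st2, list(a, fast),
                               transfer_protocol(days = 25))
  fr2 <- ser2 |>
    dplyr::group_by(day) |>
    dplyr::summarise(f = cfu_per_ml[label == "fast"] / sum(cfu_per_ml))
  # strictly increasing until the frequency saturates at 1 in double
  # precision
  expect_true(all(diff(fr2$f) > 0 | fr2$f[-1] >= 1 - 1e-12))
  expect_true(any(ser2$censored[ser2$label == "a"]))
  expect_gt(max(fr2$f), 0.999)
})

test_that("mutant injection conserves total density and validates input", {
  st <- community_state(c(benzoate = 0.6), c(anc = 0.01))
  mut <- genotype("mut", Y = 0.068, V = 10, K = 0.06, resource = "benzoate")
  st2 <- inject_mutant(st, "anc", mut, 0.5)
  expect_equal(st2$densities[["anc"]], st2$densities[["mut"]])
  expect_equal(sum(st2$densities), 0.01)
  expect_error(inject_mutant(st, "nope", mut, 0.5), "unknown parent")
  expect_error(inject_mutant(st, "anc", mut, 1), "initial_fraction")
  expect_error(inject_mutant(st2, "anc", mut, 0.5), "already present")
})

test_that("OD noise is multiplicative, floored, and seed-reproducible", {
  cv <- noiseless_curve()
  expect_identical(add_od_noise(cv, cv = 0)$od, cv$od)
  n1 <- add_od_noise(cv, cv = 0.05, seed = 7)
  n2 <- add_od_noise(cv, cv = 0.05, seed = 7)
  expect_identical(n1$od, n2$od)
  expect_true(all(n1$od >= 1e-4))

  # Monte-Carlo: sample sd of log-OD within 10% of the nominal cv
  flat <- tibble::tibble(time = seq_len(1000), od = rep(0.1, 1000))
  nz <- add_od_noise(flat, cv = 0.05, seed = 1)
  expect_lt(abs(sd(log(nz$od)) - 0.05) / 0.05, 0.1)
})

test_that("transfers support plating noise, demographic sampling and extinction", {
  a <- genotype("a", Y = 0.02, V = 10, K = 0.06, resource = "benzoate")
  st <- community_state(c(benzoate = 0.6), c(a = 6e-5))
  s1 <- run_serial_transfers(st, list(a), transfer_protocol(days = 2),
                             plating_noise_cv = 0.05, seed = 3)
  s2 <- run_serial_transfers(st, list(a), transfer_protocol(days = 2),
                             plating_noise_cv = 0.05, seed = 3)
  expect_identical(s1$cfu_per_ml, s2$cfu_per_ml)

  s3 <- run_serial_transfers(st, list(a), transfer_protocol(days = 2),
                             sample_cells = TRUE, seed = 4)
  expect_s3_class(s3, "xf_transfer_series")

  # zero total density halts with an extinction report
  tiny <- community_state(c(benzoate = 0.6), c(a = 0))
  expect_error(run_serial_transfers(tiny, list(a), transfer_protocol(days = 2)),
               "extinct")
})
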