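test_that("yield follows (ODmax - ODmin)/R0 with a no-growth flag", {
  od <- c(0.005, 0.005, 0.005, 0.1, 0.605)
  y <- estimate_yield(od, R0 = 0.6)
  expect_equal(y$Y, 1.0, tolerance = 1e-12)
  expect_false(y$no_growth)

  flat <- estimate_yield(rep(0.01, 20), R0 = 0.6)
  expect_equal(flat$Y, 0)
  expect_true(flat$no_growth)
})

test_that("sliding-window growth rates recover exact exponentials", {
  tt <- seq(0, 10, by = 1 / 6)
  od <- 0.01 * exp(0.5 * tt)
  mu <- instantaneous_growth_rates(tt, od, window = 5)
  expect_equal(mu$mu, rep(0.5, nrow(mu)), tolerance = 1e-6)

  # doubling over 1 h with a 2-point window gives ln 2
  mu2 <- instantaneous_growth_rates(c(0, 1), c(0.01, 0.02), window = 2)
  expect_equal(mu2$mu, log(2), tolerance = 1e-12)

  expect_error(instantaneous_growth_rates(tt, od[-1], window = 5))
})

test_that("resource reconstruction inverts the yield relation", {
  tt <- 0:10
  od <- c(0.005, 0.005, 0.005, seq(0.05, 0.305, length.out = 8))
  r <- reconstruct_resource(tt, od, Y = 1.0, R0 = 0.6)
  expect_equal(r$R[length(tt)], 0.6 - 0.3, tolerance = 1e-9)
  expect_true(all(diff(r$R) <= 1e-12))

  # simulator round-trip: reconstructed R matches the true R within 1% R0
  cv <- noiseless_curve()
  y <- estimate_yield(cv$od, R0 = 0.6)
  rr <- reconstruct_resource(cv$time, cv$od, y$Y, R0 = 0.6,
                             od_min = y$od_min)
  expect_lt(max(abs(rr$R - cv$resource)), 0.01 * 0.6)
})

test_that("uptake series is mu/Y on the reconstructed resource", {
  mu_tbl <- tibble::tibble(t = c(1, 2), mu = c(0.5, 0), od_mid = c(0.1, 0.2))
  res_tbl <- tibble::tibble(t = c(1, 2), od_smooth = c(0.1, 0.2),
                            R = c(0.4, 0.2))
  q <- uptake_series(mu_tbl, res_tbl, Y = 0.05)
  expect_equal(q$q, c(10, 0))
  expect_equal(q$R, c(0.4, 0.2))

  # full pipeline on exact Monod data: (R, q) lies on q = V R/(K+R)
  cv <- noiseless_curve(Y = 0.05, V = 7, K = 0.06)
  y <- estimate_yield(cv$od, 0.6)
  mu <- instantaneous_growth_rates(cv$time, cv$od, window = 5)
  rr <- reconstruct_resource(cv$time, cv$od, y$Y, 0.6, od_min = y$od_min)
  pts <- uptake_series(mu, rr, y$Y)
  keep <- pts$R > 0.06 & pts$R < 0.55   # interior of the observed range
  pred <- 7 * pts$R[keep] / (0.06 + pts$R[keep])
  expect_lt(max(abs(pts$q[keep] - pred) / pred), 0.01)
})

test_that("Monod fit recovers exact kinetics and flags saturation", {
  R <- c(0.6, 0.3, 0.12, 0.06, 0.03)
  q <- 2 * R / (0.06 + R)
  expect_equal(round(q, 4), c(1.8182, 1.6667, 1.3333, 1.0000, 0.6667))
  fit <- fit_monod(data.frame(R = R, q = q))
  expect_true(fit$converged)
  expect_equal(fit$V, 2, tolerance = 1e-4)
  expect_equal(fit$K, 0.06, tolerance = 1e-4)
  expect_equal(tidy(fit)$estimate, c(fit$V, fit$K))
  expect_true(is.finite(glance(fit)$rss))

  # saturated: flat q at R >> K
  sat <- fit_monod(data.frame(R = c(1, 2, 4, 8), q = rep(3, 4)))
  expect_true(sat$saturated)
  expect_equal(sat$V, 3, tolerance = 0.01)

  expect_error(fit_monod(data.frame(R = 1:3, q = 1:3)), "at least 4")
})

test_that("Monod fit agrees with a grid-search oracle on noisy instances", {
  set.seed(101)
  for (i in 1:10) {
    V <- runif(1, 1, 20)
    K <- runif(1, 0.01, 0.2)
    R <- runif(50, 0.005, 0.6)
    q <- V * R / (K + R) * exp(rnorm(50, 0, 0.05))
    fit <- fit_monod(data.frame(R = R, q = q))
    # 200 x 200 log-spaced grid around the truth
    Vg <- exp(seq(log(V / 4), log(V * 4), length.out = 200))
    Kg <- exp(seq(log(K / 4), log(K * 4), length.out = 200))
    rss <- outer(Vg, Kg, function(v, k) {
      vapply(seq_along(v), function(ii) {
        sum((q - v[ii] * R / (k[ii] + R))^2)
      }, numeric(1))
    })
    best <- arrayInd(which.min(rss), dim(rss))
    dV <- diff(log(Vg))[1]
    expect_lt(abs(log(fit$V) - log(Vg[best[1]])), dV * 2)
    # K rides a flat RSS valley: require the fit to beat every grid point
    # and its own cell to sit on the valley floor
    expect_lte(fit$rss, rss[best] + 1e-9)
    iV <- which.min(abs(log(Vg) - log(fit$V)))
    iK <- which.min(abs(log(Kg) - log(fit$K)))
    expect_lte(rss[iV, iK], rss[best] * 1.10)
  }
})

test_that("trait estimation round-trips the simulator (noiseless)", {
  truth <- list(Y = 0.05, V = 7, K = 0.06)
  cv <- noiseless_curve(Y = truth$Y, V = truth$V, K = truth$K)
  tr <- estimate_traits(cv, R0 = 0.6)
  expect_true(tr$converged)
  expect_lt(abs(tr$Y - truth$Y) / truth$Y, 0.02)
  expect_lt(abs(tr$V - truth$V) / truth$V, 0.05)
  expect_lt(abs(tr$K - truth$K) / truth$K, 0.05)
  expect_lt(abs(tr$mu_max - truth$Y * truth$V) / (truth$Y * truth$V), 0.05)

  # three identical replicates give the same answer as one curve
  tr3 <- estimate_traits(cv, R0 = 0.6, technical_replicates = list(cv, cv))
  expect_equal(tr3$V, tr$V, tolerance = 1e-6)
  expect_equal(tr3$Y, tr$Y, tolerance = 1e-9)

  # no growth: flagged, yield zero, fit skipped
  flat <- tibble::tibble(time = t_grid_24h,
                         od = rep(0.005, length(t_grid_24h)))
  tr0 <- estimate_traits(flat, R0 = 0.6)
  expect_true(tr0$no_growth)
  expect_equal(tr0$Y, 0)
  expect_false(tr0$converged)
})

test_that("noiseless round-trip recovers all four traits within 5% across parameter space", {
  set.seed(202)
  for (i in 1:20) {
    Y <- runif(1, 0.01, 0.1)
    V <- runif(1, 1, 20)
    K <- runif(1, 0.01, 0.2)
    # keep the curve inside 24 h: skip very slow growers
    if (Y * V < 0.12) V <- 0.12 / Y
    cv <- noiseless_curve(Y = Y, V = V, K = K)
    tr <- estimate_traits(cv, R0 = 0.6)
    expect_lt(abs(tr$Y - Y) / Y, 0.05)
    expect_lt(abs(tr$V - V) / V, 0.05)
    expect_lt(abs(tr$K - K) / K, 0.05)
    expect_lt(abs(tr$mu_max - Y * V) / (Y * V), 0.05)
    # Monod cap: the windowed estimate cannot exceed the Monod bound
    expect_lt(tr$mu_max_obs,
              tr$Y * tr$V * (0.6 / (tr$K + 0.6)) * 1.1)
  }
})

test_that("trait comparison reports Welch t, p and fold change", {
  x <- rnorm(30, 0.02, 0.001)
  same <- compare_traits(x, x)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_two_tailed, 1)
  expect_equal(same$fold_change, 1)

  res <- compare_traits(rep(c(0.019, 0.021), 15), rep(c(0.067, 0.069), 15))
  expect_equal(res$fold_change, 3.4, tolerance = 1e-12)

  set.seed(5)
  res2 <- compare_traits(rnorm(30, 0.020, 0.001), rnorm(30, 0.068, 0.001))
  expect_lt(res2$p_two_tailed, 1e-15)
  expect_equal(res2$fold_change, 3.4, tolerance = 0.02)

  # degenerate equal constants: p = 1 by convention
  expect_equal(compare_traits(rep(1, 3), rep(1, 3))$p_two_tailed, 1)
})

test_that("plate-level estimation pools technical replicates by metadata", {
  cv <- noiseless_curve()
  plate <- dplyr::bind_rows(
    tibble::tibble(well = "A1", time = cv$time, od = cv$od),
    tibble::tibble(well = "A2", time = cv$time, od = cv$od))
  meta <- tibble::tibble(well = c("A1", "A2"), R0 = 0.6,
                         replicate_of = c(NA, "A1"))
  out <- estimate_traits_plate(plate, meta)
  expect_equal(nrow(out), 1)
  expect_equal(out$well, "A1")
  expect_lt(abs(out$V - 7) / 7, 0.05)
})
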