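OD_FLOOR <- 1e-4

median3 <- function(x) {
  if (length(x) < 3) return(x)
  stats::runmed(x, 3, endrule = "keep")
}

#' Estimate the yield from a blank-corrected OD curve
#'
#' `Y = (ODmax - ODmin) / R0`, with `ODmin` the mean of the first three
#' blank-corrected readings (the "minimum OD at the start") and `ODmax` the
#' curve maximum. A curve that never rises gets `Y = 0` and a no-growth
#' flag.
#'
#' Under measurement noise the raw curve maximum is biased upward (it is a
#' maximum over ~145 noisy readings), so `ODmax` is taken from the isotonic
#' (monotone non-decreasing) regression of the median-filtered curve, whose
#' plateau averages the stationary-phase readings.
#'
#' @param od Numeric vector of blank-corrected OD readings.
#' @param R0 Initial resource concentration, mM (> 0).
#' @return A list with `Y` (OD per mM), `od_min`, `od_max` and `no_growth`.
#' @export
estimate_yield <- function(od, R0) {
  stopifnot(is.numeric(od), length(od) >= 3, R0 > 0)
  od_min <- mean(od[1:3])
  od_max <- max(stats::isoreg(seq_along(od), median3(od))$yf)
  # a rise below the instrument floor is no growth
  if (od_max <= od_min + OD_FLOOR) {
    return(list(Y = 0, od_min = od_min, od_max = od_max, no_growth = TRUE))
  }
  list(Y = (od_max - od_min) / R0, od_min = od_min, od_max = od_max,
       no_growth = FALSE)
}

#' Instantaneous growth rates by sliding log-linear regression
#'
#' `mu = d ln(OD)/dt`, estimated by centred sliding-window least squares of
#' `ln(OD)` on time after a width-3 median filter. Readings at or below the
#' instrument floor (1e-4 OD) are floored before the log.
#'
#' @param time Time vector, hours, strictly increasing.
#' @param od Blank-corrected OD readings, same length.
#' @param window Window size in points (default 5, i.e. 50 min at 10-min
#'   sampling); must be >= 2.
#' @return A tibble with one row per window: `t` (window centre), `mu`
#'   (1/h) and `od_mid` (mean OD in the window, used for phase gating).
#' @export
instantaneous_growth_rates <- function(time, od, window = 5) {
  stopifnot(length(time) == length(od), window >= 2,
            all(diff(time) > 0))
  n <- length(od)
  if (n < window) stop("curve shorter than the window", call. = FALSE)
  ods <- pmax(median3(od), OD_FLOOR)
  logod <- log(ods)
  idx <- seq_len(n - window + 1L)
  mu <- vapply(idx, function(i) {
    sel <- i:(i + window - 1L)
    tt <- time[sel]
    yy <- logod[sel]
    sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  }, numeric(1))
  od_mid <- vapply(idx, function(i) mean(ods[i:(i + window - 1L)]), numeric(1))
  t_mid <- vapply(idx, function(i) mean(time[i:(i + window - 1L)]), numeric(1))
  tibble::tibble(t = t_mid, mu = mu, od_mid = od_mid)
}

#' Reconstruct the resource concentration from biomass
#'
#' Inverts the yield relation `dR/dt = -(1/Y) dP/dt`:
#' `R(t) = R0 - (OD(t) - ODmin)/Y`, clipped at zero. The OD curve is made
#' monotone non-decreasing by isotonic regression first, so the
#' reconstructed resource never increases.
#'
#' @param time,od The curve (blank-corrected).
#' @param Y Yield (> 0).
#' @param R0 Initial resource, mM.
#' @param od_min Starting OD; defaults to the mean of the first 3 readings.
#' @return A tibble with `t`, `od_smooth` and `R` (mM).
#' @export
reconstruct_resource <- function(time, od, Y, R0, od_min = NULL) {
  stopifnot(Y > 0, length(time) == length(od))
  if (is.null(od_min)) od_min <- mean(od[1:3])
  iso <- stats::isoreg(time, median3(od))$yf
  R <- pmax(R0 - (iso - od_min) / Y, 0)
  tibble::tibble(t = time, od_smooth = iso, R = R)
}

#' Pair uptake rates with resource concentrations
#'
#' The specific uptake rate is `q = mu / Y` (mM per OD per h). Growth-rate
#' windows are matched to the reconstructed resource at the window centres
#' by linear interpolation, giving the (R, q) cloud the Monod fit consumes.
#'
#' @param mu_tbl Output of [instantaneous_growth_rates()].
#' @param resource_tbl Output of [reconstruct_resource()].
#' @param Y Yield (> 0).
#' @param half_span Optional half-width (h) over which `R` is averaged
#'   around each window centre instead of point interpolation; windowed
#'   growth rates are averages over the window, so pairing them with the
#'   window-averaged resource keeps the two aligned during the fast
#'   depletion phase.
#' @return A tibble with `t`, `R` and `q`.
#' @export
uptake_series <- function(mu_tbl, resource_tbl, Y, half_span = NULL) {
  stopifnot(Y > 0)
  if (is.null(half_span)) {
    R_at <- stats::approx(resource_tbl$t, resource_tbl$R, xout = mu_tbl$t,
                          rule = 2)$y
  } else {
    R_at <- vapply(mu_tbl$t, function(tc) {
      sel <- resource_tbl$t >= tc - half_span & resource_tbl$t <= tc + half_span
      mean(resource_tbl$R[sel])
    }, numeric(1))
  }
  tibble::tibble(t = mu_tbl$t, R = R_at, q = mu_tbl$mu / Y)
}

#' Fit Monod uptake kinetics to (R, q) points
#'
#' Nonlinear least squares of `q = V R / (K + R)` with multi-start
#' initialisation: `V0 = max(q)`, `K0 = median(R) * {0.2, 1, 5}`, bounds
#' `V in (0, 10 V0]`, `K in [1e-4, 10 max(R)]`. Returns the best fit; if no
#' start converges, the least-bad attempt is returned with
#' `converged = FALSE`. When the cloud is flat (saturated, R >> K), `V`
#' approaches `max(q)` and `K` collapses to its lower bound with a
#' saturation flag.
#'
#' @param points Data frame with columns `R` (mM) and `q` (mM/OD/h).
#' @param weights Optional per-point weights.
#' @return Object of class `monod_fit`: list with `V`, `K`, `rss`,
#'   `converged`, `saturated`, `n_points` and the `nls` fit (or `NULL`).
#' @examples
#' R <- c(0.6, 0.3, 0.12, 0.06, 0.03)
#' fit_monod(data.frame(R = R, q = 2 * R / (0.06 + R)))
#' @export
fit_monod <- function(points, weights = NULL) {
  stopifnot(is.data.frame(points), all(c("R", "q") %in% names(points)))
  pts <- points[is.finite(points$R) & is.finite(points$q) & points$R > 0, ]
  if (nrow(pts) < 4) stop("need at least 4 usable (R, q) points", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(pts))
  V0 <- max(pts$q)
  if (V0 <= 0) {
    return(structure(list(V = 0, K = NA_real_, rss = NA_real_,
                          converged = FALSE, saturated = FALSE,
                          n_points = nrow(pts), fit = NULL),
                     class = "monod_fit"))
  }
  K_starts <- stats::median(pts$R) * c(0.2, 1, 5)
  lowK <- 1e-4
  upK <- 10 * max(pts$R)
  best <- NULL
  for (K0 in K_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(q ~ V * R / (K + R), data = pts,
                        start = list(V = V0, K = min(max(K0, lowK), upK)),
                        lower = c(V = 1e-12, K = lowK),
                        upper = c(V = 10 * V0, K = upK),
                        weights = weights,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(V = V0, K = stats::median(pts$R), rss = Inf,
                          converged = FALSE, saturated = FALSE,
                          n_points = nrow(pts), fit = NULL),
                     class = "monod_fit"))
  }
  cf <- stats::coef(best$fit)
  structure(list(V = unname(cf["V"]), K = unname(cf["K"]), rss = best$rss,
                 converged = TRUE,
                 saturated = unname(cf["K"]) <= lowK * 1.001,
                 n_points = nrow(pts), fit = best$fit),
            class = "monod_fit")
}

#' @export
print.monod_fit <- function(x, ...) {
  cat(sprintf("<monod_fit> V = %.4g mM/OD/h, K = %.4g mM (rss %.3g, n %d%s%s)\n",
              x$V, x$K, x$rss, x$n_points,
              if (x$converged) "" else ", NOT converged",
              if (x$saturated) ", saturated" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.monod_fit <- function(x, ...) {
  tibble::tibble(term = c("V", "K"), estimate = c(x$V, x$K))
}

#' @export
glance.monod_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_points = x$n_points,
                 converged = x$converged, saturated = x$saturated)
}

#' Multistep estimation of the four resource-use traits from one well
#'
#' Orchestrates the full pipeline on a blank-corrected curve (plus optional
#' technical replicates): yield from the OD range, instantaneous growth
#' rates by sliding log-linear regression, resource reconstruction through
#' the yield, uptake rates `q = mu/Y` against the window-averaged resource,
#' and a Monod fit of `q` against `R`. When replicates share the time grid
#' their log-OD curves are averaged before differentiation (noise falls by
#' sqrt(replicates) before any slope is taken); otherwise the (R, q)
#' clouds are pooled. Finally, unless `refine = FALSE`, the multistep
#' estimates seed a joint fit of the integrated Monod batch model to all
#' replicate curves on the log-OD scale (the measurement noise is
#' multiplicative), which sharpens V and especially K; the half-saturation
#' constant is only expressed during the short depletion phase, where
#' differentiated estimates lose the most information.
#'
#' The reported `mu_max` is the Monod-implied maximum growth rate `Y * V`;
#' `mu_max_obs` is the largest windowed growth rate inside the
#' exponential-phase band (windows whose mean OD lies in
#' `[ODmin + 0.1 dOD, ODmin + 0.7 dOD]`), which is capped below `Y*V` by
#' resource draw-down.
#'
#' @param curve Data frame with `time` (h) and `od` columns for one well,
#'   already blank-corrected (see [read_plate_csv()]).
#' @param R0 Initial resource concentration, mM.
#' @param technical_replicates Optional list of additional curves.
#' @param window Sliding-window size in points for growth rates.
#' @param min_R_frac (R, q) points with `R < min_R_frac * R0` are excluded
#'   from the Monod fit (near-depletion noise dominates there).
#' @param refine Run the final integrated-model fit (default TRUE).
#' @return A one-row tibble of class `resource_traits`: `mu_max`, `Y`, `V`,
#'   `K`, `mu_max_obs`, `fit_rss`, `n_points_fit`, `converged`,
#'   `no_growth`, `refined`.
#' @export
estimate_traits <- function(curve, R0, technical_replicates = NULL,
                            window = 5, min_R_frac = 0.01, refine = TRUE) {
  curves <- c(list(curve), technical_replicates %||% list())
  for (cv in curves) stopifnot(all(c("time", "od") %in% names(cv)))

  shared_grid <- length(curves) == 1 ||
    all(vapply(curves[-1], function(cv) {
      length(cv$time) == length(curves[[1]]$time) &&
        max(abs(cv$time - curves[[1]]$time)) < 1e-9
    }, logical(1)))

  masters <- if (shared_grid) {
    lods <- vapply(curves, function(cv) log(pmax(median3(cv$od), OD_FLOOR)),
                   numeric(length(curves[[1]]$od)))
    list(tibble::tibble(time = curves[[1]]$time,
                        od = exp(rowMeans(as.matrix(lods)))))
  } else {
    curves
  }

  per <- purrr::map(masters, function(cv) {
    yl <- estimate_yield(cv$od, R0)
    if (yl$no_growth) {
      return(list(yield = yl, points = NULL, mu_max_obs = NA_real_))
    }
    mu_tbl <- instantaneous_growth_rates(cv$time, cv$od, window = window)
    res_tbl <- reconstruct_resource(cv$time, cv$od, yl$Y, R0,
                                    od_min = yl$od_min)
    half_span <- (mu_tbl$t[2] - mu_tbl$t[1]) * (window - 1) / 2
    pts <- uptake_series(mu_tbl, res_tbl, yl$Y, half_span = half_span)
    dOD <- yl$od_max - yl$od_min
    band <- mu_tbl$od_mid >= yl$od_min + 0.1 * dOD &
      mu_tbl$od_mid <= yl$od_min + 0.7 * dOD
    mu_max_obs <- if (any(band)) max(mu_tbl$mu[band]) else max(mu_tbl$mu)
    # growth-phase windows only: stationary-phase windows carry no kinetic
    # information, only slope noise, and small yield errors map them to
    # spurious small positive R
    grow <- mu_tbl$od_mid <= yl$od_min + 0.95 * dOD
    list(yield = yl, points = pts[grow & pts$R >= min_R_frac * R0, ],
         mu_max_obs = mu_max_obs)
  })
  Ys <- vapply(per, function(p) p$yield$Y, numeric(1))
  no_growth <- all(vapply(per, function(p) p$yield$no_growth, logical(1)))
  if (no_growth) {
    out <- tibble::tibble(mu_max = 0, Y = 0, V = NA_real_, K = NA_real_,
                          mu_max_obs = 0, fit_rss = NA_real_,
                          n_points_fit = 0L, converged = FALSE,
                          no_growth = TRUE, refined = FALSE)
    class(out) <- c("resource_traits", class(out))
    return(out)
  }
  Y <- mean(Ys[Ys > 0])
  pts <- dplyr::bind_rows(purrr::map(per, "points"))
  fit <- fit_monod(pts)
  mu_max_obs <- mean(vapply(per, `[[`, numeric(1), "mu_max_obs"), na.rm = TRUE)
  V <- fit$V
  K <- fit$K
  refined <- FALSE
  if (refine && fit$converged && shared_grid) {
    rf <- refine_integrated(curves, R0, Y0 = Y, V0 = V, K0 = K)
    if (!is.null(rf)) {
      Y <- rf$Y; V <- rf$V; K <- rf$K
      refined <- TRUE
    }
  }
  out <- tibble::tibble(mu_max = Y * V, Y = Y, V = V, K = K,
                        mu_max_obs = mu_max_obs, fit_rss = fit$rss,
                        n_points_fit = fit$n_points,
                        converged = fit$converged, no_growth = FALSE,
                        refined = refined)
  class(out) <- c("resource_traits", class(out))
  out
}

# joint lognormal least squares of the integrated Monod batch model over
# all replicate curves; parameters (Y, V, K, P0) on the log scale, started
# from the multistep estimates.  Returns NULL if the fit fails or drifts
# to an implausible region.
refine_integrated <- function(curves, R0, Y0, V0, K0) {
  tt <- curves[[1]]$time
  od_all <- vapply(curves, function(cv) pmax(cv$od, OD_FLOOR),
                   numeric(length(tt)))
  od_all <- as.matrix(od_all)
  P0g <- max(mean(od_all[1:3, ]), OD_FLOOR)
  fn <- function(p) {
    pred <- tryCatch({
      g <- genotype("refine", Y = exp(p[1]), V = exp(p[2]), K = exp(p[3]),
                    resource = "R")
      simulate_batch_growth(g, R0 = R0, P0 = exp(p[4]), t_grid = tt,
                            rtol = 1e-7, atol = 1e-9)$od
    }, error = function(e) NULL)
    if (is.null(pred)) return(rep(1e3, length(od_all)))
    as.vector(log(od_all) - log(pmax(pred, 1e-6)))
  }
  start <- log(c(max(Y0, 1e-6), max(V0, 1e-6),
                 min(max(K0, 0.02 * R0), 0.5 * R0), P0g))
  out <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = fn,
                       control = minpack.lm::nls.lm.control(maxiter = 120)),
    error = function(e) NULL)
  if (is.null(out) || !is.finite(out$deviance)) return(NULL)
  est <- exp(out$par)
  if (any(!is.finite(est)) || est[3] > 100 * R0 || est[2] > 1e4) return(NULL)
  list(Y = est[1], V = est[2], K = est[3], P0 = est[4])
}

#' Estimate traits for every well of a plate
#'
#' Data-frame-first wrapper over [estimate_traits()]: takes the long plate
#' tibble from [read_plate_csv()] and returns one row of traits per well.
#' Wells sharing a `replicate_of` entry in `meta` are pooled as technical
#' replicates of the named well.
#'
#' @param plate Long tibble with `well`, `time`, `od` (blank-corrected).
#' @param meta Data frame with per-well metadata: `well`, `R0`, optionally
#'   `replicate_of`.
#' @param ... Passed to [estimate_traits()].
#' @return A tibble with one row per (non-replicate) well.
#' @export
estimate_traits_plate <- function(plate, meta, ...) {
  stopifnot(all(c("well", "time", "od") %in% names(plate)),
            all(c("well", "R0") %in% names(meta)))
  rep_of <- if ("replicate_of" %in% names(meta)) {
    stats::setNames(meta$replicate_of, meta$well)
  } else {
    stats::setNames(rep(NA_character_, nrow(meta)), meta$well)
  }
  primaries <- meta$well[is.na(rep_of[meta$well]) | rep_of[meta$well] == ""]
  one_curve <- function(w) {
    cv <- plate[plate$well == w, c("time", "od")]
    if (!nrow(cv)) stop("well not present in plate: ", w, call. = FALSE)
    cv
  }
  purrr::map_dfr(primaries, function(w) {
    reps <- meta$well[!is.na(rep_of[meta$well]) & rep_of[meta$well] == w]
    tr <- estimate_traits(one_curve(w),
                          R0 = meta$R0[match(w, meta$well)],
                          technical_replicates = purrr::map(reps, one_curve),
                          ...)
    dplyr::bind_cols(tibble::tibble(well = w), tr)
  })
}

#' Compare a trait between ancestral and evolved samples
#'
#' Welch two-sample two-tailed t test plus the evolved/ancestral
#' fold-change of means. Identical degenerate samples (zero variance, equal
#' means) return `p = 1`.
#'
#' @param anc,evo Numeric vectors of per-clone trait values (n >= 2 each).
#' @return One-row tibble: `t_statistic`, `p_two_tailed`, `mean_anc`,
#'   `mean_evo`, `mean_diff`, `fold_change`, `df`.
#' @examples
#' compare_traits(rnorm(30, 0.020, 0.001), rnorm(30, 0.068, 0.001))
#' @export
compare_traits <- function(anc, evo) {
  stopifnot(is.numeric(anc), is.numeric(evo), length(anc) >= 2,
            length(evo) >= 2, all(is.finite(anc)), all(is.finite(evo)))
  if (stats::var(anc) == 0 && stats::var(evo) == 0) {
    if (mean(anc) == mean(evo)) {
      return(tibble::tibble(t_statistic = 0, p_two_tailed = 1,
                            mean_anc = mean(anc), mean_evo = mean(evo),
                            mean_diff = 0, fold_change = 1,
                            df = length(anc) + length(evo) - 2))
    }
    return(tibble::tibble(t_statistic = Inf * sign(mean(evo) - mean(anc)),
                          p_two_tailed = 0, mean_anc = mean(anc),
                          mean_evo = mean(evo),
                          mean_diff = mean(evo) - mean(anc),
                          fold_change = mean(evo) / mean(anc),
                          df = length(anc) + length(evo) - 2))
  }
  ht <- stats::t.test(evo, anc, var.equal = FALSE)
  tibble::tibble(t_statistic = unname(ht$statistic),
                 p_two_tailed = ht$p.value,
                 mean_anc = mean(anc), mean_evo = mean(evo),
                 mean_diff = mean(evo) - mean(anc),
                 fold_change = mean(evo) / mean(anc),
                 df = unname(ht$parameter))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
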