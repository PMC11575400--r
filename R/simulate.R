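monod_rate <- function(V, K, R) V * R / (K + R)

# shared ODE right-hand side for a set of genotypes feeding on named pools.
# state = c(resources, densities); genotypes index into both by name.
community_rhs <- function(t, state, parms) {
  nres <- parms$n_res
  R <- state[seq_len(nres)]
  P <- state[-seq_len(nres)]
  R <- pmax(R, 0)
  P <- pmax(P, 0)
  dR <- numeric(nres)
  dP <- numeric(length(P))
  for (i in seq_along(parms$genotypes)) {
    g <- parms$genotypes[[i]]
    ri <- parms$res_idx[i]
    uptake <- monod_rate(g$V, g$K, R[ri]) * P[i]   # mM/h
    dR[ri] <- dR[ri] - uptake
    dP[i] <- g$Y * uptake
    if (parms$prod_idx[i] > 0L) {
      dR[parms$prod_idx[i]] <- dR[parms$prod_idx[i]] + g$leak_fraction * uptake
    }
  }
  list(c(dR, dP))
}

integrate_community <- function(state, genotypes, t_grid,
                                rtol = 1e-8, atol = 1e-10) {
  res_names <- names(state$resources)
  lab <- vapply(genotypes, `[[`, character(1), "label")
  if (anyDuplicated(lab)) stop("duplicated genotype labels", call. = FALSE)
  missing_lab <- setdiff(lab, names(state$densities))
  if (length(missing_lab)) {
    stop("state lacks densities for: ", paste(missing_lab, collapse = ", "),
         call. = FALSE)
  }
  res_idx <- match(vapply(genotypes, `[[`, character(1), "resource"), res_names)
  if (anyNA(res_idx)) stop("genotype consumes an unknown resource pool", call. = FALSE)
  prod_idx <- vapply(genotypes, function(g) {
    if (is.null(g$produces)) 0L else {
      i <- match(g$produces, res_names)
      if (is.na(i)) stop("genotype produces an unknown resource pool", call. = FALSE)
      i
    }
  }, integer(1))
  y0 <- c(state$resources, state$densities[lab])
  parms <- list(n_res = length(res_names), genotypes = genotypes,
                res_idx = res_idx, prod_idx = prod_idx)
  sol <- deSolve::lsoda(y = y0, times = t_grid, func = community_rhs,
                        parms = parms, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed (lsoda istate = ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  }
  sol <- as.data.frame(sol)
  names(sol) <- c("time", res_names, lab)
  # solver tolerance can leave tiny negative excursions; clip them
  sol[-1] <- lapply(sol[-1], pmax, 0)
  tibble::as_tibble(sol)
}

#' Simulate single-genotype Monod batch growth
#'
#' Integrates `dP/dt = Y V R/(K+R) P`, `dR/dt = -V R/(K+R) P` from a starting
#' density `P0` and resource concentration `R0` over `t_grid`, with a
#' stiff-capable adaptive integrator. Biomass and resource are linked by the
#' conservation identity `P(t) - P0 = Y (R0 - R(t))`, which holds to solver
#' tolerance.
#'
#' @param params An [genotype()] object.
#' @param R0 Initial resource concentration, mM (>= 0).
#' @param P0 Initial density, OD (> 0).
#' @param t_grid Strictly increasing time grid starting at 0, hours.
#' @param rtol,atol Solver tolerances (defaults 1e-8 / 1e-10).
#' @return A tibble with columns `time` (h), `od` and `resource` (mM).
#' @examples
#' g <- genotype("wt", Y = 0.05, V = 10, K = 0.06, resource = "benzoate")
#' curve <- simulate_batch_growth(g, R0 = 0.6, P0 = 0.005,
#'                                t_grid = seq(0, 24, by = 1 / 6))
#' max(curve$od)  # ~ 0.005 + 0.05 * 0.6
#' @export
simulate_batch_growth <- function(params, R0, P0, t_grid,
                                  rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "xf_genotype"))
  if (!is.finite(R0) || R0 < 0) stop("R0 must be finite and >= 0", call. = FALSE)
  if (!is.finite(P0) || P0 <= 0) stop("P0 must be finite and > 0", call. = FALSE)
  if (length(t_grid) < 2 || t_grid[1] != 0 || any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing from 0", call. = FALSE)
  }
  pool <- params$resource
  st <- community_state(stats::setNames(R0, pool),
                        stats::setNames(P0, params$label))
  g <- params
  g$produces <- NULL
  g$leak_fraction <- 0
  traj <- integrate_community(st, list(g), t_grid, rtol = rtol, atol = atol)
  tibble::tibble(time = traj$time, od = traj[[params$label]],
                 resource = traj[[pool]])
}

#' Simulate one batch cycle of a cross-feeding community
#'
#' Grows all genotypes together for one cycle. A producer genotype (the
#' cross-feeder, e.g. an *A. johnsonii*-like benzyl-alcohol consumer) excretes
#' a fraction `leak_fraction` of what it consumes into its product pool,
#' where consumer genotypes take it up by Monod kinetics. With
#' `leak_fraction = 0` consumers of the product pool starve; with the
#' producer absent the dynamics reduce to shared-pool batch growth.
#'
#' @param state An [community_state()] with every resource pool and genotype
#'   density named.
#' @param genotypes List of [genotype()] objects (producers and consumers).
#' @param cycle_length_h Length of the growth cycle in hours.
#' @param dt_out Output time step in hours (default 1/6, i.e. 10 min).
#' @param rtol,atol Solver tolerances.
#' @return A tibble trajectory: `time`, one column per resource pool and one
#'   per genotype.
#' @export
simulate_crossfeed_cycle <- function(state, genotypes, cycle_length_h = 24,
                                     dt_out = 1 / 6, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(state, "xf_state"), cycle_length_h > 0)
  t_grid <- unique(c(seq(0, cycle_length_h, by = dt_out), cycle_length_h))
  integrate_community(state, genotypes, t_grid, rtol = rtol, atol = atol)
}

#' Introduce a mutant genotype into a community state
#'
#' Converts a fraction of the parent's density into a new mutant genotype.
#' Total density is conserved at the instant of injection.
#'
#' @param state An [community_state()].
#' @param parent Label of an existing genotype with positive density.
#' @param mutant An [genotype()] object for the new type.
#' @param initial_fraction Fraction of the parent's density converted,
#'   in (0, 1).
#' @return The updated `xf_state`.
#' @export
inject_mutant <- function(state, parent, mutant, initial_fraction) {
  stopifnot(inherits(state, "xf_state"), inherits(mutant, "xf_genotype"))
  if (!(initial_fraction > 0 && initial_fraction < 1)) {
    stop("initial_fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!parent %in% names(state$densities)) {
    stop("unknown parent label: ", parent, call. = FALSE)
  }
  if (state$densities[[parent]] <= 0) {
    stop("parent has no density to split", call. = FALSE)
  }
  if (mutant$label %in% names(state$densities)) {
    stop("mutant label already present: ", mutant$label, call. = FALSE)
  }
  d <- state$densities
  moved <- d[[parent]] * initial_fraction
  d[[parent]] <- d[[parent]] - moved
  d <- c(d, stats::setNames(moved, mutant$label))
  community_state(state$resources, d, t = state$t)
}

#' Run a daily serial-transfer experiment
#'
#' Each day the community grows for one cycle (deterministic Monod ODE),
#' end-of-cycle densities are recorded in CFU/mL (optionally with
#' multiplicative lognormal plating noise), every density is divided by the
#' dilution factor, and resources are replenished to the fresh-medium
#' concentrations. Genotypes listed in `injections` are introduced from
#' their parent just after the stated day's transfer. Densities recorded
#' below the protocol's detection limit are flagged `censored` (the
#' underlying deterministic dynamics are not truncated). Growth within a
#' cycle is deterministic; stochasticity enters only through observation
#' noise and, optionally, Poisson sampling of transferred cells.
#'
#' @param state Initial [community_state()] (day-0, already in fresh medium).
#' @param genotypes List of [genotype()] objects; injected mutants are added
#'   automatically.
#' @param protocol An [transfer_protocol()].
#' @param fresh_resources Named numeric vector: resource concentrations of
#'   fresh medium used to replenish after each transfer. Defaults to the
#'   initial state's resources.
#' @param injections Optional list of
#'   `list(day =, parent =, mutant =, fraction =)` entries.
#' @param plating_noise_cv Coefficient of variation of multiplicative
#'   lognormal plating noise on recorded CFU (0 = noiseless).
#' @param sample_cells If `TRUE`, the number of cells surviving each
#'   transfer is drawn from a Poisson with mean `density/dilution`
#'   (demographic sampling; default `FALSE`, deterministic dilution).
#' @param seed Integer seed for the observation noise / sampling.
#' @return A tibble of class `xf_transfer_series` with columns
#'   `day`, `label`, `cfu_per_ml`, `censored`. Day 0 records the initial
#'   densities before any growth.
#' @examples
#' anc <- genotype("anc", Y = 0.02, V = 10, K = 0.06, resource = "benzoate")
#' st <- community_state(c(benzoate = 0.06), c(anc = 1e-4))
#' run_serial_transfers(st, list(anc), transfer_protocol(days = 3))
#' @export
run_serial_transfers <- function(state, genotypes, protocol,
                                 fresh_resources = NULL, injections = NULL,
                                 plating_noise_cv = 0, sample_cells = FALSE,
                                 seed = NULL) {
  stopifnot(inherits(state, "xf_state"), inherits(protocol, "xf_protocol"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fresh_resources)) fresh_resources <- state$resources
  lab_known <- vapply(genotypes, `[[`, character(1), "label")
  for (inj in injections) {
    if (!inj$parent %in% lab_known) {
      stop("injection parent not among genotypes: ", inj$parent, call. = FALSE)
    }
  }

  observe <- function(day, dens_od) {
    cfu <- dens_od * protocol$od_to_cfu
    if (plating_noise_cv > 0) {
      cfu <- cfu * exp(stats::rnorm(length(cfu), 0, plating_noise_cv))
    }
    tibble::tibble(day = day, label = names(dens_od),
                   cfu_per_ml = unname(cfu),
                   censored = unname(cfu) < protocol$detection_limit)
  }

  records <- list(observe(0L, state$densities))
  cur <- state
  gts <- genotypes
  day <- 0L
  while (day < protocol$days) {
    day <- day + 1L
    if (sum(cur$densities) <= 0) {
      stop("total density reached zero on day ", day - 1L,
           ": community extinct", call. = FALSE)
    }
    traj <- simulate_crossfeed_cycle(cur, gts, protocol$cycle_length_h)
    endrow <- traj[nrow(traj), ]
    res <- unlist(endrow[names(cur$resources)])
    dens <- unlist(endrow[vapply(gts, `[[`, character(1), "label")])
    records[[length(records) + 1L]] <- observe(day, dens)
    # transfer: dilute, replenish
    if (sample_cells) {
      cells <- stats::rpois(length(dens),
                            dens * protocol$od_to_cfu * protocol$transfer_volume_ml)
      dens <- stats::setNames(
        cells / protocol$od_to_cfu /
          (protocol$transfer_volume_ml + protocol$culture_volume_ml),
        names(dens))
    } else {
      dens <- dens / protocol$dilution
    }
    res <- res / protocol$dilution + fresh_resources[names(cur$resources)] *
      protocol$culture_volume_ml / (protocol$transfer_volume_ml + protocol$culture_volume_ml)
    cur <- community_state(res, dens, t = 0)
    for (inj in injections) {
      if (identical(as.integer(inj$day), day)) {
        cur <- inject_mutant(cur, inj$parent, inj$mutant, inj$fraction)
        gts <- c(gts, list(inj$mutant))
      }
    }
  }
  out <- dplyr::bind_rows(records)
  class(out) <- c("xf_transfer_series", class(out))
  out
}

#' Add multiplicative measurement noise to an OD curve
#'
#' Replaces each OD reading by `od * exp(e)` with `e ~ Normal(0, cv)`, then
#' floors at `floor`. Deterministic given `seed`; `cv = 0` returns the curve
#' unchanged.
#'
#' @param curve A data frame with an `od` column (other columns pass
#'   through).
#' @param cv Standard deviation of the log-scale noise (>= 0).
#' @param floor Minimum reported OD (default 1e-4, the instrument floor).
#' @param seed Integer seed.
#' @return The curve with noisy `od`.
#' @export
add_od_noise <- function(curve, cv, floor = 1e-4, seed = NULL) {
  stopifnot(is.data.frame(curve), "od" %in% names(curve), cv >= 0)
  if (cv == 0) return(tibble::as_tibble(curve))
  if (!is.null(seed)) set.seed(seed)
  out <- tibble::as_tibble(curve)
  out$od <- pmax(out$od * exp(stats::rnorm(nrow(out), 0, cv)), floor)
  out
}
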