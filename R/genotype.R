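#' Define a genotype by its Monod resource-use parameters
#'
#' A genotype is characterised by the four resource-use traits used throughout
#' the package: the yield `Y` (OD per mM), the maximum uptake rate `V`
#' (mM per OD per h), the half-saturation constant `K` (mM) and the maximum
#' growth rate `mu_max` (1/h). The three rate parameters are linked by
#' `mu_max = Y * V`; supply any two of `Y`, `V`, `mu_max` and the third is
#' derived. Attempting to supply all three with inconsistent values is an
#' error.
#'
#' @param label Character, genotype name (unique within a community).
#' @param Y Yield, OD per mM. Must be > 0.
#' @param V Maximum uptake rate, mM per OD per h. Must be > 0.
#' @param K Half-saturation constant, mM. Must be > 0.
#' @param mu_max Maximum growth rate, 1/h. Derived from `Y * V` when missing.
#' @param resource Name of the resource pool this genotype consumes, e.g.
#'   `"benzyl_alcohol"`, `"benzoate"` or `"residual"`.
#' @param produces Optional name of a resource pool this genotype excretes
#'   while growing (cross-feeding); `NULL` for none.
#' @param leak_fraction Fraction (0..1) of consumed resource excreted into
#'   the `produces` pool, mM per mM. Ignored when `produces` is `NULL`.
#'
#' @return An object of class `xf_genotype`: a named list with the validated
#'   parameters.
#' @examples
#' anc <- genotype("ancestor", Y = 0.020, V = 10, K = 0.06, resource = "benzoate")
#' anc$mu_max  # 0.2
#' @export
genotype <- function(label, Y = NULL, V = NULL, K = NULL, mu_max = NULL,
                     resource = "benzoate", produces = NULL,
                     leak_fraction = 1.0) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  given <- !vapply(list(Y, V, mu_max), is.null, logical(1))
  if (sum(given) < 2L) {
    stop("supply at least two of Y, V, mu_max (mu_max = Y * V)", call. = FALSE)
  }
  if (is.null(mu_max)) mu_max <- Y * V
  if (is.null(V)) V <- mu_max / Y
  if (is.null(Y)) Y <- mu_max / V
  vals <- c(Y = Y, V = V, K = K, mu_max = mu_max)
  if (any(!is.finite(vals)) || Y <= 0 || K <= 0 || V < 0) {
    stop("Y and K must be finite and > 0; V finite and >= 0", call. = FALSE)
  }
  if (abs(mu_max - Y * V) > 1e-8 * max(abs(mu_max), abs(Y * V), 1e-12)) {
    stop("inconsistent parameters: mu_max must equal Y * V", call. = FALSE)
  }
  if (!is.null(produces)) {
    stopifnot(is.character(produces), length(produces) == 1L)
    if (!is.finite(leak_fraction) || leak_fraction < 0 || leak_fraction > 1) {
      stop("leak_fraction must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(label = label, Y = Y, V = V, K = K, mu_max = mu_max,
         resource = resource, produces = produces,
         leak_fraction = if (is.null(produces)) 0 else leak_fraction),
    class = "xf_genotype"
  )
}

#' @export
print.xf_genotype <- function(x, ...) {
  prod <- if (is.null(x$produces)) "" else {
    sprintf(" -> %s (leak %.2f)", x$produces, x$leak_fraction)
  }
  cat(sprintf(
    "<xf_genotype> %s: mu_max=%.4g /h, Y=%.4g OD/mM, V=%.4g mM/OD/h, K=%.4g mM, eats %s%s\n",
    x$label, x$mu_max, x$Y, x$V, x$K, x$resource, prod))
  invisible(x)
}

#' Community state: resource concentrations and genotype densities
#'
#' Snapshot of a batch culture: time, the concentration of every resource
#' pool (mM) and the density of every genotype (unitless OD). All entries
#' must be non-negative.
#'
#' @param resources Named numeric vector of resource concentrations in mM,
#'   e.g. `c(benzyl_alcohol = 0.6, benzoate = 0)`.
#' @param densities Named numeric vector of genotype densities in OD units;
#'   names must match genotype labels.
#' @param t Time in hours (default 0).
#' @return An object of class `xf_state`.
#' @examples
#' community_state(c(benzoate = 0.6), c(ancestor = 0.005))
#' @export
community_state <- function(resources, densities, t = 0) {
  stopifnot(is.numeric(resources), !is.null(names(resources)),
            is.numeric(densities), !is.null(names(densities)))
  if (any(!is.finite(resources)) || any(resources < 0)) {
    stop("resource concentrations must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(densities)) || any(densities < 0)) {
    stop("densities must be finite and >= 0", call. = FALSE)
  }
  if (anyDuplicated(names(densities))) {
    stop("duplicated genotype labels in densities", call. = FALSE)
  }
  structure(list(t = t, resources = resources, densities = densities),
            class = "xf_state")
}

#' @export
print.xf_state <- function(x, ...) {
  cat(sprintf("<xf_state> t = %.3g h\n  resources (mM): %s\n  densities (OD): %s\n",
              x$t,
              paste(sprintf("%s=%.4g", names(x$resources), x$resources), collapse = ", "),
              paste(sprintf("%s=%.4g", names(x$densities), x$densities), collapse = ", ")))
  invisible(x)
}

#' Serial-transfer protocol
#'
#' Describes the daily dilution regime: culture volume, transferred volume,
#' cycle length and the plating detection limit. The dilution factor is
#' `(transfer_volume + culture_volume) / transfer_volume`; each cycle
#' contributes `log2(dilution factor)` generations of regrowth.
#'
#' @param days Number of transfer days to simulate.
#' @param transfer_volume_ml Volume carried over, mL (default 0.1, i.e.
#'   100 uL).
#' @param culture_volume_ml Fresh-medium volume, mL (default 9.9).
#' @param cycle_length_h Hours of growth per cycle (default 24).
#' @param detection_limit Plating detection limit in CFU/mL (default 1e2);
#'   recorded densities below it are flagged censored.
#' @param od_to_cfu Conversion factor from OD units to CFU/mL
#'   (default 5e8; fixed, configurable — plate-reader OD and plate counts
#'   are linked only through this calibration).
#' @return An object of class `xf_protocol`.
#' @export
transfer_protocol <- function(days, transfer_volume_ml = 0.1,
                              culture_volume_ml = 9.9, cycle_length_h = 24,
                              detection_limit = 1e2, od_to_cfu = 5e8) {
  stopifnot(days >= 0, transfer_volume_ml > 0, culture_volume_ml > 0,
            cycle_length_h > 0, detection_limit >= 0, od_to_cfu > 0)
  dilution <- (transfer_volume_ml + culture_volume_ml) / transfer_volume_ml
  if (!is.finite(dilution) || dilution <= 1) {
    stop("dilution factor must be finite and > 1", call. = FALSE)
  }
  structure(list(days = as.integer(days),
                 transfer_volume_ml = transfer_volume_ml,
                 culture_volume_ml = culture_volume_ml,
                 cycle_length_h = cycle_length_h,
                 detection_limit = detection_limit,
                 od_to_cfu = od_to_cfu,
                 dilution = dilution),
            class = "xf_protocol")
}

#' @export
print.xf_protocol <- function(x, ...) {
  cat(sprintf(
    "<xf_protocol> %d days, %.3g mL into %.3g mL (1:%.0f), %.3g h cycles, detection %.3g CFU/mL\n",
    x$days, x$transfer_volume_ml, x$culture_volume_ml, x$dilution,
    x$cycle_length_h, x$detection_limit))
  invisible(x)
}
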