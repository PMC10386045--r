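#' Proton pools and exchange physics
#'
#' A pool is one population of exchangeable (or bulk-water) protons:
#' its chemical shift relative to water, longitudinal/transverse relaxation
#' times, proton fraction relative to water, and a pH-dependent exchange
#' rate. The exchange rate follows base catalysis:
#' \deqn{k(pH) = k_{ref} \times 10^{s (pH - 7)}}
#' with `base_rate` \eqn{k_{ref}} the rate at pH 7.0 and `ph_slope` \eqn{s}
#' the decadic sensitivity (1 per pH unit for purely base-catalyzed
#' exchange, 0 for pH-independent pools such as magnetization transfer).
#'
#' @param shift_ppm Chemical shift relative to water (ppm).
#' @param t1,t2 Longitudinal and transverse relaxation times (s);
#'   `0 < t2 <= t1`.
#' @param fraction Proton fraction relative to water, in `[0, 1)` (water
#'   itself uses 1 via [pool_system()]).
#' @param base_rate Exchange rate with water at pH 7.0 (1/s, >= 0).
#' @param ph_slope Decadic pH sensitivity exponent (per pH unit).
#'
#' @return An object of class `cest_pool`.
#' @export
pool <- function(shift_ppm, t1, t2, fraction = 0, base_rate = 0, ph_slope = 0) {
  if (!is_number(shift_ppm)) stopf("shift_ppm must be a single finite number")
  if (!is_number(t1) || t1 <= 0) stopf("t1 must be > 0")
  if (!is_number(t2) || t2 <= 0) stopf("t2 must be > 0")
  if (t2 > t1) stopf("t2 must not exceed t1")
  if (!is_number(fraction) || fraction < 0 || fraction >= 1)
    stopf("fraction must be in [0, 1)")
  if (!is_number(base_rate) || base_rate < 0) stopf("base_rate must be >= 0")
  if (!is_number(ph_slope)) stopf("ph_slope must be a single finite number")
  structure(list(shift_ppm = shift_ppm, t1 = t1, t2 = t2, fraction = fraction,
                 base_rate = base_rate, ph_slope = ph_slope),
            class = "cest_pool")
}

#' pH-resolved exchange rate of a pool
#'
#' @param pool A [pool()].
#' @param ph pH value in `[0, 14]`.
#' @return Exchange rate in 1/s.
#' @examples
#' amide <- pool(3.5, 1, 0.01, 7e-4, base_rate = 30, ph_slope = 1)
#' exchange_rate(amide, 7.0)  # 30
#' exchange_rate(amide, 8.0)  # 300
#' @export
exchange_rate <- function(pool, ph) {
  stopifnot(inherits(pool, "cest_pool"))
  if (!is.numeric(ph) || any(!is.finite(ph)) || any(ph < 0 | ph > 14))
    stopf("ph must lie in [0, 14]")
  pool$base_rate * 10^(pool$ph_slope * (ph - 7.0))
}

#' Assemble a water + solutes pool system
#'
#' @param water A [pool()] with `shift_ppm = 0`; its `fraction` is ignored
#'   (water is the unit-magnetization reference).
#' @param solutes List of solute [pool()]s with distinct chemical shifts.
#' @param field_mhz Water resonance frequency in MHz (> 0); 400.22 MHz
#'   corresponds to 9.4 T.
#' @return An object of class `pool_system`.
#' @export
pool_system <- function(water, solutes = list(), field_mhz = 400.22) {
  stopifnot(inherits(water, "cest_pool"))
  if (water$shift_ppm != 0) stopf("water pool must have shift_ppm = 0")
  if (!is.list(solutes) || !all(vapply(solutes, inherits, TRUE, "cest_pool")))
    stopf("solutes must be a list of pool() objects")
  shifts <- vapply(solutes, `[[`, 0, "shift_ppm")
  if (anyDuplicated(shifts)) stopf("solute chemical shifts must be distinct")
  if (!is_number(field_mhz) || field_mhz <= 0) stopf("field_mhz must be > 0")
  structure(list(water = water, solutes = solutes, field_mhz = field_mhz),
            class = "pool_system")
}

#' Default 3-pool brain-like system at 9.4 T
#'
#' Water (T1 = 2 s, T2 = 60 ms), a slow-exchanging amide pool at +3.5 ppm
#' (fraction 7e-4, 30 1/s at pH 7, base-catalyzed) and a fast/intermediate
#' amine pool at +2.75 ppm (fraction 5e-4, 1500 1/s at pH 7,
#' base-catalyzed). With these rates the amide CEST effect grows with pH
#' while the amine effect shrinks, so the AACID ratio decreases as tissue
#' becomes more alkaline. An optional broad magnetization-transfer pool can
#' be switched on.
#'
#' @param mt Include a broad pH-independent magnetization-transfer pool.
#' @param field_mhz Water resonance frequency (MHz).
#' @return A [pool_system()].
#' @export
default_pool_system <- function(mt = FALSE, field_mhz = 400.22) {
  solutes <- list(
    amide = pool(3.5, t1 = 1.0, t2 = 0.010, fraction = 7e-4,
                 base_rate = 30, ph_slope = 1.0),
    amine = pool(2.75, t1 = 1.0, t2 = 0.005, fraction = 5e-4,
                 base_rate = 1500, ph_slope = 1.0))
  if (mt) {
    solutes$mt <- pool(-2.4, t1 = 1.0, t2 = 1e-5, fraction = 0.05,
                       base_rate = 25, ph_slope = 0)
  }
  pool_system(pool(0, t1 = 2.0, t2 = 0.060, fraction = 0),
              solutes, field_mhz = field_mhz)
}

#' @export
print.pool_system <- function(x, ...) {
  cat(sprintf("<pool_system> water + %d solute pool(s) at %.2f MHz\n",
              length(x$solutes), x$field_mhz))
  for (s in x$solutes)
    cat(sprintf("  %+.2f ppm  f = %g  k(pH7) = %g 1/s  slope = %g\n",
                s$shift_ppm, s$fraction, s$base_rate, s$ph_slope))
  invisible(x)
}
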