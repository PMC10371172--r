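#' Parameters of the delayed-rectifier KV2.1 current model
#'
#' Hodgkin-Huxley-type whole-cell model of the KV2.1 conductance with a
#' single activation gate and an optional inactivation gate:
#' `I / C_m = f_functional * g_max * x(t) * [y(t)] * (V - E_K)` in pA/pF,
#' with `x_inf(V) = 1 / (1 + exp(-(V - V_half_act) / k_act))` and a
#' bell-shaped activation time constant. `f_functional` scales the current
#' for the fraction of membrane channels that actually conduct — the key
#' quantity when most channels are structural rather than conductive.
#'
#' The gating defaults are plausible delayed-rectifier values, not traceable
#' to a published parameter table (`unverified_from_ref`): with
#' [calibrate_gmax()] every steady-state density prediction is pinned to a
#' measured/printed value and becomes independent of them.
#'
#' @param g_max Maximal specific conductance, nS/pF (>= 0).
#' @param f_functional Fraction of channels that conduct, in `[0, 1]`.
#' @param E_K K+ reversal potential, mV. Default from the Nernst equation at
#'   295 K with 5 mM external / 107 mM internal K+ (about -78 mV).
#' @param V_half_act,k_act Activation Boltzmann midpoint and slope, mV
#'   (`k_act` nonzero).
#' @param tau_base_ms,tau_amp_ms,tau_vpeak_mV,tau_width_mV Bell-shaped
#'   activation time constant: `tau(V) = tau_base + tau_amp *
#'   exp(-((V - tau_vpeak) / tau_width)^2)`, ms.
#' @param inactivation Optional list with `V_half`, `k`, `tau_ms` for a
#'   Boltzmann inactivation gate (default NULL: non-inactivating).
#' @param C_m Membrane capacitance, pF (bookkeeping only; currents are
#'   reported as densities).
#' @return A `kv_model_params` object.
#' @examples
#' kv_model_params(g_max = 1, f_functional = 0.5)
#' @export
kv_model_params <- function(g_max = 1, f_functional = 1,
                            E_K = nernst_potential(5, 107, 295),
                            V_half_act = 9, k_act = 9,
                            tau_base_ms = 3, tau_amp_ms = 25,
                            tau_vpeak_mV = -10, tau_width_mV = 35,
                            inactivation = NULL, C_m = 16) {
  check_number(g_max, "g_max", lower = 0)
  check_prob(f_functional, "f_functional")
  check_number(E_K, "E_K")
  check_number(V_half_act, "V_half_act")
  check_number(k_act, "k_act")
  if (k_act == 0) abort("`k_act` must be nonzero.")
  check_number(tau_base_ms, "tau_base_ms", lower = 1e-9)
  check_number(tau_amp_ms, "tau_amp_ms", lower = 0)
  check_number(C_m, "C_m", lower = 1e-9)
  if (!is.null(inactivation)) {
    stopifnot(is.list(inactivation),
              all(c("V_half", "k", "tau_ms") %in% names(inactivation)))
  }
  structure(list(g_max = g_max, f_functional = f_functional, E_K = E_K,
                 V_half_act = V_half_act, k_act = k_act,
                 tau_base_ms = tau_base_ms, tau_amp_ms = tau_amp_ms,
                 tau_vpeak_mV = tau_vpeak_mV, tau_width_mV = tau_width_mV,
                 inactivation = inactivation, C_m = C_m),
            class = "kv_model_params")
}

x_inf <- function(v, v_half, k) 1 / (1 + exp(-(v - v_half) / k))

tau_act <- function(v, p) {
  p$tau_base_ms + p$tau_amp_ms * exp(-((v - p$tau_vpeak_mV) / p$tau_width_mV)^2)
}

#' Voltage-step protocol
#'
#' @param holding_mV Holding potential, mV.
#' @param step_mVs Test-pulse voltages, mV.
#' @param step_ms Pulse duration, ms (default 500).
#' @param dt_ms Sample interval, ms; must be at most `step_ms / 100`.
#' @return A `voltage_protocol` object.
#' @examples
#' voltage_protocol(step_mVs = seq(-70, 70, by = 10))
#' @export
voltage_protocol <- function(holding_mV = -70, step_mVs = seq(-70, 70, 10),
                             step_ms = 500, dt_ms = 0.25) {
  check_number(holding_mV, "holding_mV")
  stopifnot(is.numeric(step_mVs), length(step_mVs) >= 1L)
  check_number(step_ms, "step_ms", lower = 1e-9)
  check_number(dt_ms, "dt_ms", lower = 1e-12)
  if (dt_ms > step_ms / 100) {
    abort("`dt_ms` must be at most step_ms / 100.")
  }
  structure(list(holding_mV = holding_mV, step_mVs = step_mVs,
                 step_ms = step_ms, dt_ms = dt_ms),
            class = "voltage_protocol")
}

#' Simulate voltage-step KV2.1 current traces
#'
#' Gates start from their steady state at the holding potential and relax
#' towards their steady state at each step voltage. Because the voltage is
#' constant within a step the gate ODE `dx/dt = (x_inf - x)/tau` is linear
#' and is integrated exactly (`x(t+dt) = x_inf + (x - x_inf) exp(-dt/tau)`),
#' so reported currents are invariant to the sample interval `dt_ms` up to
#' the quadrature of the late-current window.
#'
#' @param params A [kv_model_params()].
#' @param protocol A [voltage_protocol()].
#' @return A tibble: `v_step_mV`, `time_ms`, `i_pA_pF`, `gate`.
#' @examples
#' tr <- simulate_kv_step(kv_model_params(), voltage_protocol(step_mVs = 50))
#' tail(tr, 3)
#' @export
simulate_kv_step <- function(params, protocol = voltage_protocol()) {
  stopifnot(inherits(params, "kv_model_params"),
            inherits(protocol, "voltage_protocol"))
  tau_min <- params$tau_base_ms
  if (protocol$dt_ms > tau_min / 10) {
    abort(sprintf(
      "`dt_ms` (%.3g ms) is too coarse: must be at most tau_min/10 = %.3g ms",
      protocol$dt_ms, tau_min / 10))
  }
  times <- seq(0, protocol$step_ms, by = protocol$dt_ms)
  purrr::map_dfr(protocol$step_mVs, function(v) {
    xi <- x_inf(v, params$V_half_act, params$k_act)
    x0 <- x_inf(protocol$holding_mV, params$V_half_act, params$k_act)
    tau <- tau_act(v, params)
    x <- xi + (x0 - xi) * exp(-times / tau)
    gate <- x
    if (!is.null(params$inactivation)) {
      ia <- params$inactivation
      yi <- x_inf(v, ia$V_half, -abs(ia$k))  # inactivation falls with V
      y0 <- x_inf(protocol$holding_mV, ia$V_half, -abs(ia$k))
      y <- yi + (y0 - yi) * exp(-times / ia$tau_ms)
      gate <- gate * y
    }
    tibble::tibble(
      v_step_mV = v, time_ms = times,
      i_pA_pF = params$f_functional * params$g_max * gate * (v - params$E_K),
      gate = gate)
  })
}

#' Steady-state current-voltage relationship
#'
#' The reported density per step voltage is the mean current over the final
#' 10% of the pulse (the late current).
#'
#' @inheritParams simulate_kv_step
#' @return A tibble of class `iv_curve`: `v_mV`, `i_pA_pF`.
#' @examples
#' iv_curve(kv_model_params(), voltage_protocol(step_mVs = c(-70, 0, 50)))
#' @export
iv_curve <- function(params, protocol = voltage_protocol()) {
  traces <- simulate_kv_step(params, protocol)
  out <- traces |>
    dplyr::group_by(.data$v_step_mV) |>
    dplyr::filter(.data$time_ms >= 0.9 * max(.data$time_ms)) |>
    dplyr::summarise(i_pA_pF = mean(.data$i_pA_pF), .groups = "drop") |>
    dplyr::rename(v_mV = "v_step_mV")
  class(out) <- c("iv_curve", class(out))
  out
}

#' Calibrate the maximal conductance to a target current density
#'
#' Because the steady-state density is strictly linear in `g_max`, the
#' calibration is a closed-form rescale: the model is run once and `g_max`
#' multiplied by `target / observed`. The returned parameter set reproduces
#' `target_density` at `at_voltage` to numerical precision.
#'
#' @param params A [kv_model_params()].
#' @param target_density Target late-current density, pA/pF (> 0).
#' @param at_voltage Voltage at which to match, mV.
#' @param protocol A [voltage_protocol()] (its `step_mVs` are replaced by
#'   `at_voltage` for the calibration run).
#' @return The input `params` with `g_max` rescaled.
#' @examples
#' m <- calibrate_gmax(kv_model_params(), 7006, 50)
#' iv_curve(m, voltage_protocol(step_mVs = 50))$i_pA_pF
#' @export
calibrate_gmax <- function(params, target_density, at_voltage,
                           protocol = voltage_protocol()) {
  stopifnot(inherits(params, "kv_model_params"))
  check_number(target_density, "target_density", lower = 1e-12)
  check_number(at_voltage, "at_voltage")
  if (params$f_functional <= 0) {
    abort("cannot calibrate with `f_functional` = 0 (no current at any g_max)")
  }
  proto <- protocol
  proto$step_mVs <- at_voltage
  base <- iv_curve(params, proto)$i_pA_pF
  if (abs(base) < 1e-12) {
    abort(sprintf(
      "open probability (or driving force) is zero at %g mV; pick a depolarized voltage",
      at_voltage))
  }
  params$g_max <- params$g_max * target_density / base
  params
}

#' Isolate a blocker-sensitive current by trace subtraction
#'
#' Pointwise difference between a composite current record and the record in
#' the presence of a selective pore blocker (RY785-style isolation of the
#' KV2 component). Negative excursions are preserved.
#'
#' @param total,blocked Data frames with identical `time_ms` (and, when
#'   present, `v_step_mV`) columns and an `i_pA_pF` column.
#' @return A tibble like `total` with `i_pA_pF` replaced by the difference.
#' @export
ry785_subtract <- function(total, blocked) {
  stopifnot(is.data.frame(total), is.data.frame(blocked),
            "i_pA_pF" %in% names(total), "i_pA_pF" %in% names(blocked),
            "time_ms" %in% names(total), "time_ms" %in% names(blocked))
  if (nrow(total) != nrow(blocked) ||
      !isTRUE(all.equal(total$time_ms, blocked$time_ms)) ||
      ("v_step_mV" %in% names(total) && "v_step_mV" %in% names(blocked) &&
         !isTRUE(all.equal(total$v_step_mV, blocked$v_step_mV)))) {
    abort("`total` and `blocked` must share an identical time base")
  }
  out <- tibble::as_tibble(total)
  out$i_pA_pF <- total$i_pA_pF - blocked$i_pA_pF
  out
}

#' Predicted current densities across functional fractions
#'
#' Convenience wrapper for the in silico scaling analysis: calibrate the
#' 100%-functional model so its late-current density at `at_voltage` equals
#' `density_100`, then report densities for each functional fraction.
#'
#' @param density_100 Measured/assumed density with all channels functional,
#'   pA/pF.
#' @param fractions Functional fractions to evaluate (default
#'   `c(1, 0.5, 0.1, 0.01, 0.001)`).
#' @param at_voltage Voltage of the calibration/report, mV (default +50).
#' @param params Base [kv_model_params()].
#' @param protocol A [voltage_protocol()].
#' @return A tibble: `f_functional`, `i_pA_pF`.
#' @examples
#' functional_fraction_scan(7006)
#' @export
functional_fraction_scan <- function(density_100,
                                     fractions = c(1, 0.5, 0.1, 0.01, 0.001),
                                     at_voltage = 50,
                                     params = kv_model_params(),
                                     protocol = voltage_protocol()) {
  params$f_functional <- 1
  params <- calibrate_gmax(params, density_100, at_voltage, protocol)
  proto <- protocol
  proto$step_mVs <- at_voltage
  purrr::map_dfr(fractions, function(f) {
    p <- params
    p$f_functional <- f
    tibble::tibble(f_functional = f,
                   i_pA_pF = iv_curve(p, proto)$i_pA_pF)
  })
}
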