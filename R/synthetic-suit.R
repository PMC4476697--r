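# Truth-known oxygraph simulator: a SUIT run as a piecewise-linear O2 decline
# with titration spike artifacts and Gaussian sensor noise.

#' Default SUIT phase plan
#'
#' A four-step substrate-uncoupler-inhibitor titration: complex-I LEAK
#' (substrates only), complex-I OXPHOS (ADP), convergent CI+CII OXPHOS
#' (succinate), and CI+CII LEAK after ATP-synthase inhibition (oligomycin,
#' State 4o). Default fluxes place OXPHOS(CI+CII) at 82.6 and
#' LEAK(CI+CII) at 13.97 pmol O2/s/mg, i.e. a respiratory control ratio of
#' 5.91, the healthy hippocampal reference level of the assay this package
#' models.
#'
#' @param fluxes True fluxes (pmol O2/s/mg), one per phase.
#' @param durations Phase durations in seconds.
#' @return Data frame with columns `state`, `flux`, `duration`.
#' @export
default_suit_plan <- function(fluxes = c(12, 55, 82.6, 13.97),
                              durations = rep(600, 4)) {
  states <- c("LEAK_CI", "OXPHOS_CI", "OXPHOS_CI+CII", "LEAK_CI+CII")
  stopifnot(length(fluxes) == 4, length(durations) == 4)
  data.frame(state = states, flux = fluxes, duration = durations,
             stringsAsFactors = FALSE)
}

#' Parameters for the synthetic SUIT trace generator
#'
#' @param phase_plan Data frame with columns `state`, `flux`
#'   (pmol O2/s/mg, >= 0), `duration` (s); phases run in row order and a
#'   titration event opens each one.
#' @param equilibration_s Seconds after each titration excluded from
#'   steady-state analysis downstream; must be shorter than every phase.
#' @param artifact_magnitude Size (uM) of the transient positive spike at
#'   each titration (exponentially decaying, mimicking reoxygenation and
#'   stirring transients).
#' @param artifact_tau_s Decay time constant of the spike (s).
#' @param noise_sd Gaussian sensor noise on O2 (uM).
#' @param sample_conc Tissue homogenate concentration (mg/ml).
#' @param o2_start Initial chamber O2 concentration (uM).
#' @param dt Sampling interval (s).
#' @param temperature Chamber temperature (degrees C).
#' @param solubility_factor Medium O2 solubility relative to pure water.
#' @param seed Integer seed.
#' @return A validated list of class `suit_generator_params`.
#' @export
suit_generator_params <- function(phase_plan = default_suit_plan(),
                                  equilibration_s = 60, artifact_magnitude = 5,
                                  artifact_tau_s = 10, noise_sd = 0.2,
                                  sample_conc = 1, o2_start = 250, dt = 1,
                                  temperature = 37, solubility_factor = 0.92,
                                  seed = 1) {
  stopifnot(is.data.frame(phase_plan),
            all(c("state", "flux", "duration") %in% names(phase_plan)),
            nrow(phase_plan) >= 1,
            all(phase_plan$flux >= 0), all(is.finite(phase_plan$flux)),
            .is_number(equilibration_s), equilibration_s >= 0,
            all(phase_plan$duration > equilibration_s),
            .is_number(artifact_magnitude), artifact_magnitude >= 0,
            .is_number(artifact_tau_s), artifact_tau_s > 0,
            .is_number(noise_sd), noise_sd >= 0,
            .is_number(sample_conc), sample_conc > 0,
            .is_number(o2_start), o2_start > 0,
            .is_number(dt), dt > 0)
  structure(list(phase_plan = phase_plan, equilibration_s = equilibration_s,
                 artifact_magnitude = artifact_magnitude,
                 artifact_tau_s = artifact_tau_s, noise_sd = noise_sd,
                 sample_conc = sample_conc, o2_start = o2_start, dt = dt,
                 temperature = temperature,
                 solubility_factor = solubility_factor,
                 seed = as.integer(seed)),
            class = "suit_generator_params")
}

#' Simulate a SUIT oxygraph trace with known phase fluxes
#'
#' O2(t) declines piecewise linearly with slope
#' `-flux * sample_conc / 1000` uM/s within each phase; each titration adds a
#' decaying positive spike (none at run start, when the chamber is closed),
#' and Gaussian noise is superimposed. Titration event marks are placed at
#' every phase start. The true flux per phase is recorded as the `truth`
#' attribute.
#'
#' @param params A [suit_generator_params()] object.
#' @return An [oxygraph_trace()] object with attribute `truth`, a data frame
#'   (`state`, `flux`, `t_start`, `t_end`).
#' @examples
#' tr <- make_suit_trace(suit_generator_params(seed = 3))
#' attr(tr, "truth")
#' @export
make_suit_trace <- function(params) {
  stopifnot(inherits(params, "suit_generator_params"))
  plan <- params$phase_plan
  t_end <- cumsum(plan$duration)
  t_start <- c(0, head(t_end, -1))
  time <- seq(0, sum(plan$duration), by = params$dt)

  slope <- -plan$flux * params$sample_conc / 1000 # uM/s, consumption negative
  phase_of <- pmin(findInterval(time, t_start), nrow(plan))
  # noiseless piecewise-linear signal
  o2_at_start <- params$o2_start + cumsum(c(0, head(slope * plan$duration, -1)))
  o2 <- o2_at_start[phase_of] + slope[phase_of] * (time - t_start[phase_of])

  floor_o2 <- params$o2_start + cumsum(slope * plan$duration)
  if (any(floor_o2 < 0)) {
    bad <- which(floor_o2 < 0)[1L]
    stop(sprintf("O2 would fall below zero during phase '%s'; increase o2_start or shorten the run",
                 plan$state[bad]), call. = FALSE)
  }

  if (params$artifact_magnitude > 0) {
    for (ts in t_start[-1L]) { # no spike at run start
      after <- time >= ts
      o2[after] <- o2[after] +
        params$artifact_magnitude * exp(-(time[after] - ts) / params$artifact_tau_s)
    }
  }

  withr::with_seed(params$seed, {
    if (params$noise_sd > 0) o2 <- o2 + rnorm(length(o2), 0, params$noise_sd)
  })

  trace <- oxygraph_trace(
    time = time, o2 = o2,
    events = data.frame(time = t_start, label = plan$state,
                        stringsAsFactors = FALSE),
    sample_conc = params$sample_conc, temperature = params$temperature,
    solubility_factor = params$solubility_factor
  )
  attr(trace, "truth") <- data.frame(state = plan$state, flux = plan$flux,
                                     t_start = t_start, t_end = t_end,
                                     stringsAsFactors = FALSE)
  attr(trace, "equilibration_s") <- params$equilibration_s
  trace
}
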