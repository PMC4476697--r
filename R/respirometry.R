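# SUIT-protocol respirometry analysis: O2 calibration, Savitzky-Golay flux
# computation, titration-event phase segmentation, most-stable-plateau flux
# extraction, and the OXPHOS/LEAK/RCR profile.

#' Construct an oxygraph trace
#'
#' @param time Sample times in seconds, strictly increasing, (near-)uniformly
#'   spaced.
#' @param o2 O2 concentration series (uM), same length as `time`.
#' @param events Data frame of titration marks with columns `time` (within
#'   the trace range, sorted) and `label`.
#' @param sample_conc Tissue homogenate concentration (mg/ml, > 0).
#' @param temperature Chamber temperature (degrees C).
#' @param solubility_factor Medium O2 solubility relative to pure water, in
#'   (0, 2].
#' @return An object of class `oxygraph_trace`.
#' @export
oxygraph_trace <- function(time, o2,
                           events = data.frame(time = numeric(), label = character()),
                           sample_conc = 1, temperature = 37,
                           solubility_factor = 0.92) {
  stopifnot(is.numeric(time), is.numeric(o2), length(time) == length(o2),
            length(time) >= 2, all(is.finite(time)), all(is.finite(o2)),
            all(diff(time) > 0),
            .is_number(sample_conc), sample_conc > 0,
            .is_number(solubility_factor), solubility_factor > 0,
            solubility_factor <= 2,
            is.data.frame(events), all(c("time", "label") %in% names(events)))
  if (nrow(events)) {
    stopifnot(!is.unsorted(events$time),
              all(events$time >= time[1L] & events$time <= time[length(time)]))
  }
  structure(list(time = time, o2 = o2, events = events,
                 sample_conc = sample_conc, temperature = temperature,
                 solubility_factor = solubility_factor),
            class = "oxygraph_trace")
}

#' @export
print.oxygraph_trace <- function(x, ...) {
  cat(sprintf("oxygraph_trace: %d samples over %.0f s, %d titration event(s), %.2g mg/ml\n",
              length(x$time), diff(range(x$time)), nrow(x$events), x$sample_conc))
  invisible(x)
}

#' Two-point O2 calibration
#'
#' Linear calibration of a raw oxygraph signal between a zero mark and an
#' air-saturation mark: the air-saturation signal maps to
#' `saturation_reference * solubility_factor` uM (the solubility factor
#' rescales pure-water saturation to the respiration medium).
#'
#' @param raw_signal Raw sensor signal.
#' @param saturation_reference O2 concentration (uM) of air-saturated pure
#'   water at the working temperature and pressure (instrument-dependent, so
#'   a required input rather than a built-in constant).
#' @param solubility_factor Medium solubility factor (default 0.92).
#' @param saturation_signal Raw signal at the air-saturation mark.
#' @param zero_signal Raw signal at the zero-oxygen mark.
#' @return Calibrated O2 series in uM.
#' @export
calibrate_o2 <- function(raw_signal, saturation_reference,
                         solubility_factor = 0.92,
                         saturation_signal = saturation_reference,
                         zero_signal = 0) {
  if (any(!is.finite(raw_signal))) stop("non-finite raw signal values", call. = FALSE)
  stopifnot(.is_number(saturation_reference), saturation_reference > 0,
            saturation_signal != zero_signal)
  (raw_signal - zero_signal) / (saturation_signal - zero_signal) *
    saturation_reference * solubility_factor
}

#' Oxygen flux from an oxygraph trace
#'
#' Mass-specific oxygen flux `J = -d[O2]/dt * 1000 / sample_conc` in
#' pmol O2/s/mg (consumption positive; negative flux, e.g. reoxygenation
#' artifacts, is reported, never clipped). The derivative comes from a local
#' quadratic Savitzky-Golay fit over `smooth_window` seconds; plain central
#' differences are available as a fallback mode for oracle checks.
#'
#' @param trace An [oxygraph_trace()] object.
#' @param smooth_window Derivative window in seconds (>= 2 sampling
#'   intervals; must not exceed the trace).
#' @param method `"sgolay"` (default) or `"diff"`.
#' @return Data frame with columns `time` and `flux`.
#' @export
oxygen_flux <- function(trace, smooth_window = 21, method = c("sgolay", "diff")) {
  stopifnot(inherits(trace, "oxygraph_trace"))
  method <- match.arg(method)
  dt <- median(diff(trace$time))
  if (max(abs(diff(trace$time) - dt)) > 1e-6 * dt) {
    stop("trace must be uniformly sampled for flux computation", call. = FALSE)
  }
  if (smooth_window < 2 * dt) stop("'smooth_window' must span >= 2 sampling intervals",
                                   call. = FALSE)
  n <- length(trace$o2)
  if (method == "sgolay") {
    np <- round(smooth_window / dt)
    if (np %% 2 == 0) np <- np + 1
    np <- max(np, 5)
    if (np > n) stop("'smooth_window' is longer than the trace", call. = FALSE)
    dodt <- signal::sgolayfilt(trace$o2, p = 2, n = np, m = 1, ts = dt)
  } else {
    dodt <- c(trace$o2[2L] - trace$o2[1L],
              (trace$o2[3:n] - trace$o2[1:(n - 2L)]) / 2,
              trace$o2[n] - trace$o2[n - 1L]) / dt
  }
  data.frame(time = trace$time, flux = -dodt * 1000 / trace$sample_conc)
}

#' Segment a trace into SUIT phases at titration events
#'
#' Phase i spans from titration i to the next titration (the last phase ends
#' at the trace end); its analysis window starts `equilibration_s` seconds
#' after the titration, excluding mixing/reoxygenation transients. Any
#' record before the first titration becomes a `"baseline"` phase (no
#' equilibration exclusion, since nothing was injected). A phase whose
#' window is emptied by the exclusion is kept, flagged by a warning, never
#' silently dropped. With no events the whole trace is one baseline phase.
#'
#' @param trace An [oxygraph_trace()] object.
#' @param equilibration_s Equilibration exclusion in seconds (>= 0).
#' @return Data frame with `label`, `phase_start`, `phase_end`, `win_start`,
#'   `win_end`.
#' @export
segment_phases <- function(trace, equilibration_s = 60) {
  stopifnot(inherits(trace, "oxygraph_trace"),
            .is_number(equilibration_s), equilibration_s >= 0)
  t0 <- trace$time[1L]
  t_end <- trace$time[length(trace$time)]
  ev <- trace$events
  rows <- list()
  if (!nrow(ev) || ev$time[1L] > t0) {
    rows[[1L]] <- data.frame(label = "baseline", phase_start = t0,
                             phase_end = if (nrow(ev)) ev$time[1L] else t_end,
                             stringsAsFactors = FALSE)
  }
  if (nrow(ev)) {
    nxt <- c(ev$time[-1L], t_end)
    for (i in seq_len(nrow(ev))) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = ev$label[i], phase_start = ev$time[i], phase_end = nxt[i],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$win_start <- ifelse(out$label == "baseline", out$phase_start,
                          out$phase_start + equilibration_s)
  out$win_end <- out$phase_end
  empty <- out$win_start >= out$win_end
  if (any(empty)) {
    warning("phase(s) emptied by equilibration exclusion: ",
            paste(out$label[empty], collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Steady-state flux of one phase
#'
#' Within the phase's analysis window, slides a `window_s`-second window over
#' the flux series and selects the one with the smallest flux standard
#' deviation (the most stable plateau); the phase flux is the mean over that
#' window and `stability` its SD. Robust to early-phase drift because the
#' stable tail, not the whole-phase mean, is reported.
#'
#' @param flux Data frame from [oxygen_flux()] (columns `time`, `flux`).
#' @param phase One row of [segment_phases()] (or a list with `label`,
#'   `win_start`, `win_end`).
#' @param window_s Plateau window length in seconds.
#' @return One-row data frame: `state`, `flux`, `t_start`, `t_end`,
#'   `stability`.
#' @export
steady_state_flux <- function(flux, phase, window_s = 30) {
  stopifnot(is.data.frame(flux), all(c("time", "flux") %in% names(flux)))
  if (is.data.frame(phase)) phase <- as.list(phase[1, ])
  sel <- flux$time >= phase$win_start & flux$time < phase$win_end
  f <- flux$flux[sel]
  tt <- flux$time[sel]
  dt <- median(diff(flux$time))
  k <- max(2L, round(window_s / dt))
  if (length(f) < k) {
    stop(sprintf("phase '%s' is shorter than the %g s plateau window",
                 phase$label, window_s), call. = FALSE)
  }
  rsd <- zoo::rollapply(f, width = k, FUN = sd, align = "left")
  i <- which.min(rsd)
  data.frame(state = phase$label,
             flux = mean(f[i:(i + k - 1L)]),
             t_start = tt[i], t_end = tt[i + k - 1L],
             stability = rsd[i], stringsAsFactors = FALSE)
}

#' Extract steady-state fluxes for every SUIT phase
#'
#' Convenience wrapper: computes the flux series, segments the trace at its
#' titration events, and extracts the most stable plateau of every phase
#' whose window survives the equilibration exclusion and is long enough for
#' the plateau window.
#'
#' @inheritParams oxygen_flux
#' @inheritParams segment_phases
#' @inheritParams steady_state_flux
#' @return Data frame of phase fluxes (one row per phase).
#' @export
extract_phase_fluxes <- function(trace, equilibration_s = 60, window_s = 30,
                                 smooth_window = 21,
                                 method = c("sgolay", "diff")) {
  fl <- oxygen_flux(trace, smooth_window = smooth_window,
                    method = match.arg(method))
  ph <- segment_phases(trace, equilibration_s = equilibration_s)
  rows <- list()
  for (i in seq_len(nrow(ph))) {
    if (ph$win_start[i] >= ph$win_end[i]) next # already warned in segment_phases
    rows[[length(rows) + 1L]] <- steady_state_flux(fl, ph[i, ], window_s = window_s)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.STATE_ALIASES <- list(
  "OXPHOS_CI+CII" = c("OXPHOS_CI+CII", "OXPHOSCICII", "STATE3", "STATE 3"),
  "LEAK_CI+CII" = c("LEAK_CI+CII", "LEAKCICII", "STATE4O", "STATE 4O", "STATE 4_O")
)

.find_state <- function(phase_fluxes, canonical) {
  lab <- toupper(trimws(phase_fluxes$state))
  hit <- which(lab %in% toupper(.STATE_ALIASES[[canonical]]))
  if (!length(hit)) return(NULL)
  phase_fluxes[hit[length(hit)], , drop = FALSE] # last occurrence: protocol order
}

#' Assemble a respiratory profile (OXPHOS, LEAK, RCR)
#'
#' Collects the convergent CI+CII OXPHOS (State 3) and CI+CII LEAK
#' (State 4o, after ATP-synthase inhibition) fluxes from a phase-flux table
#' and computes the respiratory control ratio `RCR = OXPHOS / LEAK`, the
#' coupling index of the tissue. Missing optional states stay absent
#' (`NA`), and a non-positive LEAK flux leaves the RCR undefined with an
#' explicit flag rather than a misleading number.
#'
#' @param phase_fluxes Data frame from [extract_phase_fluxes()] (or any with
#'   columns `state` and `flux`). Labels `State 3` / `State 4o` are accepted
#'   as aliases.
#' @return Object of class `respiratory_profile`: list with `oxphos_ci_cii`,
#'   `leak_ci_cii`, `rcr`, `rcr_defined`, and the full `states` table.
#' @export
respiratory_profile <- function(phase_fluxes) {
  stopifnot(is.data.frame(phase_fluxes),
            all(c("state", "flux") %in% names(phase_fluxes)))
  ox <- .find_state(phase_fluxes, "OXPHOS_CI+CII")
  lk <- .find_state(phase_fluxes, "LEAK_CI+CII")
  oxphos <- if (is.null(ox)) NA_real_ else ox$flux
  leak <- if (is.null(lk)) NA_real_ else lk$flux
  rcr_defined <- is.finite(oxphos) && is.finite(leak) && leak > 0
  structure(list(
    oxphos_ci_cii = oxphos, leak_ci_cii = leak,
    rcr = if (rcr_defined) oxphos / leak else NA_real_,
    rcr_defined = rcr_defined,
    states = phase_fluxes
  ), class = "respiratory_profile")
}

#' @export
print.respiratory_profile <- function(x, ...) {
  cat("respiratory_profile\n")
  cat(sprintf("  OXPHOS(CI+CII): %s pmol O2/s/mg\n", format(x$oxphos_ci_cii, digits = 4)))
  cat(sprintf("  LEAK(CI+CII):   %s pmol O2/s/mg\n", format(x$leak_ci_cii, digits = 4)))
  cat(sprintf("  RCR:            %s%s\n", format(x$rcr, digits = 4),
              if (!x$rcr_defined) " (undefined: LEAK <= 0 or missing)" else ""))
  invisible(x)
}
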