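# Synthetic wearable-band data generator. Emulates the statistical structure
# of a multi-rate personal-sensor log — 8 Hz tri-axial motion channels, 1 Hz
# heart rate / pedometer / distance / calories, slow skin-temperature and UV
# readouts, battery-gap discontinuities — plus five staged anomaly scenarios
# (sprinting, stairs, boxing, falls, breath-holding). The generative model is
# deliberately simple: a hidden activity-state Markov chain (rest/walk/brisk)
# modulating Gaussian motion noise and vital-sign levels, with a circadian
# sinusoid on heart rate. Anomaly effects are deterministic transforms of the
# same random draws, so zero effect sizes reproduce the normal process
# exactly.

.states <- data.frame(
  state = c("rest", "walk", "brisk"),
  accel_sd = c(0.02, 0.15, 0.30),     # g
  gyro_sd = c(2, 30, 60),             # deg/s
  hr_shift = c(0, 15, 35),            # bpm
  steps_rate = c(0, 1.7, 2.6),        # steps/s
  speed = c(0, 130, 220),             # cm/s
  calories_rate = c(0.02, 0.07, 0.13) # kcal/s
)

#' Subject profile for the synthetic generator
#'
#' @param subject_id Subject identifier.
#' @param resting_hr Resting heart rate in bpm (must lie in `[40, 120]`).
#' @param hr_circadian_amplitude Amplitude of the circadian heart-rate
#'   sinusoid in bpm.
#' @param hr_noise_sd Per-second heart-rate noise sd in bpm.
#' @param baseline_skin_temp Baseline skin temperature in degrees Celsius.
#' @param activity_level Multiplier on the motion-noise standard deviations
#'   (subject heterogeneity knob, default 1).
#' @param stay_prob Probability of remaining in the current activity state
#'   from one second to the next (default 0.95, i.e. mean bouts of about
#'   20 s, in line with the short activity bouts of free-living behavior).
#' @param seed Default RNG seed for this subject's simulations.
#' @return Object of class `"subject_profile"`.
#' @export
subject_profile <- function(subject_id = "TS1", resting_hr = 70,
                            hr_circadian_amplitude = 8, hr_noise_sd = 2,
                            baseline_skin_temp = 33, activity_level = 1,
                            stay_prob = 0.95, seed = 1) {
  if (resting_hr < 40 || resting_hr > 120) {
    stop("resting_hr must be in [40, 120] bpm")
  }
  if (activity_level < 0 || hr_noise_sd < 0 || hr_circadian_amplitude < 0) {
    stop("variances and amplitudes must be >= 0")
  }
  structure(list(subject_id = subject_id, resting_hr = resting_hr,
                 hr_circadian_amplitude = hr_circadian_amplitude,
                 hr_noise_sd = hr_noise_sd,
                 baseline_skin_temp = baseline_skin_temp,
                 activity_level = activity_level, stay_prob = stay_prob,
                 seed = seed),
            class = "subject_profile")
}

#' Effect parameterization of the five anomaly scenarios
#'
#' Returns the per-scenario effect sizes: heart-rate shift and its temporal
#' profile, motion and gyroscope variance multipliers, step-rate multiplier,
#' fall-impact spike amplitude, and the default duration. `effect_scale`
#' interpolates every effect toward the null (`0` = indistinguishable from
#' normal behavior, `1` = defaults), which is how the generator's
#' dose-response and null-calibration properties are exercised.
#'
#' @param scenario One of `"rushing_100m"`, `"stairs"`, `"boxing"`,
#'   `"falling"`, `"breath_holding"`.
#' @param effect_scale Scaling in `[0, 1]` applied to all effects (default 1).
#' @return List of effect parameters.
#' @export
scenario_effects <- function(scenario = c("rushing_100m", "stairs", "boxing",
                                          "falling", "breath_holding"),
                             effect_scale = 1) {
  scenario <- match.arg(scenario)
  e <- switch(scenario,
    # sprinting: maximal effort, cadence ~2.5-4.6 steps/s on top of the
    # suppressed state rate, large motion variance, HR ramping up ~50 bpm
    rushing_100m = list(duration = 60, hr_shift = 50, hr_profile = "ramp",
                        motion_var_mult = 10, gyro_var_mult = 10,
                        step_mult = 0, step_shift = 3, spike_amplitude = 0),
    stairs = list(duration = 120, hr_shift = 45, hr_profile = "ramp",
                  motion_var_mult = 10, gyro_var_mult = 10,
                  step_mult = 0, step_shift = 2.5, spike_amplitude = 0),
    # boxing: stationary but punches register on the wrist pedometer as
    # spurious steps (and hence spurious derived speed/distance)
    boxing = list(duration = 120, hr_shift = 30, hr_profile = "ramp",
                  motion_var_mult = 15, gyro_var_mult = 15,
                  step_mult = 0, step_shift = 1.5, spike_amplitude = 0),
    # repeated falls: impact spikes, struggle-up motion, impact artifacts on
    # the pedometer
    falling = list(duration = 60, hr_shift = 15, hr_profile = "constant",
                   motion_var_mult = 2, gyro_var_mult = 4,
                   step_mult = 0, step_shift = 0.5, spike_amplitude = 4),
    # maximal breath hold: stillness, diving-reflex bradycardia then rebound
    # tachycardia (around +-35 bpm for holds to the breaking point)
    breath_holding = list(duration = 60, hr_shift = 35,
                          hr_profile = "dip_rebound",
                          motion_var_mult = 0.05, gyro_var_mult = 0.05,
                          step_mult = 0, step_shift = 0, spike_amplitude = 0)
  )
  s <- effect_scale
  e$scenario <- scenario
  e$hr_shift <- e$hr_shift * s
  e$motion_var_mult <- 1 + (e$motion_var_mult - 1) * s
  e$gyro_var_mult <- 1 + (e$gyro_var_mult - 1) * s
  e$step_mult <- 1 + (e$step_mult - 1) * s
  e$step_shift <- e$step_shift * s
  e$spike_amplitude <- e$spike_amplitude * s
  e
}

# Heart-rate shift profile over the scenario, per second.
.hr_profile <- function(effects, n_seconds) {
  if (is.null(effects)) return(rep(0, n_seconds))
  t <- seq_len(n_seconds)
  switch(effects$hr_profile %||% "constant",
    constant = rep(effects$hr_shift, n_seconds),
    ramp = pmin(t / 5, 1) * effects$hr_shift,
    dip_rebound = ifelse(t <= n_seconds / 2, -effects$hr_shift,
                         effects$hr_shift)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Core simulator shared by the normal and anomaly generators. `effects` with
# unit multipliers and zero shifts consumes the RNG stream identically to
# `effects = NULL` and produces the same log.
.simulate_log <- function(profile, n_seconds, gap_schedule = NULL,
                          seed = profile$seed, effects = NULL, t0 = 28800) {
  stopifnot(inherits(profile, "subject_profile"))
  if (n_seconds < 60) stop("n_seconds must be >= 60")
  set.seed(seed)

  ns <- n_seconds
  # hidden activity-state chain at 1 s resolution; rest-heavy target mix
  # (~70% rest / 20% walk / 10% brisk, matching sedentary free-living time)
  state_p <- c(0.7, 0.2, 0.1)
  state <- integer(ns)
  state[1] <- sample.int(3L, 1L, prob = state_p)
  u <- runif(ns)
  jump <- sample.int(3L, ns, replace = TRUE, prob = state_p)
  for (i in 2:ns) {
    state[i] <- if (u[i] < profile$stay_prob) state[i - 1L] else jump[i]
  }
  st <- .states[state, ]

  mv <- if (is.null(effects)) 1 else effects$motion_var_mult
  gv <- if (is.null(effects)) 1 else effects$gyro_var_mult
  sm <- if (is.null(effects)) 1 else effects$step_mult
  ss <- if (is.null(effects)) 0 else effects$step_shift
  spike_amp <- if (is.null(effects)) 0 else effects$spike_amplitude

  # fall-impact spike seconds (drawn unconditionally so the RNG stream does
  # not depend on the amplitude)
  spike_secs <- sort(sample.int(ns, max(1L, ns %/% 6)))

  # 8 Hz motion channels: 9 channels x 8 samples per second
  hi_t <- rep(seq_len(ns) - 1L, each = 8L) + rep(0:7 / 8, ns)
  nhi <- length(hi_t)
  accel_mean <- c(x = 0, y = 0, z = 1)
  sd_sec_accel <- st$accel_sd * profile$activity_level * sqrt(mv)
  sd_sec_gyro <- st$gyro_sd * profile$activity_level * sqrt(gv)
  spike_sec <- rep(FALSE, ns)
  spike_sec[spike_secs] <- TRUE
  spike_hi <- rep(spike_sec, each = 8L) & (rep(0:7, ns) < 4L)  # first half-second

  logs <- vector("list", 16L)
  li <- 0L
  add <- function(channel, timestamp, value) {
    li <<- li + 1L
    logs[[li]] <<- data.frame(timestamp = timestamp, channel = channel,
                              value = value)
  }

  for (ax in c("x", "y", "z")) {
    for (block in c("gyro_accel", "accel")) {
      v <- accel_mean[[ax]] + rnorm(nhi) * rep(sd_sec_accel, each = 8L)
      v <- v + spike_amp * spike_hi
      add(paste(block, ax, sep = "_"), hi_t, v)
    }
    g <- rnorm(nhi) * rep(sd_sec_gyro, each = 8L)
    g <- g + 40 * spike_amp * spike_hi
    add(paste("gyro", ax, sep = "_"), hi_t, g)
  }

  # 1 Hz vitals and cumulative counters
  sec_t <- seq_len(ns) - 1L
  circ <- profile$hr_circadian_amplitude * sin(2 * pi * (t0 + sec_t) / 86400)
  hr <- profile$resting_hr + circ + st$hr_shift +
    rnorm(ns, sd = profile$hr_noise_sd) + .hr_profile(effects, ns)
  add("heart_rate", sec_t, hr)

  # pedometer rate: state rate scaled by the suppression multiplier plus the
  # scenario shift (true cadence or spurious impact/punch counts); the band
  # derives speed, pace and distance from the step stream (~1 m stride)
  step_rate <- st$steps_rate * sm + ss
  steps_inc <- stats::rpois(ns, step_rate)
  add("steps_total", sec_t, cumsum(steps_inc))
  speed <- st$speed * sm + 100 * ss
  add("speed", sec_t, speed)
  add("pace", sec_t, ifelse(speed > 0, 1e5 / speed, 0))
  add("distance_total", sec_t, cumsum(speed))
  add("calories_total", sec_t,
      cumsum(st$calories_rate * (0.5 + 0.5 * sm) + 0.02 * ss))

  # slow channels
  temp_t <- seq(0L, ns - 1L, by = 30L)
  add("skin_temp", temp_t,
      profile$baseline_skin_temp + rnorm(length(temp_t), sd = 0.2))
  uv_t <- seq(0L, ns - 1L, by = 60L)
  hour <- ((t0 + uv_t) %% 86400) / 3600
  add("uv", uv_t, ifelse(hour >= 10 & hour < 16, 1, 0))

  log <- do.call(rbind, logs[seq_len(li)])
  log <- log[order(log$timestamp, log$channel), , drop = FALSE]
  rownames(log) <- NULL

  if (!is.null(gap_schedule)) {
    gaps <- if (is.matrix(gap_schedule)) {
      lapply(seq_len(nrow(gap_schedule)), function(i) gap_schedule[i, ])
    } else if (is.list(gap_schedule)) gap_schedule else list(gap_schedule)
    keep <- rep(TRUE, nrow(log))
    for (g in gaps) {
      keep <- keep & !(log$timestamp >= g[1] & log$timestamp < g[2])
    }
    log <- log[keep, , drop = FALSE]
  }
  log
}

#' Simulate a normal-behavior multi-rate sensor log
#'
#' Produces a raw log (columns `timestamp`, `channel`, `value`) at the band's
#' native rates: 8 Hz tri-axial motion blocks, 1 Hz heart rate / pedometer /
#' distance / speed / pace / calories, skin temperature every 30 s and UV
#' every 60 s. A hidden rest/walk/brisk Markov chain modulates motion noise,
#' heart rate, step rate and speed; heart rate additionally follows a
#' circadian sinusoid. Scheduled gaps (battery recharging) remove all
#' readings in the given intervals.
#'
#' @param profile A [subject_profile()].
#' @param n_seconds Log length in seconds (>= 60).
#' @param gap_schedule Optional list of `c(start, end)` intervals (seconds) or
#'   a two-column matrix; readings with `start <= timestamp < end` are
#'   dropped.
#' @param seed RNG seed (defaults to the profile's seed).
#' @param t0 Clock time of the first sample, seconds after midnight (default
#'   28800 = 08:00), anchoring the circadian phase and the UV daylight rule.
#' @return Data frame with columns `timestamp`, `channel`, `value`.
#' @export
simulate_normal_log <- function(profile, n_seconds = 3600, gap_schedule = NULL,
                                seed = profile$seed, t0 = 28800) {
  .simulate_log(profile, n_seconds, gap_schedule, seed, effects = NULL, t0 = t0)
}

#' Simulate an anomaly-scenario sensor log
#'
#' Same generative core as [simulate_normal_log()] with the scenario's effects
#' applied on top: a heart-rate shift with a scenario-specific temporal
#' profile (ramp for sprinting/stairs/boxing, dip-then-rebound for
#' breath-holding), motion/gyroscope variance multipliers, a step-rate
#' multiplier that also scales speed and pace, and, for falls, sparse
#' high-amplitude acceleration spikes (> 3 g at default scale) followed by
#' stillness.
#'
#' @inheritParams simulate_normal_log
#' @param scenario Scenario name, see [scenario_effects()].
#' @param duration Scenario length in seconds (default: the scenario's own).
#' @param effect_scale Effect-size scaling in `[0, 1]` (default 1; 0 makes
#'   the log statistically identical to normal behavior).
#' @return Data frame with columns `timestamp`, `channel`, `value`.
#' @export
simulate_anomaly_log <- function(profile, scenario, duration = NULL,
                                 effect_scale = 1, seed = profile$seed,
                                 t0 = 28800) {
  effects <- scenario_effects(scenario, effect_scale)
  if (is.null(duration)) duration <- effects$duration
  duration <- max(duration, 60)
  .simulate_log(profile, duration, gap_schedule = NULL, seed = seed,
                effects = effects, t0 = t0)
}

#' Generate a per-subject synthetic dataset of labeled feature tables
#'
#' Simulates, for each subject, one normal-behavior log and one log per
#' anomaly scenario, runs all logs through [build_feature_vectors()], and
#' labels the rows `"typical"` / `"atypical"`. Fully deterministic under
#' `master_seed`.
#'
#' @param n_subjects Number of subjects.
#' @param n_seconds Normal-log length per subject in seconds (default 3600,
#'   one simulated hour).
#' @param scenarios Anomaly scenarios to include (default: all five).
#' @param master_seed Master RNG seed.
#' @param effect_scale Anomaly effect-size scaling (see [scenario_effects()]).
#' @param gap_schedule Optional gap schedule applied to the normal logs.
#' @return Named list, one element per subject: a list with `normal` and
#'   `anomalous` feature data frames (26 features, `t` and `label` columns)
#'   and the subject's `profile`.
#' @export
generate_dataset <- function(n_subjects = 2, n_seconds = 3600,
                             scenarios = c("rushing_100m", "stairs", "boxing",
                                           "falling", "breath_holding"),
                             master_seed = 1, effect_scale = 1,
                             gap_schedule = NULL) {
  set.seed(master_seed)
  seeds <- matrix(sample.int(.Machine$integer.max,
                             n_subjects * (length(scenarios) + 1L)),
                  nrow = n_subjects)
  resting <- round(runif(n_subjects, 58, 82))
  amp <- runif(n_subjects, 5, 10)
  act <- runif(n_subjects, 0.8, 1.2)

  out <- lapply(seq_len(n_subjects), function(i) {
    prof <- subject_profile(subject_id = paste0("TS", i),
                            resting_hr = resting[i],
                            hr_circadian_amplitude = amp[i],
                            activity_level = act[i],
                            seed = seeds[i, 1L])
    normal <- build_feature_vectors(
      simulate_normal_log(prof, n_seconds, gap_schedule, seed = seeds[i, 1L]))
    normal$label <- "typical"
    anom <- lapply(seq_along(scenarios), function(j) {
      fv <- build_feature_vectors(
        simulate_anomaly_log(prof, scenarios[j], effect_scale = effect_scale,
                             seed = seeds[i, j + 1L]))
      fv$label <- "atypical"
      fv
    })
    list(normal = normal, anomalous = do.call(rbind, anom), profile = prof)
  })
  names(out) <- paste0("TS", seq_len(n_subjects))
  out
}
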