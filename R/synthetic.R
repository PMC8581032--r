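# Seeded synthetic cohorts of Go/NoGo sessions. The generator exists so the
# whole pipeline is testable without any recorded cohort: it reproduces the
# game's timing protocol exactly and injects group contrasts in gaze-approach
# dynamics, gaze noise, response accuracy and RT variability whose direction
# mirrors the contrasts the analysis is designed to detect.

#' Stimulus schedule configuration
#'
#' Timing protocol of the game: each stimulus appears for a fixed duration at
#' one of nine screen locations, followed by a waiting period drawn uniformly
#' between `wait_min` and `wait_max`; Go and NoGo stimuli occur in a preset
#' pseudo-random order with proportion `go_proportion`.
#'
#' @param duration Session length, ms (default 240 000 — a four-minute run).
#' @param appearance Stimulus appearance time, ms (default 700).
#' @param wait_min,wait_max Waiting-period bounds, ms (defaults 700 and 1000).
#' @param n_locations Number of stimulus locations (fixed 3 x 3 grid of 9).
#' @param go_proportion Fraction of Go stimuli (default 0.5, balanced).
#' @param sample_rate_hz Nominal gaze logging rate, Hz (default 144).
#' @return A `schedule_config` list.
#' @export
schedule_config <- function(duration = 240000, appearance = 700,
                            wait_min = 700, wait_max = 1000,
                            n_locations = 9, go_proportion = 0.5,
                            sample_rate_hz = 144) {
  if (wait_min > wait_max) abort("`wait_min` must be <= `wait_max`")
  if (go_proportion < 0 || go_proportion > 1) {
    abort("`go_proportion` must lie in [0, 1]")
  }
  if (n_locations != 9) abort("the game uses exactly 9 stimulus locations")
  structure(
    list(duration = duration, appearance = appearance, wait_min = wait_min,
         wait_max = wait_max, n_locations = n_locations,
         go_proportion = go_proportion, sample_rate_hz = sample_rate_hz),
    class = "schedule_config"
  )
}

#' Fixed stimulus locations
#'
#' The nine possible stimulus positions, a 3 x 3 grid inside the unit square.
#'
#' @return Tibble with columns `location` (0-8), `cx`, `cy`.
#' @export
stimulus_locations <- function() {
  tibble::tibble(
    location = 0:8,
    cx = 0.2 + 0.3 * (0:8 %% 3),
    cy = 0.2 + 0.3 * (0:8 %/% 3)
  )
}

#' Generate a stimulus schedule
#'
#' Tiles the session with stimulus events: the first onset follows an initial
#' waiting period, and consecutive onsets are separated by
#' `appearance + wait` with `wait ~ Uniform(wait_min, wait_max)`, so every
#' inter-onset gap lies in `[appearance + wait_min, appearance + wait_max]`
#' (1400-1700 ms at the defaults). Kinds are a seeded permutation of a
#' balanced Go/NoGo sequence (the preset order); locations are uniform over
#' the nine grid positions.
#'
#' @param config A [schedule_config()].
#' @param seed Integer seed fixing the preset order; `NULL` uses the current
#'   RNG state.
#' @return Tibble of stimulus events (`trial_id`, `onset`, `offset`,
#'   `location`, `cx`, `cy`, `kind`); empty when the session is shorter than
#'   one appearance.
#' @export
generate_stimulus_schedule <- function(config = schedule_config(),
                                       seed = NULL) {
  run <- function() {
    onsets <- numeric()
    t <- runif(1, config$wait_min, config$wait_max)
    while (t + config$appearance <= config$duration) {
      onsets <- c(onsets, t)
      t <- t + config$appearance + runif(1, config$wait_min, config$wait_max)
    }
    n <- length(onsets)
    empty <- tibble::tibble(
      trial_id = integer(), onset = numeric(), offset = numeric(),
      location = integer(), cx = numeric(), cy = numeric(), kind = character()
    )
    if (n == 0) return(empty)
    n_go <- round(n * config$go_proportion)
    kinds <- sample(c(rep("go", n_go), rep("nogo", n - n_go)))
    loc <- sample.int(config$n_locations, n, replace = TRUE) - 1L
    grid <- stimulus_locations()
    tibble::tibble(
      trial_id = seq_len(n), onset = onsets,
      offset = onsets + config$appearance, location = loc,
      cx = grid$cx[loc + 1L], cy = grid$cy[loc + 1L], kind = kinds
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Subject simulation profile
#'
#' Behavioral parameters of one simulated subject. The gaze model is a noisy
#' proportional pursuit: from `gaze_latency` ms after stimulus onset the gaze
#' moves a fraction `gaze_gain` of the remaining distance toward the stimulus
#' center at every sample, plus isotropic Gaussian noise; between stimuli it
#' drifts toward screen center (0.5, 0.5) with the same gain. Responses are
#' Bernoulli per trial with lognormal response times; with probability
#' `p_anticipatory` a press is replaced by a premature one (RT < 120 ms),
#' giving the outlier filter something to remove.
#'
#' @param group Group label the profile emulates.
#' @param p_go_respond Probability of pressing on a Go trial.
#' @param p_nogo_inhibit Probability of withholding on a NoGo trial.
#' @param rt_log_mean,rt_log_sd Lognormal RT parameters (log-ms).
#' @param p_anticipatory Probability a press is anticipatory (RT < 120 ms).
#' @param gaze_gain Per-sample approach fraction, in (0, 1).
#' @param gaze_latency Ms between stimulus onset and approach start.
#' @param gaze_noise_sd Gaze noise SD, normalized screen units per sample.
#' @param drift_to_center Drift toward screen center between stimuli?
#' @param p_lapse Probability a trial is unattended (an attention lapse).
#'   Lapsed trials couple response and gaze: the pursuit gain is multiplied
#'   by `lapse_gain_factor` and a lapsed Go trial is pressed only with
#'   probability `p_go_lapsed`, so Go misses mostly carry weak-approach gaze
#'   dynamics and correct responses carry engaged ones — the
#'   response-type-dependent structure the by-type analysis exploits.
#'   Default 0 (every trial attended).
#' @param lapse_gain_factor Gain multiplier on lapsed trials (default 0.3).
#' @param p_go_lapsed Press probability on a lapsed Go trial (default 0.1).
#' @return A `subject_profile` list.
#' @export
subject_profile <- function(group = "typical",
                            p_go_respond = 0.9, p_nogo_inhibit = 0.8,
                            rt_log_mean = log(450), rt_log_sd = 0.25,
                            p_anticipatory = 0.05,
                            gaze_gain = 0.35, gaze_latency = 120,
                            gaze_noise_sd = 0.01, drift_to_center = TRUE,
                            p_lapse = 0, lapse_gain_factor = 0.3,
                            p_go_lapsed = 0.1) {
  probs <- c(p_go_respond, p_nogo_inhibit, p_anticipatory, p_lapse,
             p_go_lapsed)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (gaze_gain <= 0 || gaze_gain >= 1) abort("`gaze_gain` must lie in (0, 1)")
  if (rt_log_sd < 0) abort("`rt_log_sd` must be >= 0")
  structure(
    list(group = group, p_go_respond = p_go_respond,
         p_nogo_inhibit = p_nogo_inhibit, rt_log_mean = rt_log_mean,
         rt_log_sd = rt_log_sd, p_anticipatory = p_anticipatory,
         gaze_gain = gaze_gain, gaze_latency = gaze_latency,
         gaze_noise_sd = gaze_noise_sd, drift_to_center = drift_to_center,
         p_lapse = p_lapse, lapse_gain_factor = lapse_gain_factor,
         p_go_lapsed = p_go_lapsed),
    class = "subject_profile"
  )
}

#' Default group presets
#'
#' Config values (not measured quantities) chosen so the injected contrasts
#' point the way clinical contrasts are expected to point: the ASD presets
#' have a lower pursuit gain and longer latency (slower, less steady gaze
#' approach, hence shorter stimulus dwell and higher gaze-to-stimulus
#' entropy), more gaze noise, lower Go accuracy and inhibition, more
#' variable response times, and a higher attention-lapse rate (which ties
#' incorrect responses to weak-approach gaze dynamics) than the typical
#' preset.
#'
#' @return Named list of three [subject_profile()] objects.
#' @export
group_presets <- function() {
  list(
    typical = subject_profile(
      group = "typical", p_go_respond = 0.92, p_nogo_inhibit = 0.85,
      rt_log_mean = log(450), rt_log_sd = 0.25, p_anticipatory = 0.05,
      gaze_gain = 0.32, gaze_latency = 120, gaze_noise_sd = 0.01,
      p_lapse = 0.10, lapse_gain_factor = 0.25
    ),
    asd_no_adhd = subject_profile(
      group = "asd_no_adhd", p_go_respond = 0.82, p_nogo_inhibit = 0.72,
      rt_log_mean = log(480), rt_log_sd = 0.40, p_anticipatory = 0.05,
      gaze_gain = 0.27, gaze_latency = 160, gaze_noise_sd = 0.02,
      p_lapse = 0.30, lapse_gain_factor = 0.25
    ),
    asd_adhd = subject_profile(
      group = "asd_adhd", p_go_respond = 0.84, p_nogo_inhibit = 0.65,
      rt_log_mean = log(470), rt_log_sd = 0.45, p_anticipatory = 0.05,
      gaze_gain = 0.27, gaze_latency = 150, gaze_noise_sd = 0.022,
      p_lapse = 0.34, lapse_gain_factor = 0.25
    )
  )
}

#' Simulate one session
#'
#' Generates the gaze track at `config$sample_rate_hz` with the pursuit model
#' described in [subject_profile()], and the keypress events per trial. The
#' result is a valid [session_log()]. Same profile, schedule and seed give an
#' identical session.
#'
#' @param profile A [subject_profile()].
#' @param schedule Stimulus events from [generate_stimulus_schedule()].
#' @param config The [schedule_config()] used for the schedule.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param subject_id Subject identifier stored in the log.
#' @return A [session_log()].
#' @export
simulate_session <- function(profile, schedule, config = schedule_config(),
                             seed = NULL, subject_id = "sim") {
  run <- function() {
    dt <- 1000 / config$sample_rate_hz
    n <- max(1L, floor(config$duration / dt))
    t <- (seq_len(n) - 1) * dt

    # per-trial attention lapses couple gaze dynamics with response behavior
    attended <- if (nrow(schedule) > 0) {
      runif(nrow(schedule)) >= profile$p_lapse
    } else {
      logical(0)
    }

    # piecewise target: stimulus center while it is on screen (shifted by the
    # subject's latency), screen center otherwise; lapsed trials approach
    # with a reduced gain
    tx <- rep(0.5, n)
    ty <- rep(0.5, n)
    gain <- rep(if (profile$drift_to_center) profile$gaze_gain else 0, n)
    if (nrow(schedule) > 0) {
      for (i in seq_len(nrow(schedule))) {
        idx <- which(t >= schedule$onset[i] + profile$gaze_latency &
                       t < schedule$offset[i] + profile$gaze_latency)
        tx[idx] <- schedule$cx[i]
        ty[idx] <- schedule$cy[i]
        gain[idx] <- profile$gaze_gain *
          if (attended[i]) 1 else profile$lapse_gain_factor
      }
    }
    x <- .pursuit_cpp(tx, gain, rnorm(n, 0, profile$gaze_noise_sd), 0.5)
    y <- .pursuit_cpp(ty, gain, rnorm(n, 0, profile$gaze_noise_sd), 0.5)

    presses <- numeric()
    if (nrow(schedule) > 0) {
      window_end <- c(schedule$onset[-1], config$duration)
      for (i in seq_len(nrow(schedule))) {
        p_press <- if (schedule$kind[i] == "go") {
          if (attended[i]) profile$p_go_respond else profile$p_go_lapsed
        } else {
          if (attended[i]) 1 - profile$p_nogo_inhibit else 0
        }
        if (runif(1) >= p_press) next
        win <- window_end[i] - schedule$onset[i]
        if (runif(1) < profile$p_anticipatory) {
          rt <- runif(1, 10, 119)
        } else {
          rt <- rlnorm(1, profile$rt_log_mean, profile$rt_log_sd)
          if (rt >= win) rt <- win - 1  # truncate to the trial window
        }
        presses <- c(presses, schedule$onset[i] + rt)
      }
    }
    session_log(
      subject_id = subject_id, group = profile$group,
      sample_rate_hz = config$sample_rate_hz,
      gaze = tibble::tibble(t = t, x = x, y = y),
      stimuli = schedule,
      responses = tibble::tibble(t = presses)
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Cohort specification
#'
#' @param n_typical,n_asd_no_adhd,n_asd_adhd Subjects per group (defaults
#'   31/11/10, the processed cohort composition the analysis is sized for).
#' @param seed Master seed; every subject seed and jitter derives from it.
#' @param profiles Named list of per-group [subject_profile()] presets.
#' @param jitter Between-subject lognormal jitter SD applied to gain, noise
#'   and RT spread (default 0.08).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_typical = 31, n_asd_no_adhd = 11, n_asd_adhd = 10,
                        seed = 1, profiles = group_presets(), jitter = 0.08) {
  counts <- c(n_typical, n_asd_no_adhd, n_asd_adhd)
  if (any(counts < 0)) abort("group counts must be >= 0")
  structure(
    list(n_typical = n_typical, n_asd_no_adhd = n_asd_no_adhd,
         n_asd_adhd = n_asd_adhd, seed = seed, profiles = profiles,
         jitter = jitter),
    class = "cohort_spec"
  )
}

jitter_profile <- function(profile, jitter) {
  clamp01 <- function(p) pmin(pmax(p, 0.01), 0.99)
  profile$gaze_gain <- min(max(profile$gaze_gain * exp(rnorm(1, 0, jitter)),
                               0.02), 0.95)
  profile$gaze_noise_sd <- profile$gaze_noise_sd * exp(rnorm(1, 0, jitter))
  profile$rt_log_sd <- profile$rt_log_sd * exp(rnorm(1, 0, jitter))
  profile$rt_log_mean <- profile$rt_log_mean + rnorm(1, 0, jitter / 2)
  profile$gaze_latency <- max(0, profile$gaze_latency * exp(rnorm(1, 0, jitter)))
  profile$p_go_respond <- clamp01(profile$p_go_respond + rnorm(1, 0, jitter / 2))
  profile$p_nogo_inhibit <- clamp01(profile$p_nogo_inhibit +
                                      rnorm(1, 0, jitter / 2))
  profile$p_lapse <- clamp01(profile$p_lapse + rnorm(1, 0, jitter / 2))
  profile
}

#' Generate a seeded cohort of sessions
#'
#' One independent session per subject: per-subject profiles are drawn around
#' the group presets with small between-subject jitter, and each subject gets
#' their own preset stimulus order. Identical specs give identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param config A [schedule_config()] shared by all subjects.
#' @return List of [session_log()] objects; each log carries its group label.
#' @export
generate_cohort <- function(spec = cohort_spec(), config = schedule_config()) {
  counts <- c(typical = spec$n_typical, asd_no_adhd = spec$n_asd_no_adhd,
              asd_adhd = spec$n_asd_adhd)
  groups <- rep(names(counts), counts)
  with_seed(spec$seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, 2L * max(1L, length(groups)))
    purrr::imap(groups, function(g, i) {
      profile <- jitter_profile(spec$profiles[[g]], spec$jitter)
      sched <- generate_stimulus_schedule(config, seed = seeds[2 * i - 1])
      simulate_session(profile, sched, config, seed = seeds[2 * i],
                       subject_id = sprintf("%s_%02d", g, i))
    })
  })
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
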