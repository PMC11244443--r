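#' Cohort generator specification
#'
#' Describes the synthetic wrist %BAC cohort emulating the pilot drinking
#' study: eight subjects consume six 50 mL shots of 35% alcohol at 10-minute
#' intervals; each recorded trajectory rises after a short onset delay,
#' holds a plateau of 20--120 min (average ~60 min) and decays over
#' 10--30 min (average ~20 min). Plateau and decay durations are drawn from
#' scaled Beta distributions whose means sit at the reported averages and
#' whose support is exactly the reported range.
#'
#' Peak %BAC, rise duration and onset delay are not reported per subject
#' anywhere; their defaults below are assumptions, configurable here.
#'
#' @param n_subjects Number of subjects.
#' @param plateau_range,plateau_mean Plateau duration support and mean, min.
#' @param decay_range,decay_mean Decay duration support and mean, min.
#' @param rise_range Rise (onset-to-peak) duration range, min (uniform).
#' @param onset_range Delay from recording start to signal onset, min
#'   (uniform).
#' @param peak_range Peak %BAC range, g/dL (uniform).
#' @param shots Drinking protocol, recorded in the spec for provenance.
#' @param noise_sd Additive Gaussian noise on %BAC, g/dL.
#' @param dt_min Sampling interval, min.
#' @param beta_conc Concentration of the Beta draws (higher = tighter around
#'   the mean).
#' @param seed Master seed; all generation is reproducible from the spec
#'   alone.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 8,
                        plateau_range = c(20, 120), plateau_mean = 60,
                        decay_range = c(10, 30), decay_mean = 20,
                        rise_range = c(30, 90),
                        onset_range = c(5, 15),
                        peak_range = c(0.05, 0.15),
                        shots = list(n = 6, volume_ml = 50, abv = 0.35,
                                     interval_min = 10),
                        noise_sd = 0.002, dt_min = 1, beta_conc = 5,
                        seed = 1) {
  check_range <- function(r, m, what) {
    if (length(r) != 2 || r[1] >= r[2])
      stop(what, " range must be an ordered pair")
    if (m <= r[1] || m >= r[2])
      stop(what, " mean must lie strictly inside its range")
  }
  check_range(plateau_range, plateau_mean, "plateau")
  check_range(decay_range, decay_mean, "decay")
  stopifnot(n_subjects >= 1, dt_min > 0, noise_sd >= 0,
            rise_range[1] < rise_range[2], onset_range[1] <= onset_range[2],
            peak_range[1] < peak_range[2])
  structure(list(n_subjects = n_subjects,
                 plateau_range = plateau_range, plateau_mean = plateau_mean,
                 decay_range = decay_range, decay_mean = decay_mean,
                 rise_range = rise_range, onset_range = onset_range,
                 peak_range = peak_range, shots = shots,
                 noise_sd = noise_sd, dt_min = dt_min,
                 beta_conc = beta_conc, seed = seed),
            class = "cohort_spec")
}

# Beta draw rescaled to [lo, hi] with the requested mean; `conc` controls
# the spread. Support is exactly the range, mean exact in expectation.
rbeta_range <- function(n, range, mean, conc) {
  mf <- (mean - range[1]) / (range[2] - range[1])
  range[1] + (range[2] - range[1]) * rbeta(n, conc * mf, conc * (1 - mf))
}

# Deterministic per-subject sub-seed: depends on (master, k) only, so
# subject k is stable when n_subjects grows.
subject_seed <- function(master, k) {
  (as.integer(master) * 1009L + as.integer(k) * 9173L) %% 2147483629L
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

smoothstep <- function(s) {
  s <- pmin(1, pmax(0, s))
  s * s * (3 - 2 * s)
}

#' Generate one synthetic subject trajectory
#'
#' The backbone is piecewise smooth: zero before onset, a smoothstep rise to
#' the peak, a flat plateau with a slight (3%) downward drift, and a
#' smoothstep decay back to zero, followed by a short zero tail. Additive
#' Gaussian noise is applied and the result clamped at zero.
#'
#' @param spec A [cohort_spec()].
#' @param subject Subject index (1-based).
#' @return A `subject_series`: `subject`, `times_min`, `bac_gdl`,
#'   `onset_min`, and the drawn shape parameters in `draws`.
#' @export
generate_subject_series <- function(spec, subject = 1) {
  stopifnot(inherits(spec, "cohort_spec"), subject >= 1)
  with_seed(subject_seed(spec$seed, subject), {
    onset <- runif(1, spec$onset_range[1], spec$onset_range[2])
    rise <- runif(1, spec$rise_range[1], spec$rise_range[2])
    plateau <- rbeta_range(1, spec$plateau_range, spec$plateau_mean,
                           spec$beta_conc)
    decay <- rbeta_range(1, spec$decay_range, spec$decay_mean, spec$beta_conc)
    peak <- runif(1, spec$peak_range[1], spec$peak_range[2])
    total <- onset + rise + plateau + decay + 20
    times <- seq(0, total, by = spec$dt_min)
    t1 <- onset + rise          # plateau start
    t2 <- t1 + plateau          # decay start
    t3 <- t2 + decay            # back to zero
    v <- numeric(length(times))
    ris <- times > onset & times <= t1
    v[ris] <- peak * smoothstep((times[ris] - onset) / rise)
    pla <- times > t1 & times <= t2
    v[pla] <- peak * (1 - 0.03 * (times[pla] - t1) / plateau)
    dec <- times > t2 & times <= t3
    v[dec] <- peak * 0.97 * (1 - smoothstep((times[dec] - t2) / decay))
    if (spec$noise_sd > 0)
      v <- pmax(0, v + rnorm(length(v), 0, spec$noise_sd))
    structure(list(subject = subject, times_min = times, bac_gdl = v,
                   onset_min = onset,
                   draws = list(onset = onset, rise = rise, plateau = plateau,
                                decay = decay, peak = peak)),
              class = "subject_series")
  })
}

#' @export
print.subject_series <- function(x, ...) {
  cat(sprintf("subject %d: %d samples over %.4g min, peak %%BAC %.4g g/dL\n",
              x$subject, length(x$times_min), max(x$times_min),
              max(x$bac_gdl)))
  invisible(x)
}

#' @export
as.data.frame.subject_series <- function(x, ...) {
  data.frame(time_min = x$times_min, bac_g_dl = x$bac_gdl)
}

#' Generate a synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return A list of [subject_series][generate_subject_series()], one per
#'   subject; independent per-subject sub-seeds are derived from the master
#'   seed.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  lapply(seq_len(spec$n_subjects), function(k)
    generate_subject_series(spec, k))
}

#' Forward-simulated sensor series with optional noise
#'
#' Runs the transport model under a known ground-truth input profile and
#' adds i.i.d. Gaussian noise — the fixture for parameter-recovery tests.
#' With `sigma = 0` the output is exactly the solver's sensor series.
#'
#' @param profile Ground-truth [input_profile][piecewise_linear_profile].
#' @param stack A [layer_stack()].
#' @param config A [solver_config()].
#' @param sigma Noise standard deviation, mol/m^3.
#' @param seed Seed for the noise draw.
#' @param every Keep every `every`-th stored time point (thins the series
#'   for fitting).
#' @return A `noisy_sensor_series`: `times_min`, `conc`, `ground_truth`,
#'   `sigma`, `seed`.
#' @export
forward_synthetic <- function(profile, stack = default_layer_stack(),
                              config = solver_config(), sigma = 0, seed = 1,
                              every = 60) {
  field <- solve_diffusion(stack, profile, config)
  ss <- sensor_series(field)
  keep <- seq(1, length(ss$times_min), by = every)
  conc <- ss$conc[keep]
  if (sigma > 0)
    conc <- with_seed(seed, pmax(0, conc + rnorm(length(conc), 0, sigma)))
  structure(list(times_min = ss$times_min[keep], conc = conc,
                 ground_truth = profile, sigma = sigma, seed = seed),
            class = c("noisy_sensor_series", "sensor_series"))
}
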