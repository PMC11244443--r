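#' Align and average a cohort of %BAC series
#'
#' Each subject is aligned to a common time reference at its onset marker
#' (the first time the signal exceeds 5% of its own peak), converted from
#' g/dL to mol/m^3, linearly interpolated onto the union of all aligned time
#' stamps, arithmetic-averaged across the subjects contributing at each
#' time, and truncated at the cutoff (beyond which too few subjects remain).
#'
#' @param cohort List of [subject_series][generate_subject_series()] (or any
#'   list with `times_min` and `bac_gdl`).
#' @param cutoff_min Truncation time, min (default 130).
#' @param onset_frac Onset marker threshold as a fraction of the subject
#'   peak.
#' @return An `average_series`: `times_min`, `conc_mol_m3`, `n_contrib`.
#' @export
average_series <- function(cohort, cutoff_min = 130, onset_frac = 0.05) {
  if (length(cohort) < 1) stop("empty cohort")
  aligned <- lapply(cohort, function(s) {
    v <- bac_gdl_to_mol_m3(s$bac_gdl)
    pk <- max(v)
    if (pk <= 0) stop("subject series is identically zero; no onset marker")
    t0 <- s$times_min[which(v > onset_frac * pk)[1]]
    list(t = s$times_min - t0, v = v)
  })
  tgrid <- sort(unique(unlist(lapply(aligned, `[[`, "t"))))
  tgrid <- tgrid[tgrid >= 0 & tgrid <= cutoff_min]
  vals <- vapply(aligned, function(a) {
    if (length(a$t) < 2) {
      out <- rep(NA_real_, length(tgrid))
      out[tgrid == a$t] <- a$v
      out
    } else {
      approx(a$t, a$v, xout = tgrid, rule = 1)$y
    }
  }, numeric(length(tgrid)))
  vals <- matrix(vals, nrow = length(tgrid))
  n_contrib <- rowSums(!is.na(vals))
  keep <- n_contrib > 0
  structure(list(times_min = tgrid[keep],
                 conc_mol_m3 = rowMeans(vals, na.rm = TRUE)[keep],
                 n_contrib = n_contrib[keep]),
            class = "average_series")
}

#' @export
print.average_series <- function(x, ...) {
  cat(sprintf(
    "average series: %d points over %.4g min, peak %.6g mol/m^3, %d-%d contributing subjects\n",
    length(x$times_min), max(x$times_min), max(x$conc_mol_m3),
    min(x$n_contrib), max(x$n_contrib)))
  invisible(x)
}

#' @export
as.data.frame.average_series <- function(x, ...) {
  data.frame(time_min = x$times_min, conc_mol_m3 = x$conc_mol_m3,
             n_contrib = x$n_contrib)
}

#' Skin-thickness sensitivity study
#'
#' Re-runs the forward model with all four skin-layer thicknesses scaled
#' uniformly (the air gap, being apparatus, is untouched) while the input
#' profile is held fixed. Thinner skin offers less diffusive resistance, so
#' the output peak arrives earlier and higher; thicker skin lowers and
#' flattens it.
#'
#' @param profile Fixed [input_profile][piecewise_linear_profile].
#' @param stack Baseline [layer_stack()].
#' @param scales Positive thickness multipliers (e.g. `c(0.8, 1, 1.2)`).
#' @param config A [solver_config()].
#' @return Named list (by scale) of [sensor_series()] objects.
#' @export
thickness_sensitivity <- function(profile, stack = default_layer_stack(),
                                  scales = c(0.8, 1, 1.2),
                                  config = solver_config()) {
  stopifnot(all(scales > 0))
  out <- lapply(scales, function(s)
    sensor_series(solve_diffusion(scale_skin_thickness(stack, s), profile,
                                  config)))
  names(out) <- format(scales)
  out
}

#' Time of the output-profile maximum
#'
#' @param series A [sensor_series()] (or anything with `times_min`, `conc`).
#' @return Time of the maximum in minutes; ties broken by the earliest.
#' @export
cmax_time <- function(series) {
  if (length(series$conc) == 0) stop("empty series")
  series$times_min[which.max(series$conc)]
}

#' Time at which the spatial gradient in a layer reverses
#'
#' During the absorptive phase the concentration in the stratum corneum
#' decreases outward (the blood side feeds it); once the headspace has
#' accumulated past the skin-side supply the profile flips and increases
#' outward. This marks the absorptive to post-absorptive transition and
#' essentially coincides with the output-profile maximum.
#'
#' @param field A `concentration_field`.
#' @param layer Layer name (default the stratum corneum).
#' @return First stored time (min) at which the layer profile is monotone
#'   non-decreasing in x; `NA` if it never reverses within the horizon.
#' @export
gradient_reversal_time <- function(field, layer = "stratum_corneum") {
  li <- match(layer, field$grid$layer_names)
  if (is.na(li)) stop("unknown layer '", layer, "'")
  idx <- field$grid$layer_first[li]:field$grid$layer_last[li]
  sub <- field$C[idx, , drop = FALSE]
  tol <- 1e-12 * max(sub)
  inc <- apply(diff(sub) >= -tol, 2, all)
  inc[1] <- FALSE  # the all-zero initial condition is not a reversal
  k <- which(inc)[1]
  if (is.na(k)) return(NA_real_)
  field$times_s[k] / 60
}

#' Peak-delay study
#'
#' For each combination of absorption time `T_Ab` (time for the input
#' profile to reach its peak `BAC_max`) and `BAC_max`, builds a piecewise
#' linear input profile with `t_top = T_Ab` and slope `m = BAC_max / T_Ab`,
#' runs the forward model, and records the peak delay time
#' `T_PD = t(C_max) - T_Ab` between the input and output peaks. Per `T_Ab`,
#' a logarithmic trend `T_PD = a log(BAC_max) + b` is fitted by least
#' squares.
#'
#' Because the transport model is linear with linear boundary conditions,
#' scaling `BAC_max` at fixed `T_Ab` rescales the whole solution, so `T_PD`
#' is constant (hence trivially non-decreasing) in `BAC_max`; the trend fit
#' is reported with this in mind (its `r2` is meaningless when the response
#' is flat and is set to `NA` in the degenerate case).
#'
#' @param t_ab_h Absorption times, hours (e.g. `c(0.05, 0.6)`).
#' @param bac_max Input-peak values, mol/m^3.
#' @param stack A [layer_stack()].
#' @param config A [solver_config()]; its horizon must comfortably exceed
#'   the expected output peaks, otherwise results are flagged.
#' @param decline_min Duration of the linear decline after the input peak,
#'   min (the field protocol does not pin it down).
#' @return A list of `peak_delay_result` objects, one per `t_ab_h`, each
#'   with `t_ab_h`, `bac_max`, `t_pd_min`, `cmax_time_min`, trend
#'   coefficients `a`, `b`, `r2`, and `at_horizon` flags.
#' @export
peak_delay_study <- function(t_ab_h, bac_max, stack = default_layer_stack(),
                             config = solver_config(), decline_min = 100) {
  stopifnot(all(t_ab_h > 0), all(bac_max > 0))
  lapply(t_ab_h, function(tab) {
    t_top <- tab * 60
    res <- lapply(bac_max, function(bm) {
      prof <- piecewise_linear_profile(m = bm / t_top, t_top = t_top,
                                       t_max = t_top + decline_min)
      ss <- sensor_series(solve_diffusion(stack, prof, config))
      tc <- cmax_time(ss)
      list(t_cmax = tc, t_pd = tc - t_top,
           at_horizon = tc >= max(ss$times_min) - 1e-9)
    })
    t_pd <- vapply(res, `[[`, 0, "t_pd")
    at_h <- vapply(res, `[[`, TRUE, "at_horizon")
    if (any(at_h))
      warning("output peak at the horizon edge for T_Ab = ", tab,
              " h; extend the solver horizon")
    a <- b <- r2 <- NA_real_
    if (length(bac_max) >= 2) {
      fit <- lm(t_pd ~ log(bac_max))
      a <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
      ss_tot <- sum((t_pd - mean(t_pd))^2)
      r2 <- if (ss_tot > 1e-12) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
    }
    structure(list(t_ab_h = tab, bac_max = bac_max, t_pd_min = t_pd,
                   cmax_time_min = vapply(res, `[[`, 0, "t_cmax"),
                   a = a, b = b, r2 = r2, at_horizon = at_h),
              class = "peak_delay_result")
  })
}

#' @export
print.peak_delay_result <- function(x, ...) {
  cat(sprintf("peak delay at T_Ab = %.3g h:\n", x$t_ab_h))
  print(data.frame(bac_max = x$bac_max, t_pd_min = x$t_pd_min),
        row.names = FALSE)
  cat(sprintf("log trend: T_PD = %.4g log(BAC_max) + %.4g (R^2 = %.3g)\n",
              x$a, x$b, x$r2))
  invisible(x)
}
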