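#' Parametric blood-side input concentration profiles
#'
#' The driving term of the transport model is the ethanol concentration
#' imposed at the blood / stratum basale boundary, C(0, t). Three parametric
#' families are supported:
#'
#' * **piecewise linear** — a linear build-up `m * t` to a peak at `t_top`
#'   followed by a linear decline to zero at `t_max`;
#' * **exponential linear** — `a_e + b_e * exp(r * t) + d_e * t`, a saturating
#'   exponential plus a linear drift (four parameters);
#' * **Hoerl** — `a_h * b_h^t * t^d_h`, combined geometric and power
#'   growth/decay (three parameters).
#'
#' Time is in minutes, concentrations in mol/m^3. Evaluation clamps negative
#' values to zero (a concentration boundary condition cannot be negative);
#' the clamp lives in the evaluator, not in the parameter space, so that
#' optimizers may roam freely over the box.
#'
#' @param m Build-up slope, mol/m^3 per minute (>= 0).
#' @param t_top Time of the peak, minutes (0 < t_top < t_max).
#' @param t_max Time of return to zero, minutes.
#' @return An object of class `input_profile`.
#' @examples
#' p <- piecewise_linear_profile(m = 0.5, t_top = 60, t_max = 160)
#' profile_eval(p, c(0, 60, 160))
#' @name input_profile
NULL

#' @rdname input_profile
#' @export
piecewise_linear_profile <- function(m, t_top, t_max) {
  stopifnot(is.numeric(m), is.numeric(t_top), is.numeric(t_max))
  if (m < 0) stop("build-up slope m must be >= 0")
  if (!(t_top > 0 && t_max > t_top))
    stop("profile requires 0 < t_top < t_max (got t_top = ", t_top,
         ", t_max = ", t_max, ")")
  structure(list(m = m, t_top = t_top, t_max = t_max),
            class = c("piecewise_linear_profile", "input_profile"))
}

#' @rdname input_profile
#' @param a_e Offset, mol/m^3.
#' @param b_e Exponential amplitude, mol/m^3.
#' @param r Exponential rate, 1/minute.
#' @param d_e Linear slope, mol/m^3 per minute.
#' @export
exponential_linear_profile <- function(a_e, b_e, r, d_e) {
  stopifnot(is.numeric(a_e), is.numeric(b_e), is.numeric(r), is.numeric(d_e))
  structure(list(a_e = a_e, b_e = b_e, r = r, d_e = d_e),
            class = c("exponential_linear_profile", "input_profile"))
}

#' @rdname input_profile
#' @param a_h Amplitude, mol/m^3 (>= 0).
#' @param b_h Geometric base per minute (> 0).
#' @param d_h Power exponent (dimensionless).
#' @export
hoerl_profile <- function(a_h, b_h, d_h) {
  stopifnot(is.numeric(a_h), is.numeric(b_h), is.numeric(d_h))
  if (a_h < 0) stop("Hoerl amplitude a_h must be >= 0")
  if (b_h <= 0) stop("Hoerl base b_h must be > 0")
  structure(list(a_h = a_h, b_h = b_h, d_h = d_h),
            class = c("hoerl_profile", "input_profile"))
}

#' Evaluate an input profile
#'
#' @param profile An `input_profile`.
#' @param t Times in minutes (>= 0); vectorized.
#' @return Concentrations in mol/m^3, clamped at zero.
#' @export
profile_eval <- function(profile, t) UseMethod("profile_eval")

#' @export
profile_eval.piecewise_linear_profile <- function(profile, t) {
  stopifnot(all(t >= 0))
  v <- ifelse(t <= profile$t_top,
              profile$m * t,
              profile$m * profile$t_top *
                (profile$t_max - t) / (profile$t_max - profile$t_top))
  pmax(0, ifelse(t > profile$t_max, 0, v))
}

#' @export
profile_eval.exponential_linear_profile <- function(profile, t) {
  stopifnot(all(t >= 0))
  v <- profile$a_e + profile$b_e * exp(profile$r * t) + profile$d_e * t
  if (any(!is.finite(v)))
    stop("exponential linear profile overflows within the window ",
         "(r = ", profile$r, "); parameters invalid")
  pmax(0, v)
}

#' @export
profile_eval.hoerl_profile <- function(profile, t) {
  stopifnot(all(t >= 0))
  if (profile$d_h < 0 && any(t == 0))
    stop("Hoerl profile with d_h < 0 is singular at t = 0")
  # t^0 = 1 at t = 0 (pure geometric case); t^d -> 0 at t = 0 for d > 0
  v <- profile$a_h * profile$b_h^t * t^profile$d_h
  v[t == 0 & profile$d_h > 0] <- 0
  pmax(0, v)
}

#' Locate the peak of an input profile on a window
#'
#' The input-side peak value is the profile's BAC_max and the time to reach
#' it the absorption time T_Ab. For the piecewise linear family the peak is
#' analytic, `(t_top, m * t_top)`; for the others it is found by a dense
#' grid scan followed by local refinement with [stats::optimize()].
#'
#' @param profile An `input_profile`.
#' @param t_end Window end, minutes (> 0).
#' @param n_grid Number of scan points for the numeric families.
#' @return A list of class `profile_peak` with `t_peak` (min) and
#'   `c_peak` (mol/m^3).
#' @export
profile_peak <- function(profile, t_end, n_grid = 10001) {
  stopifnot(t_end > 0)
  UseMethod("profile_peak")
}

#' @export
profile_peak.piecewise_linear_profile <- function(profile, t_end, n_grid = 10001) {
  if (profile$t_top <= t_end) {
    pk <- list(t_peak = profile$t_top, c_peak = profile$m * profile$t_top)
  } else {
    pk <- list(t_peak = t_end, c_peak = unname(profile_eval(profile, t_end)))
  }
  if (pk$c_peak <= 0) pk <- list(t_peak = 0, c_peak = 0)
  structure(pk, class = "profile_peak")
}

#' @export
profile_peak.input_profile <- function(profile, t_end, n_grid = 10001) {
  tg <- seq(0, t_end, length.out = n_grid)
  vg <- profile_eval(profile, tg)
  if (max(vg) <= 0) return(structure(list(t_peak = 0, c_peak = 0),
                                     class = "profile_peak"))
  i <- which.max(vg)
  lo <- tg[max(1L, i - 1L)]
  hi <- tg[min(n_grid, i + 1L)]
  if (hi > lo) {
    op <- optimize(function(t) profile_eval(profile, t),
                   interval = c(lo, hi), maximum = TRUE,
                   tol = (hi - lo) * 1e-8)
    if (op$objective >= vg[i]) {
      return(structure(list(t_peak = op$maximum, c_peak = op$objective),
                       class = "profile_peak"))
    }
  }
  structure(list(t_peak = tg[i], c_peak = vg[i]), class = "profile_peak")
}

#' @export
print.profile_peak <- function(x, ...) {
  cat(sprintf("profile peak: %.6g mol/m^3 at t = %.6g min\n",
              x$c_peak, x$t_peak))
  invisible(x)
}

#' Profile family name
#' @param profile An `input_profile`.
#' @return One of `"piecewise_linear"`, `"exponential_linear"`, `"hoerl"`.
#' @export
profile_family <- function(profile) {
  sub("_profile$", "", class(profile)[1])
}

profile_param_names <- function(family) {
  switch(family,
         piecewise_linear = c("m", "t_top", "t_max"),
         exponential_linear = c("a_e", "b_e", "r", "d_e"),
         hoerl = c("a_h", "b_h", "d_h"),
         stop("unknown profile family: ", family))
}

#' Build a profile from a family name and a named parameter vector
#'
#' @param family Family name (see [profile_family()]).
#' @param params Named numeric vector with the family's parameters.
#' @return An `input_profile`.
#' @export
make_profile <- function(family, params) {
  nm <- profile_param_names(family)
  if (!all(nm %in% names(params)))
    stop("family '", family, "' needs parameters: ", paste(nm, collapse = ", "))
  params <- as.list(params[nm])
  switch(family,
         piecewise_linear = piecewise_linear_profile(params$m, params$t_top,
                                                     params$t_max),
         exponential_linear = exponential_linear_profile(params$a_e, params$b_e,
                                                         params$r, params$d_e),
         hoerl = hoerl_profile(params$a_h, params$b_h, params$d_h))
}

#' Serialize an input profile to / from a key-value config block
#'
#' The block is a plain list `list(family = ..., <param> = ...)`, suitable
#' for YAML round trips and the command-line interface.
#'
#' @param profile An `input_profile`.
#' @return `profile_to_config()`: a named list; `profile_from_config()`: an
#'   `input_profile`.
#' @export
profile_to_config <- function(profile) {
  c(list(family = profile_family(profile)), unclass(profile))
}

#' @rdname profile_to_config
#' @param config A list as produced by `profile_to_config()`.
#' @export
profile_from_config <- function(config) {
  if (is.null(config$family)) stop("profile config needs a 'family' entry")
  make_profile(config$family, unlist(config[names(config) != "family"]))
}

#' @export
print.input_profile <- function(x, ...) {
  p <- unclass(x)
  cat(sprintf("%s input profile: %s\n", profile_family(x),
              paste(sprintf("%s = %.6g", names(p), unlist(p)),
                    collapse = ", ")))
  invisible(x)
}
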