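# Shared fixtures: coarse configurations keep the suite fast while the
# acceptance file uses the resolutions stated in the vignette.

# single homogeneous slab, no advection: the analytic benchmark geometry
slab_stack <- function(thickness_cm = 0.1, diffusivity_cm2_s = 5e-6) {
  layer_stack(list(layer("slab", thickness_cm, diffusivity_cm2_s)))
}

# coarse solver for cheap behavioural checks
coarse_config <- function(horizon_min = 230, dt_s = 5)
  solver_config(nodes_per_layer = c(6, 6, 6, 10, 12), dt_s = dt_s,
                horizon_min = horizon_min)

# the fitting configuration used by the recovery experiments
fit_config <- function() coarse_config()

# a constant-concentration boundary (step input)
constant_profile <- function(c0)
  exponential_linear_profile(a_e = c0, b_e = 0, r = -0.01, d_e = 0)

# a §3.1-shaped reference input: linear build-up to ~21 mol/m^3 at 60 min,
# back to zero at 160 min
reference_profile <- function()
  piecewise_linear_profile(m = 0.35, t_top = 60, t_max = 160)

# hand-built subject series (bypasses the generator)
constant_subject <- function(value_gdl, t_end = 150, subject = 1L) {
  structure(list(subject = subject, times_min = seq(0, t_end),
                 bac_gdl = rep(value_gdl, t_end + 1), onset_min = 0),
            class = "subject_series")
}
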