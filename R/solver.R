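#' Discretize a layer stack into a 1-D vertex-centred grid
#'
#' Node spacing is uniform within each layer and every layer interface
#' coincides with a node, so a face between two adjacent nodes always lies
#' inside exactly one layer. Node 1 sits at x = 0 (the blood side), the last
#' node at the outer wall of the air gap. All coordinates are in metres.
#'
#' @param stack A [layer_stack()].
#' @param nodes_per_layer Integer count(s) of nodes per layer (each >= 3);
#'   recycled over layers.
#' @return A `diffusion_grid`: node coordinates `x` (m), per-cell layer
#'   index `cell_layer`, layer names, and per-layer first/last node indices.
#' @export
build_grid <- function(stack, nodes_per_layer) {
  nl <- length(stack$layers)
  counts <- rep_len(as.integer(nodes_per_layer), nl)
  if (any(counts < 3)) stop("each layer needs at least 3 nodes")
  thick_m <- vapply(stack$layers, `[[`, 0, "thickness_cm") / 100
  bounds <- c(0, cumsum(thick_m))
  x <- 0
  cell_layer <- integer(0)
  for (i in seq_len(nl)) {
    xi <- seq(bounds[i], bounds[i + 1], length.out = counts[i])
    x <- c(x, xi[-1])
    cell_layer <- c(cell_layer, rep(i, counts[i] - 1L))
  }
  # interface coordinates are exact cumulative sums by construction
  iface <- match(bounds, x)
  structure(list(
    x = x,
    cell_layer = cell_layer,
    layer_names = vapply(stack$layers, `[[`, "", "name"),
    layer_first = iface[-length(iface)],
    layer_last = iface[-1],
    nodes_per_layer = counts,
    stack = stack), class = "diffusion_grid")
}

#' Solver configuration
#'
#' @param nodes_per_layer Nodes per layer for [build_grid()]; default 15 per
#'   skin layer and 30 in the air gap.
#' @param dt_s Time step in seconds (> 0).
#' @param horizon_min Simulated horizon in minutes; must cover the data
#'   window being fitted.
#' @param theta Time-integration weight in `[0.5, 1]`; 1 is backward Euler
#'   (default, unconditionally stable under the four-orders-of-magnitude
#'   diffusivity contrast between viable epidermis and stratum corneum),
#'   0.5 is Crank-Nicolson.
#' @param reaction Volumetric source/sink term; the model has none and only
#'   0 is accepted.
#' @return A `solver_config` list.
#' @export
solver_config <- function(nodes_per_layer = c(15, 15, 15, 15, 30),
                          dt_s = 1, horizon_min = 230, theta = 1,
                          reaction = 0) {
  stopifnot(dt_s > 0, horizon_min > 0)
  if (theta < 0.5 || theta > 1) stop("theta must lie in [0.5, 1]")
  if (reaction != 0) stop("the transport model has no source/sink term")
  structure(list(nodes_per_layer = nodes_per_layer, dt_s = dt_s,
                 horizon_min = horizon_min, theta = theta),
            class = "solver_config")
}

# Tridiagonal spatial operator for vol * dC/dt = L C on a layered grid:
# central differences for diffusion, first-order upwind for the air-gap
# advection (cell Peclet number >> 1 there at any practical resolution).
assemble_operator <- function(grid) {
  x <- grid$x
  N <- length(x)
  h <- diff(x)
  D_cell <- vapply(grid$stack$layers, `[[`, 0, "diffusivity_cm2_s")[grid$cell_layer] * 1e-4
  u_cell <- vapply(grid$stack$layers, `[[`, 0, "velocity_m_s")[grid$cell_layer]
  if (any(u_cell < 0)) stop("velocity must point outward (u >= 0)")
  vol <- c(h[1] / 2, (h[-1] + h[-(N - 1)]) / 2, h[N - 1] / 2)
  g <- D_cell / h                     # face conductances
  Ll <- c(0, g + u_cell)              # coefficient of C[i-1] in row i
  Ld <- numeric(N)
  Ld[2:(N - 1)] <- -(g[1:(N - 2)] + g[2:(N - 1)] + u_cell[2:(N - 1)])
  Ld[N] <- -g[N - 1]
  Lu <- c(0, g[-1], 0)                # coefficient of C[i+1] in row i
  list(vol = vol, Ll = Ll, Ld = Ld, Lu = Lu)
}

#' Solve the multilayer diffusion--convection model
#'
#' Integrates `dC/dt = div(D grad C) - u dC/dx` on the layered 1-D domain
#' with a Dirichlet boundary `C(0, t) = profile(t)` (clamped at zero) at the
#' blood side, zero total (diffusive + advective) flux at the outer wall of
#' the air gap, and `C(x, 0) = 0`. Interfaces enforce concentration and flux
#' continuity (finite-volume faces lie within single layers, so the
#' interface flux is single-valued by construction). Advection is active
#' only in the air gap, upwinded for stability.
#'
#' @param stack A [layer_stack()].
#' @param profile An [input_profile][piecewise_linear_profile] evaluated in
#'   minutes.
#' @param config A [solver_config()].
#' @return A `concentration_field`: `times_s`, `grid`, and the
#'   nodes x times concentration matrix `C` (mol/m^3).
#' @export
solve_diffusion <- function(stack, profile, config = solver_config()) {
  stopifnot(inherits(stack, "layer_stack"), inherits(profile, "input_profile"),
            inherits(config, "solver_config"))
  grid <- build_grid(stack, config$nodes_per_layer)
  op <- assemble_operator(grid)
  nt <- ceiling(config$horizon_min * 60 / config$dt_s)
  times_s <- seq(0, by = config$dt_s, length.out = nt + 1)
  g <- profile_eval(profile, times_s / 60)
  C <- theta_step_tridiag(op$vol, op$Ll, op$Ld, op$Lu, g,
                          config$dt_s, config$theta)
  if (any(!is.finite(C)))
    stop("solver diverged (non-finite concentrations) at dt_s = ",
         config$dt_s, "; reduce the time step or use theta = 1")
  structure(list(times_s = times_s, grid = grid, C = C,
                 profile = profile, config = config),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf(
    "concentration field: %d nodes x %d times (0..%.4g min), max %.6g mol/m^3\n",
    nrow(x$C), ncol(x$C), max(x$times_s) / 60, max(x$C)))
  invisible(x)
}

#' Extract the sensor-side output profile
#'
#' The sensor sits at the far wall of the air gap; its signal is the
#' concentration at the outermost grid node, reported in minutes.
#'
#' @param field A `concentration_field` from [solve_diffusion()].
#' @param node `"wall"` (outermost node, default), `"gap_mean"`
#'   (volume-weighted mean over the air gap headspace) or `"skin_surface"`
#'   (the stratum corneum / air gap interface node). With a gas-phase
#'   headspace diffusivity the three choices nearly coincide.
#' @return A `sensor_series`: `times_min`, `conc` (mol/m^3).
#' @export
sensor_series <- function(field, node = c("wall", "gap_mean", "skin_surface")) {
  node <- match.arg(node)
  if (node == "wall") {
    conc <- field$C[nrow(field$C), ]
  } else if (node == "skin_surface") {
    gap <- which(field$grid$layer_names == "air_gap")
    if (length(gap) != 1) stop("no layer named 'air_gap' in the grid")
    conc <- field$C[field$grid$layer_first[gap], ]
  } else {
    gap <- which(field$grid$layer_names == "air_gap")
    if (length(gap) != 1) stop("no layer named 'air_gap' in the grid")
    idx <- field$grid$layer_first[gap]:field$grid$layer_last[gap]
    w <- assemble_operator(field$grid)$vol[idx]
    conc <- as.numeric(w %*% field$C[idx, , drop = FALSE]) / sum(w)
  }
  structure(list(times_min = field$times_s / 60, conc = pmax(0, conc)),
            class = "sensor_series")
}

#' @export
print.sensor_series <- function(x, ...) {
  i <- which.max(x$conc)
  cat(sprintf("sensor series: %d points over %.4g min, peak %.6g mol/m^3 at %.4g min\n",
              length(x$conc), max(x$times_min), x$conc[i], x$times_min[i]))
  invisible(x)
}

#' @export
as.data.frame.sensor_series <- function(x, ...) {
  data.frame(time_min = x$times_min, conc_mol_m3 = x$conc)
}

#' Spatial concentration profiles within one layer
#'
#' Returns C(x, t) restricted to the named layer at the stored times nearest
#' the requested ones — e.g. to follow the diffusion front and the gradient
#' reversal in the stratum corneum.
#'
#' @param field A `concentration_field`.
#' @param layer Layer name.
#' @param times_min Requested times in minutes (within the solved horizon).
#' @return A data.frame with columns `time_min` (the nearest stored time),
#'   `x_m`, `conc`.
#' @export
layer_slice <- function(field, layer, times_min) {
  li <- match(layer, field$grid$layer_names)
  if (is.na(li)) stop("unknown layer '", layer, "'; layers are: ",
                      paste(field$grid$layer_names, collapse = ", "))
  if (any(times_min * 60 > max(field$times_s) + 1e-9))
    stop("requested times exceed the solved horizon")
  idx <- field$grid$layer_first[li]:field$grid$layer_last[li]
  out <- lapply(times_min, function(tm) {
    k <- which.min(abs(field$times_s - tm * 60))
    data.frame(time_min = field$times_s[k] / 60, x_m = field$grid$x[idx],
               conc = field$C[idx, k])
  })
  do.call(rbind, out)
}
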