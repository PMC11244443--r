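#' Physical layers and the default skin + air-gap stack
#'
#' The domain is a stack of 1-D layers from the stratum basale (innermost,
#' adjacent to the blood supply) outward to the air gap between the stratum
#' corneum and the sensor. Each layer carries a thickness (cm), an ethanol
#' molecular diffusivity (cm^2/s) and a convective velocity (m/s, along x
#' away from the blood); only the air gap convects.
#'
#' @param name Layer identifier.
#' @param thickness_cm Thickness in cm (> 0).
#' @param diffusivity_cm2_s Ethanol diffusivity in cm^2/s (> 0).
#' @param velocity_m_s Convective velocity in m/s (0 for skin layers).
#' @param role `"skin"` or `"gap"`; thickness scaling in the sensitivity
#'   study touches skin layers only.
#' @return A `layer` object.
#' @export
layer <- function(name, thickness_cm, diffusivity_cm2_s, velocity_m_s = 0,
                  role = "skin") {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(thickness_cm) || thickness_cm <= 0)
    stop("layer '", name, "': thickness must be > 0")
  if (!is.numeric(diffusivity_cm2_s) || diffusivity_cm2_s <= 0)
    stop("layer '", name, "': diffusivity must be > 0")
  role <- match.arg(role, c("skin", "gap"))
  if (role == "skin" && velocity_m_s != 0)
    stop("layer '", name, "': skin layers do not convect (velocity must be 0)")
  structure(list(name = name, thickness_cm = thickness_cm,
                 diffusivity_cm2_s = diffusivity_cm2_s,
                 velocity_m_s = velocity_m_s, role = role),
            class = "layer")
}

#' Ordered layer stack
#'
#' @param layers List of [layer()] objects ordered from the blood side
#'   outward.
#' @return A `layer_stack`.
#' @export
layer_stack <- function(layers) {
  stopifnot(length(layers) >= 1, all(vapply(layers, inherits, TRUE, "layer")))
  nm <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("layer names must be unique")
  structure(list(layers = layers), class = "layer_stack")
}

#' Default five-layer stack
#'
#' Four epidermis layers plus the 0.1 cm sensor air gap, with the thickness
#' and diffusivity values used throughout the model:
#'
#' | layer | thickness (cm) | diffusivity (cm^2/s) |
#' |---|---|---|
#' | stratum basale | 0.001 | 6.25e-6 |
#' | stratum spinosum | 0.002 | 5.00e-6 |
#' | stratum granulosum and lucidum | 0.0026 | 3.75e-6 |
#' | stratum corneum | 0.0015 | 5.00e-10 |
#' | air gap | 0.1 | 5.00e-10 |
#'
#' The four skin layers sum to an epidermis thickness of 0.0071 cm. The air
#' gap convects outward at 25e-6 m/s by default.
#'
#' The air-gap diffusivity defaults to the gas-phase molecular diffusivity
#' of ethanol vapour in air near room temperature, 0.12 cm^2/s. A headspace
#' this thin (0.1 cm) is therefore diffusively well mixed on a time scale of
#' well under a second, which is what lets the accumulated headspace
#' concentration couple back into the stratum corneum during the
#' post-absorptive phase (the gradient reversal) and gives the sensor signal
#' a finite peak. Assigning the headspace a condensed-phase diffusivity
#' instead (e.g. the stratum corneum value) turns the closed gap into a
#' one-way accumulator whose wall concentration never peaks; the parameter
#' is exposed here so that such variants can be explored deliberately.
#'
#' @param air_velocity_m_s Air-gap convective velocity, m/s.
#' @param air_gap_diffusivity_cm2_s Ethanol diffusivity in the headspace,
#'   cm^2/s.
#' @return A `layer_stack`.
#' @export
default_layer_stack <- function(air_velocity_m_s = 25e-6,
                                air_gap_diffusivity_cm2_s = 0.12) {
  layer_stack(list(
    layer("stratum_basale", 0.001, 6.25e-6),
    layer("stratum_spinosum", 0.002, 5.00e-6),
    layer("stratum_granulosum_lucidum", 0.0026, 3.75e-6),
    layer("stratum_corneum", 0.0015, 5.00e-10),
    layer("air_gap", 0.1, air_gap_diffusivity_cm2_s,
          velocity_m_s = air_velocity_m_s, role = "gap")))
}

#' @export
print.layer_stack <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("layer stack (%d layers, skin thickness %.4g cm):\n",
              nrow(df), skin_thickness_cm(x)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.layer_stack <- function(x, ...) {
  do.call(rbind, lapply(x$layers, function(l)
    data.frame(layer = l$name, thickness_cm = l$thickness_cm,
               diffusivity_cm2_s = l$diffusivity_cm2_s,
               velocity_m_s = l$velocity_m_s, role = l$role,
               stringsAsFactors = FALSE)))
}

#' Total skin (epidermis) thickness of a stack, in cm
#'
#' Sums the thicknesses of the layers with role `"skin"`, excluding the air
#' gap (which is apparatus, not skin).
#'
#' @param stack A `layer_stack`.
#' @return Thickness in cm.
#' @export
skin_thickness_cm <- function(stack) {
  sum(vapply(stack$layers, function(l)
    if (l$role == "skin") l$thickness_cm else 0, 0))
}

#' Scale the skin-layer thicknesses of a stack
#'
#' Multiplies the thickness of every skin layer by `scale`; the air gap is
#' left untouched.
#'
#' @param stack A `layer_stack`.
#' @param scale Positive multiplier.
#' @return A new `layer_stack`.
#' @export
scale_skin_thickness <- function(stack, scale) {
  stopifnot(scale > 0)
  layer_stack(lapply(stack$layers, function(l) {
    if (l$role == "skin") l$thickness_cm <- l$thickness_cm * scale
    l
  }))
}

#' Read / write a layer stack as a tabular parameter file
#'
#' Tab-delimited text with columns `layer`, `thickness_cm`,
#' `diffusivity_cm2_s`, `velocity_m_s` and optionally `role` (defaults to
#' `"gap"` for a layer named `air_gap`, `"skin"` otherwise).
#'
#' @param path File path.
#' @return `read_layer_stack()`: a `layer_stack`.
#' @export
read_layer_stack <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("layer", "thickness_cm", "diffusivity_cm2_s", "velocity_m_s")
  if (!all(need %in% names(df)))
    stop("layer table needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$role))
    df$role <- ifelse(df$layer == "air_gap", "gap", "skin")
  layer_stack(lapply(seq_len(nrow(df)), function(i)
    layer(df$layer[i], df$thickness_cm[i], df$diffusivity_cm2_s[i],
          df$velocity_m_s[i], df$role[i])))
}

#' @rdname read_layer_stack
#' @param stack A `layer_stack`.
#' @export
write_layer_stack <- function(stack, path) {
  write.table(as.data.frame(stack), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Ultrasound skin-thickness survey
#'
#' Upper-arm skin thickness estimated by B-mode ultrasound for eight
#' subjects, used to motivate the representative 0.15 cm skin thickness
#' (the modelled epidermis is about one twentieth of it).
#'
#' @return A data.frame with columns `subject`, `skin_fat_thickness_cm`,
#'   `skin_thickness_cm`.
#' @export
skin_thickness_table <- function() {
  read.delim(system.file("extdata", "skin_thickness_ultrasound.tsv",
                         package = "tracsim"), stringsAsFactors = FALSE)
}
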