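# Probe mechanics: layered-cylinder flexural rigidity, Euler buckling,
# cantilever tip deflection.

#' Reference Young's moduli for probe materials
#'
#' Handbook values (N/m^2), all overridable when building layers: fused
#' silica 72 GPa, carbon fiber (grade 34-700) 234 GPa, parylene-C 2.8 GPa,
#' tungsten 3.5e11 (mid-range of the 3-4e11 spread quoted for drawn rod).
#'
#' @export
material_moduli <- c(
  fused_silica = 72e9,
  carbon_fiber = 234e9,
  parylene_c = 2.8e9,
  tungsten = 3.5e11
)

#' Define one concentric probe layer
#'
#' @param material material name; if it matches [material_moduli] and `E`
#'   is missing, the tabulated modulus is used.
#' @param d_outer,d_inner outer and inner diameters (m); `d_inner = 0` for
#'   a solid core.
#' @param E Young's modulus (N/m^2); overrides the material table.
#' @return A `probe_layer` list.
#' @export
probe_layer <- function(material, d_outer, d_inner = 0, E = NULL) {
  E <- E %||% unname(material_moduli[material])
  if (is.null(E) || is.na(E)) {
    stop_with("validation_error",
              sprintf("unknown material '%s' and no E given", material))
  }
  if (E <= 0) stop_with("validation_error", "E must be positive")
  if (d_inner < 0 || d_outer <= d_inner) {
    stop_with("validation_error", "require d_outer > d_inner >= 0")
  }
  structure(list(material = material, E = E,
                 d_outer = d_outer, d_inner = d_inner),
            class = "probe_layer")
}

#' Define a probe geometry
#'
#' @param layers list of `probe_layer`s, concentric and non-overlapping.
#' @param length_m free (unsupported) length L (m).
#' @param end_condition boundary condition for buckling, default
#'   `"fixed-free"` (cantilevered insertion).
#' @return A `probe_spec` list.
#' @export
probe_spec <- function(layers, length_m,
                       end_condition = c("fixed-free", "pinned-pinned",
                                         "fixed-pinned", "fixed-fixed")) {
  end_condition <- match.arg(end_condition)
  if (inherits(layers, "probe_layer")) layers <- list(layers)
  if (length_m <= 0) stop_with("validation_error", "length must be positive")
  check_layers(layers)
  structure(list(layers = layers, length_m = length_m,
                 end_condition = end_condition),
            class = "probe_spec")
}

check_layers <- function(layers) {
  ord <- order(vapply(layers, function(l) l$d_inner, numeric(1)))
  layers <- layers[ord]
  for (i in seq_along(layers)[-1]) {
    if (layers[[i]]$d_inner < layers[[i - 1]]$d_outer - 1e-15) {
      stop_with("overlap_error", "layers overlap radially")
    }
  }
  invisible(layers)
}

#' Flexural rigidity of a layered cylindrical probe
#'
#' \eqn{K = \sum_i E_i \pi (D_{out,i}^4 - D_{in,i}^4) / 64}: each annular
#' layer contributes its modulus times its area moment of inertia, so K is
#' additive over layers and scales with the fourth power of diameter. A
#' 90 um solid fused-silica tube comes out near 2.3e-7 N m^2, while a
#' parylene-insulated 7 um carbon fiber stays below 8e-11 N m^2 -- three
#' orders of magnitude more compliant.
#'
#' @param spec a `probe_spec`, a `probe_layer`, or a list of layers.
#' @return Flexural rigidity K (N m^2).
#' @examples
#' flexural_rigidity(probe_layer("fused_silica", d_outer = 90e-6))
#' @export
flexural_rigidity <- function(spec) {
  layers <- if (inherits(spec, "probe_spec")) spec$layers
  else if (inherits(spec, "probe_layer")) list(spec)
  else spec
  check_layers(layers)
  sum(vapply(layers, function(l) {
    l$E * pi * (l$d_outer^4 - l$d_inner^4) / 64
  }, numeric(1)))
}

# Effective-length factors for Euler buckling.
EFFECTIVE_LENGTH <- c("fixed-free" = 2, "pinned-pinned" = 1,
                      "fixed-pinned" = 0.699, "fixed-fixed" = 0.5)

#' Euler critical buckling load
#'
#' \eqn{P_{cr} = \pi^2 K / (K_e L)^2} with the standard effective-length
#' factor \eqn{K_e} (fixed-free 2, pinned-pinned 1, fixed-pinned 0.699,
#' fixed-fixed 0.5). Fixed-free models a probe advanced from a guide tube:
#' axial insertion force beyond \eqn{P_{cr}} buckles the free segment, the
#' dominant failure mode for long flexible fiber tips.
#'
#' @param K flexural rigidity (N m^2).
#' @param L free length (m).
#' @param end_condition one of the names above, default `"fixed-free"`.
#' @return Critical load (N).
#' @export
buckling_load <- function(K, L, end_condition = "fixed-free") {
  if (K <= 0 || L <= 0) stop_with("validation_error", "K and L must be > 0")
  if (!end_condition %in% names(EFFECTIVE_LENGTH)) {
    stop_with("validation_error",
              sprintf("unknown end condition '%s'", end_condition))
  }
  pi^2 * K / (EFFECTIVE_LENGTH[[end_condition]] * L)^2
}

#' Cantilever tip deflection under an end load
#'
#' \eqn{\delta = F L^3 / (3 K)} for an end-loaded cantilever: lateral
#' compliance grows with the cube of the free length.
#'
#' @param K flexural rigidity (N m^2).
#' @param L free length (m).
#' @param F end load (N).
#' @return Tip deflection (m).
#' @export
tip_deflection <- function(K, L, F) {
  if (K <= 0 || L <= 0) stop_with("validation_error", "K and L must be > 0")
  F * L^3 / (3 * K)
}

#' Insertion yield percentage
#'
#' Fraction of recording sites retaining functionality after insertion,
#' as a percentage.
#'
#' @param n_functional functional sites.
#' @param n_total sites attempted.
#' @return Percentage (0-100).
#' @examples
#' insertion_yield(3, 14)  # 21.4%
#' insertion_yield(3, 9)   # 33.3%
#' @export
insertion_yield <- function(n_functional, n_total) {
  if (n_total < 1 || n_functional < 0 || n_functional > n_total) {
    stop_with("validation_error", "require 0 <= n_functional <= n_total")
  }
  100 * n_functional / n_total
}
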