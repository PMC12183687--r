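#' Build unit-response analyte voltammogram templates
#'
#' Constructs the per-analyte cyclic-voltammogram shapes used both to
#' synthesize sessions and as training standards for principal component
#' regression: dopamine (anodic oxidation peak near +0.6 V and cathodic
#' reduction trough near -0.2 V on the standard waveform), a pH shift
#' (broad low-frequency features across the sweep), and a broadband
#' movement-artifact shape constructed to be uncorrelated with the dopamine
#' template.
#'
#' Peak shapes are Gaussian bumps in the potential/sample domain placed on
#' the stated sweep; the functional form is a modelling choice (real
#' voltammograms are not parameterized here), with widths exposed so peak
#' separation can be controlled. The movement template is a smooth
#' whole-scan trend explicitly orthogonalized against the dopamine template
#' (correlation 0 by construction, satisfying |r| < 0.3).
#'
#' @param waveform a `scan_waveform`.
#' @param da_ox_v,da_red_v dopamine oxidation (anodic) and reduction
#'   (cathodic) peak potentials (V).
#' @param da_width_v,ph_width_v Gaussian peak widths (V).
#' @param gains named current-per-unit gains: `dopamine` in nA/nM,
#'   `ph` in nA per pH unit, `movement` in nA per unit artifact amplitude.
#'   Default dopamine gain 0.01 nA/nM (10 nA per uM, typical carbon-fiber
#'   sensitivity scale).
#' @return An object of class `analyte_templates`: list with `templates`
#'   (3 x samples matrix, rows dopamine/ph/movement, unit response in nA),
#'   `peaks` (declared peak potentials), `gains`, and the `waveform`.
#' @examples
#' tpl <- make_templates(generate_waveform())
#' rownames(tpl$templates)
#' @export
make_templates <- function(waveform,
                           da_ox_v = 0.6, da_red_v = -0.2,
                           da_width_v = 0.15, ph_width_v = 0.45,
                           gains = c(dopamine = 0.01, ph = 10, movement = 50)) {
  pots <- waveform$potentials
  rng <- range(pots)
  for (v in c(da_ox_v, da_red_v)) {
    if (v < rng[1] || v > rng[2]) {
      stop_with("config_error",
                sprintf("peak potential %.2f V outside scan range", v))
    }
  }
  n <- waveform$n_samples
  apex <- which.max(pots)
  anodic <- seq_len(apex)
  cathodic <- setdiff(seq_len(n), anodic)

  gauss_on <- function(idx, center_v, width_v, amp) {
    g <- numeric(n)
    g[idx] <- amp * exp(-0.5 * ((pots[idx] - center_v) / width_v)^2)
    g
  }

  # Dopamine: unit (+1) oxidation bump on the anodic sweep, -0.5 reduction
  # trough on the cathodic sweep (reduction current is smaller in vivo).
  da <- gauss_on(anodic, da_ox_v, da_width_v, 1) +
    gauss_on(cathodic, da_red_v, da_width_v, -0.5)

  # pH: broad features, opposite polarity on the two sweeps near the apex.
  ph <- gauss_on(anodic, 0.25, ph_width_v, 1) +
    gauss_on(cathodic, 1.0, ph_width_v, -0.6)

  # Movement: smooth whole-scan trend, then remove its projection on the
  # dopamine shape so the two are exactly uncorrelated.
  tt <- seq(-1, 1, length.out = n)
  mv <- tt + 0.5 * tt^2
  mv <- mv - mean(mv)
  dac <- da - mean(da)
  mv <- mv - sum(mv * dac) / sum(dac * dac) * dac
  mv <- mv / max(abs(mv))

  tmpl <- rbind(dopamine = da, ph = ph, movement = mv)
  structure(list(
    templates = tmpl,
    peaks = c(da_ox_v = da_ox_v, da_red_v = da_red_v),
    gains = gains,
    waveform = waveform
  ), class = "analyte_templates")
}

#' Peak potential of a voltammogram on one sweep
#'
#' Locates the applied potential at which a voltammogram's current is
#' extremal on the anodic (rising) or cathodic (falling) sweep. Used e.g.
#' to verify that a background-subtracted dopamine CV peaks at the expected
#' oxidation potential.
#'
#' @param cv numeric voltammogram (length = samples per scan).
#' @param waveform the `scan_waveform` it was recorded under.
#' @param sweep `"anodic"` or `"cathodic"`.
#' @param extremum `"max"` or `"min"`.
#' @return The applied potential (V) at the extremum.
#' @export
peak_potential <- function(cv, waveform, sweep = c("anodic", "cathodic"),
                           extremum = c("max", "min")) {
  sweep <- match.arg(sweep)
  extremum <- match.arg(extremum)
  if (length(cv) != waveform$n_samples) {
    stop_with("dimension_error", "cv length does not match waveform samples")
  }
  apex <- which.max(waveform$potentials)
  idx <- if (sweep == "anodic") seq_len(apex) else apex:waveform$n_samples
  pick <- if (extremum == "max") idx[which.max(cv[idx])] else idx[which.min(cv[idx])]
  waveform$potentials[pick]
}

# Unit-amplitude background CV shape: the smoothed capacitive current
# (proportional to dV/dt, so a smoothed square wave over the triangular
# sweep). Shared by the session simulator and the drift training standards.
background_cv <- function(waveform) {
  n <- waveform$n_samples
  apex <- which.max(waveform$potentials)
  cap <- c(rep(1, apex), rep(-1, n - apex))
  bg <- hanning_smooth(cap, max(5, n %/% 8))
  bg / max(abs(bg))
}
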