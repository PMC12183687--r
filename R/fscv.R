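# FSCV chemometrics: event-referenced background subtraction, principal
# component regression, Q-residual gating, movement-correlation veto,
# sensitivity normalization.

#' Background-subtract a color plot at an event reference
#'
#' FSCV reports concentration *changes*: the large stable background and
#' slow drift are removed by subtracting the voltammogram recorded at a
#' reference time point (conventionally the value-cue display event) from
#' every frame. The reference maps to the nearest frame at or before the
#' requested time.
#'
#' @param colorplot a `color_plot`.
#' @param reference_time reference time (s) within the recording, or an
#'   event label present in `colorplot$events` (first occurrence used).
#' @param n_ref_frames number of consecutive frames ending at the
#'   reference frame to average as the background (default 1: exactly the
#'   frame at the event). Averaging a short pre-event window reduces the
#'   reference's own measurement noise, which is otherwise imprinted on
#'   every subtracted frame and inflates the Q residual.
#' @return A `color_plot` of differential currents; the reference frame
#'   index is recorded in `meta$background_ref_index`.
#' @export
background_subtract <- function(colorplot, reference_time,
                                n_ref_frames = 1) {
  if (is.character(reference_time)) {
    ev <- colorplot$events
    hit <- ev$time_s[ev$label == reference_time]
    if (!length(hit)) {
      stop_with("validation_error",
                sprintf("no event labelled '%s'", reference_time))
    }
    reference_time <- hit[1]
  }
  i <- frame_at(colorplot$frame_times, reference_time)
  rows <- max(1L, i - n_ref_frames + 1L):i
  ref <- colMeans(colorplot$currents[rows, , drop = FALSE])
  colorplot$currents <- sweep(colorplot$currents, 2, ref)
  colorplot$meta$background_ref_index <- i
  colorplot
}

#' Jackson-Mudholkar Q-residual threshold
#'
#' Closed-form upper control limit for the squared reconstruction residual
#' (Q statistic) of observations projected onto a truncated PCA subspace,
#' computed from the eigenvalues of the discarded components:
#' \deqn{Q_\alpha = \theta_1 \left[ \frac{c_\alpha h_0 \sqrt{2\theta_2}}{\theta_1}
#'   + 1 + \frac{\theta_2 h_0 (h_0 - 1)}{\theta_1^2} \right]^{1/h_0}}
#' with \eqn{\theta_i = \sum \lambda_j^i} over discarded components,
#' \eqn{h_0 = 1 - 2\theta_1\theta_3 / (3\theta_2^2)} and \eqn{c_\alpha} the
#' standard normal upper-\eqn{\alpha} quantile.
#'
#' @param discarded_eigenvalues eigenvalues of the components left out of
#'   the model (>= 0).
#' @param alpha significance level in (0, 1).
#' @return The threshold (same units as Q). Zero, with a warning, if there
#'   is no residual space (no or all-zero discarded eigenvalues).
#' @examples
#' q_alpha(c(1, 1, 1), 0.05)  # ~7.77
#' @export
q_alpha <- function(discarded_eigenvalues, alpha = 0.05) {
  lam <- discarded_eigenvalues
  if (any(lam < 0)) stop_with("validation_error", "eigenvalues must be >= 0")
  if (alpha <= 0 || alpha >= 1) {
    stop_with("validation_error", "alpha must lie in (0, 1)")
  }
  if (!length(lam)) return(0)
  if (all(lam == 0)) {
    warning("all discarded eigenvalues are zero; Q threshold is 0")
    return(0)
  }
  th1 <- sum(lam); th2 <- sum(lam^2); th3 <- sum(lam^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  ca <- stats::qnorm(1 - alpha)
  th1 * (ca * h0 * sqrt(2 * th2) / th1 + 1 +
           th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
}

#' Fit a principal component regression model for FSCV
#'
#' PCA of (by default mean-centered) training voltammograms recorded at
#' known analyte levels, followed by a least-squares map from retained
#' component scores to concentrations. The discarded eigenvalues define the
#' Jackson-Mudholkar Q threshold used to veto frames the model cannot
#' explain.
#'
#' @param standards training matrix, standards x samples-per-scan (nA).
#' @param concentrations matrix, standards x analytes, with column names
#'   (e.g. `dopamine` in nM, `ph` in pH units, `movement` as a unitless
#'   artifact amplitude).
#' @param k number of retained components; `NULL` selects the smallest k
#'   explaining at least `var_explained` of the training variance.
#' @param var_explained variance fraction for the automatic k rule.
#' @param alpha significance level of the Q threshold.
#' @param center mean-center standards before PCA (the training mean is
#'   stored and applied at prediction). `FALSE` uses raw residuals.
#' @param movement_standards optional matrix of movement-artifact CVs for
#'   the correlation veto; defaults to the training rows whose `movement`
#'   concentration is non-zero.
#' @return An object of class `pcr_model`.
#' @export
fit_pcr <- function(standards, concentrations, k = NULL,
                    var_explained = 0.995, alpha = 0.05, center = TRUE,
                    movement_standards = NULL) {
  X <- as.matrix(standards)
  C <- as.matrix(concentrations)
  if (nrow(X) != nrow(C)) {
    stop_with("dimension_error",
              "standards and concentrations row counts differ")
  }
  if (ncol(C) < 2) stop_with("validation_error", "need at least 2 analytes")
  if (nrow(X) < 4) {
    stop_with("validation_error", "need at least 2 standards per analyte")
  }
  mu <- if (center) colMeans(X) else numeric(ncol(X))
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  lambda <- sv$d^2 / (nrow(X) - 1)
  tol <- max(lambda) * 1e-10
  rank <- sum(lambda > tol)
  if (rank < ncol(C)) {
    stop_with("rank_deficiency_error", sprintf(
      "training set is rank-deficient: rank %d < %d analytes (standards are collinear)",
      rank, ncol(C)))
  }
  if (is.null(k)) {
    k <- which(cumsum(lambda) / sum(lambda) >= var_explained)[1]
  }
  k <- max(1L, min(as.integer(k), rank, nrow(X) - 1L))
  V <- sv$v[, seq_len(k), drop = FALSE]
  scores <- Xc %*% V
  c_bar <- colMeans(C)
  B <- qr.solve(scores, sweep(C, 2, c_bar))
  lam_disc <- lambda[lambda > tol]
  lam_disc <- if (k < length(lam_disc)) lam_disc[(k + 1):length(lam_disc)] else numeric(0)
  if (is.null(movement_standards) && "movement" %in% colnames(C)) {
    rows <- which(abs(C[, "movement"]) > 0)
    if (length(rows)) movement_standards <- X[rows, , drop = FALSE]
  }
  structure(list(
    center = mu, centered = center, loadings = V, coef = B,
    conc_mean = c_bar, analytes = colnames(C),
    k = k, eigenvalues = lambda, discarded_eigenvalues = lam_disc,
    alpha = alpha, q_alpha = q_alpha(lam_disc, alpha),
    movement_standards = movement_standards,
    n_standards = nrow(X), n_samples = ncol(X)
  ), class = "pcr_model")
}

#' @export
print.pcr_model <- function(x, ...) {
  cat(sprintf(
    "PCR model: %d standards x %d samples, %d component%s retained\n",
    x$n_standards, x$n_samples, x$k, if (x$k > 1) "s" else ""))
  cat(sprintf("  analytes: %s | Q_alpha = %.4g (alpha = %g)\n",
              paste(x$analytes, collapse = ", "), x$q_alpha, x$alpha))
  invisible(x)
}

#' Predict analyte concentration changes for every frame
#'
#' Projects each (background-subtracted) voltammogram onto the retained
#' principal components, maps scores to concentrations, and records the
#' squared reconstruction residual Q per frame. No gating is applied here;
#' see [apply_qc()].
#'
#' @param model a `pcr_model`.
#' @param colorplot a background-subtracted `color_plot`, or a plain
#'   frames x samples matrix.
#' @return An object of class `chem_trace`: per-frame time, concentration
#'   matrix (one column per analyte), Q, validity mask and null reason.
#' @export
predict_concentrations <- function(model, colorplot) {
  X <- if (inherits(colorplot, "color_plot")) colorplot$currents else as.matrix(colorplot)
  if (ncol(X) != model$n_samples) {
    stop_with("dimension_error", sprintf(
      "frame sample dimension %d does not match model (%d)",
      ncol(X), model$n_samples))
  }
  times <- if (inherits(colorplot, "color_plot")) colorplot$frame_times else seq_len(nrow(X))
  Xc <- sweep(X, 2, model$center)
  scores <- Xc %*% model$loadings
  conc <- sweep(scores %*% model$coef, 2, model$conc_mean, `+`)
  colnames(conc) <- model$analytes
  resid <- Xc - scores %*% t(model$loadings)
  q <- rowSums(resid^2)
  ref <- if (inherits(colorplot, "color_plot")) {
    colorplot$meta$background_ref_index %||% NA_integer_
  } else NA_integer_
  new_chem_trace(times, conc, q, background_ref_index = ref)
}

new_chem_trace <- function(time_s, conc, q, valid = NULL, reason = NULL,
                           background_ref_index = NA_integer_,
                           sensitivity_factor = 1) {
  n <- length(time_s)
  structure(list(
    time_s = time_s, conc = conc, q = q,
    valid = valid %||% rep(TRUE, n),
    reason = reason %||% rep("none", n),
    background_ref_index = background_ref_index,
    sensitivity_factor = sensitivity_factor
  ), class = "chem_trace")
}

#' @export
print.chem_trace <- function(x, ...) {
  cat(sprintf("Chem trace: %d frames, analytes %s\n", length(x$time_s),
              paste(colnames(x$conc), collapse = ", ")))
  cat(sprintf("  %d frames nulled (%s)\n", sum(!x$valid),
              paste(names(table(x$reason[x$reason != "none"])),
                    collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.chem_trace <- function(x, ...) {
  data.frame(time_s = x$time_s, as.data.frame(x$conc), Q = x$q,
             valid = x$valid, reason = x$reason)
}

#' Null unreliable frames by Q residual and movement correlation
#'
#' Two vetoes, applied independently: frames whose Q exceeds the model's
#' Jackson-Mudholkar threshold are nulled (reason `"Q-fail"`), and frames
#' whose background-subtracted CV has Pearson correlation above
#' `r_threshold` with any movement standard are nulled (reason
#' `"movement-correlation"`; both reasons are recorded when both fire).
#' Nulled frames carry `NA` concentrations and are excluded (not zeroed)
#' by downstream averaging.
#'
#' @param chem_trace a `chem_trace` from [predict_concentrations()].
#' @param model the `pcr_model` (supplies the Q threshold and movement
#'   standards bank).
#' @param colorplot the background-subtracted `color_plot` (or matrix) the
#'   trace was computed from.
#' @param r_threshold movement-correlation veto threshold, default 0.8.
#' @return The gated `chem_trace`.
#' @export
apply_qc <- function(chem_trace, model, colorplot, r_threshold = 0.8) {
  if (r_threshold <= 0 || r_threshold > 1) {
    stop_with("validation_error", "r_threshold must lie in (0, 1]")
  }
  X <- if (inherits(colorplot, "color_plot")) colorplot$currents else as.matrix(colorplot)
  # numerical floor so an exactly-reconstructable frame is never vetoed
  # when the training residual space is empty (noiseless standards)
  q_tol <- 1e-10 * sum(model$eigenvalues)
  q_fail <- chem_trace$q > model$q_alpha + q_tol
  mv_fail <- rep(FALSE, nrow(X))
  if (!is.null(model$movement_standards)) {
    M <- t(model$movement_standards)            # samples x standards
    r <- suppressWarnings(stats::cor(t(X), M))  # frames x standards
    r[is.na(r)] <- 0
    mv_fail <- apply(r, 1, max) > r_threshold
  }
  bad <- q_fail | mv_fail
  reason <- rep("none", length(bad))
  reason[q_fail] <- "Q-fail"
  reason[mv_fail & !q_fail] <- "movement-correlation"
  reason[mv_fail & q_fail] <- "Q-fail+movement-correlation"
  chem_trace$valid <- chem_trace$valid & !bad
  chem_trace$reason <- reason
  chem_trace$conc[bad, ] <- NA_real_
  chem_trace
}

#' Normalize concentrations by electrode sensitivity
#'
#' Sensor sensitivity scales with the background current (both track the
#' effective exposed carbon surface area). Sensitivity is defined as the
#' dopamine oxidation current divided by the background current; the in
#' vivo estimate is transferred from the in vitro calibration by the ratio
#' \eqn{\rho = s_{vivo} / s_{cal}}: recorded currents scale with
#' sensitivity, so concentrations are corrected by dividing by \eqn{\rho}.
#'
#' @param chem_trace a `chem_trace`.
#' @param in_vivo list with `oxidation_current` and `background_current`
#'   (nA) measured on the implanted electrode.
#' @param calibration list with `oxidation_current` and
#'   `background_current` (nA) from the in vitro calibration standard.
#' @return The rescaled `chem_trace`; the applied sensitivity factor
#'   \eqn{\rho} is recorded in `sensitivity_factor`.
#' @export
sensitivity_normalize <- function(chem_trace, in_vivo, calibration) {
  for (s in list(in_vivo, calibration)) {
    if (s$background_current <= 0) {
      stop_with("validation_error", "background current must be positive")
    }
  }
  s_vivo <- in_vivo$oxidation_current / in_vivo$background_current
  s_cal <- calibration$oxidation_current / calibration$background_current
  rho <- s_vivo / s_cal
  chem_trace$conc <- chem_trace$conc / rho
  chem_trace$sensitivity_factor <- rho
  chem_trace
}

#' Extract gated concentration changes trial by trial
#'
#' The per-trial form of the analysis chain: every event (typically each
#' trial's value cue) defines an epoch `window` seconds around it, the
#' epoch is background-subtracted at its own event reference (the mean of
#' `n_ref_frames` frames ending at the event frame), concentrations are
#' predicted, and Q/movement gating is applied. Referencing each epoch to
#' its own cue keeps slow drift excursions small over the analyzed
#' stretch, so the Q veto responds to genuine unexplained signal rather
#' than accumulated drift. Frames outside every epoch are marked invalid
#' with reason `"not-analyzed"`; overlapping epochs are resolved in favor
#' of the later event.
#'
#' @param colorplot a raw (not yet subtracted) `color_plot`.
#' @param model a `pcr_model`.
#' @param event_times per-trial reference event times (s).
#' @param window epoch extent (s) around each event.
#' @param n_ref_frames frames averaged for each per-trial background.
#' @param r_threshold movement-correlation veto threshold.
#' @return A `chem_trace` on the full session frame grid, with a
#'   `ref_frame` field giving the reference frame index used for each
#'   analyzed frame.
#' @export
analyze_fscv_trials <- function(colorplot, model, event_times,
                                window = c(-2, 7), n_ref_frames = 30,
                                r_threshold = 0.8) {
  X <- colorplot$currents
  n <- nrow(X)
  dt <- colorplot$waveform$repetition_interval
  k0 <- as.integer(round(window[1] / dt))
  k1 <- as.integer(round(window[2] / dt))
  conc <- matrix(NA_real_, n, length(model$analytes),
                 dimnames = list(NULL, model$analytes))
  q <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  reason <- rep("not-analyzed", n)
  ref_frame <- rep(NA_integer_, n)
  for (e in event_times) {
    i <- frame_at(colorplot$frame_times, e)
    rows <- max(1L, i + k0):min(n, i + k1)
    rr <- max(1L, i - n_ref_frames + 1L):i
    ref <- colMeans(X[rr, , drop = FALSE])
    sub <- sweep(X[rows, , drop = FALSE], 2, ref)
    ct <- predict_concentrations(model, sub)
    ct <- apply_qc(ct, model, sub, r_threshold = r_threshold)
    conc[rows, ] <- ct$conc
    q[rows] <- ct$q
    valid[rows] <- ct$valid
    reason[rows] <- ct$reason
    ref_frame[rows] <- i
  }
  out <- new_chem_trace(colorplot$frame_times, conc, q, valid, reason)
  out$ref_frame <- ref_frame
  out$n_ref_frames <- n_ref_frames
  out
}

#' Generate a bank of training standards
#'
#' Builds a synthetic in vitro training bank: voltammograms of dopamine,
#' pH and movement templates at known levels plus white measurement noise.
#' The paper-style training bank comes from separate calibrated sensors;
#' the default level grids here (dopamine 0-200 nM, pH +-0.1, movement
#' 0/1) are stated modelling assumptions, not measured values.
#'
#' @param templates `analyte_templates`.
#' @param n_per standards per analyte.
#' @param da_range,ph_range level ranges for dopamine (nM) and pH.
#' @param movement_levels artifact amplitudes for movement standards.
#' @param drift_range background-drift levels (nA at the background peak);
#'   `NULL` omits drift standards. Slow capacitive drift survives
#'   background subtraction, so including its shape in the training span
#'   keeps drifting frames explainable by the model (small Q) while the
#'   drift loading absorbs it away from the analyte estimates.
#' @param noise_sd white noise sd (nA).
#' @param seed RNG seed.
#' @return list with `standards` (matrix) and `concentrations` (matrix with
#'   columns dopamine, ph, movement and, if enabled, drift).
#' @export
make_standards <- function(templates, n_per = 8,
                           da_range = c(0, 200), ph_range = c(-0.1, 0.1),
                           movement_levels = c(0.5, 1),
                           drift_range = c(-40, 40),
                           noise_sd = 0, seed = NULL) {
  with_seed(seed, {
    g <- templates$gains
    tm <- templates$templates
    da_lv <- seq(da_range[1], da_range[2], length.out = n_per)
    ph_lv <- seq(ph_range[1], ph_range[2], length.out = n_per)
    mv_lv <- rep(movement_levels, length.out = max(2, n_per %/% 2))
    conc <- rbind(
      cbind(dopamine = da_lv, ph = 0, movement = 0),
      cbind(dopamine = 0, ph = ph_lv, movement = 0),
      cbind(dopamine = 0, ph = 0, movement = mv_lv)
    )
    gained <- sweep(conc, 2, g[c("dopamine", "ph", "movement")], `*`)
    X <- gained %*% tm[c("dopamine", "ph", "movement"), , drop = FALSE]
    if (!is.null(drift_range)) {
      dr_lv <- seq(drift_range[1], drift_range[2], length.out = n_per)
      Xd <- dr_lv %o% background_cv(templates$waveform)
      X <- rbind(X, Xd)
      conc <- cbind(conc, drift = 0)
      conc <- rbind(conc, cbind(dopamine = 0, ph = 0, movement = 0,
                                drift = dr_lv))
    }
    if (noise_sd > 0) {
      X <- X + matrix(stats::rnorm(length(X), 0, noise_sd), nrow(X), ncol(X))
    }
    list(standards = X, concentrations = conc)
  })
}
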