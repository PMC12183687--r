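# FSCV chemometrics: background subtraction, PCR, Q threshold, gating,
# sensitivity normalization.

test_that("background subtraction zeroes the reference and constants", {
  cs <- clean_session()
  cp <- cs$sim$colorplot
  sub <- background_subtract(cp, cs$trials$t_value[1])
  i <- sub$meta$background_ref_index
  expect_equal(max(abs(sub$currents[i, ])), 0)
  # constant-in-time plot becomes identically zero
  flat <- cp
  flat$currents <- matrix(rep(cp$currents[1, ], each = nrow(cp$currents)),
                          nrow(cp$currents))
  expect_equal(max(abs(background_subtract(flat, 5)$currents)), 0)
  expect_error(background_subtract(cp, 1e6), class = "validation_error")
})

test_that("subtracted frame at the transient peak matches template arithmetic", {
  cs <- clean_session()
  sub <- background_subtract(cs$sim$colorplot, cs$trials$t_value[1])
  pk <- which.max(cs$sim$truth$da_nM)
  expected <- cs$sim$truth$da_nM[pk] * tpl10k$gains[["dopamine"]] *
    tpl10k$templates["dopamine", ]
  expect_equal(sub$currents[pk, ], unname(expected), tolerance = 1e-8)
})

test_that("q_alpha matches the closed form and its limiting cases", {
  # independent scalar evaluation of the Jackson-Mudholkar form for
  # lambda = {1,1,1}, alpha = 0.05: theta = (3,3,3), h0 = 1/3,
  # 3*(qnorm(.95)*sqrt(6)/9 + 1 - 2/27)^3 = 7.7750
  expect_equal(q_alpha(c(1, 1, 1), 0.05), 7.775003, tolerance = 1e-6)
  expect_identical(q_alpha(numeric(0), 0.05), 0)
  expect_warning(z <- q_alpha(c(0, 0), 0.05))
  expect_identical(z, 0)
  lam <- c(2, 1, 0.5, 0.1)
  expect_gt(q_alpha(lam, 0.01), q_alpha(lam, 0.05))
  expect_gt(q_alpha(lam, 0.05), q_alpha(lam, 0.2))
  expect_error(q_alpha(c(-1, 1), 0.05), class = "validation_error")
  expect_error(q_alpha(c(1, 1), 1.5), class = "validation_error")
})

test_that("noiseless PCR recovers training concentrations exactly", {
  std <- make_standards(tpl10k, n_per = 8, noise_sd = 0)
  m <- fit_pcr(std$standards, std$concentrations, k = 4)
  ct <- predict_concentrations(m, std$standards)
  expect_equal(unname(ct$conc), unname(std$concentrations),
               tolerance = 1e-8)
  expect_lt(max(ct$q), 1e-16)            # full-rank reconstruction
  # all-zero frame maps to zero concentrations and zero Q
  z <- predict_concentrations(m, matrix(0, 1, wf10k$n_samples))
  expect_equal(max(abs(z$conc)), 0, tolerance = 1e-10)
  expect_lt(z$q, 1e-18)
})

test_that("prediction is linear on in-span frames", {
  std <- make_standards(tpl10k, n_per = 8, noise_sd = 0)
  m <- fit_pcr(std$standards, std$concentrations, k = 4)
  X <- std$standards[3, , drop = FALSE]
  Y <- std$standards[12, , drop = FALSE]
  lhs <- predict_concentrations(m, 2 * X + 5 * Y)$conc
  rhs <- 2 * predict_concentrations(m, X)$conc +
    5 * predict_concentrations(m, Y)$conc
  expect_equal(lhs, rhs, tolerance = 1e-8)
  # frame = dopamine template x gain x c returns exactly c
  c0 <- 73.2
  fr <- matrix(c0 * tpl10k$gains[["dopamine"]] *
                 tpl10k$templates["dopamine", ], 1)
  expect_equal(unname(predict_concentrations(m, fr)$conc[1, "dopamine"]), c0,
               tolerance = 1e-6)
})

test_that("rank-deficient training sets are rejected with a named error", {
  one <- matrix(rep(tpl10k$templates["dopamine", ], 6), 6, byrow = TRUE) *
    (1:6)
  conc <- cbind(dopamine = 1:6, ph = 0)
  expect_error(fit_pcr(one, conc), class = "rank_deficiency_error")
  expect_error(fit_pcr(one, conc), "rank")
})

test_that("noisy-mixture concentration recovery beats 10% of range", {
  set.seed(42)
  n <- 20
  da <- runif(n, 0, 100)
  ph <- runif(n, -0.05, 0.05)
  g <- tpl10k$gains
  Xs <- cbind(da * g[["dopamine"]], ph * g[["ph"]]) %*%
    tpl10k$templates[c("dopamine", "ph"), ]
  # SNR 10 on the dopamine peak current
  sd_n <- max(abs(Xs)) / 10
  std <- list(standards = Xs + matrix(rnorm(n * ncol(Xs), 0, sd_n), n),
              concentrations = cbind(dopamine = da, ph = ph))
  m <- fit_pcr(std$standards, std$concentrations, k = 2)
  da_t <- runif(200, 0, 100); ph_t <- runif(200, -0.05, 0.05)
  mix <- cbind(da_t * g[["dopamine"]], ph_t * g[["ph"]]) %*%
    tpl10k$templates[c("dopamine", "ph"), ]
  ct <- predict_concentrations(m, mix + matrix(rnorm(length(mix), 0, sd_n),
                                               200))
  rmse <- sqrt(mean((ct$conc[, "dopamine"] - da_t)^2))
  expect_lt(rmse, 0.1 * diff(range(da_t)))
})

test_that("Q gating and movement veto fire on the right frames", {
  m <- fit_session_model()
  # a frame equal to a movement standard is vetoed with r = 1
  mvf <- m$movement_standards[1, , drop = FALSE]
  ct <- predict_concentrations(m, mvf)
  ct <- apply_qc(ct, m, mvf)
  expect_false(ct$valid[1])
  expect_match(ct$reason[1], "movement-correlation")
  expect_true(all(is.na(ct$conc[1, ])))
  # a clean in-span frame is retained
  cf <- matrix(50 * tpl10k$gains[["dopamine"]] *
                 tpl10k$templates["dopamine", ], 1)
  ct2 <- apply_qc(predict_concentrations(m, cf), m, cf)
  expect_true(ct2$valid[1])
  expect_identical(ct2$reason[1], "none")
  expect_error(apply_qc(ct2, m, cf, r_threshold = 0), class = "validation_error")
})

test_that("sensitivity normalization follows the current ratio", {
  ct <- new_chem_trace(1:3, cbind(dopamine = c(10, 20, 30)), rep(0, 3))
  idn <- sensitivity_normalize(ct, list(oxidation_current = 2,
                                        background_current = 100),
                               list(oxidation_current = 2,
                                    background_current = 100))
  expect_equal(idn$conc, ct$conc)
  expect_equal(idn$sensitivity_factor, 1)
  # halving the background at fixed oxidation current doubles the factor
  half <- sensitivity_normalize(ct, list(oxidation_current = 2,
                                         background_current = 50),
                                list(oxidation_current = 2,
                                     background_current = 100))
  expect_equal(half$sensitivity_factor, 2)
  expect_equal(half$conc[, "dopamine"], c(5, 10, 15))
  # an electrode at 0.8x calibration sensitivity is corrected to truth
  raw <- new_chem_trace(1:3, cbind(dopamine = 0.8 * c(10, 20, 30)),
                        rep(0, 3))
  fixed <- sensitivity_normalize(raw, list(oxidation_current = 1.6,
                                           background_current = 100),
                                 list(oxidation_current = 2,
                                      background_current = 100))
  expect_equal(fixed$conc[, "dopamine"], c(10, 20, 30), tolerance = 1e-10)
  expect_error(
    sensitivity_normalize(ct, list(oxidation_current = 1,
                                   background_current = 0),
                          list(oxidation_current = 2,
                               background_current = 100)),
    class = "validation_error")
})

test_that("per-trial extraction analyzes epochs and flags the rest", {
  cs <- clean_session()
  std <- make_standards(tpl10k, n_per = 8, noise_sd = 0)
  m <- fit_pcr(std$standards, std$concentrations, k = 4)
  chem <- analyze_fscv_trials(cs$sim$colorplot, m, cs$trials$t_value,
                              n_ref_frames = 1)
  analyzed <- chem$reason != "not-analyzed"
  expect_true(any(analyzed) && any(!analyzed))
  # noiseless: recovered dopamine equals the (re-referenced) ground truth
  ok <- which(chem$valid)
  truth <- cs$sim$truth$da_nM[ok] - cs$sim$truth$da_nM[chem$ref_frame[ok]]
  expect_equal(unname(chem$conc[ok, "dopamine"]), truth, tolerance = 1e-6)
})
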