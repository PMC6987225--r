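make_titration <- function(n = 20, noise_sd = 0, seed = 1,
                           params = energy_params()) {
  seqs <- design_constructs(n = n, seed = seed)
  tab <- synthetic_titration(seqs, params,
                             ionic_strength_M = rep(c(0.06, 0.16, 0.36),
                                                    length.out = n),
                             noise_sd = noise_sd, seed = seed + 1000L)
  list(table = tab, sequences = seqs)
}

test_that("noise-free titrations return the generating parameters", {
  truth <- energy_params()
  dat <- make_titration(n = 20, noise_sd = 0, seed = 3, params = truth)
  fit <- fit_binding_params(dat$table, dat$sequences, seed = 5)
  expect_equal(unname(coef(fit)),
               c(truth$dG_consensus_core, truth$dG_degenerate_AT,
                 truth$dG_cp, truth$dG_elec0),
               tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  # refitting from the optimum reproduces it
  fit2 <- fit_binding_params(dat$table, dat$sequences, seed = 5,
                             init = fit$params, n_starts = 1)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-8)
})

test_that("the pwm variant frees only the electrostatic constant", {
  probs <- matrix(0.1, 6, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  cons <- c("T", "A", "A", "T", "T", "A")
  for (k in 1:6) probs[k, cons[k]] <- 0.7
  pwm <- pwm_matrix(probs)
  dat <- make_titration(n = 12, noise_sd = 0, seed = 4)
  fit <- fit_binding_params(dat$table, dat$sequences, variant = "pwm",
                            pwm = pwm, seed = 2)
  expect_identical(names(coef(fit)), "dG_elec0")
  expect_identical(fit$dof, 11L)
})

test_that("under-determined systems and missing sequences are rejected", {
  dat <- make_titration(n = 20, seed = 6)
  expect_error(fit_binding_params(dat$table[1:3, ], dat$sequences),
               "under-determined")
  expect_error(fit_binding_params(dat$table, dat$sequences[-1]),
               "no sequence")
  bad <- dat$table; bad$kd_M[1] <- -1
  expect_error(fit_binding_params(bad, dat$sequences), "> 0")
})

test_that("optimizer deviance traces are non-increasing", {
  dat <- make_titration(n = 15, noise_sd = 0.05, seed = 7)
  fit <- fit_binding_params(dat$table, dat$sequences, seed = 8,
                            n_starts = 3)
  for (tr in fit$rss_trace) expect_true(all(diff(tr) <= 1e-8 * tr[-1]))
})

test_that("predict() reproduces the forward model at the optimum", {
  truth <- energy_params()
  dat <- make_titration(n = 12, noise_sd = 0, seed = 9, params = truth)
  fit <- fit_binding_params(dat$table, dat$sequences, seed = 10)
  pred <- predict(fit, dat$sequences[1:3],
                  ionic_strength_M = dat$table$ionic_strength_M[1:3],
                  log10 = TRUE)
  expect_equal(unname(pred), log10(dat$table$kd_M[1:3]), tolerance = 1e-5)
})

test_that("variance-ratio comparison behaves like an F test", {
  dat <- make_titration(n = 15, noise_sd = 0.05, seed = 11)
  fit <- fit_binding_params(dat$table, dat$sequences, seed = 12,
                            n_starts = 2)
  same <- model_ftest(fit, fit)
  expect_equal(same$F, 1)
  expect_equal(same$p_value, 0.5)
  # a fit with 50-fold larger residual variance is overwhelmingly worse
  worse <- fit
  worse$rss <- fit$rss * 50
  comp <- model_ftest(worse, fit)
  expect_gt(comp$F, 49)
  expect_lt(comp$p_value, 0.05)
  # direction: the simpler model fitting better gives F < 1, p > 0.5
  better <- fit; better$rss <- fit$rss / 2
  expect_gt(model_ftest(better, fit)$p_value, 0.5)
  other <- fit; other$data <- fit$data[c(2, 1, 3:15), ]
  expect_error(model_ftest(other, fit), "identical record sets")
})

test_that("weighted averaging pools replicates by inverse variance", {
  one <- weighted_mean_kd(-8.1, 0.2)
  expect_equal(one$mean, -8.1)
  expect_equal(one$uncertainty, 0.2)
  eq <- weighted_mean_kd(c(-8.0, -8.4), c(0.2, 0.2))
  expect_equal(eq$mean, -8.2)
  uneq <- weighted_mean_kd(c(-8.0, -9.0), c(0.1, 0.3))
  expect_equal(uneq$mean, -8.1, tolerance = 1e-9)
  # permutation invariance and equal-weight reduction to the mean
  x <- c(-7.8, -8.3, -8.9); u <- c(0.15, 0.4, 0.25)
  expect_equal(weighted_mean_kd(x, u)$mean,
               weighted_mean_kd(rev(x), rev(u))$mean)
  expect_equal(weighted_mean_kd(x, rep(0.3, 3))$mean, mean(x))
  expect_error(weighted_mean_kd(numeric(0), numeric(0)), "no estimates")
  expect_error(weighted_mean_kd(c(-8, -8), c(0.1, 0)), "> 0")
})
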