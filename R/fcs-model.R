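#' FCS autocorrelation model parameters
#'
#' Parameters of the fluorescence-correlation autocorrelation model
#' used for binding titrations: a two-component 3D diffusion term
#' (free labeled protein and protein-DNA complex), a triplet-state
#' blinking term and a free-dye term, multiplied together.
#'
#' @param n_mean Mean number of labeled molecules in the confocal
#'   volume.
#' @param tau_prot,tau_comp Diffusion times of free protein and
#'   complex, s (`tau_prot <= tau_comp`: the complex diffuses slower).
#' @param aspect Confocal aspect ratio `omega_xy / omega_z`.
#' @param brightness Dye brightness (a.u.).
#' @param p_prot Fraction of protein in free form (see
#'   [bound_fraction()]).
#' @param triplet Triplet fraction T in `[0, 1)`.
#' @param tau_triplet Triplet relaxation time, s.
#' @param free_dye Fraction of dye not attached to protein, in
#'   `[0, 1)`.
#' @param tau_free_dye Free-dye relaxation time, s.
#' @return Object of class `fcs_params`.
#' @export
fcs_params <- function(n_mean = 1, tau_prot = 1.28e-4, tau_comp = 1e-3,
                       aspect = 0.2, brightness = 1, p_prot = 1,
                       triplet = 0, tau_triplet = 5e-6,
                       free_dye = 0, tau_free_dye = 2e-5) {
  stopifnot(n_mean > 0, tau_prot > 0, tau_comp > 0, aspect > 0,
            brightness > 0, p_prot >= 0, p_prot <= 1,
            tau_triplet > 0, tau_free_dye > 0)
  if (tau_prot > tau_comp)
    stop("the complex must diffuse at least as slowly as the free protein")
  if (triplet < 0 || triplet >= 1 || free_dye < 0 || free_dye >= 1)
    stop("triplet and free-dye fractions must lie in [0, 1)")
  structure(list(n_mean = n_mean, tau_prot = tau_prot, tau_comp = tau_comp,
                 aspect = aspect, brightness = brightness, p_prot = p_prot,
                 triplet = triplet, tau_triplet = tau_triplet,
                 free_dye = free_dye, tau_free_dye = tau_free_dye),
            class = "fcs_params")
}

#' Free-protein fraction of a two-state binding isotherm
#'
#' With a simple two-state model (each labeled protein molecule free
#' or bound to DNA, DNA in excess), the free fraction at a DNA
#' concentration `[DNA]` is `1 / (1 + [DNA]/K_D)`; half the protein is
#' bound at `[DNA] = K_D`.
#'
#' @param dna_conc DNA concentration(s), mol/L.
#' @param kd Dissociation constant, mol/L.
#' @return Free fraction in `[0, 1]`.
#' @export
bound_fraction <- function(dna_conc, kd) {
  if (kd <= 0) stop("K_D must be > 0")
  if (any(dna_conc < 0)) stop("DNA concentration must be >= 0")
  1 / (1 + dna_conc / kd)
}

#' Diffusion time across the confocal waist
#'
#' `tau_D = omega_xy^2 / (4 D)`: the mean dwell time of a molecule
#' with diffusion coefficient `D` in a Gaussian spot of lateral waist
#' `omega_xy`.
#'
#' @param D Diffusion coefficient, um^2/s.
#' @param omega_xy Lateral beam waist, um.
#' @return Diffusion time, s.
#' @export
diffusion_time <- function(D, omega_xy) {
  stopifnot(D > 0, omega_xy > 0)
  omega_xy^2 / (4 * D)
}

#' FCS autocorrelation curve
#'
#' `G(t) = G_F(t) * G_T(t) * G_D(t)` with a two-component 3D-diffusion
#' term
#' `G_D = (1/<N>) [ g(t; tau_prot) (eps*P)^2 + g(t; tau_comp) (eps*(1-P))^2 ]`,
#' `g(t; tau) = (1 + t/tau)^-1 (1 + aspect^2 t/tau)^-1/2`, a triplet
#' factor `G_T = 1 + (T/(1-T)) exp(-t/tau_T)` and a free-dye factor
#' `G_F = 1 + (Fr/(1-Fr)) exp(-t/tau_F)`. The default normalization
#' keeps the squared-brightness numerator with the plain `1/<N>`
#' prefactor; `normalization = "textbook"` switches to the standard
#' composition-weighted form
#' `sum(eps_i^2 f_i g_i) / (<N> (sum eps_i f_i)^2)`.
#'
#' @param t Lag times, s.
#' @param params An [fcs_params()].
#' @param normalization `"printed"` (default) or `"textbook"`.
#' @return `G(t)` values.
#' @export
fcs_curve <- function(t, params, normalization = c("printed", "textbook")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(params, "fcs_params"))
  g3d <- function(tau) (1 + t / tau)^-1 * (1 + params$aspect^2 * t / tau)^-0.5
  eps <- params$brightness
  P <- params$p_prot
  gd_raw <- g3d(params$tau_prot) * (eps * P)^2 +
    g3d(params$tau_comp) * (eps * (1 - P))^2
  GD <- if (normalization == "printed") gd_raw / params$n_mean
  else gd_raw / (params$n_mean * (eps * P + eps * (1 - P))^2)
  GT <- 1 + (params$triplet / (1 - params$triplet)) *
    exp(-t / params$tau_triplet)
  GF <- 1 + (params$free_dye / (1 - params$free_dye)) *
    exp(-t / params$tau_free_dye)
  GF * GT * GD
}

#' A simulated or measured FCS decay
#'
#' @param t Strictly increasing lag-time grid, s.
#' @param G Autocorrelation values.
#' @param dna_conc DNA concentration of the titration point, mol/L.
#' @param replicate Replicate identifier.
#' @return Object of class `fcs_decay`.
#' @export
fcs_decay <- function(t, G, dna_conc, replicate = "r1") {
  if (any(diff(t) <= 0)) stop("lag times must be strictly increasing")
  if (any(!is.finite(G))) stop("G values must be finite")
  structure(list(t = t, G = G, dna_conc = dna_conc, replicate = replicate),
            class = "fcs_decay")
}

#' @export
print.fcs_decay <- function(x, ...) {
  cat(sprintf("FCS decay (%s): %d lags %.3g-%.3g s, [DNA] = %.3g M, G(0+) = %.4g\n",
              x$replicate, length(x$t), min(x$t), max(x$t), x$dna_conc,
              x$G[1]))
  invisible(x)
}

#' Simulate a noisy FCS decay
#'
#' Model curve multiplied by i.i.d. relative Gaussian noise
#' `(1 + eps_t)`, `eps_t ~ N(0, noise_sd)`; seeded and reproducible.
#'
#' @param params An [fcs_params()].
#' @param t Lag-time grid (default 64 log-spaced lags, 1e-6 to 1 s).
#' @param noise_sd Relative noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @param dna_conc,replicate Metadata stored on the decay.
#' @return An [fcs_decay()].
#' @export
simulate_decay <- function(params, t = lag_grid(), noise_sd = 0,
                           seed = 1L, dna_conc = 0, replicate = "sim") {
  stopifnot(noise_sd >= 0)
  G <- fcs_curve(t, params)
  if (noise_sd > 0)
    G <- with_seed(seed, G * (1 + stats::rnorm(length(t), 0, noise_sd)))
  fcs_decay(t, G, dna_conc, replicate)
}

#' Logarithmic lag-time grid
#'
#' @param from,to Grid limits, s.
#' @param n Number of lags.
#' @return Numeric vector of log-spaced lag times.
#' @export
lag_grid <- function(from = 1e-6, to = 1, n = 64L) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Read / write two-column FCS decay files
#'
#' Whitespace-delimited `lag_s G` rows with `#` metadata headers
#' carrying `dna_conc_M` and `replicate`.
#'
#' @param path File path.
#' @return [read_decay()]: an [fcs_decay()].
#' @export
read_decay <- function(path) {
  lines <- readLines(path)
  meta <- lines[grepl("^#", lines)]
  get_meta <- function(key, default) {
    hit <- grep(paste0(key, "\\s*="), meta, value = TRUE)
    if (length(hit) == 0L) return(default)
    sub(paste0(".*", key, "\\s*=\\s*(\\S+).*"), "\\1", hit[1])
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines) & nzchar(lines)])
  fcs_decay(dat[[1]], dat[[2]],
            dna_conc = as.numeric(get_meta("dna_conc_M", "0")),
            replicate = get_meta("replicate", "r1"))
}

#' @rdname read_decay
#' @param decay An [fcs_decay()].
#' @export
write_decay <- function(decay, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dna_conc_M = %.8g", decay$dna_conc),
               sprintf("# replicate = %s", decay$replicate)), con)
  utils::write.table(data.frame(decay$t, decay$G), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Global fit of an FCS titration series
#'
#' Fits a set of autocorrelation decays measured at different DNA
#' concentrations to the FCS model with one shared `log10 K_D` linking
#' every decay through the two-state isotherm ([bound_fraction()]),
#' and one local mean molecule number `<N>` per decay. Diffusion
#' times, aspect ratio, brightness and the triplet/free-dye terms are
#' fixed globally. The fit is ordinary least squares on `G`, in
#' `log10 K_D` to sample the constant linearly; lags below `t_min` are
#' excluded (after-pulsing guard). The 95% interval is two standard
#' deviations from the covariance at the optimum.
#'
#' @param decays List of [fcs_decay()] objects at >= 3 concentrations.
#' @param tau_prot,tau_comp,aspect,brightness,triplet,tau_triplet,free_dye,tau_free_dye
#'   Fixed model constants (see [fcs_params()]).
#' @param t_min Smallest lag retained in the fit, s.
#' @param init_log10_kd Optional starting value; defaults to the log10
#'   median concentration.
#' @return Object of class `fcs_fit` with methods `coef`, `vcov`,
#'   `summary`, `predict`, `residuals`, `print`. `coef` returns
#'   `log10_kd` and the per-decay `<N>` values.
#' @export
fit_fcs_titration <- function(decays, tau_prot = 1.28e-4, tau_comp = 1e-3,
                              aspect = 0.2, brightness = 1, triplet = 0,
                              tau_triplet = 5e-6, free_dye = 0,
                              tau_free_dye = 2e-5, t_min = 1e-6,
                              init_log10_kd = NULL) {
  lapply(decays, function(d) stopifnot(inherits(d, "fcs_decay")))
  conc <- vapply(decays, `[[`, 0, "dna_conc")
  if (length(decays) < 3L || length(unique(conc)) < 3L)
    stop("need decays at >= 3 distinct DNA concentrations")
  kd0 <- init_log10_kd %||% log10(stats::median(conc[conc > 0]))
  keep <- lapply(decays, function(d) d$t >= t_min)
  base_par <- function(p_prot, n_mean)
    fcs_params(n_mean = n_mean, tau_prot = tau_prot, tau_comp = tau_comp,
               aspect = aspect, brightness = brightness, p_prot = p_prot,
               triplet = triplet, tau_triplet = tau_triplet,
               free_dye = free_dye, tau_free_dye = tau_free_dye)
  resid_fun <- function(theta) {
    kd <- 10^theta[1]
    unlist(lapply(seq_along(decays), function(i) {
      d <- decays[[i]]
      P <- bound_fraction(d$dna_conc, kd)
      Gm <- fcs_curve(d$t[keep[[i]]], base_par(P, exp(theta[1 + i])))
      Gm - d$G[keep[[i]]]
    }))
  }
  # local <N> starts from the raw G(0+) amplitude of each decay
  n0 <- vapply(decays, function(d) max(1e-3, 1 / max(d$G[1], 1e-6)), 0)
  theta0 <- c(kd0, log(n0))
  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 300))
  kd_hat <- 10^fit$par[1]
  pos <- conc[conc > 0]
  if (length(pos) && (kd_hat < min(pos) / 2 || kd_hat > 2 * max(pos)))
    warning("fitted K_D lies outside the titrated concentration range; ",
            "the titration does not span the isotherm and the estimate ",
            "is ill-conditioned")
  if (!fit$info %in% 1:4)
    stop("FCS global fit did not converge (best log10 K_D so far ",
         sprintf("%.3f", fit$par[1]), "): ", fit$message)
  nres <- length(resid_fun(fit$par))
  dof <- nres - length(fit$par)
  sigma2 <- fit$deviance / dof
  covm <- tryCatch(sigma2 * solve(fit$hessian),
                   error = function(e) matrix(NA_real_, length(fit$par),
                                              length(fit$par)))
  se_log10 <- sqrt(covm[1, 1])
  coefs <- c(log10_kd = fit$par[1],
             stats::setNames(exp(fit$par[-1]),
                             paste0("n_mean_", seq_along(decays))))
  structure(list(coefficients = coefs, log10_kd = fit$par[1],
                 kd = 10^fit$par[1], se_log10_kd = se_log10,
                 ci95_log10_kd = fit$par[1] + c(-2, 2) * se_log10,
                 vcov = covm, deviance = fit$deviance, dof = dof,
                 decays = decays, t_min = t_min,
                 fixed = list(tau_prot = tau_prot, tau_comp = tau_comp,
                              aspect = aspect, brightness = brightness,
                              triplet = triplet, tau_triplet = tau_triplet,
                              free_dye = free_dye,
                              tau_free_dye = tau_free_dye),
                 converged = TRUE),
            class = "fcs_fit")
}

#' @export
coef.fcs_fit <- function(object, ...) object$coefficients

#' @export
vcov.fcs_fit <- function(object, ...) object$vcov

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("FCS titration fit: %d decays, log10 K_D = %.3f +/- %.3f (1 sd)\n",
              length(x$decays), x$log10_kd, x$se_log10_kd))
  cat(sprintf("  K_D = %.4g M, 95%% interval [%.4g, %.4g] M\n", x$kd,
              10^x$ci95_log10_kd[1], 10^x$ci95_log10_kd[2]))
  invisible(x)
}

#' @export
summary.fcs_fit <- function(object, ...) {
  cat("Global FCS titration fit\n")
  print(object)
  cat(sprintf("  residual deviance %.4g on %d dof\n", object$deviance,
              object$dof))
  conc <- vapply(object$decays, `[[`, 0, "dna_conc")
  cat("  bound fractions at fitted K_D:",
      paste(sprintf("%.3f", 1 - bound_fraction(conc, object$kd)),
            collapse = ", "), "\n")
  invisible(object)
}

#' Model curves from a fitted FCS titration
#'
#' @param object An `fcs_fit`.
#' @param which Decay indices (default all).
#' @param ... Unused.
#' @return List of model `G(t)` vectors on each decay's full lag grid.
#' @export
predict.fcs_fit <- function(object, which = seq_along(object$decays), ...) {
  lapply(which, function(i) {
    d <- object$decays[[i]]
    P <- bound_fraction(d$dna_conc, object$kd)
    f <- object$fixed
    fcs_curve(d$t, fcs_params(
      n_mean = unname(object$coefficients[1 + i]), tau_prot = f$tau_prot,
      tau_comp = f$tau_comp, aspect = f$aspect, brightness = f$brightness,
      p_prot = P, triplet = f$triplet, tau_triplet = f$tau_triplet,
      free_dye = f$free_dye, tau_free_dye = f$tau_free_dye))
  })
}

#' @export
residuals.fcs_fit <- function(object, ...) {
  pred <- predict(object)
  lapply(seq_along(object$decays), function(i)
    object$decays[[i]]$G - pred[[i]])
}
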