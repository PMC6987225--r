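#' Globally fit site-energy parameters to K_D titration data
#'
#' Least-squares fit, in log10 K_D space, of the energy model to a
#' table of measured global dissociation constants for a set of DNA
#' constructs at known ionic strengths. The `"structure"` variant frees
#' the four energetic constants (`dG_consensus_core`,
#' `dG_degenerate_AT`, `dG_cp`, `dG_elec0`); the `"pwm"` variant frees
#' `dG_elec0` only, the specific part being pinned by the PWM. Because
#' every site energy is linear in these constants given the
#' interaction counts, the per-construct count matrices are computed
#' once and each objective evaluation is a cheap matrix product.
#'
#' Optimization uses bounded Levenberg-Marquardt least squares
#' (`minpack.lm::nls.lm`) with seeded random multi-start restarts;
#' bounds are +/-50 kJ/mol on every energy. When the table carries
#' per-record uncertainties (`sigma_log10`) the residuals are
#' inverse-variance weighted; otherwise the fit is unweighted.
#'
#' @param data `data.frame` with columns `construct_id`, `fasta_id`,
#'   `ionic_strength_M`, `kd_M` and optionally `sigma_log10`
#'   (the titration-table TSV schema).
#' @param sequences Named character vector supplying the sequence of
#'   every `fasta_id`.
#' @param variant `"structure"` or `"pwm"`.
#' @param pwm A [pwm_matrix()] (pwm variant only).
#' @param init [energy_params()] used as template and starting point.
#' @param n_starts Number of optimizer starts (1 from `init`, the rest
#'   random within the bounds).
#' @param seed Integer seed for the random restarts.
#' @param bound Half-width of the box constraint on each energy, kJ/mol.
#' @return Object of class `binding_fit` with methods [coef()],
#'   [vcov()], `summary()`, `predict()`, `residuals()`, `print()`.
#' @export
fit_binding_params <- function(data, sequences,
                               variant = c("structure", "pwm"), pwm = NULL,
                               init = energy_params(), n_starts = 10L,
                               seed = 1L, bound = 50) {
  variant <- match.arg(variant)
  req <- c("construct_id", "fasta_id", "ionic_strength_M", "kd_M")
  if (!all(req %in% names(data)))
    stop("titration table must have columns ", paste(req, collapse = ", "))
  if (any(data$kd_M <= 0)) stop("measured K_D must be > 0")
  free <- if (variant == "structure")
    c("dG_consensus_core", "dG_degenerate_AT", "dG_cp", "dG_elec0")
  else "dG_elec0"
  n_free <- length(free)
  if (nrow(data) <= n_free)
    stop("under-determined: ", nrow(data), " records for ", n_free,
         " free parameters")
  missing_seq <- setdiff(data$fasta_id, names(sequences))
  if (length(missing_seq))
    stop("no sequence for construct(s): ", paste(missing_seq, collapse = ", "))
  rt <- rt_kj(init)
  sigma <- if ("sigma_log10" %in% names(data) &&
               all(is.finite(data$sigma_log10)) && all(data$sigma_log10 > 0))
    data$sigma_log10 else rep(1, nrow(data))

  # precomputed design: one block of site rows per record
  blocks <- lapply(seq_len(nrow(data)), function(i) {
    seq <- sequences[[data$fasta_id[i]]]
    st <- site_table(toupper(seq), init$end_margin)
    n_elec <- ifelse(st$central, init$n_elec_central,
                     init$n_elec_central - 1L)
    screen <- exp(-sqrt(data$ionic_strength_M[i]))
    if (variant == "structure") {
      f <- site_feature_matrix(st$hexamer, init)
      list(X = cbind(f, elec = n_elec * screen))
    } else {
      list(spec = pwm_energy(st$hexamer, pwm, init),
           elec = n_elec * screen)
    }
  })
  obs <- log10(data$kd_M)
  pred_fun <- function(theta) {
    vapply(blocks, function(b) {
      dG <- if (variant == "structure") drop(b$X %*% theta)
      else b$spec + b$elec * theta
      -log10(init$w0 * sum(exp(-dG / rt)))
    }, 0)
  }
  resid_fun <- function(theta) (pred_fun(theta) - obs) / sigma

  theta0 <- unlist(init[free])
  set.seed(seed)
  starts <- rbind(theta0,
                  matrix(stats::runif((n_starts - 1L) * n_free, -20, 5),
                         ncol = n_free))
  best <- NULL
  traces <- list()
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], fn = resid_fun,
                         lower = rep(-bound, n_free),
                         upper = rep(bound, n_free),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    traces[[length(traces) + 1L]] <- fit$rsstrace
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("optimizer failed to converge from every start")
  theta <- stats::setNames(best$par, free)
  dof <- nrow(data) - n_free
  dev <- best$deviance
  sigma2 <- dev / dof
  covm <- tryCatch(sigma2 * solve(best$hessian), error = function(e) {
    warning("singular information matrix; standard errors unavailable")
    matrix(NA_real_, n_free, n_free)
  })
  dimnames(covm) <- list(free, free)
  fitted_log10 <- pred_fun(theta)
  params_hat <- init
  params_hat[free] <- as.list(theta)
  structure(list(variant = variant, coefficients = theta,
                 se = sqrt(pmax(diag(covm), 0)), vcov = covm,
                 rss = sum((fitted_log10 - obs)^2), weighted_rss = dev,
                 dof = dof, n = nrow(data),
                 fitted = fitted_log10, observed = obs, sigma = sigma,
                 data = data, params = params_hat, pwm = pwm,
                 rss_trace = traces, converged = best$info %in% 1:4),
            class = "binding_fit")
}

#' @export
coef.binding_fit <- function(object, ...) object$coefficients

#' @export
vcov.binding_fit <- function(object, ...) object$vcov

#' @export
residuals.binding_fit <- function(object, ...) object$fitted - object$observed

#' @export
fitted.binding_fit <- function(object, ...) object$fitted

#' Predict global dissociation constants from a fitted energy model
#'
#' @param object A `binding_fit`.
#' @param sequences Named character vector of sequences to score.
#' @param ionic_strength_M Ionic strength(s), recycled over sequences.
#' @param log10 Return log10(K_D) instead of K_D in mol/L.
#' @param ... Unused.
#' @export
predict.binding_fit <- function(object, sequences,
                                ionic_strength_M = object$params$ionic_strength,
                                log10 = FALSE, ...) {
  I <- rep_len(ionic_strength_M, length(sequences))
  out <- vapply(seq_along(sequences), function(i) {
    p <- object$params
    p$ionic_strength <- I[i]
    binding_landscape(sequences[[i]], p, variant = object$variant,
                      pwm = object$pwm)$kd
  }, 0)
  names(out) <- names(sequences)
  if (log10) base::log10(out) else out
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Global energy-model fit (", x$variant, " variant), ", x$n,
      " constructs\n", sep = "")
  for (i in seq_along(x$coefficients))
    cat(sprintf("  %-18s %+8.3f +/- %.3f kJ/mol\n",
                names(x$coefficients)[i], x$coefficients[i], x$se[i]))
  cat(sprintf("  RSS(log10 K_D) = %.4g on %d dof\n", x$rss, x$dof))
  invisible(x)
}

#' @export
summary.binding_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  structure(list(variant = object$variant, coefficients = tab,
                 rss = object$rss, weighted_rss = object$weighted_rss,
                 dof = object$dof, n = object$n,
                 converged = object$converged),
            class = "summary.binding_fit")
}

#' @export
print.summary.binding_fit <- function(x, ...) {
  cat("Energy-model fit,", x$variant, "variant:", x$n, "records,",
      x$dof, "dof\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("RSS (log10 K_D) = %.5g; converged: %s\n", x$rss,
              x$converged))
  invisible(x)
}

#' Variance-ratio (F) comparison of two model fits
#'
#' Compares the residual variance of a statistically simpler fit
#' against a more complex one on the same records:
#' `F = (RSS_A/dof_A) / (RSS_B/dof_B)` with A the simpler model, and
#' the p-value is the upper tail of `F(dof_A, dof_B)`. The two
#' variants are not nested, so this is a heuristic variance-ratio
#' test, not a partial F-test.
#'
#' @param fit_simple,fit_complex `binding_fit` objects fitted to
#'   identical record sets.
#' @return List with `F`, `p_value`, `dof`.
#' @export
model_ftest <- function(fit_simple, fit_complex) {
  stopifnot(inherits(fit_simple, "binding_fit"),
            inherits(fit_complex, "binding_fit"))
  if (!identical(fit_simple$data$construct_id,
                 fit_complex$data$construct_id))
    stop("fits must be on identical record sets")
  Fstat <- (fit_simple$rss / fit_simple$dof) /
    (fit_complex$rss / fit_complex$dof)
  p <- stats::pf(Fstat, fit_simple$dof, fit_complex$dof, lower.tail = FALSE)
  list(F = Fstat, p_value = p, dof = c(fit_simple$dof, fit_complex$dof))
}

#' Inverse-variance weighted mean of replicate log10 K_D estimates
#'
#' Combines replicate estimates with weights proportional to the
#' inverse squared uncertainty, normalized to sum to one; the combined
#' uncertainty is `sqrt(1 / sum(1/sigma_i^2))`, in the same units as
#' the inputs (95% half-widths in, 95% half-width out).
#'
#' @param log10_kd Numeric vector of replicate log10 K_D estimates.
#' @param uncertainty Positive uncertainties, one per estimate.
#' @return List with `mean`, `uncertainty`, `weights`.
#' @export
weighted_mean_kd <- function(log10_kd, uncertainty) {
  if (length(log10_kd) == 0L) stop("no estimates to combine")
  if (length(uncertainty) != length(log10_kd))
    stop("estimates and uncertainties differ in length")
  if (any(uncertainty <= 0)) stop("uncertainties must be > 0")
  w <- 1 / uncertainty^2
  w <- w / sum(w)
  list(mean = sum(w * log10_kd),
       uncertainty = sqrt(1 / sum(1 / uncertainty^2)),
       weights = w)
}
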