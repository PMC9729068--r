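#' Log-likelihood of per-locus pairwise difference counts
#'
#' Loci are independent, so the log-likelihood is the sum over loci of the
#' log marginal probability of the observed difference count,
#' `sum_l log f(x_l | theta)`. Counts are aggregated to unique `(x, n)`
#' pairs before evaluation, and everything is computed in log space, so the
#' function is safe for sites-per-locus up to the tens of thousands. A locus
#' with zero probability under the model yields `-Inf` (flagged via the
#' `"support_violation"` attribute) rather than an error.
#'
#' @param params An [mscm_params()] or [msci_params()] object.
#' @param data A data frame with columns `x` and `n` (one row per locus),
#'   e.g. from [simulate_locus_counts()].
#' @param mutation_model `"binomial_jc"` or `"poisson"`.
#' @return The log-likelihood (scalar).
#' @examples
#' p <- msci_params(0.004, 0.002, 0.01, 0.002, phi = 0.2)
#' counts <- simulate_locus_counts(p, L = 200, n = 500, seed = 1)
#' coal_loglik(p, counts)
#' @export
coal_loglik <- function(params, data,
                        mutation_model = c("binomial_jc", "poisson")) {
  mutation_model <- match.arg(mutation_model)
  if (!all(c("x", "n") %in% names(data)) || !nrow(data)) {
    abort("`data` needs non-empty columns `x` and `n`.")
  }
  density <- if (inherits(params, "coal_density")) params else coal_density(params)
  agg <- dplyr::count(as_tibble(data[c("x", "n")]), .data$x, .data$n,
                      name = "w")
  ll <- 0
  violated <- FALSE
  for (nn in unique(agg$n)) {
    sub <- agg[agg$n == nn, ]
    lp <- marginal_log_pmf(sub$x, nn, density, mutation_model)
    if (any(!is.finite(lp))) violated <- TRUE
    ll <- ll + sum(sub$w * lp)
  }
  structure(ll, support_violation = violated)
}

#' Maximum-likelihood fit of a two-species model to difference counts
#'
#' Maximises [coal_loglik()] under the parameter constraints of a fitting
#' method (see [fit_method_spec()]), for the introgression model or any of
#' the migration models. Optimisation runs on transformed parameters (log
#' times and population sizes, logit introgression probability, an
#' order-preserving map for `tauS < tauR`) with multiple restarts; standard
#' errors come from the observed information (central-difference Hessian on
#' the transformed scale, delta-method back-transform).
#'
#' As the number of loci grows, estimates under a misspecified introgression
#' model converge to the pseudo-true values computed by [minimize_kl()] at
#' the matching number of sites.
#'
#' @param data Data frame of per-locus counts with columns `x`, `n`.
#' @param model `"msci"` to fit the introgression model (the misspecification
#'   study's fitting model), or `"im"`/`"iim"`/`"sc"` to fit a migration
#'   model.
#' @param spec For `model = "msci"`: a [fit_method_spec()] or method letter;
#'   the fixed true values are taken from `gen` when supplied, otherwise all
#'   five identifiable parameters are free (method `d`).
#' @param gen Optional generating parameters used to build `spec` from a
#'   method letter and to seed the truth-informed start.
#' @param mutation_model Passed to [coal_loglik()].
#' @param restarts Number of optimisation restarts.
#' @param init Optional named list of starting values.
#' @return An object of class `ml_fit` with estimates, standard errors,
#'   log-likelihood and convergence diagnostics. See [tidy.ml_fit()].
#' @examples
#' \donttest{
#' truth <- msci_params(0.004, 0.002, 0.01, 0.002, phi = 0.2)
#' counts <- simulate_locus_counts(truth, L = 1000, n = 1000, seed = 1)
#' fit <- fit_ml(counts, "msci", spec = "b", gen = truth, restarts = 2)
#' tidy(fit)
#' }
#' @export
fit_ml <- function(data, model = c("msci", "im", "iim", "sc"), spec = "d",
                   gen = NULL,
                   mutation_model = c("binomial_jc", "poisson"),
                   restarts = 5, init = NULL) {
  model <- match.arg(model)
  mutation_model <- match.arg(mutation_model)
  if (!all(c("x", "n") %in% names(data)) || !nrow(data)) {
    abort("`data` needs non-empty columns `x` and `n`.")
  }
  agg <- dplyr::count(as_tibble(data[c("x", "n")]), .data$x, .data$n,
                      name = "w")
  loglik_fast <- function(params) {
    density <- coal_density(params)
    ll <- 0
    for (nn in unique(agg$n)) {
      sub <- agg[agg$n == nn, ]
      lp <- marginal_log_pmf(sub$x, nn, density, mutation_model)
      if (any(!is.finite(lp) & sub$w > 0)) return(-Inf)
      ll <- ll + sum(sub$w * lp)
    }
    ll
  }
  if (model == "msci") {
    if (is.character(spec)) {
      anchor <- if (!is.null(gen)) gen else
        msci_params(0.01, 0.002, 0.01, 0.01, phi = 0.5)
      spec <- fit_method_spec(spec, anchor)
    }
    objective <- function(est) {
      fit <- do.call(msci_params, est)
      if (nrow(validate_params(fit))) return(1e10)
      ll <- loglik_fast(fit)
      if (!is.finite(ll)) 1e10 else -ll
    }
    gen_anchor <- if (!is.null(gen)) gen else
      msci_params(0.01, 0.002, 0.01, 0.01, phi = 0.5)
    out <- run_constrained_fit(
      objective = objective, spec = spec, gen = gen_anchor, n = max(agg$n),
      restarts = restarts, init = init, support_min = 0, smooth = TRUE)
    est_params <- do.call(msci_params, out$estimates)
    ses <- ml_standard_errors(out, objective)
    return(structure(
      list(model = model, estimates = out$estimates,
         std_errors = ses, loglik = -out$value,
         L = sum(agg$w), spec = spec, mutation_model = mutation_model,
         convergence = out$convergence, restarts = out$restarts,
         params = est_params),
      class = "ml_fit"))
  }
  # migration-model fits: free (tauR, [tauT], thetaA, thetaR, M); the
  # density depends on thetaB only through w, so thetaB is held at 1 and M
  # absorbs the scale (w = 4 M)
  free <- c("tauR", if (model != "im") "tauT", "thetaA", "thetaR", "w")
  mk <- function(u) {
    v <- exp(u)
    tauR <- v[1]
    tauT <- if (model != "im") tauR * plogis(u[2]) else 0
    off <- if (model != "im") 1 else 0
    mscm_params(model, tauR = tauR, tauT = tauT,
                thetaA = v[2 + off], thetaB = 1, thetaR = v[3 + off],
                M = v[4 + off] / 4)
  }
  objective <- function(u) {
    p <- tryCatch(mk(u), error = function(e) NULL)
    if (is.null(p) || nrow(validate_params(p))) return(1e10)
    ll <- loglik_fast(p)
    if (!is.finite(ll)) 1e10 else -ll
  }
  # moment-informed start: invert the JC mismatch fraction for a mean
  # coalescent time, and ladder the scaled migration rate across restarts
  p_hat <- min(max(sum(agg$w * agg$x / agg$n) / sum(agg$w), 1e-5), 0.74)
  t_hat <- -3 / 8 * log1p(-4 * p_hat / 3)
  tau0 <- min(max(t_hat / 2, 2e-4), 0.02)
  u0 <- c(log(tau0), if (model != "im") 0, log(0.002), log(t_hat),
          log(1))
  w_ladder <- c(1, 20, 200, 1000)
  best <- NULL
  for (r in seq_len(restarts)) {
    u_start <- if (r == 1) u0 else u0 + runif(length(u0), -1, 1)
    u_start[length(u_start)] <- log(w_ladder[(r - 1) %% 4 + 1]) +
      runif(1, -0.3, 0.3) * (r > 1)
    ans <- tryCatch(
      suppressWarnings(optim(u_start, objective, method = "Nelder-Mead",
                             control = list(maxit = 2000, reltol = 1e-12))),
      error = function(e) NULL)
    if (!is.null(ans)) {
      polish <- tryCatch(
        optim(ans$par, objective, method = "BFGS",
              control = list(maxit = 300, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(polish) && polish$value < ans$value) ans <- polish
    }
    if (!is.null(ans) && (is.null(best) || ans$value < best$value)) best <- ans
  }
  if (is.null(best)) abort("all restarts failed")
  p <- mk(best$par)
  structure(
    list(model = model,
         estimates = list(tauR = p$tauR, tauT = p$tauT, thetaA = p$thetaA,
                          thetaR = p$thetaR, w = migration_rate_scaled(p)),
         std_errors = NULL, loglik = -best$value, L = sum(agg$w),
         spec = NULL, mutation_model = mutation_model,
         convergence = best$convergence == 0, restarts = NULL, params = p),
    class = "ml_fit")
}

# curvature-based standard errors on the natural scale: numerical Hessian of
# the negative log-likelihood on the transformed scale, inverted, and mapped
# through the delta method
ml_standard_errors <- function(out, objective) {
  par <- out$par
  free_eff <- out$free_eff
  if (!length(par)) return(NULL)
  fn <- function(u) {
    est <- out$to_params(u, out$tauS_override)
    objective(est)
  }
  H <- tryCatch(pracma::hessian(fn, par, h = 1e-4), error = function(e) NULL)
  if (is.null(H)) return(NULL)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) return(NULL)
  se_u <- sqrt(pmax(diag(V), 0))
  est <- out$to_params(par, out$tauS_override)
  se <- setNames(rep(NA_real_, length(free_eff)), free_eff)
  for (i in seq_along(free_eff)) {
    nm <- free_eff[i]
    # derivative of the back-transform at the optimum
    deriv <- switch(nm,
      tauR = est$tauR,
      tauS = {
        frac <- plogis(par[i])
        est$tauR * frac * (1 - frac)  # holding tauR fixed
      },
      thetaR = est$thetaR,
      thetaS = est$thetaS,
      theta = est$thetaR,
      phi = est$phi * (1 - est$phi))
    se[nm] <- se_u[i] * abs(deriv)
  }
  if (!is.null(out$tauS_override)) se["tauS"] <- 0
  se
}

#' @export
print.ml_fit <- function(x, ...) {
  cat(sprintf("<ml_fit: %s, L = %d loci, logLik = %.3f>\n", x$model, x$L,
              x$loglik))
  est <- unlist(x$estimates)
  cat(" ", paste(sprintf("%s = %.6g", names(est), est), collapse = ", "),
      "\n")
  if (!x$convergence) cat("  WARNING: optimisation did not converge\n")
  invisible(x)
}

#' Tidy maximum-likelihood fits
#'
#' @param x An `ml_fit` from [fit_ml()].
#' @param ... Unused.
#' @return `tidy()`: tibble with `term`, `estimate`, `std.error`;
#'   `glance()`: one-row tibble with `logLik`, `L`, `converged`.
#' @export
tidy.ml_fit <- function(x, ...) {
  est <- unlist(x$estimates)
  se <- rep(NA_real_, length(est))
  if (!is.null(x$std_errors)) {
    nm <- names(est)
    nm[nm %in% c("thetaR", "thetaS") & x$model == "msci" &
         isTRUE(x$spec$equal_thetas)] <- "theta"
    se <- unname(x$std_errors[nm])
  }
  tibble(term = names(est), estimate = unname(est), std.error = se)
}

#' @rdname tidy.ml_fit
#' @export
glance.ml_fit <- function(x, ...) {
  tibble(logLik = x$loglik, L = x$L, converged = x$convergence,
         model = x$model)
}

#' Compare maximum-likelihood fits on the same data
#'
#' @param fits A list of `ml_fit` objects fitted to the same dataset.
#' @return A tibble with one row per fit: model, method, log-likelihood,
#'   difference to the best log-likelihood, and the parameter estimates as
#'   list column `estimates`.
#' @export
compare_fits <- function(fits) {
  if (inherits(fits, "ml_fit")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, TRUE, "ml_fit")))
  Ls <- vapply(fits, `[[`, 0, "L")
  if (length(unique(Ls)) > 1L) {
    abort("fits were computed on datasets of different sizes")
  }
  ll <- vapply(fits, `[[`, 0, "loglik")
  base <- tibble(
    model = vapply(fits, `[[`, "", "model"),
    method = vapply(fits, function(f) {
      if (is.null(f$spec)) NA_character_ else f$spec$method
    }, ""),
    logLik = ll,
    delta_logLik = ll - max(ll))
  est <- dplyr::bind_rows(lapply(fits, function(f) as_tibble(f$estimates)))
  dplyr::bind_cols(base, est)
}
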