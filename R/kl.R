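#' Expected proportion of migrant ancestry under continuous migration
#'
#' Under a migration model with rate `M` migrants per generation into a
#' recipient population of size parameter `thetaB`, sustained over a time
#' interval of length `delta_tau` (expected mutations per site), the
#' probability that a lineage sampled from the recipient traces back to the
#' donor is `phi0 = 1 - exp(-4 M delta_tau / thetaB)`. This is the natural
#' introgression-probability analogue of a continuous migration episode and
#' the reference point against which pseudo-true introgression estimates are
#' compared.
#'
#' @param M Migration rate in migrants per generation, `>= 0`.
#' @param delta_tau Duration of gene flow, `>= 0`.
#' @param thetaB Recipient population size parameter, `> 0`.
#' @return The migrant proportion, in `[0, 1)`.
#' @examples
#' phi0(M = 0.1, delta_tau = 0.004, thetaB = 0.01)  # 0.148
#' phi0(M = 0.04, delta_tau = 0.002, thetaB = 0.01) # 0.031
#' @export
phi0 <- function(M, delta_tau, thetaB) {
  check_scalar(M, "M", lower = 0)
  check_scalar(delta_tau, "delta_tau", lower = 0)
  check_scalar(thetaB, "thetaB")
  if (thetaB <= 0) abort("`thetaB` must be > 0.")
  -expm1(-4 * M * delta_tau / thetaB)
}

#' Fitting-method specifications for the misspecified introgression model
#'
#' Five ways of fitting the two-species introgression model to
#' migration-model data, differing in which of the identifiable parameters
#' `(tauR, tauS, thetaR, thetaS, phi)` are estimated:
#'
#' * `a`: estimate `(tauR, phi)`; `tauS` fixed at the time gene flow stopped
#'   (0 for IM and SC, `tauT` for IIM); `thetaR`, `thetaS` fixed at their
#'   true analogues in the generating model.
#' * `b`: as `a` but `tauS` estimated too.
#' * `c`: `tauS = 0` fixed; estimate `(tauR, thetaR, thetaS, phi)`.
#' * `d`: all five estimated.
#' * `e`: estimate four parameters with the constraint `thetaR = thetaS`.
#'
#' The "true analogues" are `thetaR` of the generating model for `thetaR`
#' and `thetaA` (the donor lineage the introgressed segment lives in) for
#' `thetaS`.
#'
#' @param method One of `"a"` to `"e"`.
#' @param gen The generating [mscm_params()] (or [msci_params()] for
#'   self-fits) supplying the fixed true values.
#' @return A `fit_method_spec` object: list with `method`, `free`, `fixed`,
#'   `equal_thetas`.
#' @export
fit_method_spec <- function(method = c("a", "b", "c", "d", "e"), gen) {
  method <- match.arg(method)
  if (inherits(gen, "mscm_params")) {
    truth <- list(tauR = gen$tauR, thetaR = gen$thetaR, thetaS = gen$thetaA,
                  tauS_fix = if (gen$variant == "iim") gen$tauT else 0)
  } else if (inherits(gen, "msci_params")) {
    truth <- list(tauR = gen$tauR, thetaR = gen$thetaR, thetaS = gen$thetaS,
                  tauS_fix = gen$tauS)
  } else {
    abort("`gen` must be an mscm_params or msci_params object.")
  }
  spec <- switch(method,
    a = list(free = c("tauR", "phi"),
             fixed = list(tauS = truth$tauS_fix, thetaR = truth$thetaR,
                          thetaS = truth$thetaS)),
    b = list(free = c("tauR", "tauS", "phi"),
             fixed = list(thetaR = truth$thetaR, thetaS = truth$thetaS)),
    c = list(free = c("tauR", "thetaR", "thetaS", "phi"),
             fixed = list(tauS = 0)),
    d = list(free = c("tauR", "tauS", "thetaR", "thetaS", "phi"),
             fixed = list()),
    e = list(free = c("tauR", "tauS", "theta", "phi"),
             fixed = list()))
  structure(list(method = method, free = spec$free, fixed = spec$fixed,
                 equal_thetas = identical(method, "e")),
            class = "fit_method_spec")
}

#' Kullback-Leibler divergence from a generating to a fitting model
#'
#' Distance from the fitting introgression model to the generating model,
#' computed either on the observable difference counts (finite `n`:
#' `sum_x f_m(x) log(f_m(x) / f_i(x))`, with the sum truncated once the
#' generating mass reaches `1 - 1e-12`) or on the coalescent times
#' themselves (`n = Inf`: the integral of `f_m(t) log(f_m(t) / f_i(t))`).
#' When the fitting model's support excludes part of the generating support
#' (an introgression time above the earliest possible coalescent time, with
#' `n = Inf`), the divergence is `+Inf`; this is detected analytically
#' before any integration.
#'
#' @param gen Generating model parameters ([mscm_params()] or
#'   [msci_params()]).
#' @param fit Fitting [msci_params()].
#' @param n Sites per sequence, a positive integer or `Inf`.
#' @param mutation_model `"binomial_jc"` or `"poisson"` (finite `n` only).
#' @return A non-negative number (possibly `Inf`).
#' @examples
#' gen <- preset_scenario("fig1-im")$params
#' fit <- msci_params(0.002, 0, 0.01, 0.002, phi = 0.14)
#' kl_divergence(gen, fit, n = Inf)
#' @export
kl_divergence <- function(gen, fit, n = Inf,
                          mutation_model = c("binomial_jc", "poisson")) {
  mutation_model <- match.arg(mutation_model)
  stopifnot(inherits(fit, "msci_params"))
  dm <- coal_density(gen)
  di <- coal_density(fit)
  if (is.infinite(n)) {
    if (fit$tauS > dm$support_min + 1e-15) return(Inf)
    return(kl_density_level(dm, di))
  }
  n <- check_count(n, "n")
  xmax_hard <- if (mutation_model == "binomial_jc") n else Inf
  xs <- integer(); lm <- numeric()
  lo <- 0L
  repeat {
    hi <- min(lo + 255L, xmax_hard)
    xi <- lo:hi
    lm <- c(lm, marginal_log_pmf(xi, n, dm, mutation_model))
    xs <- c(xs, xi)
    if (sum(exp(lm)) >= 1 - 1e-12 || hi >= xmax_hard) break
    lo <- hi + 1L
  }
  li <- marginal_log_pmf(xs, n, di, mutation_model)
  pm <- exp(lm)
  contrib <- ifelse(pm == 0, 0, pm * (lm - li))
  if (any(!is.finite(li) & pm > 0)) return(Inf)
  max(sum(contrib), 0)
}

kl_density_level <- function(dm, di) {
  # truncate where the generating tail mass drops below ~1e-18; the
  # integrand is O(f_m * t) there and contributes nothing at 1e-10 tolerance
  t_hi <- max(dm$breaks[is.finite(dm$breaks)]) + 21 * dm$params$thetaR
  brk <- sort(unique(c(dm$breaks, di$breaks, t_hi)))
  brk <- brk[brk >= dm$support_min & brk <= t_hi]
  total <- 0
  for (j in seq_len(length(brk) - 1)) {
    l <- brk[j]; u <- brk[j + 1]
    f <- function(t) {
      fm <- dcoal(t, dm)
      fi <- dcoal(t, di)
      out <- numeric(length(t))
      pos <- fm > 0
      out[pos] <- fm[pos] * (log(fm[pos]) - log(fi[pos]))
      out
    }
    # probe for support violation inside the interval
    mid <- if (is.finite(u)) (l + u) / 2 else l + 1
    if (dcoal(mid, dm) > 0 && dcoal(mid, di) <= 0) return(Inf)
    val <- integrate(f, l, u, rel.tol = 1e-10, abs.tol = 1e-13,
                     stop.on.error = FALSE)
    if (!is.finite(val$value)) return(Inf)
    total <- total + val$value
  }
  max(total, 0)
}

#' Pseudo-true introgression parameters by KL minimisation
#'
#' Minimises [kl_divergence()] over the free parameters of a fitting method
#' (see [fit_method_spec()]), yielding the pseudo-true parameter values that
#' maximum-likelihood estimates converge to as the number of loci grows.
#' Optimisation runs on transformed parameters (log population sizes and
#' divergence time, logit introgression probability, and an
#' order-preserving map keeping `tauS < tauR`) with BFGS from multiple
#' starts. With `n = Inf` the introgression time is additionally profiled
#' against the support boundary (0 for IM/SC data, the end of gene flow for
#' IIM data), where the objective is typically minimised: interior search
#' cannot reach the boundary exactly, so both boundary values are evaluated
#' as candidate optima in their own right.
#'
#' @param gen Generating model parameters.
#' @param spec A [fit_method_spec()], or a method letter `"a"`-`"e"`.
#' @param n Sites per sequence (positive integer or `Inf`).
#' @param mutation_model Passed to [kl_divergence()].
#' @param restarts Number of random restarts (the first start is
#'   truth-informed).
#' @param init Optional named list of starting values for free parameters.
#' @return A `pseudo_true_fit` object; see [tidy.pseudo_true_fit()].
#' @examples
#' \donttest{
#' gen <- preset_scenario("fig1-iim")$params
#' fit <- minimize_kl(gen, "b", n = Inf, restarts = 2)
#' tidy(fit)
#' }
#' @export
minimize_kl <- function(gen, spec = "b", n = Inf,
                        mutation_model = c("binomial_jc", "poisson"),
                        restarts = 10, init = NULL) {
  mutation_model <- match.arg(mutation_model)
  if (is.character(spec)) spec <- fit_method_spec(spec, gen)
  stopifnot(inherits(spec, "fit_method_spec"))
  if (restarts < 1) abort("`restarts` must be >= 1.")
  dm <- coal_density(gen)
  dm_support <- dm$support_min
  # cache the generating side: the density (n = Inf) or its marginal pmf
  if (is.finite(n)) {
    xmax_hard <- if (mutation_model == "binomial_jc") n else Inf
    xs <- integer(); lm <- numeric(); lo <- 0L
    repeat {
      hi <- min(lo + 255L, xmax_hard)
      xi <- lo:hi
      lm <- c(lm, marginal_log_pmf(xi, n, dm, mutation_model))
      xs <- c(xs, xi)
      if (sum(exp(lm)) >= 1 - 1e-12 || hi >= xmax_hard) break
      lo <- hi + 1L
    }
    pm <- exp(lm)
  }
  objective <- function(est) {
    fit <- do.call(msci_params, est)
    if (nrow(validate_params(fit))) return(1e10)
    kl <- if (is.infinite(n)) {
      if (fit$tauS > dm_support + 1e-15) Inf
      else kl_density_level(dm, coal_density(fit))
    } else {
      li <- marginal_log_pmf(xs, n, coal_density(fit), mutation_model)
      if (any(!is.finite(li) & pm > 0)) Inf
      else max(sum(ifelse(pm == 0, 0, pm * (lm - li))), 0)
    }
    if (!is.finite(kl)) 1e10 else kl
  }
  out <- run_constrained_fit(
    objective = objective, spec = spec, gen = gen, n = n,
    restarts = restarts, init = init, support_min = dm_support)
  structure(
    list(estimates = out$estimates, objective = out$value,
         kl = out$value, method = spec, gen = gen, n = n,
         mutation_model = mutation_model,
         convergence = out$convergence, restarts = out$restarts),
    class = "pseudo_true_fit")
}

# shared constrained-optimisation engine for KL and ML fits.
# `objective(est)` takes a named list of natural-scale MSci parameters and
# returns the value to minimise.
run_constrained_fit <- function(objective, spec, gen, n, restarts, init,
                                support_min, smooth = FALSE) {
  free <- spec$free
  fixed <- spec$fixed
  # tauS handling: with n = Inf, feasible tauS lie in [0, support_min]
  tauS_mode <- if (!("tauS" %in% free)) {
    "fixed"
  } else if (is.infinite(n)) {
    if (support_min <= 0) "pinned0" else "bounded"
  } else {
    "ordered"
  }
  free_eff <- free
  if (tauS_mode == "pinned0") free_eff <- setdiff(free_eff, "tauS")

  to_params <- function(u, tauS_override = NULL) {
    est <- list()
    iu <- 0
    for (nm in free_eff) {
      iu <- iu + 1
      est[[nm]] <- switch(nm,
        tauR = exp(u[iu]),
        tauS = NA_real_,  # filled below, needs tauR
        thetaR = exp(u[iu]),
        thetaS = exp(u[iu]),
        theta = exp(u[iu]),
        phi = plogis(u[iu]))
      if (nm == "tauS") est$tauS_u <- u[iu]
    }
    for (nm in names(fixed)) est[[nm]] <- fixed[[nm]]
    if (spec$equal_thetas) {
      est$thetaR <- est$theta; est$thetaS <- est$theta; est$theta <- NULL
    }
    if (!is.null(tauS_override)) {
      est$tauS <- tauS_override
    } else if (!is.null(est$tauS_u)) {
      est$tauS <- if (tauS_mode == "bounded") {
        support_min * plogis(est$tauS_u)
      } else {
        est$tauR * plogis(est$tauS_u)
      }
    } else if (tauS_mode == "pinned0" && "tauS" %in% free) {
      est$tauS <- 0
    }
    est$tauS_u <- NULL
    est[c("tauR", "tauS", "thetaR", "thetaS", "phi")]
  }

  start_values <- function(r) {
    # first start is truth-informed, the rest log-uniform over plausible
    # ranges
    if (r == 1L) {
      tauR0 <- if (!is.null(init$tauR)) init$tauR else
        if (inherits(gen, "mscm_params")) gen$tauR else gen$tauR
      thR0 <- if (!is.null(init$thetaR)) init$thetaR else
        if (inherits(gen, "mscm_params")) gen$thetaR else gen$thetaR
      thS0 <- if (!is.null(init$thetaS)) init$thetaS else
        if (inherits(gen, "mscm_params")) gen$thetaA else gen$thetaS
      phi0_guess <- if (!is.null(init$phi)) init$phi else {
        if (inherits(gen, "mscm_params")) {
          dt <- switch(gen$variant, im = gen$tauR,
                       iim = gen$tauR - gen$tauT, sc = gen$tauT)
          min(max(phi0(gen$M, dt, gen$thetaB), 0.02), 0.95)
        } else min(max(gen$phi, 0.02), 0.95)
      }
      tauS0 <- if (!is.null(init$tauS)) init$tauS else NA
      vals <- list(tauR = tauR0, thetaR = thR0, thetaS = thS0,
                   theta = sqrt(thR0 * thS0), phi = phi0_guess)
      u <- numeric(0)
      for (nm in free_eff) {
        u <- c(u, switch(nm,
          tauR = log(vals$tauR),
          tauS = if (!is.na(tauS0) && tauS0 > 0) qlogis(min(
            tauS0 / max(if (tauS_mode == "bounded") support_min else vals$tauR,
                        1e-12), 0.99)) else 0,
          thetaR = log(vals$thetaR),
          thetaS = log(vals$thetaS),
          theta = log(vals$theta),
          phi = qlogis(vals$phi)))
      }
      return(u)
    }
    if (r %% 2 == 0) {
      # local jitter around the truth-informed start
      return(start_values(1L) + runif(length(free_eff), -1.5, 1.5))
    }
    vapply(free_eff, function(nm) {
      switch(nm,
        tauR = runif(1, log(3e-4), log(0.03)),
        tauS = runif(1, -3, 3),
        thetaR = runif(1, log(3e-4), log(0.03)),
        thetaS = runif(1, log(3e-4), log(0.03)),
        theta = runif(1, log(3e-4), log(0.03)),
        phi = qlogis(runif(1, 0.05, 0.95)))
    }, 0)
  }

  fn <- function(u, tauS_override = NULL) {
    est <- to_params(u, tauS_override)
    objective(est)
  }

  # the KL objective has kinks where the fitted and generating densities'
  # discontinuities align (which is where optima live when n = Inf), so each
  # run is a Nelder-Mead search followed by a BFGS polish, keeping whichever
  # is better
  run_one <- function(f, u0) {
    if (smooth) {
      # smooth likelihood surfaces: derivative-based search first, simplex
      # only as fallback
      bf <- tryCatch(
        optim(u0, f, method = "BFGS",
              control = list(maxit = 300, reltol = 1e-12)),
        error = function(e) { if (isTRUE(getOption("misflow.debug"))) message("OPT ERR: ", conditionMessage(e)); NULL })
      nm <- tryCatch(
        suppressWarnings(optim(if (is.null(bf)) u0 else bf$par, f,
                               method = "Nelder-Mead",
                               control = list(maxit = 500,
                                              reltol = 1e-12))),
        error = function(e) { if (isTRUE(getOption("misflow.debug"))) message("OPT ERR: ", conditionMessage(e)); NULL })
    } else {
      nm <- tryCatch(
        suppressWarnings(optim(u0, f, method = "Nelder-Mead",
                               control = list(maxit = 2000,
                                              reltol = 1e-14))),
        error = function(e) { if (isTRUE(getOption("misflow.debug"))) message("OPT ERR: ", conditionMessage(e)); NULL })
      bf <- tryCatch(
        optim(if (is.null(nm)) u0 else nm$par, f, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-14)),
        error = function(e) { if (isTRUE(getOption("misflow.debug"))) message("OPT ERR: ", conditionMessage(e)); NULL })
    }
    cands <- Filter(Negate(is.null), list(nm, bf))
    if (!length(cands)) return(NULL)
    cands[[which.min(vapply(cands, `[[`, 0, "value"))]]
  }

  runs <- list()
  for (r in seq_len(restarts)) {
    ans <- run_one(fn, start_values(r))
    if (!is.null(ans)) {
      runs[[length(runs) + 1L]] <- list(par = ans$par, value = ans$value,
                                        conv = ans$convergence,
                                        tauS_override = NULL)
    }
  }
  # boundary candidates for tauS with n = Inf
  if (tauS_mode == "bounded") {
    i_tauS <- match("tauS", free_eff)
    for (bv in unique(c(0, support_min))) {
      fn_b <- function(u_red) {
        u <- numeric(length(free_eff)); u[-i_tauS] <- u_red; u[i_tauS] <- 0
        fn(u, tauS_override = bv)
      }
      ans <- run_one(fn_b, start_values(1L)[-i_tauS])
      if (!is.null(ans)) {
        par_full <- numeric(length(free_eff))
        par_full[-i_tauS] <- ans$par
        runs[[length(runs) + 1L]] <- list(par = par_full, value = ans$value,
                                          conv = ans$convergence,
                                          tauS_override = bv)
      }
    }
  }
  if (!length(runs)) abort("all optimisation restarts failed")
  vals <- vapply(runs, `[[`, 0, "value")
  best <- runs[[which.min(vals)]]
  # coordinate polish: golden-section over each free coordinate in turn,
  # which is robust to the kinks that derivative-based steps stall on and
  # sharpens the smooth coordinates (phi, thetas) to ~1e-10
  skip <- if (!is.null(best$tauS_override)) match("tauS", free_eff) else 0L
  u <- best$par
  vbest <- best$value
  for (sweep in seq_len(if (smooth) 1 else 3)) {
    for (i in seq_along(u)) {
      if (i == skip) next
      g <- function(ui) { uu <- u; uu[i] <- ui; fn(uu, best$tauS_override) }
      o <- optimize(g, lower = u[i] - 0.4, upper = u[i] + 0.4, tol = 1e-11)
      if (o$objective < vbest) { u[i] <- o$minimum; vbest <- o$objective }
    }
  }
  best$par <- u
  best$value <- vbest
  est <- to_params(best$par, best$tauS_override)
  list(estimates = est, value = best$value,
       convergence = best$conv == 0,
       restarts = tibble(run = seq_along(runs), value = vals,
                         converged = vapply(runs, function(r) r$conv == 0,
                                            TRUE)),
       par = best$par, free_eff = free_eff, to_params = to_params,
       tauS_override = best$tauS_override)
}

#' @export
print.pseudo_true_fit <- function(x, ...) {
  cat(sprintf("<pseudo_true_fit: method %s, n = %s>\n", x$method$method,
              format(x$n)))
  est <- unlist(x$estimates)
  cat(" ", paste(sprintf("%s = %.6g", names(est), est), collapse = ", "), "\n")
  cat(sprintf("  KL = %.6g (%s)\n", x$kl,
              if (x$convergence) "converged" else "NOT converged"))
  invisible(x)
}

#' Tidy pseudo-true fits
#'
#' @param x A `pseudo_true_fit` from [minimize_kl()].
#' @param ... Unused.
#' @return `tidy()`: a tibble with columns `term`, `estimate`, `free`;
#'   `glance()`: a one-row tibble with the KL value and diagnostics.
#' @export
tidy.pseudo_true_fit <- function(x, ...) {
  est <- unlist(x$estimates)
  free <- names(est) %in% x$method$free |
    (x$method$equal_thetas & names(est) %in% c("thetaR", "thetaS")) |
    (names(est) == "tauS" & "tauS" %in% x$method$free)
  tibble(term = names(est), estimate = unname(est), free = free)
}

#' @rdname tidy.pseudo_true_fit
#' @export
glance.pseudo_true_fit <- function(x, ...) {
  tibble(kl = x$kl, converged = x$convergence,
         restarts = nrow(x$restarts), n = x$n, method = x$method$method)
}

#' Closed-form low-migration pseudo-true introgression probability
#'
#' Analytic approximations to the KL-minimising introgression probability
#' when the divergence time and population sizes are held at their true
#' values, the introgression time sits at the end of the gene-flow period,
#' and the fitted density matches the true density beyond the divergence
#' time. Accurate at low migration rates; the expressions are singular at
#' `w thetaA = 2`, which is outside their validity region and raises an
#' error. They imply the strict ordering `phi0 > phi*(SC) > phi*(IIM) =
#' phi*(IM)` (the IIM and IM values coincide for one sequence per species,
#' where IIM is an IM model shifted in time).
#'
#' @param params An [mscm_params()] object; its `variant` selects the
#'   expression.
#' @return The approximate pseudo-true introgression probability.
#' @examples
#' phi_star_closed_form(preset_scenario("fig1-sc")$params)
#' @export
phi_star_closed_form <- function(params) {
  stopifnot(inherits(params, "mscm_params"))
  stop_if_invalid(params)
  w <- migration_rate_scaled(params)
  thA <- params$thetaA
  if (w * thA >= 2) {
    abort(sprintf("closed form requires w * thetaA < 2 (got %g)", w * thA))
  }
  tauR <- params$tauR; tauT <- params$tauT
  a <- 2 / thA
  switch(params$variant,
    im = {
      p0 <- phi0(params$M, tauR, params$thetaB)
      g <- -expm1(-a * tauR)
      (p0 - w * thA / 2 * g) / ((1 - w * thA / 2) * g)
    },
    iim = {
      p0 <- phi0(params$M, tauR - tauT, params$thetaB)
      g <- -expm1(-a * (tauR - tauT))
      (p0 - w * thA / 2 * g) / ((1 - w * thA / 2) * g)
    },
    sc = {
      p0 <- phi0(params$M, tauT, params$thetaB)
      leak <- w * thA / (2 - w * thA) *
        (exp(-w * tauT) - exp(-a * tauT)) * exp(-a * (tauR - tauT))
      (p0 - leak) / (-expm1(-a * tauR))
    })
}

#' Pseudo-true parameter values along a migration-rate grid
#'
#' Runs [minimize_kl()] at each migration rate, warm-starting each fit from
#' its neighbour, and returns one row per rate with the pseudo-true
#' parameter values and the minimised KL divergence.
#'
#' @param gen Generating [mscm_params()]; its `M` field is replaced by each
#'   grid value in turn.
#' @param spec Method letter or [fit_method_spec()] (rebuilt per grid point
#'   when a letter is given).
#' @param M_grid Migration rates to sweep (defaults to
#'   [migration_rate_grid()]).
#' @param n Sites per sequence or `Inf`.
#' @param mutation_model Passed through.
#' @param restarts Restarts for the first grid point; subsequent points use
#'   the warm start plus one random restart.
#' @return A tibble with columns `M`, `tauR`, `tauS`, `thetaR`, `thetaS`,
#'   `phi`, `kl`, `converged`.
#' @export
sweep_migration_rate <- function(gen, spec = "b",
                                 M_grid = migration_rate_grid(),
                                 n = Inf,
                                 mutation_model = c("binomial_jc", "poisson"),
                                 restarts = 5) {
  mutation_model <- match.arg(mutation_model)
  stopifnot(inherits(gen, "mscm_params"))
  rows <- vector("list", length(M_grid))
  warm <- NULL
  for (i in seq_along(M_grid)) {
    gi <- gen
    gi$M <- M_grid[i]
    sp <- if (is.character(spec)) fit_method_spec(spec, gi) else spec
    fit <- minimize_kl(gi, sp, n = n, mutation_model = mutation_model,
                       restarts = if (i == 1L) restarts else 2,
                       init = warm)
    warm <- fit$estimates
    rows[[i]] <- tibble(M = M_grid[i],
                        tauR = fit$estimates$tauR,
                        tauS = fit$estimates$tauS,
                        thetaR = fit$estimates$thetaR,
                        thetaS = fit$estimates$thetaS,
                        phi = fit$estimates$phi,
                        kl = fit$kl, converged = fit$convergence)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("migration_sweep", class(out))
  out
}
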