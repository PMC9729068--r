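#' Probability of x pairwise differences given the coalescent time
#'
#' Under the Jukes-Cantor model, two sequences that coalesced `t` expected
#' mutations per site ago differ at each site independently with probability
#' `p(t) = 3/4 - (3/4) exp(-8 t / 3)`, so the number of differences `x` at
#' `n` sites is binomial. The infinite-sites Poisson approximation replaces
#' this with a Poisson count of mean `2 n t`.
#'
#' @param x Vector of difference counts, `>= 0` (and `<= n` for the binomial
#'   model).
#' @param n Number of sites, `> 0`.
#' @param t Coalescent time, `>= 0`.
#' @param mutation_model `"binomial_jc"` or `"poisson"`.
#' @param log Return log-probabilities?
#' @return Numeric vector of probabilities, one per element of `x`.
#' @examples
#' prob_x_given_t(0:3, n = 1000, t = 0.002)
#' @export
prob_x_given_t <- function(x, n, t,
                           mutation_model = c("binomial_jc", "poisson"),
                           log = FALSE) {
  mutation_model <- match.arg(mutation_model)
  n <- check_count(n, "n")
  check_scalar(t, "t", lower = 0)
  if (any(x < 0) || any(x != floor(x))) abort("`x` must be non-negative integers.")
  if (mutation_model == "binomial_jc") {
    if (any(x > n)) abort("`x` cannot exceed `n` under the binomial model.")
    p <- jc_mismatch_prob(t)
    return(dbinom(x, n, p, log = log))
  }
  dpois(x, 2 * n * t, log = log)
}

# p(t) = 3/4 (1 - e^{-8t/3}), computed without cancellation at small t
jc_mismatch_prob <- function(t) -0.75 * expm1(-8 * t / 3)

#' Marginal probability of x differences under a gene-flow model
#'
#' Integrates the per-locus sampling probability over the coalescent-time
#' density: `f(x | theta) = integral of f(x | t) f(t | theta) dt`. The
#' `"quadrature"` method uses adaptive quadrature piece by piece with the
#' exact exponential tail (the integrand beyond the species divergence time
#' is a single exponential times the sampling probability, integrated to
#' infinity). The `"closed_form"` method (Poisson mutation model only)
#' evaluates each exponential term of the density against the Poisson kernel
#' as a lower-incomplete-gamma difference, in log space; it agrees with the
#' quadrature route to near machine precision and is the fast path used by
#' the Kullback-Leibler and likelihood machinery.
#'
#' @param x Vector of difference counts.
#' @param n Sites per sequence.
#' @param params An [mscm_params()] or [msci_params()] object, or a
#'   pre-built [coal_density()].
#' @param mutation_model `"binomial_jc"` or `"poisson"`.
#' @param method `"quadrature"` or `"closed_form"`.
#' @return Numeric vector of marginal probabilities.
#' @examples
#' p <- preset_scenario("fig1-iim")$params
#' marginal_prob_x(0:5, n = 1000, p)
#' @export
marginal_prob_x <- function(x, n, params,
                            mutation_model = c("binomial_jc", "poisson"),
                            method = c("quadrature", "closed_form")) {
  mutation_model <- match.arg(mutation_model)
  method <- match.arg(method)
  density <- if (inherits(params, "coal_density")) params else coal_density(params)
  n <- check_count(n, "n")
  if (method == "closed_form") {
    if (mutation_model != "poisson") {
      abort("closed_form marginals are available for the poisson model only")
    }
    if (is.null(density$terms)) {
      # exponential-term decomposition degenerates at w = 2/thetaA
      method <- "quadrature"
    } else {
      return(exp(marginal_log_pmf_poisson(density, n, x)))
    }
  }
  kernel <- function(xi, t) {
    if (mutation_model == "binomial_jc") {
      if (xi > n) abort("`x` cannot exceed `n` under the binomial model.")
      dbinom(xi, n, jc_mismatch_prob(t))
    } else {
      dpois(xi, 2 * n * t)
    }
  }
  vapply(x, function(xi) {
    total <- 0
    br <- density$breaks
    for (j in seq_along(density$pieces)) {
      f <- density$pieces[[j]]
      l <- br[j]; u <- br[j + 1]
      # sub-split sharply decaying pieces so the adaptive rule sees them
      cuts <- c(l, u)
      if (!is.null(density$terms) && nrow(density$terms[[j]])) {
        r_max <- max(density$terms[[j]]$rate)
        if (is.finite(u) && r_max * (u - l) > 50) {
          cuts <- c(l, l + 50 / r_max, u)
        }
      }
      for (ci in seq_len(length(cuts) - 1)) {
        val <- integrate(function(t) kernel(xi, t) * f(t),
                         cuts[ci], cuts[ci + 1], rel.tol = 1e-12,
                         abs.tol = 1e-15, stop.on.error = FALSE)
        if (val$message != "OK" && abs(val$value) > 1e-12) {
          abort(sprintf("quadrature failed on piece %d: %s", j, val$message))
        }
        total <- total + val$value
      }
    }
    total
  }, 0)
}

# log f(x) for the Poisson model from the exponential-term decomposition:
# each term amp * e^{-rate (t - l)} over (l, u) contributes
# amp e^{rate l} (2n)^x / s^{x+1} * (P(x+1, s u) - P(x+1, s l)) with
# s = 2 n + rate, accumulated with signs in log space; the incomplete-gamma
# difference is taken on whichever tail is numerically clean
marginal_log_pmf_poisson <- function(density, n, x) {
  br <- density$breaks
  out <- numeric(length(x))
  for (k in seq_along(x)) {
    xi <- x[k]
    logs <- c(); signs <- c()
    for (j in seq_along(density$terms)) {
      tm <- density$terms[[j]]
      if (!nrow(tm)) next
      l <- br[j]; u <- br[j + 1]
      for (i in seq_len(nrow(tm))) {
        amp <- tm$amp[i]
        if (amp == 0) next
        s <- 2 * n + tm$rate[i]
        ldiff <- lgamma_interval(xi + 1, s, l, u)
        if (!is.finite(ldiff)) next
        # log coef = log|amp| + rate * l
        logs <- c(logs, log(abs(amp)) + tm$rate[i] * l + xi * log(2 * n) -
                    (xi + 1) * log(s) + ldiff)
        signs <- c(signs, sign(amp))
      }
    }
    if (!length(logs)) { out[k] <- -Inf; next }
    m <- max(logs)
    acc <- sum(signs * exp(logs - m))
    out[k] <- if (acc <= 0) -Inf else m + log(acc)
  }
  out
}

# log of P(Gamma(shape, rate = s) in (l, u)), choosing the tail whose
# difference avoids cancellation
lgamma_interval <- function(shape, s, l, u) {
  lp_u <- pgamma(u, shape, rate = s, log.p = TRUE)
  if (lp_u < log(0.5)) {
    lp_l <- pgamma(l, shape, rate = s, log.p = TRUE)
    if (lp_u <= lp_l) return(-Inf)
    return(lp_u + log1p(-exp(lp_l - lp_u)))
  }
  lq_l <- pgamma(l, shape, rate = s, log.p = TRUE, lower.tail = FALSE)
  lq_u <- pgamma(u, shape, rate = s, log.p = TRUE, lower.tail = FALSE)
  if (lq_l <= lq_u) return(-Inf)
  lq_l + log1p(-exp(lq_u - lq_l))
}

#' Fast vectorised marginal pmf over many difference counts
#'
#' Shared-node quadrature: the density is sampled once on Gauss-Legendre
#' nodes per piece (with the exact exponential substitution
#' `u = exp(-2 (t - tauR) / thetaR)` mapping the infinite tail to `(0, 1)`),
#' and the marginal probability of every requested `x` is a weighted sum of
#' binomial (or Poisson) kernels over those nodes, assembled in log space.
#' This is the work-horse behind [kl_divergence()] and [coal_loglik()]; the
#' Poisson model dispatches to the closed-form incomplete-gamma route when
#' the density's term decomposition is available.
#'
#' @inheritParams marginal_prob_x
#' @param nodes Gauss-Legendre nodes per density piece.
#' @return Numeric vector of `log` marginal probabilities (same length as
#'   `x`).
#' @export
marginal_log_pmf <- function(x, n, params,
                             mutation_model = c("binomial_jc", "poisson"),
                             nodes = 96) {
  mutation_model <- match.arg(mutation_model)
  density <- if (inherits(params, "coal_density")) params else coal_density(params)
  n <- check_count(n, "n")
  if (mutation_model == "poisson" && !is.null(density$terms)) {
    return(marginal_log_pmf_poisson(density, n, x))
  }
  qn <- density_quad_nodes(density, nodes)
  keep <- qn$w != 0
  wk <- qn$w[keep]
  logW <- log(abs(wk))
  sgn <- sign(wk)
  if (!length(logW)) return(rep(-Inf, length(x)))
  # kernel log-probabilities as an |x| x nodes matrix
  lk <- if (mutation_model == "binomial_jc") {
    p <- jc_mismatch_prob(qn$t[keep])
    lchoose(n, x) + outer(x, log(p)) + outer(n - x, log1p(-p))
  } else {
    mu <- 2 * n * qn$t[keep]
    outer(x, log(mu)) - rep(mu, each = length(x)) - lgamma(x + 1)
  }
  M <- sweep(lk, 2, logW, "+")
  rm_ <- apply(M, 1, max)
  acc <- as.vector(exp(M - rm_) %*% sgn)
  out <- ifelse(is.finite(rm_) & acc > 0, rm_ + log(pmax(acc, 0)), -Inf)
  out
}

# cached Gauss-Legendre rule on (0, 1); rescaled per piece
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre01 <- function(nodes) {
  key <- as.character(nodes)
  if (is.null(.gl_cache[[key]])) {
    gl <- pracma::gaussLegendre(nodes, 0, 1)
    .gl_cache[[key]] <- gl
  }
  .gl_cache[[key]]
}

# Gauss-Legendre nodes/weights absorbing the density: integral g(t) f(t) dt
# ~ sum w_i g(t_i). Where the exponential-term decomposition is available,
# each term coef * e^{-rate t} over (l, u) is mapped through
# v = e^{-rate (t - l)} so that the nodes track the term's own scale exactly
# (a near-point-mass piece from a tiny theta is resolved as well as a broad
# one); weights can be negative for the mixed-sign migration terms. The
# fallback (at the w = 2/thetaA singularity, where no decomposition exists)
# samples the pieces directly on the time scale.
density_quad_nodes <- function(density, nodes = 96) {
  gl <- gauss_legendre01(nodes)
  br <- density$breaks
  ts <- c(); ws <- c()
  if (!is.null(density$terms)) {
    for (j in seq_along(density$terms)) {
      l <- br[j]; u <- br[j + 1]
      tm <- density$terms[[j]]
      for (i in seq_len(nrow(tm))) {
        amp <- tm$amp[i]; r <- tm$rate[i]
        if (amp == 0) next
        if (r <= 0) {  # constant term (only arises with zero amp upstream)
          ts <- c(ts, l + (u - l) * gl$x)
          ws <- c(ws, (u - l) * gl$w * amp)
          next
        }
        v0 <- if (is.finite(u)) exp(-r * (u - l)) else 0
        v <- v0 + (1 - v0) * gl$x
        ts <- c(ts, l - log(v) / r)
        ws <- c(ws, gl$w * (1 - v0) * amp / r)
      }
    }
    return(list(t = ts, w = ws))
  }
  for (j in seq_along(density$pieces)) {
    l <- br[j]; u <- br[j + 1]
    f <- density$pieces[[j]]
    if (is.finite(u)) {
      if (u <= l) next
      x <- l + (u - l) * gl$x
      ts <- c(ts, x)
      ws <- c(ws, (u - l) * gl$w * f(x))
    } else {
      r <- 2 / density$params$thetaR
      K <- f(l) / r
      ts <- c(ts, l - log(gl$x) / r)
      ws <- c(ws, gl$w * K)
    }
  }
  list(t = ts, w = ws)
}
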