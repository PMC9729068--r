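#' Transition probabilities of the two-lineage coalescent-with-migration chain
#'
#' Backwards in time, one sequence from each of species A and B evolves
#' through a three-state Markov chain: state `AB` (one lineage in each
#' species), `AA` (the B lineage has migrated into A) and `A` (the lineages
#' have coalesced). Migration occurs at the mutation-scaled rate
#' `w = 4 M / thetaB` and coalescence in A at rate `2 / thetaA`. This returns
#' the matrix exponential of the generator in closed form; the removable
#' singularity at `w = 2 / thetaA` is evaluated by its analytic limit, so the
#' matrix is smooth in `w` everywhere.
#'
#' @param w Mutation-scaled migration rate, `>= 0`.
#' @param thetaA Population size parameter of the receiving-ancestry species
#'   A, `> 0`.
#' @param t Elapsed time (expected mutations per site), `>= 0`.
#' @return A 3x3 row-stochastic matrix with dimnames `AB`, `AA`, `A`.
#' @examples
#' transition_matrix(w = 80, thetaA = 0.002, t = 0.002)
#' @export
transition_matrix <- function(w, thetaA, t) {
  check_scalar(w, "w", lower = 0)
  check_scalar(thetaA, "thetaA")
  if (thetaA <= 0) abort("`thetaA` must be > 0.")
  check_scalar(t, "t", lower = 0)
  a <- 2 / thetaA
  p11 <- exp(-w * t)
  p12 <- p_ab_aa(w, a, t)
  p22 <- exp(-a * t)
  m <- matrix(c(p11, p12, 1 - p11 - p12,
                0, p22, 1 - p22,
                0, 0, 1),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("AB", "AA", "A"), c("AB", "AA", "A")))
  m
}

# P[AB -> AA](t) = w/(a-w) (e^{-wt} - e^{-at}), stable through w = a
p_ab_aa <- function(w, a, t) {
  z <- (a - w) * t
  small <- abs(z) < 30
  out <- numeric(length(t))
  zt <- z[small]
  out[small] <- w * t[small] * exp(-a * t[small]) * expm1_ratio(zt)
  if (any(!small)) {
    tl <- t[!small]
    out[!small] <- w / (a - w) * (exp(-w * tl) - exp(-a * tl))
  }
  out
}

#' Coalescent-time density objects
#'
#' Builds the piecewise density of the between-species coalescent time `t`
#' for one sequence per species under a migration model ([mscm_params()]) or
#' the introgression model ([msci_params()]). The density is represented by
#' its breakpoints (`0`, the gene-flow change point, the species divergence
#' time, infinity) together with per-piece evaluators and, where available,
#' an exact decomposition into exponential terms used for closed-form
#' integration. The last piece always decays at rate `2 / thetaR`.
#'
#' The migration densities depend on `M` and `thetaB` only through the
#' mutation-scaled rate `w = 4 M / thetaB`. The IM density is the IIM density
#' with `tauT = 0`; the MSci density is zero below `tauS`, a scaled
#' exponential with rate `2 / thetaS` on `(tauS, tauR)` and a mixed
#' exponential beyond `tauR`.
#'
#' @param params An [mscm_params()] or [msci_params()] object.
#' @return An object of class `coal_density` with elements `model`,
#'   `breaks`, `pieces` (evaluator functions), `terms` (exponential-term
#'   decomposition, or `NULL` near the `w = 2 / thetaA` singularity where the
#'   decomposition degenerates) and `support_min`.
#' @seealso [density_mscm()], [density_msci()], [density_moments()]
#' @examples
#' d <- coal_density(preset_scenario("fig1-im")$params)
#' dcoal(c(0.001, 0.003), d)
#' @export
coal_density <- function(params) {
  if (inherits(params, "mscm_params")) return(coal_density_mscm(params))
  if (inherits(params, "msci_params")) return(coal_density_msci(params))
  abort("`params` must be an mscm_params or msci_params object.")
}

new_coal_density <- function(model, params, breaks, pieces, terms,
                             support_min) {
  structure(list(model = model, params = params, breaks = breaks,
                 pieces = pieces, terms = terms, support_min = support_min),
            class = "coal_density")
}

# a term set is a data.frame(amp, rate): on a piece starting at l,
# f(t) = sum amp * exp(-rate * (t - l)); anchoring at the piece start keeps
# the amplitudes O(f) even when a rate is enormous (tiny theta)
coal_density_mscm <- function(params) {
  stop_if_invalid(params)
  w <- migration_rate_scaled(params)
  a <- 2 / params$thetaA
  r <- 2 / params$thetaR
  tauR <- params$tauR
  singular <- abs(2 - params$thetaA * w) < 1e-8
  if (params$variant %in% c("im", "iim")) {
    tT <- params$tauT  # 0 for IM
    # survivor weight entering the root: 1 - P[AB -> A](tauR - tT)
    P <- transition_matrix(w, params$thetaA, tauR - tT)
    K <- P["AB", "AB"] + P["AB", "AA"]
    pieces <- list(
      function(t) rep(0, length(t)),
      function(t) a * p_ab_aa(w, a, t - tT),
      function(t) K * r * exp(-r * (t - tauR)))
    breaks <- c(0, tT, tauR, Inf)
    terms <- if (singular) NULL else list(
      data.frame(amp = numeric(), rate = numeric()),
      data.frame(amp = c(2 * w / (2 - params$thetaA * w),
                         -2 * w / (2 - params$thetaA * w)),
                 rate = c(w, a)),
      data.frame(amp = K * r, rate = r))
    if (tT == 0) {  # drop the empty leading piece for IM
      pieces <- pieces[-1]; breaks <- breaks[-2]
      if (!is.null(terms)) terms <- terms[-1]
    }
    return(new_coal_density(params$variant, params, breaks, pieces, terms,
                            support_min = tT))
  }
  # secondary contact: migration over (0, tauT)
  tT <- params$tauT
  P <- transition_matrix(w, params$thetaA, tT)
  p12 <- P["AB", "AA"]
  K <- p12 * exp(-a * (tauR - tT)) + P["AB", "AB"]
  pieces <- list(
    function(t) a * p_ab_aa(w, a, t),
    function(t) a * p12 * exp(-a * (t - tT)),
    function(t) K * r * exp(-r * (t - tauR)))
  breaks <- c(0, tT, tauR, Inf)
  terms <- if (singular) NULL else list(
    data.frame(amp = c(2 * w / (2 - params$thetaA * w),
                       -2 * w / (2 - params$thetaA * w)),
               rate = c(w, a)),
    data.frame(amp = a * p12, rate = a),
    data.frame(amp = K * r, rate = r))
  new_coal_density("sc", params, breaks, pieces, terms, support_min = 0)
}

coal_density_msci <- function(params) {
  stop_if_invalid(params)
  s <- 2 / params$thetaS
  r <- 2 / params$thetaR
  tauS <- params$tauS
  tauR <- params$tauR
  phi <- params$phi
  K <- phi * exp(-s * (tauR - tauS)) + (1 - phi)
  pieces <- list(
    function(t) rep(0, length(t)),
    function(t) phi * s * exp(-s * (t - tauS)),
    function(t) K * r * exp(-r * (t - tauR)))
  breaks <- c(0, tauS, tauR, Inf)
  terms <- list(
    data.frame(amp = numeric(), rate = numeric()),
    data.frame(amp = phi * s, rate = s),
    data.frame(amp = K * r, rate = r))
  if (tauS == 0) {
    pieces <- pieces[-1]; breaks <- breaks[-2]; terms <- terms[-1]
  }
  new_coal_density("msci", params, breaks, pieces, terms,
                   support_min = tauS)
}

#' Evaluate coalescent-time densities
#'
#' `dcoal()` evaluates a [coal_density()] object; `density_mscm()` and
#' `density_msci()` are direct evaluators taking the parameter objects.
#' `pcoal()` is the corresponding distribution function (exact exponential
#' integrals piece by piece).
#'
#' @param t,q Vector of times (expected mutations per site), `>= 0`.
#' @param density A [coal_density()] object.
#' @param params Parameter object of the matching class.
#' @return Numeric vector of density (or distribution-function) values.
#' @export
dcoal <- function(t, density) {
  stopifnot(inherits(density, "coal_density"))
  if (any(t < 0)) abort("`t` must be >= 0.")
  out <- numeric(length(t))
  br <- density$breaks
  for (j in seq_along(density$pieces)) {
    in_piece <- t >= br[j] & t < br[j + 1]
    if (any(in_piece)) out[in_piece] <- density$pieces[[j]](t[in_piece])
  }
  out
}

#' @rdname dcoal
#' @export
density_mscm <- function(t, params) {
  stopifnot(inherits(params, "mscm_params"))
  dcoal(t, coal_density(params))
}

#' @rdname dcoal
#' @export
density_msci <- function(t, params) {
  stopifnot(inherits(params, "msci_params"))
  dcoal(t, coal_density(params))
}

#' @rdname dcoal
#' @export
pcoal <- function(q, density) {
  stopifnot(inherits(density, "coal_density"))
  br <- density$breaks
  terms <- density$terms
  piece_cdf <- function(tm, l, u) {
    # integral of the term set over (l, min(u, t)), vectorised in t
    function(t) {
      tt <- pmin(pmax(t, l), u)
      val <- numeric(length(t))
      for (i in seq_len(nrow(tm))) {
        amp <- tm$amp[i]; rt <- tm$rate[i]
        if (rt == 0) {
          val <- val + amp * (tt - l)
        } else {
          val <- val - amp / rt * expm1(-rt * (tt - l))
        }
      }
      val
    }
  }
  if (is.null(terms)) {
    # fall back to per-point quadrature (only needed at w = 2/thetaA exactly)
    return(vapply(q, function(tq) {
      if (tq <= density$support_min) return(0)
      integrate_density(density, upper = tq)
    }, 0))
  }
  fs <- lapply(seq_along(terms), function(j) {
    piece_cdf(terms[[j]], br[j], br[j + 1])
  })
  out <- numeric(length(q))
  for (j in seq_along(fs)) out <- out + fs[[j]](q)
  pmin(pmax(out, 0), 1)
}

# quadrature of g(t) * f(t) over the support; default g = 1
integrate_density <- function(density, g = NULL, upper = Inf,
                              rel.tol = 1e-10) {
  br <- density$breaks
  total <- 0
  for (j in seq_along(density$pieces)) {
    l <- br[j]; u <- min(br[j + 1], upper)
    if (u <= l) next
    f <- density$pieces[[j]]
    h <- if (is.null(g)) f else function(t) g(t) * f(t)
    total <- total + integrate(h, l, u, rel.tol = rel.tol,
                               abs.tol = 1e-14)$value
  }
  total
}

#' Moments of a coalescent-time density
#'
#' Mean and variance of the coalescent time by adaptive quadrature over the
#' density's pieces (exact exponential tail included through the infinite
#' upper limit). Errors if the density does not integrate to 1, which guards
#' against malformed piecewise inputs.
#'
#' @param density A [coal_density()] object.
#' @return A tibble with columns `mean` and `variance`.
#' @examples
#' d <- coal_density(msci_params(0.004, 0.002, 0.01, 0.002, phi = 0))
#' density_moments(d)  # mean = tauR + thetaR / 2 when phi = 0
#' @export
density_moments <- function(density) {
  stopifnot(inherits(density, "coal_density"))
  mass <- integrate_density(density)
  if (abs(mass - 1) > 1e-6) {
    abort(sprintf("density integrates to %.8g, not 1; refusing to compute moments",
                  mass))
  }
  m1 <- integrate_density(density, g = function(t) t) / mass
  m2 <- integrate_density(density, g = function(t) t^2) / mass
  tibble(mean = m1, variance = m2 - m1^2)
}

#' @export
print.coal_density <- function(x, ...) {
  cat(sprintf("<coal_density: %s>\n", x$model))
  cat("  breakpoints:", paste(signif(x$breaks, 6), collapse = ", "), "\n")
  invisible(x)
}
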