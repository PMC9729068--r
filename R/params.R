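#' Parameters of a two-species migration (MSC-M) model
#'
#' Constructs the parameter set of a two-species multispecies-coalescent model
#' with continuous gene flow from species A to species B. Three variants are
#' supported: `"im"` (isolation with migration, gene flow over the whole
#' interval from the present back to the divergence time `tauR`), `"iim"`
#' (isolation with initial migration: gene flow over `(tauT, tauR)`, i.e. from
#' divergence until it stops at `tauT`), and `"sc"` (secondary contact: gene
#' flow over `(0, tauT)`, starting at `tauT` and ongoing).
#'
#' Times (`tauR`, `tauT`) and population sizes (`theta* = 4 N mu`) are both
#' measured in expected mutations per site; time 0 is the present and
#' increases into the past. `M` is the population migration rate in migrants
#' per generation. The mutation-scaled migration rate `w = 4 M / thetaB` is a
#' derived quantity, available through [migration_rate_scaled()], and the
#' coalescent-time density depends on `M` and `thetaB` only through `w`.
#'
#' The constructor performs type checks only; semantic invariants (positive
#' thetas, `0 <= tauT < tauR`, `tauT == 0` for IM) are reported by
#' [validate_params()] so that deliberately invalid sets can be inspected.
#'
#' @param variant One of `"im"`, `"iim"`, `"sc"`.
#' @param tauR Species divergence time (root of the two-species tree).
#' @param tauT Time at which gene flow stops (IIM) or starts (SC); must be 0
#'   for the IM variant.
#' @param thetaA,thetaB Population sizes of the extant species; A is the
#'   donor, B the recipient of migrants.
#' @param thetaR Population size of the common ancestor.
#' @param thetaT Population size of the ghost/ancestral segment used to
#'   define the IIM and SC variants (does not enter the one-sequence-per-species
#'   coalescent density).
#' @param M Population migration rate, migrants per generation, `>= 0`.
#' @return An object of class `mscm_params`.
#' @seealso [msci_params()], [validate_params()], [preset_scenario()]
#' @examples
#' p <- mscm_params("iim", tauR = 0.004, tauT = 0.002,
#'                  thetaA = 0.002, thetaB = 0.01, thetaR = 0.01, M = 0.2)
#' migration_rate_scaled(p)
#' @export
mscm_params <- function(variant = c("im", "iim", "sc"), tauR, tauT = 0,
                        thetaA, thetaB, thetaR, thetaT = thetaR, M) {
  variant <- match.arg(variant)
  for (nm in c("tauR", "tauT", "thetaA", "thetaB", "thetaR", "thetaT", "M")) {
    check_scalar(get(nm), nm)
  }
  structure(
    list(variant = variant, tauR = tauR, tauT = tauT,
         thetaA = thetaA, thetaB = thetaB, thetaR = thetaR, thetaT = thetaT,
         M = M),
    class = "mscm_params")
}

#' Parameters of the two-species introgression (MSci) model
#'
#' Species A and B diverge at `tauR`; at time `tauS` a fraction `phi` of
#' lineages in B trace back into the donor segment S of the A lineage
#' (episodic introgression). With one sequence per species per locus only
#' `(tauR, tauS, thetaR, thetaS, phi)` are identifiable; `thetaA`, `thetaB`
#' and `thetaH` (the recipient segment of B above the hybridisation point)
#' never see a coalescent event in that regime and may be left `NA`. They are
#' required when simulating multiple sequences per species.
#'
#' @param tauR Species divergence time.
#' @param tauS Introgression time, `0 <= tauS < tauR`.
#' @param thetaR,thetaS Population sizes of the root and of the donor segment.
#' @param phi Introgression probability in `[0, 1]`.
#' @param thetaA,thetaB,thetaH Optional population sizes for the
#'   non-identifiable populations (tips and the recipient segment above the
#'   hybridisation point).
#' @return An object of class `msci_params`.
#' @examples
#' msci_params(tauR = 0.004, tauS = 0.002, thetaR = 0.01, thetaS = 0.002,
#'             phi = 0.2)
#' @export
msci_params <- function(tauR, tauS, thetaR, thetaS, phi,
                        thetaA = NA_real_, thetaB = NA_real_,
                        thetaH = NA_real_) {
  for (nm in c("tauR", "tauS", "thetaR", "thetaS", "phi")) {
    check_scalar(get(nm), nm)
  }
  structure(
    list(tauR = tauR, tauS = tauS, thetaR = thetaR, thetaS = thetaS,
         phi = phi, thetaA = thetaA, thetaB = thetaB, thetaH = thetaH),
    class = "msci_params")
}

#' Mutation-scaled migration rate
#'
#' The backward-in-time per-lineage jump rate of a B lineage into A,
#' `w = 4 M / thetaB`, derived from the stored migration rate and recipient
#' population size (never stored independently).
#'
#' @param params An [mscm_params()] object.
#' @return A single number.
#' @export
migration_rate_scaled <- function(params) {
  stopifnot(inherits(params, "mscm_params"))
  4 * params$M / params$thetaB
}

#' Validate gene-flow parameter objects
#'
#' Checks the semantic invariants of a parameter set or species network and
#' returns the violations as data rather than raising a condition. An empty
#' tibble means the object is valid.
#'
#' @param x An [mscm_params()], [msci_params()] or [species_network()] object.
#' @return A tibble with columns `field` and `rule`, one row per violation.
#' @examples
#' validate_params(msci_params(0.004, 0.002, 0.01, 0.002, phi = 0.2))
#' validate_params(msci_params(0.002, 0.004, 0.01, 0.002, phi = 0.2))
#' @export
validate_params <- function(x) UseMethod("validate_params")

violation <- function(field, rule) tibble(field = field, rule = rule)

no_violations <- function() tibble(field = character(), rule = character())

#' @export
validate_params.mscm_params <- function(x) {
  v <- no_violations()
  for (nm in c("thetaA", "thetaB", "thetaR", "thetaT")) {
    if (x[[nm]] <= 0) v <- rbind(v, violation(nm, "theta must be > 0"))
  }
  if (x$tauT < 0) v <- rbind(v, violation("tauT", "tauT must be >= 0"))
  if (x$tauT >= x$tauR) {
    v <- rbind(v, violation("tauT", "must satisfy tauT < tauR"))
  }
  if (x$M < 0) v <- rbind(v, violation("M", "migration rate must be >= 0"))
  if (x$variant == "im" && x$tauT != 0) {
    v <- rbind(v, violation("tauT", "IM variant requires tauT = 0"))
  }
  v
}

#' @export
validate_params.msci_params <- function(x) {
  v <- no_violations()
  for (nm in c("thetaR", "thetaS")) {
    if (x[[nm]] <= 0) v <- rbind(v, violation(nm, "theta must be > 0"))
  }
  for (nm in c("thetaA", "thetaB", "thetaH")) {
    if (!is.na(x[[nm]]) && x[[nm]] <= 0) {
      v <- rbind(v, violation(nm, "theta must be > 0 when given"))
    }
  }
  if (x$tauS < 0) v <- rbind(v, violation("tauS", "tauS must be >= 0"))
  if (x$tauS >= x$tauR) {
    v <- rbind(v, violation("tauS", "must satisfy tauS < tauR"))
  }
  if (x$phi < 0 || x$phi > 1) {
    v <- rbind(v, violation("phi", "phi must lie in [0, 1]"))
  }
  v
}

stop_if_invalid <- function(x) {
  v <- validate_params(x)
  if (nrow(v)) {
    abort(paste0("invalid parameters: ",
                 paste(sprintf("%s (%s)", v$field, v$rule), collapse = "; ")))
  }
  invisible(x)
}

#' Identifiable parameter subset for one sequence per species
#'
#' @param params An [msci_params()] object.
#' @return Character vector of the identifiable parameter names in the
#'   pairwise (one sequence per species) data regime.
#' @export
identifiable_params <- function(params) {
  stopifnot(inherits(params, "msci_params"))
  c("tauR", "tauS", "thetaR", "thetaS", "phi")
}

#' @export
print.mscm_params <- function(x, ...) {
  cat(sprintf("<mscm_params: %s>\n", toupper(x$variant)))
  cat(sprintf("  tauR = %g, tauT = %g\n", x$tauR, x$tauT))
  cat(sprintf("  thetaA = %g, thetaB = %g, thetaR = %g, thetaT = %g\n",
              x$thetaA, x$thetaB, x$thetaR, x$thetaT))
  cat(sprintf("  M = %g  (w = 4M/thetaB = %g)\n", x$M,
              migration_rate_scaled(x)))
  invisible(x)
}

#' @export
print.msci_params <- function(x, ...) {
  cat("<msci_params>\n")
  cat(sprintf("  tauR = %g, tauS = %g\n", x$tauR, x$tauS))
  cat(sprintf("  thetaR = %g, thetaS = %g, phi = %g\n",
              x$thetaR, x$thetaS, x$phi))
  cat(sprintf("  thetaA = %s, thetaB = %s, thetaH = %s (non-identifiable for S=1)\n",
              format(x$thetaA), format(x$thetaB), format(x$thetaH)))
  invisible(x)
}
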