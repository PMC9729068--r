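# shared model fixtures, built in code

fig1_im <- function() preset_scenario("fig1-im")$params
fig1_iim <- function() preset_scenario("fig1-iim")$params
fig1_sc <- function() preset_scenario("fig1-sc")$params

msci_truth <- function(phi = 0.2) {
  msci_params(tauR = 0.004, tauS = 0.002, thetaR = 0.01, thetaS = 0.002,
              phi = phi, thetaA = 0.002, thetaB = 0.01, thetaH = 0.01)
}

# randomised-but-reproducible parameter grid for property tests
random_mscm_grid <- function(k, seed = 42) {
  withr::with_seed(seed, {
    lapply(seq_len(k), function(i) {
      variant <- sample(c("im", "iim", "sc"), 1)
      tauR <- runif(1, 1e-3, 0.05)
      mscm_params(variant,
                  tauR = tauR,
                  tauT = if (variant == "im") 0 else runif(1, 1e-4, tauR * 0.9),
                  thetaA = runif(1, 1e-4, 0.05),
                  thetaB = runif(1, 1e-3, 0.05),
                  thetaR = runif(1, 1e-3, 0.05),
                  M = runif(1, 0, 2))
    })
  })
}

random_msci_grid <- function(k, seed = 43) {
  withr::with_seed(seed, {
    lapply(seq_len(k), function(i) {
      tauR <- runif(1, 1e-3, 0.05)
      msci_params(tauR = tauR, tauS = runif(1, 0, tauR * 0.9),
                  thetaR = runif(1, 1e-3, 0.05),
                  thetaS = runif(1, 1e-4, 0.05),
                  phi = runif(1))
    })
  })
}

# generator matrix of the coalescent-with-migration chain, for the
# matrix-exponential oracle
mscm_generator <- function(w, thetaA) {
  matrix(c(-w, w, 0,
           0, -2 / thetaA, 2 / thetaA,
           0, 0, 0),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("AB", "AA", "A"), c("AB", "AA", "A")))
}
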