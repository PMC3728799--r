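# Independent brute-force oracles, written from first principles with their
# own parametrization (direct stepwise-ratio speciation, grid search +
# bisection) so they share no code path with the package solver.

# Brute-force equilibrium pH for media containing HCl, NaOH and sodium
# phosphates. totals: named list/vector with any of hcl, naoh, na3po4,
# na2hpo4, nah2po4 (mol/L).
oracle_ph <- function(totals, mode = c("ideal", "davies")) {
  mode <- match.arg(mode)
  g <- function(nm) if (!is.null(totals[[nm]])) totals[[nm]] else 0
  cl <- g("hcl")
  na <- g("naoh") + 3 * g("na3po4") + 2 * g("na2hpo4") + g("nah2po4")
  pt <- g("na3po4") + g("na2hpo4") + g("nah2po4")
  K <- 10^(-c(2.148, 7.198, 12.35))
  Kw <- 1e-14

  balance <- function(h, gam) {
    # gam: activity coefficients for |z| = 1, 2, 3
    a_h <- gam[1] * h
    r1 <- K[1] / a_h            # gamma0/gamma1 ratio folded: gamma0 = 1,
    r1 <- r1 / gam[1]           # [H2PO4-]/[H3PO4] = K1 / (a_H * g1)
    r2 <- K[2] * gam[1] / (a_h * gam[2])
    r3 <- K[3] * gam[2] / (a_h * gam[3])
    den <- 1 + r1 + r1 * r2 + r1 * r2 * r3
    avg_charge <- (r1 + 2 * r1 * r2 + 3 * r1 * r2 * r3) / den
    oh <- Kw / (gam[1]^2 * h)
    h + na - cl - oh - pt * avg_charge
  }
  speciation_I <- function(h, gam) {
    a_h <- gam[1] * h
    r1 <- K[1] / (a_h * gam[1])
    r2 <- K[2] * gam[1] / (a_h * gam[2])
    r3 <- K[3] * gam[2] / (a_h * gam[3])
    den <- 1 + r1 + r1 * r2 + r1 * r2 * r3
    p <- pt * c(1, r1, r1 * r2, r1 * r2 * r3) / den
    oh <- Kw / (gam[1]^2 * h)
    0.5 * (h + oh + na + cl + sum(p * c(0, 1, 4, 9)))
  }
  solve_h <- function(gam) {
    ph_grid <- seq(0, 14, by = 0.01)
    fb <- vapply(10^(-ph_grid), balance, numeric(1), gam = gam)
    idx <- which(fb[-1] * fb[-length(fb)] <= 0)[1]
    if (is.na(idx)) stop("oracle: no sign change")
    lo <- 10^(-ph_grid[idx + 1]); hi <- 10^(-ph_grid[idx])
    for (i in 1:80) {
      mid <- sqrt(lo * hi)
      if (balance(mid, gam) * balance(hi, gam) <= 0) lo <- mid else hi <- mid
    }
    sqrt(lo * hi)
  }
  if (mode == "ideal") {
    h <- solve_h(c(1, 1, 1))
    return(-log10(h))
  }
  I <- 0
  for (it in 1:200) {
    lg <- if (I > 0) -0.509 * c(1, 4, 9) * (sqrt(I) / (1 + sqrt(I)) - 0.3 * I) else c(0, 0, 0)
    gam <- 10^lg
    h <- solve_h(gam)
    I_new <- speciation_I(h, gam)
    if (abs(I_new - I) < 1e-12 * max(1, I_new)) break
    I <- I_new
  }
  -log10(gam[1] * h)
}

# brute-force titration: smallest volume on a uniform grid bringing the
# mixture's pH within tol of the target
oracle_titrant_volume <- function(vessel_L, hcl_M, naoh_titrant_M, target_pH,
                                  tol = 0.01, dv = 1e-6, v_max = 2e-3) {
  v <- seq(0, v_max, by = dv)
  for (vi in v) {
    hcl_mix <- hcl_M * vessel_L / (vessel_L + vi)
    naoh_mix <- naoh_titrant_M * vi / (vessel_L + vi)
    ph <- oracle_ph(list(hcl = hcl_mix, naoh = naoh_mix), "ideal")
    if (abs(ph - target_pH) <= tol) return(vi)
  }
  NA_real_
}

# template physiology whose free parameters are deliberately displaced from
# the synthetic ground truth (calibration must find its way back)
perturbed_template <- function() {
  p <- unclass(default_physiology())
  p[["PA_si"]] <- 1
  p[["CL_hepatic"]] <- 15
  p[["Q_tissues"]] <- 50
  p[["F_unbound_factor"]] <- 1
  physiology_spec(p)
}
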