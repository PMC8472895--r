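# Independent oracles used across the suite.

# Two-flux boundary-value problem solved by numerical integration
# (deSolve::lsoda + shooting), independent of the closed form in
# kmForward(): dI/dz = -(S+K) I + S J, dJ/dz = -S I + (S+K) J with
# I(0) = 1, J(t) = 0. Returns R = J(0), T = I(t).
twoflux_ode_oracle <- function(mu_a, mu_s, g, t) {
  K <- 2 * mu_a
  S <- (3 * (1 - g) * mu_s - mu_a) / 4
  flux <- function(z, y, p)
    list(c(-(S + K) * y[1] + S * y[2], -S * y[1] + (S + K) * y[2]))
  j_end <- function(j0)
    deSolve::lsoda(c(1, j0), c(0, t), flux, NULL,
                   rtol = 1e-12, atol = 1e-14)[2, 3]
  j0 <- stats::uniroot(j_end, c(0, 1), tol = 1e-13)$root
  out <- deSolve::lsoda(c(1, j0), c(0, t), flux, NULL,
                        rtol = 1e-12, atol = 1e-14)
  list(rd = j0, td = unname(out[2, 2]))
}

# Reference slab from the classic multi-layer Monte Carlo validation
# literature (van de Hulst tables): mu_a = 10, mu_s = 90, g = 0.75,
# d = 0.02 cm, matched boundaries -> R_d = 0.09739, T_d = 0.66096.
vdh_slab <- list(mu_a = 10, mu_s = 90, g = 0.75, d = 0.02,
                 rd = 0.09739, td = 0.66096)

# Standard error of a binomial fraction estimate.
se_frac <- function(p, n) sqrt(p * (1 - p) / n)
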