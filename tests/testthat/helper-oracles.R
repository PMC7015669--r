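# Shared oracles and small fixtures, independent of the implementation paths
# they are used to check.

# numeric orientational average of exp(-b * Dpar * cos^2 theta) on the sphere
numeric_stick_mean <- function(f, Da_par, b) {
  f * stats::integrate(function(x) exp(-b * Da_par * x^2), 0, 1,
                       rel.tol = 1e-12)$value
}

# literature values of the first roots of dJ1/dx = 0
J1PRIME_ROOTS <- c(1.8411837813406593, 5.3314427735250326,
                   8.5363163663462858, 11.7060049025920845)

# population moment of a GEV density by numeric integration
gev_moment <- function(p, mu, sigma, xi, upper = Inf) {
  stats::integrate(function(x) x^p * dgev(x, mu, sigma, xi),
                   max(0, mu - sigma / xi + 1e-12), upper,
                   rel.tol = 1e-10)$value
}

# small deterministic decay fixture from the truncated power law
make_tpl_decay <- function(beta = 0.35, Da_perp = 8.6e-4, f_im = 0,
                           protocol = protocol_preset("connectom")) {
  b <- protocol_bvalues(protocol)
  b <- b[b > 0]
  spherical_mean_decay(b, truncated_powerlaw(beta, Da_perp, f_im, b))
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
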