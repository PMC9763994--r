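# Independent oracles used to validate the analytic machinery.

# Pr(p1 > p2) by quadrature written independently of the package internals
pe_oracle <- function(a1, b1, a2, b2) {
  integrate(function(u) dbeta(u, a2, b2) * pbeta(u, a1, b1, lower.tail = FALSE),
            0, 1, rel.tol = 1e-11, abs.tol = 1e-11)$value
}

# Monte Carlo completion oracle for the two-sample predictive probability:
# draw the response rate of each arm from its posterior, complete both arms
# with binomial futures, and apply the end-of-trial posterior decision.
ppp_mc_oracle <- function(x_t, n_t, N_t, x_c, n_c, N_c, prior = c(0.5, 0.5),
                          theta, n_draws = 1e5) {
  a0 <- prior[1]; b0 <- prior[2]
  pt <- rbeta(n_draws, a0 + x_t, b0 + n_t - x_t)
  pc <- rbeta(n_draws, a0 + x_c, b0 + n_c - x_c)
  yt <- rbinom(n_draws, N_t - n_t, pt)
  yc <- rbinom(n_draws, N_c - n_c, pc)
  states <- unique(cbind(yt, yc))
  pe_tab <- apply(states, 1, function(s)
    pe_oracle(a0 + x_t + s[1], b0 + N_t - x_t - s[1],
              a0 + x_c + s[2], b0 + N_c - x_c - s[2]))
  key <- paste(yt, yc)
  ind <- setNames(pe_tab > theta, paste(states[, 1], states[, 2]))
  mean(ind[key])
}
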