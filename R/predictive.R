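#' Two-sample posterior predictive probability of end-of-trial success
#'
#' The posterior predictive probability (PPP) is the probability, given the
#' data observed so far and the prior, that the experimental arm will be
#' declared efficacious over the control arm at full enrollment, i.e. that
#' `Pr(p_trt > p_ctrl | completed data) > theta` once both arms reach their
#' planned maxima.  It is computed by exact joint enumeration over the two
#' arms' beta-binomial predictive distributions: with `n*` future patients
#' per arm the sum runs over all `(n*_trt + 1) * (n*_ctrl + 1)` joint future
#' outcomes, whose predictive masses factorize because the arms are
#' independent.
#'
#' During trial conduct the PPP is compared with the predictive threshold
#' `theta_star`: enrollment in a comparison stops for futility when
#' `PPP < theta_star`.  With no future patients left the PPP degenerates to
#' the 0/1 indicator of the final posterior decision.
#'
#' @param x_trt,n_trt,N_trt Observed responses, observed patients, and
#'   planned maximum for the experimental arm.
#' @param x_ctrl,n_ctrl,N_ctrl Same for the control arm.
#' @param prior Shared [beta_prior()] for both arms.
#' @param theta Posterior threshold in (0, 1) defining end-of-trial success.
#'
#' @return The predictive probability, in `[0, 1]`.
#'
#' @examples
#' # early look of a 50 + 50 comparison, 4/20 vs 1/20 observed
#' predictive_prob(4, 20, 50, 1, 20, 50, theta = 0.9)
#' @export
predictive_prob <- function(x_trt, n_trt, N_trt, x_ctrl, n_ctrl, N_ctrl,
                            prior = beta_prior(), theta) {
  stopifnot(x_trt >= 0, x_trt <= n_trt, n_trt <= N_trt,
            x_ctrl >= 0, x_ctrl <= n_ctrl, n_ctrl <= N_ctrl,
            theta > 0, theta < 1)
  prior <- as_beta_prior(prior)
  ns_t <- N_trt - n_trt
  ns_c <- N_ctrl - n_ctrl
  w_t <- .bb_weights(x_trt, n_trt, ns_t, prior)
  w_c <- .bb_weights(x_ctrl, n_ctrl, ns_c, prior)
  M <- .pe_matrix(N_trt, N_ctrl, prior)
  Ind <- M[x_trt + 1 + 0:ns_t, x_ctrl + 1 + 0:ns_c, drop = FALSE] > theta
  as.numeric(t(w_t) %*% Ind %*% w_c)
}

# predictive weight vector over k = 0..ns future responses
.bb_weights <- function(x, n, ns, prior) {
  if (ns == 0) return(1)
  sh <- .proper_shapes(prior$a0 + x, prior$b0 + n - x)
  k <- 0:ns
  exp(lchoose(ns, k) + lbeta(sh$a + k, sh$b + ns - k) - lbeta(sh$a, sh$b))
}

# PPP over every reachable state at one interim look: entry
# [x_t + 1, x_c + 1] is the PPP at current counts (x_t of n_t) vs
# (x_c of n_c).  Two banded matrix products against the terminal decision
# surface give all states at once; cached per look and threshold so that
# grid calibration reuses trajectories across replicates.
.ppp_state_matrix <- function(n_t, N_t, n_c, N_c, prior, theta) {
  prior <- as_beta_prior(prior)
  key <- sprintf("ppp:%d,%d,%d,%d,%.10g,%.10g,%.10g",
                 n_t, N_t, n_c, N_c, prior$a0, prior$b0, theta)
  .cache_get_or(key, function() {
    Ind <- (.pe_matrix(N_t, N_c, prior) > theta) * 1
    Wt <- .bb_shift_matrix(n_t, N_t, prior)
    Wc <- .bb_shift_matrix(n_c, N_c, prior)
    P <- Wt %*% Ind %*% t(Wc)
    # clamp tiny negative / >1 rounding noise
    P[P < 0] <- 0
    P[P > 1] <- 1
    P
  })
}
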