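#' Beta-binomial posterior predictive mass function
#'
#' Probability of `k` responses among `size` future patients when the
#' response rate carries a `Beta(a, b)` posterior: the posterior predictive
#' distribution of future responses in an arm with `size = N - n` patients
#' yet to enroll.
#'
#' @param k Number of future responses (vectorized), `0 <= k <= size`.
#' @param size Number of future patients.
#' @param post A [update_posterior()] object or `c(a, b)` shape pair.
#'
#' @return Probability masses; they sum to one over `k = 0..size`.
#'
#' @examples
#' post <- update_posterior(beta_prior(), 3, 10)   # Beta(3.5, 7.5)
#' dbetabinom(0:5, size = 5, post = post)
#' @export
dbetabinom <- function(k, size, post) {
  p <- as_beta_posterior(post)
  stopifnot(size >= 0, size == round(size))
  out <- numeric(length(k))
  ok <- k >= 0 & k <= size & k == round(k)
  if (any(!ok)) stop("k must be integers in [0, size]", call. = FALSE)
  if (size == 0) return(as.numeric(k == 0))
  exp(lchoose(size, k) + lbeta(p$a + k, p$b + size - k) - lbeta(p$a, p$b))
}

# Shifted predictive-weight matrix for one arm: rows index the current
# response count x = 0..n, columns the completed count x_final = 0..N;
# entry [x + 1, x + k + 1] = Pr(k future responses | x of n observed).
# Row r of (W %*% A) is then the predictive expectation of A's rows over
# the arm's completion, which is what the joint PPP factorizes into.
.bb_shift_matrix <- function(n, N, prior) {
  prior <- as_beta_prior(prior)
  key <- sprintf("bbW:%d,%d,%.10g,%.10g", n, N, prior$a0, prior$b0)
  .cache_get_or(key, function() {
    ns <- N - n
    W <- matrix(0, n + 1, N + 1)
    k <- 0:ns
    for (x in 0:n) {
      sh <- .proper_shapes(prior$a0 + x, prior$b0 + n - x)
      lw <- lchoose(ns, k) + lbeta(sh$a + k, sh$b + ns - k) - lbeta(sh$a, sh$b)
      W[x + 1, x + k + 1] <- exp(lw)
    }
    W
  })
}
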