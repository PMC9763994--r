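#' Beta prior for a response rate
#'
#' Constructs the conjugate beta prior `Beta(a0, b0)` placed on the true
#' response probability of each trial arm.  The default `Beta(0.5, 0.5)`
#' (Jeffreys) prior carries the effective information of a single patient's
#' observation.  The improper limit `Beta(0, 0)` is admitted for sensitivity
#' analysis and is flagged; downstream posterior computations substitute a
#' small positive shape (`1e-6`) whenever an observed data configuration
#' would otherwise leave a posterior shape at zero.
#'
#' @param a0,b0 Non-negative shape hyperparameters.
#'
#' @return An object of class `beta_prior` with elements `a0`, `b0` and
#'   `improper` (logical).
#'
#' @examples
#' beta_prior()            # Jeffreys, the default
#' beta_prior(1, 1)        # uniform
#' beta_prior(0, 0)        # improper, flagged
#' @export
beta_prior <- function(a0 = 0.5, b0 = 0.5) {
  stopifnot(is.numeric(a0), is.numeric(b0), length(a0) == 1, length(b0) == 1,
            is.finite(a0), is.finite(b0), a0 >= 0, b0 >= 0)
  structure(list(a0 = a0, b0 = b0, improper = (a0 == 0 || b0 == 0)),
            class = "beta_prior")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) prior%s\n", x$a0, x$b0,
              if (x$improper) " [improper]" else ""))
  invisible(x)
}

as_beta_prior <- function(x) {
  if (inherits(x, "beta_prior")) return(x)
  if (is.numeric(x) && length(x) == 2) return(beta_prior(x[1], x[2]))
  stop("`prior` must be a beta_prior or a numeric vector of two shapes",
       call. = FALSE)
}

#' Conjugate posterior update for binomial data
#'
#' Given `x` responses in `n` patients and a `Beta(a0, b0)` prior, the
#' posterior of the response rate is `Beta(a0 + x, b0 + n - x)`.
#'
#' @param prior A [beta_prior()].
#' @param x Number of observed responses, `0 <= x <= n`.
#' @param n Number of observed patients.
#'
#' @return An object of class `beta_posterior` with shape parameters `a`
#'   and `b`.  An error is raised if either posterior shape is zero (an
#'   improper posterior, possible only under an improper prior).
#'
#' @examples
#' update_posterior(beta_prior(), x = 3, n = 10)  # Beta(3.5, 7.5)
#' @export
update_posterior <- function(prior, x, n) {
  prior <- as_beta_prior(prior)
  stopifnot(length(x) == 1, length(n) == 1, x >= 0, n >= 0, x <= n,
            x == round(x), n == round(n))
  a <- prior$a0 + x
  b <- prior$b0 + n - x
  if (a <= 0 || b <= 0)
    stop(sprintf(paste0("improper posterior Beta(%g, %g): a shape parameter ",
                        "is zero; use a proper prior or supply data with ",
                        "responses and non-responses"), a, b), call. = FALSE)
  structure(list(a = a, b = b), class = "beta_posterior")
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) posterior (mean %.4f)\n", x$a, x$b,
              x$a / (x$a + x$b)))
  invisible(x)
}

as_beta_posterior <- function(x) {
  if (inherits(x, "beta_posterior")) return(x)
  if (is.numeric(x) && length(x) == 2 && all(x > 0))
    return(structure(list(a = x[1], b = x[2]), class = "beta_posterior"))
  stop("expected a beta_posterior or a numeric vector of two positive shapes",
       call. = FALSE)
}

# substitute a tiny positive shape for zero shapes arising from an improper
# prior; returns shapes plus a flag saying whether substitution happened
.proper_shapes <- function(a, b, eps = 1e-6) {
  sub <- (a < eps) | (b < eps)
  list(a = pmax(a, eps), b = pmax(b, eps), substituted = any(sub))
}
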