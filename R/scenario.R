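#' True response-rate scenarios
#'
#' A scenario fixes the true response probabilities used to simulate trial
#' data: a control (standard of care) rate shared by all biomarker
#' subgroups and an experimental-treatment rate per subgroup, together with
#' the subgroup prevalences in the screened population.
#'
#' The case study uses three PD-L1 expression subgroups of equal
#' prevalence.  Under the null every rate is the 10% historical control
#' rate; under the alternative the treatment rates are 10%, 20% and 30% in
#' IC0, IC1 and IC2/3 (a predictive-biomarker pattern); the homogeneous
#' scenario puts a 30% treatment rate in every subgroup.
#'
#' @param p_ctrl Control response probability (shared across subgroups).
#' @param p_trt Named vector of treatment response probabilities, one per
#'   subgroup.
#' @param prevalence Subgroup prevalences, summing to one.
#'
#' @return A `trial_scenario` object.
#' @examples
#' scenario_null()
#' scenario_alternative()
#' @export
trial_scenario <- function(p_ctrl,
                           p_trt,
                           prevalence = rep(1 / length(p_trt), length(p_trt))) {
  stopifnot(length(p_ctrl) == 1, p_ctrl >= 0, p_ctrl <= 1,
            all(p_trt >= 0), all(p_trt <= 1),
            length(prevalence) == length(p_trt),
            all(prevalence >= 0), abs(sum(prevalence) - 1) < 1e-8)
  if (is.null(names(p_trt))) names(p_trt) <- ppd_subgroups()[seq_along(p_trt)]
  structure(list(p_ctrl = p_ctrl, p_trt = p_trt,
                 prevalence = setNames(prevalence, names(p_trt))),
            class = "trial_scenario")
}

#' @rdname trial_scenario
#' @export
scenario_null <- function() {
  trial_scenario(p_ctrl = 0.1, p_trt = c("IC0" = 0.1, "IC1" = 0.1, "IC2/3" = 0.1))
}

#' @rdname trial_scenario
#' @export
scenario_alternative <- function() {
  trial_scenario(p_ctrl = 0.1, p_trt = c("IC0" = 0.1, "IC1" = 0.2, "IC2/3" = 0.3))
}

#' @rdname trial_scenario
#' @export
scenario_homogeneous <- function() {
  trial_scenario(p_ctrl = 0.1, p_trt = c("IC0" = 0.3, "IC1" = 0.3, "IC2/3" = 0.3))
}

#' @export
print.trial_scenario <- function(x, ...) {
  cat("Trial scenario\n")
  cat("  control rate:", x$p_ctrl, "\n")
  cat("  treatment rates:",
      paste(sprintf("%s=%g", names(x$p_trt), x$p_trt), collapse = ", "), "\n")
  cat("  prevalence:",
      paste(sprintf("%.3g", x$prevalence), collapse = ", "), "\n")
  invisible(x)
}
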