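#' Decision-rule tables for trial conduct
#'
#' Once the monitoring thresholds are fixed, the stopping rule can be
#' tabulated in advance so that no mid-trial computation is needed: at each
#' interim look, for every possible control response count, the table gives
#' the minimum treatment response count for which enrollment continues
#' (predictive probability at least `theta_star`).  The final row of each
#' look table gives the efficacy boundary at full enrollment: the minimum
#' treatment count for which the posterior probability exceeds `theta`.
#'
#' For the enrichment design, tables are produced for both stages; at
#' stage 2 the treatment counts include the stage-1 responses carried
#' forward.
#'
#' @param config A [design_config()] with fixed thresholds.
#' @return A tibble with columns `stage`, `look`, `n_trt`, `n_ctrl`,
#'   `x_ctrl`, `min_x_trt_continue` (NA when no treatment count continues)
#'   and `boundary` (`"futility"` for interim looks, `"efficacy"` for the
#'   final analysis).
#' @examples
#' dt <- build_decision_table(design_config("pooled", 0.9, 0.1, n_arm = 20))
#' head(dt)
#' @export
build_decision_table <- function(config) {
  stopifnot(inherits(config, "design_config"))
  out <- .stage_decision_table(config, N_t = config$n_arm,
                               N_c = config$n_arm, offset_t = 0, stage = 1L)
  if (config$design == "enrichment") {
    half <- config$stage2_n / 2
    out2 <- .stage_decision_table(config, N_t = config$n_arm + half,
                                  N_c = half, offset_t = config$n_arm,
                                  stage = 2L)
    out <- dplyr::bind_rows(out, out2)
  }
  out
}

# one stage: interim looks at offset_t + k*interval (treatment) versus
# k*interval (control), final analysis at the maxima
.stage_decision_table <- function(config, N_t, N_c, offset_t, stage) {
  prior <- config$prior
  iv <- config$look_interval
  looks <- seq(iv, N_c, by = iv)
  looks <- looks[looks < N_c]
  rows <- lapply(seq_along(looks), function(k) {
    n_c <- looks[k]
    n_t <- offset_t + looks[k]
    P <- .ppp_state_matrix(n_t, N_t, n_c, N_c, prior, config$theta)
    cont <- P >= config$theta_star
    .boundary_rows(cont, stage, k, n_t, n_c, "futility")
  })
  Ind <- .pe_matrix(N_t, N_c, prior) > config$theta
  rows <- c(rows, list(.boundary_rows(Ind, stage, length(looks) + 1L,
                                      N_t, N_c, "efficacy")))
  dplyr::bind_rows(rows)
}

.boundary_rows <- function(flag, stage, look, n_t, n_c, boundary) {
  min_x <- apply(flag, 2, function(col) {
    w <- which(col)
    if (length(w)) w[1] - 1L else NA_integer_
  })
  tibble::tibble(stage = stage, look = look, n_trt = n_t, n_ctrl = n_c,
                 x_ctrl = seq_len(ncol(flag)) - 1L,
                 min_x_trt_continue = min_x, boundary = boundary)
}
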