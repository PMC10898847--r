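#' Map parameters between natural and unconstrained space
#'
#' Fitting happens on the real line: `alpha` passes through a logistic
#' (inverse-logit) transform so it stays in `[0, 1]`; `beta_mb`, `beta_mf`
#' and `beta_consistency` through an exponential so they stay positive;
#' `beta_rep` is unconstrained and maps through the identity. The two
#' functions are inverse bijections (round-trip error below 1e-9 in the
#' interior); `alpha` exactly 0 or 1 and betas exactly 0 are clipped at
#' 1e-9 with a warning, since their images lie at infinity.
#'
#' @param params a [parameter_set()] (or named vector).
#' @return `to_unconstrained`: an unnamed length-5 numeric `theta`;
#'   `to_natural`: a [parameter_set()].
#' @rdname transforms
#' @export
to_unconstrained <- function(params) {
  p <- as_param_vector(params)
  eps <- 1e-9
  if (p[1] <= 0 || p[1] >= 1 || any(p[c(2, 3, 5)] <= 0)) {
    warnf("boundary parameter value clipped at %g before transforming", eps)
    p[1] <- min(max(p[1], eps), 1 - eps)
    p[c(2, 3, 5)] <- pmax(p[c(2, 3, 5)], eps)
  }
  c(log(p[1] / (1 - p[1])), log(p[2]), log(p[3]), p[4], log(p[5]))
}

#' @param theta length-5 numeric vector on the unconstrained scale.
#' @rdname transforms
#' @export
to_natural <- function(theta) {
  stopifnot(length(theta) == 5)
  parameter_set(alpha = 1 / (1 + exp(-theta[1])),
                beta_mb = exp(theta[2]), beta_mf = exp(theta[3]),
                beta_rep = theta[4], beta_consistency = exp(theta[5]))
}
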