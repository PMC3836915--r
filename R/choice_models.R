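# Closed-form response probability kernels for the model family:
# Thurstone's law of comparative judgment (complete and Case V), the
# conditional logit choice model, the Rasch model, and the MAPR model that
# joins the last two.

#' Thurstone discriminal-dispersion specification
#'
#' Parameters of the complete law of comparative judgment: the discriminal
#' dispersions of the two stimuli and the correlation between their
#' discriminal processes.
#'
#' @param sigma_s,sigma_t Positive discriminal dispersions.
#' @param rho Correlation between the two discriminal processes, in
#'   \[-1, 1\].
#' @return An object of class `thurstone_spec`.
#' @export
thurstone_spec <- function(sigma_s = 1, sigma_t = 1, rho = 0) {
  if (sigma_s <= 0 || sigma_t <= 0) stop("dispersions must be positive")
  if (rho < -1 || rho > 1) stop("rho must lie in [-1, 1]")
  structure(list(sigma_s = sigma_s, sigma_t = sigma_t, rho = rho),
            class = "thurstone_spec")
}

#' Comparative dispersion of a Thurstone pair
#'
#' \eqn{\sqrt{\sigma_s^2 + \sigma_t^2 - 2\rho\sigma_s\sigma_t}}: the
#' standard deviation of the difference of the two discriminal processes.
#'
#' @param spec A `thurstone_spec`.
#' @return Non-negative scalar.
#' @export
comparative_dispersion <- function(spec) {
  stopifnot(inherits(spec, "thurstone_spec"))
  sqrt(max(0, spec$sigma_s^2 + spec$sigma_t^2 -
             2 * spec$rho * spec$sigma_s * spec$sigma_t))
}

#' Complete law of comparative judgment
#'
#' Probability that state s is judged better than state t under Thurstone's
#' complete model: \eqn{\Phi\big((v_s - v_t) / \sqrt{\sigma_s^2 + \sigma_t^2
#' - 2\rho\sigma_s\sigma_t}\big)} with \eqn{\Phi} the standard normal CDF.
#'
#' @param v_s,v_t Scale values of the two states.
#' @param spec A `thurstone_spec`.
#' @return Probability in (0, 1).
#' @export
thurstone_lcj_prob <- function(v_s, v_t, spec = thurstone_spec()) {
  disp <- comparative_dispersion(spec)
  if (disp <= 0) {
    stop("degenerate comparative dispersion (sigma_s == sigma_t, rho == 1)")
  }
  stats::pnorm((v_s - v_t) / disp)
}

#' Case V law of comparative judgment
#'
#' The basic Thurstone form with equal, uncorrelated discriminal
#' dispersions.  The scale unit is arbitrary; by default the *comparative*
#' dispersion is normalized to 1, giving \eqn{P = \Phi(v_s - v_t)}.  Set
#' `unit_dispersions = TRUE` for the convention of unit per-stimulus
#' dispersions, i.e. \eqn{P = \Phi((v_s - v_t)/\sqrt 2)}.
#'
#' @param v_s,v_t Scale values.
#' @param unit_dispersions Use unit per-stimulus dispersions instead of unit
#'   comparative dispersion.
#' @return Probability in (0, 1).
#' @export
thurstone_case5_prob <- function(v_s, v_t, unit_dispersions = FALSE) {
  denom <- if (unit_dispersions) sqrt(2) else 1
  stats::pnorm((v_s - v_t) / denom)
}

#' Conditional-logit choice probabilities
#'
#' McFadden's conditional logit: the probability that each alternative in a
#' choice set is chosen is the softmax of the alternatives' values.  For a
#' two-element set this reduces to the logistic of the value difference.
#' Evaluated through a log-sum-exp shift for numerical stability.
#'
#' @param values Numeric vector of alternative values (length K >= 2).
#' @return Probability vector summing to 1.
#' @export
clogit_prob <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("choice set needs at least 2 alternatives")
  if (any(!is.finite(values))) stop("values must be finite")
  e <- exp(values - max(values))
  e / sum(e)
}

#' Rasch response probability
#'
#' Probability that the presented state (value `v`) is judged better than
#' the respondent's own position `theta`:
#' \eqn{P = \exp(v - \theta) / (1 + \exp(v - \theta))}.  Strictly increasing
#' in `v` and decreasing in `theta`; equals the first component of the
#' two-alternative conditional logit with values `(v, theta)`.
#'
#' @param theta Person location(s) on the latent health continuum.
#' @param v State value(s).
#' @return Probability (vectorized over inputs).
#' @export
rasch_prob <- function(theta, v) {
  stopifnot(all(is.finite(theta)), all(is.finite(v)))
  stats::plogis(v - theta)
}

#' MAPR response probability
#'
#' The Rasch kernel with the state value linearly restricted to the
#' attribute decomposition \eqn{v_s = z_s \cdot \gamma}: the probability
#' that the presented multi-attribute state is judged better than the
#' respondent's own state.
#'
#' @param own_theta The respondent's location.  Either a free person
#'   parameter, or (structured mode) the value of the respondent's own
#'   state, `state_value(own_profile, vf)`.
#' @param profile Presented state: a `state_profile` or code string.
#' @param vf A `value_function`.
#' @return Probability in (0, 1).
#' @export
mapr_prob <- function(own_theta, profile, vf) {
  rasch_prob(own_theta, state_value(profile, vf))
}
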