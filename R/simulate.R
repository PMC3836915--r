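# Synthetic-data engine: patient populations spread over the latent
# health continuum, binary MAPR/Rasch response generation, random-utility
# choice simulation, and deterministic Guttman data.

#' Sample a patient population on the latent continuum
#'
#' Draws `n` person locations theta from the requested distribution.  Good
#' Rasch-type estimation needs respondents spread over the whole
#' unidimensional scale rather than clustered at one location, so the
#' default is a unit normal; a uniform option is available.  If an
#' attribute system and value function are supplied, each respondent is
#' also assigned an own state: the enumerated state whose value is nearest
#' to their theta (first-stage self-classification consistent with the
#' latent location; ties go to the milder, higher-valued state).
#'
#' @param n Number of respondents (>= 0).
#' @param theta_dist Distribution spec: a list with `family` (`"normal"` or
#'   `"uniform"`) and its parameters (`mean`/`sd`, or `min`/`max`).
#' @param seed Integer seed.
#' @param system,vf Optional `attribute_system` and `value_function` used
#'   to assign own states.
#' @param snap_theta If `TRUE`, each theta is replaced by the value of the
#'   assigned own state, so person locations coincide exactly with the
#'   structured (own-state based) locations of the two-stage mechanism.
#' @return An object of class `population`: data.frame-like list with
#'   `id`, `theta` and (if a system was given) `own_code`.
#' @export
sample_population <- function(n, theta_dist = list(family = "normal",
                                                   mean = 0, sd = 1),
                              seed, system = NULL, vf = NULL,
                              snap_theta = FALSE) {
  if (n < 0) stop("n must be >= 0")
  fam <- theta_dist$family
  if (is.null(fam)) stop("theta_dist needs a 'family' field")
  theta <- with_seed(seed, {
    if (fam == "normal") {
      m <- theta_dist$mean %||% 0
      s <- theta_dist$sd %||% 1
      if (s <= 0) stop("sd must be positive")
      stats::rnorm(n, m, s)
    } else if (fam == "uniform") {
      lo <- theta_dist$min %||% -1
      hi <- theta_dist$max %||% 1
      if (hi <= lo) stop("uniform spec needs max > min")
      stats::runif(n, lo, hi)
    } else {
      stop("unknown theta distribution family: ", fam)
    }
  })
  pop <- list(id = seq_len(n), theta = theta, own_code = NULL)
  if (!is.null(system)) {
    if (is.null(vf)) stop("own-state assignment needs a value function")
    states <- enumerate_states(system)
    values <- vapply(states, state_value, numeric(1), vf = vf)
    # nearest state value; ties -> milder (higher-valued) state
    ord <- order(values, decreasing = TRUE)
    values_sorted <- values[ord]
    pick <- vapply(theta, function(th) {
      ord[which.min(abs(values_sorted - th))]
    }, integer(1))
    pop$own_code <- profile_codes(states)[pick]
    if (snap_theta) pop$theta <- values[pick]
  }
  structure(pop, class = "population")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.population <- function(x, ...) {
  cat("Population of", length(x$id), "respondents")
  if (length(x$id)) {
    cat("; theta range [", round(min(x$theta), 2), ", ",
        round(max(x$theta), 2), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Simulate binary MAPR responses
#'
#' For every `mapr-binary` choice set, draws the respondent's answer to
#' "Is this health state better than your own health state?" as a
#' Bernoulli variable with probability
#' \eqn{P(1) = \mathrm{logistic}(v_s - \theta_r)}, the MAPR/Rasch kernel.
#' Presented `dead` alternatives use `dead_value` as their state value.
#' Random numbers are streamed per respondent (a deterministic substream
#' seed per respondent id), so reordering choice sets does not change any
#' respondent's answers.
#'
#' @param pop A `population` (provides theta and respondent ids).
#' @param design List of `mapr-binary` `choice_set`s whose `respondent`
#'   fields refer to `pop$id`.
#' @param vf A `value_function` giving presented-state values.
#' @param seed Integer seed.
#' @param dead_value Latent value attached to a presented `dead`
#'   alternative (default `NULL`: designs containing dead states error).
#' @return A data.frame of response records: `respondent_id`,
#'   `choice_set_id`, `own_code`, `state_code`, `role`, `response`.
#' @export
simulate_mapr_responses <- function(pop, design, vf, seed,
                                    dead_value = NULL) {
  stopifnot(inherits(pop, "population"))
  resp_ids <- unlist(lapply(design, function(cs) cs$respondent))
  missing <- setdiff(unique(resp_ids), pop$id)
  if (length(missing)) {
    stop("design references respondents absent from the population: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  rows <- lapply(design, function(cs) {
    if (cs$type != "mapr-binary") {
      stop("simulate_mapr_responses expects mapr-binary choice sets")
    }
    own <- cs$alternatives[[which(cs$roles == "own")]]
    k <- which(cs$roles != "own")
    pres <- cs$alternatives[[k]]
    role <- cs$roles[k]
    v <- if (role == "dead") {
      if (is.null(dead_value)) stop("design presents 'dead' but no dead_value given")
      dead_value
    } else {
      state_value(pres, vf)
    }
    data.frame(respondent_id = cs$respondent, choice_set_id = cs$id,
               own_code = own$code, state_code = pres$code, role = role,
               value = v, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  theta <- pop$theta[match(tab$respondent_id, pop$id)]
  p <- rasch_prob(theta, tab$value)
  # per-respondent substreams: draw each respondent's answers in
  # choice-set order under their own seed
  tab$response <- NA_integer_
  for (r in unique(tab$respondent_id)) {
    idx <- which(tab$respondent_id == r)
    idx <- idx[order(tab$choice_set_id[idx])]
    u <- with_seed(substream_seed(seed, match(r, pop$id)),
                   stats::runif(length(idx)))
    tab$response[idx] <- as.integer(u < p[idx])
  }
  tab$value <- NULL
  tab
}

#' Simulate random-utility choices
#'
#' Draws total utilities \eqn{U_k = v_k + \varepsilon_k} for each
#' alternative and records the argmax, the random utility maximization
#' rule.  With IID Gumbel (extreme value type I) errors the choice
#' frequencies converge to the conditional-logit probabilities; with IID
#' normal errors pairwise frequencies converge to the Thurstone
#' probabilities \eqn{\Phi((v_s - v_t)/\sqrt 2)}.
#'
#' @param values Numeric vector of systematic values (length K >= 2).
#' @param error_family `"gumbel"` or `"normal"`.
#' @param n_draws Number of simulated decision makers (>= 1).
#' @param seed Integer seed.
#' @param scale Error scale; `0` gives the deterministic maximization
#'   limit (always the max-value alternative).
#' @return Named vector of choice frequencies (proportions summing to 1).
#' @export
simulate_rum_choices <- function(values, error_family = c("gumbel", "normal"),
                                 n_draws, seed, scale = 1) {
  error_family <- match.arg(error_family)
  values <- as.numeric(values)
  K <- length(values)
  if (K < 2) stop("need at least 2 alternatives")
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (scale < 0) stop("scale must be >= 0")
  choice <- with_seed(seed, {
    if (scale == 0) {
      rep(which.max(values), n_draws)
    } else {
      eps <- if (error_family == "gumbel") {
        matrix(-log(-log(stats::runif(n_draws * K))), n_draws, K)
      } else {
        matrix(stats::rnorm(n_draws * K), n_draws, K)
      }
      U <- sweep(scale * eps, 2, values, "+")
      max.col(U, ties.method = "first")
    }
  })
  freq <- tabulate(choice, nbins = K) / n_draws
  names(freq) <- names(values) %||% paste0("alt", seq_len(K))
  freq
}

#' Deterministic Guttman response data
#'
#' The error-free limit of the Rasch response process: respondent r agrees
#' that state s is better than their own state iff \eqn{v_s > \theta_r}.
#' The resulting person-by-state matrix is a perfect Guttman scalogram
#' (zero misfits after sorting).
#'
#' @param pop A `population` (theta vector).
#' @param states List of `state_profile` objects with distinct values.
#' @param vf A `value_function`.
#' @return Binary matrix, respondents in rows (named by id), states in
#'   columns (named by code).
#' @export
simulate_guttman_deterministic <- function(pop, states, vf) {
  stopifnot(inherits(pop, "population"))
  values <- vapply(states, state_value, numeric(1), vf = vf)
  if (anyDuplicated(values)) {
    warning("tied state values: Guttman ordering not strict")
  }
  m <- outer(pop$theta, values, function(th, v) as.integer(v > th))
  dimnames(m) <- list(pop$id, profile_codes(states))
  m
}
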