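# Maximum-likelihood estimation for the model family:
#   - pairwise conditional logit (Bradley-Terry form) for paired data,
#   - Rasch conditional ML (elementary symmetric functions) and joint ML,
#   - MAPR estimation of attribute weights gamma under the linear
#     restriction v = Z gamma, with free or structured person locations.
#
# All fits use analytic gradients, Newton-type updates, and report
# observed-information standard errors on the constrained
# parameterization.

# ---------------------------------------------------------------------
# elementary symmetric functions
# ---------------------------------------------------------------------

# gamma_0 .. gamma_J of eps via the summation recursion.  The whole-vector
# update uses the previous iteration's values (R evaluates the RHS fully),
# which is exactly the textbook recursion g_r <- g_r + eps * g_{r-1}.
esf <- function(eps) {
  J <- length(eps)
  g <- c(1, numeric(J))
  for (e in eps) {
    g[2:(J + 1)] <- g[2:(J + 1)] + e * g[1:J]
  }
  g
}

# Conditional sufficient statistics of a binary person x item matrix with
# optional NAs: persons grouped by their observed-item pattern; extreme
# (score 0 or all-observed) persons are uninformative and dropped.
cml_groups <- function(X) {
  obs <- !is.na(X)
  pat <- apply(obs, 1, function(o) paste(which(o), collapse = ","))
  groups <- list()
  excluded <- integer(0)
  for (p in unique(pat)) {
    rows <- which(pat == p)
    items <- which(obs[rows[1], ])
    if (length(items) == 0) next
    scores <- rowSums(X[rows, items, drop = FALSE])
    keep <- scores > 0 & scores < length(items)
    excluded <- c(excluded, rows[!keep])
    rows <- rows[keep]
    if (length(rows) == 0) next
    scores <- scores[keep]
    groups[[length(groups) + 1]] <- list(
      items = items,
      item_totals = colSums(X[rows, items, drop = FALSE]),
      n_r = tabulate(scores, nbins = length(items) - 1),
      n_persons = length(rows)
    )
  }
  list(groups = groups, excluded = excluded)
}

# Conditional negative log-likelihood, gradient and (optionally) observed
# information for full item-parameter vector v.
cml_objective <- function(v, groups, hessian = FALSE) {
  J <- length(v)
  nll <- 0
  grad <- numeric(J)
  H <- if (hessian) matrix(0, J, J) else NULL
  for (g in groups) {
    items <- g$items
    Jg <- length(items)
    vg <- v[items] - mean(v[items])    # shift-invariant; keeps exp() tame
    eps <- exp(vg)
    gam <- esf(eps)
    rs <- seq_len(Jg - 1)
    nll <- nll - sum(g$item_totals * vg) + sum(g$n_r * log(gam[rs + 1]))
    # E[x_s | score r] = eps_s * gamma_{r-1}(-s) / gamma_r
    gam_minus <- lapply(seq_len(Jg), function(s) esf(eps[-s]))
    pi_rs <- matrix(0, Jg - 1, Jg)   # rows: score r, cols: item s
    for (s in seq_len(Jg)) {
      pi_rs[, s] <- eps[s] * gam_minus[[s]][rs] / gam[rs + 1]
    }
    grad[items] <- grad[items] +
      as.vector(crossprod(pi_rs, g$n_r)) - g$item_totals
    if (hessian) {
      Hg <- matrix(0, Jg, Jg)
      for (s in seq_len(Jg)) {
        for (t in s:Jg) {
          if (s == t) {
            cov_r <- pi_rs[, s] * (1 - pi_rs[, s])
          } else {
            gm2 <- esf(eps[-c(s, t)])
            # E[x_s x_t | r] = eps_s eps_t gamma_{r-2}(-s,-t) / gamma_r
            est <- eps[s] * eps[t] *
              c(0, gm2[rs[-length(rs)]]) / gam[rs + 1]
            if (Jg == 2) est <- 0 * rs
            cov_r <- est - pi_rs[, s] * pi_rs[, t]
          }
          Hg[s, t] <- Hg[t, s] <- sum(g$n_r * cov_r)
        }
      }
      H[items, items] <- H[items, items] + Hg
    }
  }
  list(value = nll, gradient = grad, hessian = H)
}

# ---------------------------------------------------------------------
# fit result container
# ---------------------------------------------------------------------

new_fit_result <- function(model, estimates, se, vcov, loglik, gradient_norm,
                           converged, iterations, constraint,
                           excluded = integer(0),
                           non_estimable = character(0), extra = list()) {
  structure(c(list(model = model, estimates = estimates, se = se,
                   vcov = vcov, loglik = loglik,
                   gradient_norm = gradient_norm, converged = converged,
                   iterations = iterations, constraint = constraint,
                   excluded = excluded, non_estimable = non_estimable),
              extra),
            class = "mapr_fit")
}

#' @export
print.mapr_fit <- function(x, ...) {
  cat("Model:", x$model, " (constraint:", x$constraint, ")\n")
  cat("Log-likelihood:", format(x$loglik), " converged:", x$converged,
      "in", x$iterations, "iterations\n")
  est <- x$estimates
  show <- utils::head(seq_along(est), 12)
  out <- data.frame(estimate = est[show], se = x$se[show])
  rownames(out) <- names(est)[show]
  print(round(out, 4))
  if (length(est) > 12) cat("... (", length(est) - 12, " more)\n", sep = "")
  if (length(x$non_estimable)) {
    cat("Non-estimable:", paste(x$non_estimable, collapse = ", "), "\n")
  }
  if (length(x$excluded)) {
    cat(length(x$excluded), "respondents excluded (extreme scores)\n")
  }
  invisible(x)
}

apply_constraint <- function(est, vcov, constraint) {
  J <- length(est)
  if (constraint == "sumzero") {
    keep <- is.finite(est)
    est[keep] <- est[keep] - mean(est[keep])
    C <- diag(J) - 1 / sum(keep)
    C[, !keep] <- 0
    vcov <- C %*% vcov %*% t(C)
    dimnames(vcov) <- list(names(est), names(est))
  }
  list(estimates = est, vcov = vcov, se = sqrt(pmax(0, diag(vcov))))
}

# ---------------------------------------------------------------------
# Rasch conditional maximum likelihood
# ---------------------------------------------------------------------

#' Fit the Rasch model by conditional maximum likelihood
#'
#' Estimates state values from a binary person-by-state response matrix by
#' maximizing the likelihood conditional on each person's raw score, which
#' algebraically eliminates the person parameters: the separability
#' property that makes the state estimates invariant to the respondent
#' sample.  The conditional likelihood is evaluated through elementary
#' symmetric functions (summation recursion); optimization is Newton with
#' analytic gradient and observed information.
#'
#' Persons with extreme scores (all 0 or all 1 over their observed states)
#' carry no conditional information and are dropped.  A state whose
#' observed responses are all identical has a non-finite ML estimate; it is
#' reported as non-estimable and excluded from the fit.
#'
#' @param X Binary matrix (persons x states); `NA` entries allowed.
#' @param constraint Identification: `"ref"` fixes the first (or `ref`)
#'   state at 0, `"sumzero"` centers the estimates.
#' @param ref Column index or name of the reference state.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Maximum Newton iterations.
#' @return A `mapr_fit` with state-value estimates, observed-information
#'   standard errors (on the constrained parameterization), conditional
#'   log-likelihood and diagnostics.
#' @export
fit_rasch_cml <- function(X, constraint = c("ref", "sumzero"), ref = 1L,
                          tol = 1e-8, max_iter = 100L) {
  constraint <- match.arg(constraint)
  X <- as.matrix(X)
  if (length(X) == 0 || nrow(X) == 0 || ncol(X) < 2) {
    stop("need a non-empty matrix with at least 2 states")
  }
  if (!all(X %in% c(0, 1, NA))) stop("responses must be binary (0/1 or NA)")
  if (is.null(colnames(X))) colnames(X) <- paste0("state", seq_len(ncol(X)))
  items <- colnames(X)
  if (is.character(ref)) ref <- match(ref, items)

  cg <- cml_groups(X)
  if (length(cg$groups) == 0) {
    stop("no informative respondents (all raw scores extreme)")
  }
  # estimability: pooled totals over informative persons
  tot <- numeric(ncol(X))
  cnt <- numeric(ncol(X))
  for (g in cg$groups) {
    tot[g$items] <- tot[g$items] + g$item_totals
    cnt[g$items] <- cnt[g$items] + g$n_persons
  }
  non_est <- items[cnt == 0 | tot == 0 | tot == cnt]
  keep <- setdiff(seq_len(ncol(X)), match(non_est, items))
  if (length(non_est)) {
    warning("non-estimable states (all responses identical): ",
            paste(non_est, collapse = ", "))
    if (length(keep) < 2) stop("fewer than 2 estimable states")
    Xk <- X[, keep, drop = FALSE]
    cg <- cml_groups(Xk)
  } else {
    Xk <- X
  }
  Jk <- ncol(Xk)
  if (ref %in% match(non_est, items) || !(ref %in% keep)) ref <- keep[1]
  refk <- match(ref, keep)

  v <- numeric(Jk)
  iter <- 0L
  converged <- FALSE
  obj <- cml_objective(v, cg$groups, hessian = TRUE)
  repeat {
    iter <- iter + 1L
    g_free <- obj$gradient[-refk]
    if (max(abs(g_free)) < tol) {
      converged <- TRUE
      break
    }
    if (iter > max_iter) break
    H_free <- obj$hessian[-refk, -refk, drop = FALSE]
    step <- tryCatch(solve(H_free, g_free),
                     error = function(e) g_free / max(diag(H_free), 1))
    alpha <- 1
    repeat {
      v_new <- v
      v_new[-refk] <- v[-refk] - alpha * step
      obj_new <- cml_objective(v_new, cg$groups, hessian = FALSE)
      if (obj_new$value <= obj$value + 1e-12 || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    v <- v_new
    obj <- cml_objective(v, cg$groups, hessian = TRUE)
  }
  v <- v - v[refk]

  H_free <- obj$hessian[-refk, -refk, drop = FALSE]
  V_free <- tryCatch(solve(H_free), error = function(e) {
    matrix(NA_real_, nrow(H_free), ncol(H_free))
  })
  vcov <- matrix(0, ncol(X), ncol(X), dimnames = list(items, items))
  vcov[keep[-refk], keep[-refk]] <- V_free

  est <- rep(NA_real_, ncol(X))
  names(est) <- items
  est[keep] <- v
  cc <- apply_constraint(est, vcov, constraint)

  new_fit_result(
    model = "rasch_cml", estimates = cc$estimates, se = cc$se,
    vcov = cc$vcov, loglik = -obj$value,
    gradient_norm = max(abs(obj$gradient[-refk])),
    converged = converged, iterations = iter, constraint = constraint,
    excluded = cg$excluded, non_estimable = non_est
  )
}

# ---------------------------------------------------------------------
# Rasch joint maximum likelihood
# ---------------------------------------------------------------------

#' Fit the Rasch model by joint maximum likelihood
#'
#' Alternating Newton maximization over state values and person locations
#' (the classical JML procedure; its finite-sample bias is acknowledged,
#' not corrected).  Persons with extreme raw scores have non-finite
#' location estimates and are excluded.  Identification: the reference
#' state is fixed at 0 (the joint likelihood is invariant to a common
#' shift of all v and theta).
#'
#' @inheritParams fit_rasch_cml
#' @param max_iter Maximum alternation sweeps.
#' @return A `mapr_fit`; person locations in `$theta`.
#' @export
fit_rasch_jml <- function(X, constraint = c("ref", "sumzero"), ref = 1L,
                          tol = 1e-8, max_iter = 500L) {
  constraint <- match.arg(constraint)
  X <- as.matrix(X)
  if (length(X) == 0 || nrow(X) == 0 || ncol(X) < 2) {
    stop("need a non-empty matrix with at least 2 states")
  }
  if (!all(X %in% c(0, 1, NA))) stop("responses must be binary (0/1 or NA)")
  if (is.null(colnames(X))) colnames(X) <- paste0("state", seq_len(ncol(X)))
  items <- colnames(X)
  if (is.character(ref)) ref <- match(ref, items)

  obs <- !is.na(X)
  score <- rowSums(X * obs, na.rm = TRUE)
  n_obs <- rowSums(obs)
  keep_p <- score > 0 & score < n_obs
  excluded <- which(!keep_p)
  if (length(excluded)) {
    warning(length(excluded),
            " persons with extreme scores excluded from JML")
  }
  Xk <- X[keep_p, , drop = FALSE]
  if (nrow(Xk) == 0) stop("no persons with non-extreme scores")
  tot <- colSums(Xk, na.rm = TRUE)
  nob <- colSums(!is.na(Xk))
  non_est <- items[nob == 0 | tot == 0 | tot == nob]
  if (length(non_est)) {
    warning("non-estimable states (all responses identical): ",
            paste(non_est, collapse = ", "))
  }
  keep_i <- setdiff(seq_along(items), match(non_est, items))
  if (!(ref %in% keep_i)) ref <- keep_i[1]
  Xi <- Xk[, keep_i, drop = FALSE]
  J <- ncol(Xi)
  N <- nrow(Xi)

  v <- numeric(J)
  theta <- numeric(N)
  iter <- 0L
  converged <- FALSE
  grad_norm <- Inf
  repeat {
    iter <- iter + 1L
    eta <- outer(-theta, v, "+")
    P <- stats::plogis(eta)
    P[is.na(Xi)] <- NA
    # item step (theta fixed): one Newton update per item
    g_v <- colSums(Xi - P, na.rm = TRUE)
    h_v <- colSums(P * (1 - P), na.rm = TRUE)
    v <- v + g_v / pmax(h_v, 1e-12)
    shift <- v[match(ref, keep_i)]   # re-anchor without changing v - theta
    v <- v - shift
    theta <- theta - shift
    # person step (v fixed)
    eta <- outer(-theta, v, "+")
    P <- stats::plogis(eta)
    P[is.na(Xi)] <- NA
    g_t <- rowSums(P - Xi, na.rm = TRUE)      # d loglik / d theta
    h_t <- rowSums(P * (1 - P), na.rm = TRUE)
    theta <- theta + g_t / pmax(h_t, 1e-12)
    # joint gradient norm
    eta <- outer(-theta, v, "+")
    P <- stats::plogis(eta)
    P[is.na(Xi)] <- NA
    g_v <- colSums(Xi - P, na.rm = TRUE)
    g_t <- rowSums(P - Xi, na.rm = TRUE)
    grad_norm <- max(abs(c(g_v[-match(ref, keep_i)], g_t)))
    if (grad_norm < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  loglik <- sum(Xi * log(P) + (1 - Xi) * log(1 - P), na.rm = TRUE)

  # observed-information SEs for v given theta (profile information)
  h_v <- colSums(P * (1 - P), na.rm = TRUE)
  se_k <- 1 / sqrt(pmax(h_v, 1e-12))
  se_k[match(ref, keep_i)] <- 0

  est <- rep(NA_real_, length(items))
  names(est) <- items
  est[keep_i] <- v
  vcov <- matrix(0, length(items), length(items),
                 dimnames = list(items, items))
  diag(vcov)[keep_i] <- se_k^2
  cc <- apply_constraint(est, vcov, constraint)
  theta_full <- rep(NA_real_, nrow(X))
  theta_full[keep_p] <- theta
  if (constraint == "sumzero") {
    theta_full <- theta_full - mean(est[keep_i] - cc$estimates[keep_i])
  }

  new_fit_result(
    model = "rasch_jml", estimates = cc$estimates, se = cc$se,
    vcov = cc$vcov, loglik = loglik, gradient_norm = grad_norm,
    converged = converged, iterations = iter, constraint = constraint,
    excluded = excluded, non_estimable = non_est,
    extra = list(theta = theta_full)
  )
}

# ---------------------------------------------------------------------
# weighted logistic Newton (shared by clogit and MAPR fits)
# ---------------------------------------------------------------------

logistic_newton <- function(X, y, weights = NULL, offset = NULL,
                            tol = 1e-10, max_iter = 100L) {
  if (is.null(weights)) weights <- rep(1, length(y))
  if (is.null(offset)) offset <- rep(0, length(y))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- numeric(ncol(X))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta) + offset
    p <- stats::plogis(eta)
    grad <- drop(crossprod(X, weights * (y - p)))
    if (max(abs(grad)) < tol || iter > max_iter) break
    W <- weights * p * (1 - p)
    H <- crossprod(X * W, X)
    beta <- beta + solve(H, grad)
  }
  eta <- drop(X %*% beta) + offset
  p <- stats::plogis(eta)
  W <- weights * p * (1 - p)
  list(
    coef = beta,
    loglik = sum(weights * (y * log(p) + (1 - y) * log1p(-p))),
    grad = drop(crossprod(X, weights * (y - p))),
    hessian = crossprod(X * W, X),
    fitted = p,
    converged = max(abs(drop(crossprod(X, weights * (y - p))))) < tol * 10,
    iterations = iter
  )
}

# ---------------------------------------------------------------------
# pairwise conditional logit
# ---------------------------------------------------------------------

#' Fit the conditional-logit model to paired-comparison data
#'
#' ML estimation of state values from pairwise choices under the
#' conditional logit: the probability that state s beats state t is
#' \eqn{\mathrm{logistic}(v_s - v_t)} (Bradley-Terry form).  For two
#' states the estimated difference has the closed form
#' \eqn{\log(w_{st}/w_{ts})}.
#'
#' States that win or lose *every* comparison they appear in sit at the
#' likelihood boundary (complete separation); they are flagged, reported
#' with non-finite estimates, and excluded from the finite optimization.
#'
#' @param data Either one row per judgment with columns `winner`, `loser`
#'   (state labels), or aggregated counts with columns `s`, `t`, `n_st`,
#'   `n_ts` (wins of s over t and of t over s).
#' @param states Optional character vector fixing the state set/order.
#' @param constraint `"ref"` (first state at 0) or `"sumzero"`.
#' @param tol,max_iter Newton controls.
#' @return A `mapr_fit`; separated states in `$separated`.
#' @export
fit_clogit_pairs <- function(data, states = NULL,
                             constraint = c("ref", "sumzero"),
                             tol = 1e-10, max_iter = 100L) {
  constraint <- match.arg(constraint)
  agg <- aggregate_pairs(data)
  if (is.null(states)) {
    states <- sort(unique(c(agg$s, agg$t)))
  }
  check_pair_connectivity(agg, states)

  wins <- losses <- stats::setNames(numeric(length(states)), states)
  for (i in seq_len(nrow(agg))) {
    wins[agg$s[i]] <- wins[agg$s[i]] + agg$n_st[i]
    losses[agg$s[i]] <- losses[agg$s[i]] + agg$n_ts[i]
    wins[agg$t[i]] <- wins[agg$t[i]] + agg$n_ts[i]
    losses[agg$t[i]] <- losses[agg$t[i]] + agg$n_st[i]
  }
  sep_hi <- states[wins > 0 & losses == 0]
  sep_lo <- states[losses > 0 & wins == 0]
  separated <- c(sep_hi, sep_lo)
  if (length(separated)) {
    warning("complete separation for states: ",
            paste(separated, collapse = ", "),
            " (estimates at the boundary, reported non-finite)")
  }
  keep <- setdiff(states, separated)
  if (length(keep) < 2) {
    est <- stats::setNames(rep(NA_real_, length(states)), states)
    est[sep_hi] <- Inf
    est[sep_lo] <- -Inf
    if (length(keep) == 1) est[keep] <- 0
    vc <- matrix(NA_real_, length(states), length(states),
                 dimnames = list(states, states))
    return(new_fit_result("clogit_pairs", est, sqrt(diag(vc)), vc,
                          loglik = NA_real_, gradient_norm = NA_real_,
                          converged = FALSE, iterations = 0L,
                          constraint = constraint,
                          extra = list(separated = separated)))
  }
  sub <- agg[agg$s %in% keep & agg$t %in% keep, , drop = FALSE]
  # design rows: ordered comparison (s over t) -> x = e_s - e_t, y = 1
  Xr <- matrix(0, 2 * nrow(sub), length(keep),
               dimnames = list(NULL, keep))
  yr <- wr <- numeric(2 * nrow(sub))
  for (i in seq_len(nrow(sub))) {
    si <- match(sub$s[i], keep)
    ti <- match(sub$t[i], keep)
    Xr[2 * i - 1, si] <- 1; Xr[2 * i - 1, ti] <- -1
    yr[2 * i - 1] <- 1; wr[2 * i - 1] <- sub$n_st[i]
    Xr[2 * i, si] <- 1; Xr[2 * i, ti] <- -1
    yr[2 * i] <- 0; wr[2 * i] <- sub$n_ts[i]
  }
  use <- wr > 0
  fit <- logistic_newton(Xr[use, -1, drop = FALSE], yr[use], wr[use],
                         tol = tol, max_iter = max_iter)
  v <- c(0, fit$coef)
  names(v) <- keep
  V_free <- solve(fit$hessian)
  est <- stats::setNames(rep(NA_real_, length(states)), states)
  est[keep] <- v
  est[sep_hi] <- Inf
  est[sep_lo] <- -Inf
  vcov <- matrix(0, length(states), length(states),
                 dimnames = list(states, states))
  vcov[keep[-1], keep[-1]] <- V_free
  cc <- apply_constraint(est, vcov, constraint)
  new_fit_result(
    model = "clogit_pairs", estimates = cc$estimates, se = cc$se,
    vcov = cc$vcov, loglik = fit$loglik,
    gradient_norm = max(abs(fit$grad)),
    converged = fit$converged, iterations = fit$iterations,
    constraint = constraint,
    extra = list(separated = separated)
  )
}

aggregate_pairs <- function(data) {
  if (all(c("winner", "loser") %in% names(data))) {
    key <- ifelse(data$winner < data$loser,
                  paste(data$winner, data$loser, sep = "\r"),
                  paste(data$loser, data$winner, sep = "\r"))
    out <- lapply(split(seq_len(nrow(data)), key), function(idx) {
      ab <- strsplit(key[idx[1]], "\r", fixed = TRUE)[[1]]
      data.frame(s = ab[1], t = ab[2],
                 n_st = sum(data$winner[idx] == ab[1]),
                 n_ts = sum(data$winner[idx] == ab[2]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  } else if (all(c("s", "t", "n_st", "n_ts") %in% names(data))) {
    data.frame(s = as.character(data$s), t = as.character(data$t),
               n_st = data$n_st, n_ts = data$n_ts,
               stringsAsFactors = FALSE)
  } else {
    stop("pair data needs columns winner/loser or s/t/n_st/n_ts")
  }
}

check_pair_connectivity <- function(agg, states) {
  comp <- stats::setNames(seq_along(states), states)
  find <- function(x) {
    while (comp[x] != x) x <- comp[x]
    x
  }
  for (i in seq_len(nrow(agg))) {
    if (agg$n_st[i] + agg$n_ts[i] == 0) next
    a <- find(match(agg$s[i], states))
    b <- find(match(agg$t[i], states))
    if (a != b) comp[b] <- a
  }
  roots <- vapply(seq_along(states), find, numeric(1))
  if (length(unique(roots)) > 1) {
    parts <- split(states, roots)
    stop("comparison graph is disconnected; components: ",
         paste(vapply(parts, paste, character(1), collapse = ","),
               collapse = " | "))
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------
# MAPR estimation
# ---------------------------------------------------------------------

# Build the row design matrix of presented states (plus a 'dead' column
# when the data contain dead comparisons) and the own-state matrix.
mapr_design_matrices <- function(responses, system) {
  needed <- c("respondent_id", "own_code", "state_code", "role", "response")
  missing <- setdiff(needed, names(responses))
  if (length(missing)) {
    stop("response data lacks columns: ", paste(missing, collapse = ", "))
  }
  if (!all(responses$response %in% c(0, 1))) {
    stop("responses must be binary 0/1")
  }
  if (!all(responses$role %in% c("hypothetical", "dead"))) {
    stop("presented roles must be 'hypothetical' or 'dead'")
  }
  has_dead <- any(responses$role == "dead")
  p <- system$z_length + has_dead
  Z <- matrix(0, nrow(responses), p)
  colnames(Z) <- c(system$z_names, if (has_dead) "dead")
  hyp <- responses$role == "hypothetical"
  codes <- unique(responses$state_code[hyp])
  zmap <- t(vapply(codes, function(cd) encode_profile(cd, system),
                   numeric(system$z_length)))
  Z[hyp, seq_len(system$z_length)] <-
    zmap[match(responses$state_code[hyp], codes), , drop = FALSE]
  if (has_dead) Z[!hyp, p] <- 1
  own_codes <- unique(responses$own_code)
  omap <- t(vapply(own_codes, function(cd) encode_profile(cd, system),
                   numeric(system$z_length)))
  Zown <- matrix(0, nrow(responses), p)
  colnames(Zown) <- colnames(Z)
  Zown[, seq_len(system$z_length)] <-
    omap[match(responses$own_code, own_codes), , drop = FALSE]
  list(Z = Z, Zown = Zown, has_dead = has_dead)
}

#' Fit the MAPR model
#'
#' Maximum-likelihood estimation of the attribute weights gamma under the
#' linear restriction \eqn{v_s = z_s \cdot \gamma} on the Rasch state
#' parameters, from binary own-versus-presented judgments.
#'
#' Two modes for the person locations:
#' \describe{
#'   \item{`"free"`}{theta_r is a free parameter per respondent (joint ML,
#'     alternating Newton over gamma and theta).  Respondents answering
#'     all 0 or all 1 have non-finite locations; they are excluded and
#'     listed.}
#'   \item{`"structured"`}{theta_r is tied to the first-stage
#'     self-classification, \eqn{\theta_r = z_{own} \cdot \gamma}; the
#'     model is then a plain logistic regression on the design-vector
#'     difference \eqn{z_s - z_{own}} and every respondent is retained.}
#' }
#'
#' Rows with role `"dead"` add one free pseudo-state parameter for the
#' state dead, estimable when designs place dead against bad states.
#' With a saturated design matrix (one dummy per non-reference state) the
#' free-mode fit reproduces the Rasch joint-ML state estimates.
#'
#' @param responses Data.frame of judgment records: `respondent_id`,
#'   `own_code`, `state_code`, `role` (`hypothetical`/`dead`), `response`
#'   (1 = presented state judged better than own state).
#' @param system The `attribute_system` behind the state codes.
#' @param theta_mode `"free"` or `"structured"`.
#' @param tol Gradient max-norm convergence tolerance.
#' @param max_iter Iteration cap (Newton steps or alternation sweeps).
#' @return A `mapr_fit`: `$estimates` holds gamma (and the dead
#'   parameter), `$theta` the person locations, `$value_function` the
#'   implied `value_function`.
#' @export
fit_mapr <- function(responses, system,
                     theta_mode = c("free", "structured"),
                     tol = 1e-8, max_iter = 500L) {
  theta_mode <- match.arg(theta_mode)
  stopifnot(inherits(system, "attribute_system"))
  mats <- mapr_design_matrices(responses, system)
  Z <- mats$Z
  Zown <- mats$Zown
  y <- responses$response
  rid <- as.character(responses$respondent_id)
  p <- ncol(Z)

  if (theta_mode == "structured") {
    X <- Z - Zown
    if (all(y == 1) || all(y == 0)) {
      stop("all responses identical: parameters non-estimable ",
           "(complete separation)")
    }
    fit <- logistic_newton(X, y, tol = tol, max_iter = max_iter)
    gamma <- stats::setNames(fit$coef, colnames(Z))
    vcov <- solve(fit$hessian)
    dimnames(vcov) <- list(colnames(Z), colnames(Z))
    theta <- drop(Zown %*% gamma)
    theta <- stats::setNames(theta[!duplicated(rid)],
                             rid[!duplicated(rid)])
    gn <- max(abs(fit$grad))
    res <- new_fit_result(
      "mapr_structured", gamma, sqrt(diag(vcov)), vcov,
      loglik = fit$loglik, gradient_norm = gn,
      converged = fit$converged, iterations = fit$iterations,
      constraint = "ref",
      extra = list(theta = theta, theta_mode = "structured")
    )
  } else {
    ids <- unique(rid)
    ridx <- match(rid, ids)
    n_r <- tabulate(ridx, nbins = length(ids))
    k_r <- vapply(seq_along(ids), function(r) sum(y[ridx == r]), numeric(1))
    degenerate <- k_r == 0 | k_r == n_r
    excluded <- ids[degenerate]
    if (length(excluded)) {
      warning(length(excluded), " respondents with all-identical responses",
              " excluded from free-theta estimation: ",
              paste(utils::head(excluded, 5), collapse = ", "),
              if (length(excluded) > 5) ", ...")
    }
    keep_row <- !degenerate[ridx]
    if (!any(keep_row)) {
      stop("no estimable respondents: every response vector is degenerate ",
           "(complete separation)")
    }
    Zk <- Z[keep_row, , drop = FALSE]
    yk <- y[keep_row]
    ids_k <- ids[!degenerate]
    ridk <- match(rid[keep_row], ids_k)
    R <- length(ids_k)
    # per-respondent sums aligned with ids_k regardless of id order
    gsum <- function(x) {
      out <- numeric(R)
      t <- rowsum(x, ridk)
      out[as.numeric(rownames(t))] <- t
      out
    }
    qrZ <- qr(Zk)
    if (qrZ$rank < p) {
      bad <- colnames(Zk)[qrZ$pivot[(qrZ$rank + 1):p]]
      stop("design matrix is rank deficient; collinear columns: ",
           paste(bad, collapse = ", "))
    }
    gamma <- numeric(p)
    pbar <- gsum(yk) / gsum(rep(1, length(yk)))
    theta <- -stats::qlogis(pbar)
    softplus <- function(x) {
      ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
    }
    nll_at <- function(gamma, theta) {
      eta <- drop(Zk %*% gamma) - theta[ridk]
      -sum(yk * eta - softplus(eta))
    }
    # joint Newton over (gamma, theta): the person block of the Hessian is
    # diagonal, so the full step costs one p x p solve (Schur complement)
    iter <- 0L
    converged <- FALSE
    gn <- Inf
    nll <- nll_at(gamma, theta)
    repeat {
      iter <- iter + 1L
      eta <- drop(Zk %*% gamma) - theta[ridk]
      pr <- stats::plogis(eta)
      g_g <- drop(crossprod(Zk, pr - yk))       # d(-loglik)/d gamma
      g_t <- gsum(yk - pr)                      # d(-loglik)/d theta
      gn <- max(abs(c(g_g, g_t)))
      if (gn < tol) {
        converged <- TRUE
        break
      }
      if (iter > max_iter) break
      W <- pr * (1 - pr)
      Hgg <- crossprod(Zk * W, Zk)
      d_t <- pmax(gsum(W), 1e-12)
      B <- matrix(0, R, p)
      Bt <- rowsum(Zk * W, ridk)
      B[as.numeric(rownames(Bt)), ] <- Bt       # -d2/(dgamma dtheta)
      S <- Hgg - crossprod(B / sqrt(d_t))
      rhs <- g_g - drop(crossprod(B, g_t / d_t))
      d_gamma <- solve(S, rhs)
      d_theta <- (g_t + drop(B %*% d_gamma)) / d_t
      alpha <- 1
      repeat {
        nll_new <- nll_at(gamma - alpha * d_gamma, theta - alpha * d_theta)
        if (nll_new <= nll + 1e-12 || alpha < 1e-4) break
        alpha <- alpha / 2
      }
      gamma <- gamma - alpha * d_gamma
      theta <- theta - alpha * d_theta
      nll <- nll_at(gamma, theta)
    }
    eta <- drop(Zk %*% gamma) - theta[ridk]
    pr <- stats::plogis(eta)
    loglik <- sum(yk * log(pr) + (1 - yk) * log1p(-pr))
    # SEs for gamma from the joint observed information, person block
    # profiled out (Schur complement)
    W <- pr * (1 - pr)
    Hgg <- crossprod(Zk * W, Zk)
    h_t <- gsum(W)
    B <- matrix(0, R, p)                    # respondent x p
    Bt <- rowsum(Zk * W, ridk)
    B[as.numeric(rownames(Bt)), ] <- Bt
    Hs <- Hgg - crossprod(B / sqrt(pmax(h_t, 1e-12)))
    vcov <- tryCatch(solve(Hs), error = function(e) {
      matrix(NA_real_, p, p)
    })
    dimnames(vcov) <- list(colnames(Z), colnames(Z))
    gamma <- stats::setNames(gamma, colnames(Z))
    theta_all <- stats::setNames(rep(NA_real_, length(ids)), ids)
    theta_all[ids_k] <- theta
    res <- new_fit_result(
      "mapr_free", gamma, sqrt(pmax(0, diag(vcov))), vcov,
      loglik = loglik, gradient_norm = gn, converged = converged,
      iterations = iter, constraint = "ref", excluded = excluded,
      extra = list(theta = theta_all, theta_mode = "free")
    )
  }
  gfit <- res$estimates[seq_len(system$z_length)]
  res$value_function <- value_function(gfit, system)
  if (mats$has_dead) res$dead_value <- unname(res$estimates["dead"])
  res
}

# ---------------------------------------------------------------------
# log-likelihood and analytic gradient (shared diagnostic surface)
# ---------------------------------------------------------------------

#' Log-likelihood and analytic gradient of a fitted model family member
#'
#' Evaluates the log-likelihood and its analytic gradient at an arbitrary
#' parameter point, for gradient checking and optimizer diagnostics.
#'
#' @param params Parameter vector.  `clogit_pairs`, `rasch_cml`: the full
#'   state-value vector v.  `mapr`: structured mode, gamma; free mode,
#'   `c(gamma, theta)`.
#' @param data Model data.  `clogit_pairs`: pair data as in
#'   [fit_clogit_pairs()] plus the state order via names of `params`.
#'   `rasch_cml`: the binary response matrix.  `mapr`: a list with
#'   elements `responses`, `system`, `theta_mode`.
#' @param model One of `"clogit_pairs"`, `"rasch_cml"`, `"mapr"`.
#' @return List with `loglik` (scalar) and `gradient` (same length as
#'   `params`).
#' @export
loglik_and_gradient <- function(params, data,
                                model = c("clogit_pairs", "rasch_cml",
                                          "mapr")) {
  model <- match.arg(model)
  if (model == "clogit_pairs") {
    agg <- aggregate_pairs(data)
    v <- params
    states <- names(v)
    if (is.null(states)) stop("params must be named by state")
    ll <- 0
    grad <- stats::setNames(numeric(length(v)), states)
    for (i in seq_len(nrow(agg))) {
      s <- agg$s[i]; t <- agg$t[i]
      pst <- stats::plogis(v[s] - v[t])
      ll <- ll + agg$n_st[i] * log(pst) + agg$n_ts[i] * log1p(-pst)
      g <- agg$n_st[i] * (1 - pst) - agg$n_ts[i] * pst
      grad[s] <- grad[s] + g
      grad[t] <- grad[t] - g
    }
    list(loglik = unname(ll), gradient = grad)
  } else if (model == "rasch_cml") {
    X <- as.matrix(data)
    if (is.null(colnames(X))) colnames(X) <- paste0("state", seq_len(ncol(X)))
    cg <- cml_groups(X)
    obj <- cml_objective(params, cg$groups, hessian = FALSE)
    list(loglik = -obj$value,
         gradient = stats::setNames(-obj$gradient, colnames(X)))
  } else {
    responses <- data$responses
    system <- data$system
    theta_mode <- data$theta_mode %||% "structured"
    mats <- mapr_design_matrices(responses, system)
    y <- responses$response
    if (theta_mode == "structured") {
      X <- mats$Z - mats$Zown
      eta <- drop(X %*% params)
      p <- stats::plogis(eta)
      list(loglik = sum(y * log(p) + (1 - y) * log1p(-p)),
           gradient = drop(crossprod(X, y - p)))
    } else {
      pnum <- ncol(mats$Z)
      ids <- unique(as.character(responses$respondent_id))
      ridx <- match(as.character(responses$respondent_id), ids)
      gamma <- params[seq_len(pnum)]
      theta <- params[pnum + seq_along(ids)]
      eta <- drop(mats$Z %*% gamma) - theta[ridx]
      p <- stats::plogis(eta)
      g_gamma <- drop(crossprod(mats$Z, y - p))
      g_theta <- numeric(length(ids))
      gt <- rowsum(p - y, ridx)
      g_theta[as.numeric(rownames(gt))] <- gt
      list(loglik = sum(y * log(p) + (1 - y) * log1p(-p)),
           gradient = c(g_gamma, g_theta))
    }
  }
}
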