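# Guttman scalogram sorting and misfit counting, dead-state anchoring,
# and cross-sample invariance checks.

#' Sort a binary response matrix into Guttman scalogram form
#'
#' Rows (respondents) are sorted by number of agreements, descending;
#' columns (states) by number of agreements, descending.  Ties break by
#' label, so the sort is deterministic and idempotent.  Misfits are the
#' cells of the sorted matrix that deviate from the ideal cumulative step
#' pattern implied by each row's total: a row with total k should agree
#' with exactly the first k sorted states (Goodman-style error counting).
#' A perfect scalogram has zero misfits.
#'
#' @param m Binary matrix (persons x states), no missing entries.
#' @return An object of class `scalogram`: `sorted` matrix, `row_order`
#'   and `col_order` (permutations of the input indices), `misfit_count`
#'   and `misfits` (data.frame of deviating cells in sorted coordinates).
#' @export
guttman_sort <- function(m) {
  m <- as.matrix(m)
  if (any(is.na(m)) || !all(m %in% c(0, 1))) {
    stop("matrix must be binary 0/1 with no missing entries")
  }
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  if (is.null(colnames(m))) colnames(m) <- seq_len(ncol(m))
  row_order <- order(-rowSums(m), rownames(m))
  col_order <- order(-colSums(m), colnames(m))
  s <- m[row_order, col_order, drop = FALSE]
  ideal <- outer(rowSums(s), seq_len(ncol(s)), function(k, j) {
    as.integer(j <= k)
  })
  dev <- s != ideal
  cells <- which(dev, arr.ind = TRUE)
  misfits <- data.frame(
    row = unname(cells[, 1]), col = unname(cells[, 2]),
    respondent = rownames(s)[cells[, 1]],
    state = colnames(s)[cells[, 2]],
    observed = s[cells], expected = ideal[cells],
    stringsAsFactors = FALSE
  )
  structure(list(sorted = s, row_order = row_order, col_order = col_order,
                 misfit_count = sum(dev), misfits = misfits),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat("Guttman scalogram:", nrow(x$sorted), "respondents x",
      ncol(x$sorted), "states;", x$misfit_count, "misfits\n")
  if (nrow(x$sorted) <= 15 && ncol(x$sorted) <= 20) print(x$sorted)
  invisible(x)
}

#' Anchor latent state values to the dead - full-health scale
#'
#' Latent values from choice models are interval-level but have an
#' arbitrary origin and unit.  For QALY/DALY use they are rescaled so the
#' estimated value of the state dead maps to 0 and the best state to 1:
#' \eqn{v' = (v - v_{dead}) / (v_{best} - v_{dead})}.  The transform is
#' affine, hence order preserving when \eqn{v_{best} > v_{dead}}; states
#' worse than dead map to negative rescaled values.
#'
#' @param values Numeric vector of latent state values.
#' @param dead_value Estimated value of the state dead.
#' @param best_value Estimated value of the best state.
#' @return Rescaled values, same names/length.
#' @export
anchor_to_dead <- function(values, dead_value, best_value) {
  if (!is.finite(dead_value) || !is.finite(best_value)) {
    stop("anchor values must be finite")
  }
  if (dead_value == best_value) stop("anchors coincide: cannot rescale")
  if (dead_value > best_value) {
    warning("dead anchored above the best state; transform applied, ",
            "but the estimates look pathological")
  }
  (values - dead_value) / (best_value - dead_value)
}

#' Compare state-value estimates from two fits (invariance check)
#'
#' Under the invariance principle, state estimates should not depend on
#' which respondent sample produced them.  Both estimate vectors are
#' recentred (mean zero over the shared states), then compared: mean and
#' max absolute difference and a per-state z-score from the combined
#' standard errors of the centred estimates.
#'
#' @param fit_a,fit_b `mapr_fit` objects covering the same states (at
#'   least two shared finite estimates).
#' @return An object of class `invariance_report`: data.frame `table`
#'   (state, estimate_a, estimate_b, diff, se, z), `mean_abs_diff`,
#'   `max_abs_diff`, `prop_z_within_3`.
#' @export
invariance_check <- function(fit_a, fit_b) {
  shared <- intersect(names(fit_a$estimates), names(fit_b$estimates))
  shared <- shared[is.finite(fit_a$estimates[shared]) &
                     is.finite(fit_b$estimates[shared])]
  if (length(shared) < 2) stop("fits share fewer than 2 estimable states")
  a <- fit_a$estimates[shared]
  b <- fit_b$estimates[shared]
  a <- a - mean(a)
  b <- b - mean(b)
  se <- sqrt(centered_var(fit_a, shared) + centered_var(fit_b, shared))
  d <- a - b
  z <- ifelse(se > 0, d / se, ifelse(d == 0, 0, Inf))
  tab <- data.frame(state = shared, estimate_a = a, estimate_b = b,
                    diff = d, se = se, z = z, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(list(table = tab,
                 mean_abs_diff = mean(abs(d)),
                 max_abs_diff = max(abs(d)),
                 prop_z_within_3 = mean(abs(z) <= 3)),
            class = "invariance_report")
}

# variance of the mean-centred estimates over the shared states
centered_var <- function(fit, shared) {
  V <- fit$vcov[shared, shared, drop = FALSE]
  n <- length(shared)
  C <- diag(n) - 1 / n
  pmax(0, diag(C %*% V %*% t(C)))
}

#' @export
print.invariance_report <- function(x, ...) {
  cat("Invariance check over", nrow(x$table), "states\n")
  cat("  mean |diff|:", format(x$mean_abs_diff, digits = 4),
      " max |diff|:", format(x$max_abs_diff, digits = 4), "\n")
  cat("  share of |z| <= 3:", format(x$prop_z_within_3, digits = 4), "\n")
  invisible(x)
}
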