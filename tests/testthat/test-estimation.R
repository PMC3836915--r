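test_that("pairwise conditional logit recovers the binomial closed form", {
  d <- data.frame(s = "a", t = "b", n_st = 30, n_ts = 10)
  fit <- fit_clogit_pairs(d)
  expect_equal(unname(fit$estimates["a"] - fit$estimates["b"]), log(3),
               tolerance = 1e-8)
  # symmetric data: all estimates equal
  sym <- data.frame(s = c("a", "a", "b"), t = c("b", "c", "c"),
                    n_st = c(10, 10, 10), n_ts = c(10, 10, 10))
  fs <- fit_clogit_pairs(sym)
  expect_equal(max(abs(fs$estimates - fs$estimates[1])), 0,
               tolerance = 1e-8)
})

test_that("pairwise conditional logit recovers simulated generating values", {
  v_true <- seq(-1.5, 1.5, length.out = 8)
  names(v_true) <- paste0("s", 1:8)
  set.seed(101)
  rows <- list()
  for (i in 1:7) for (j in (i + 1):8) {
    p <- plogis(v_true[i] - v_true[j])
    w <- rbinom(1, 500, p)
    rows[[length(rows) + 1]] <- data.frame(
      s = names(v_true)[i], t = names(v_true)[j], n_st = w, n_ts = 500 - w)
  }
  fit <- fit_clogit_pairs(do.call(rbind, rows), constraint = "sumzero")
  centered_truth <- v_true - mean(v_true)
  z <- abs(fit$estimates - centered_truth) / pmax(fit$se, 1e-8)
  expect_true(all(z < 3))
  expect_true(fit$converged)
})

test_that("separation and disconnected comparison graphs are surfaced", {
  sep <- data.frame(s = c("a", "a", "b"), t = c("b", "c", "c"),
                    n_st = c(10, 10, 5), n_ts = c(0, 0, 5))
  expect_warning(fit <- fit_clogit_pairs(sep), "separation")
  expect_true(is.infinite(fit$estimates["a"]))
  expect_identical(fit$separated, "a")
  disc <- data.frame(s = c("a", "c"), t = c("b", "d"),
                     n_st = c(5, 5), n_ts = c(5, 5))
  expect_error(fit_clogit_pairs(disc), "disconnected")
})

test_that("Rasch CML matches the discordant-pair closed form for two states", {
  # conditional on raw score 1, P(1,0) = logistic(v1 - v2):
  # v1 - v2 = log(n10 / n01)
  X <- rbind(
    matrix(rep(c(1, 0), 12), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 1), 4), ncol = 2, byrow = TRUE),
    matrix(rep(c(1, 1), 3), ncol = 2, byrow = TRUE),  # uninformative
    matrix(rep(c(0, 0), 2), ncol = 2, byrow = TRUE)   # uninformative
  )
  colnames(X) <- c("s1", "s2")
  fit <- fit_rasch_cml(X)
  expect_equal(unname(fit$estimates["s1"] - fit$estimates["s2"]),
               log(12 / 4), tolerance = 1e-8)
  expect_equal(length(fit$excluded), 5)
})

test_that("extreme-score respondents carry no conditional information", {
  set.seed(7)
  v <- seq(-2, 2, length.out = 6)
  X <- simulate_rasch_matrix(stats::setNames(v, paste0("s", 1:6)),
                             rnorm(300), seed = 7)
  fit_all <- fit_rasch_cml(X)
  informative <- setdiff(seq_len(nrow(X)), fit_all$excluded)
  fit_trim <- fit_rasch_cml(X[informative, ])
  expect_equal(fit_trim$estimates, fit_all$estimates, tolerance = 1e-10)
})

test_that("non-estimable states and empty matrices are rejected or flagged", {
  X <- simulate_rasch_matrix(stats::setNames(numeric(3), paste0("s", 1:3)),
                             rnorm(40), seed = 2)
  X <- cbind(X, s4 = 1)  # everyone agrees with s4
  expect_warning(fit <- fit_rasch_cml(X), "non-estimable")
  expect_true(is.na(fit$estimates["s4"]))
  expect_identical(fit$non_estimable, "s4")
  expect_error(fit_rasch_cml(matrix(numeric(0), 0, 2)), "non-empty")
  expect_error(fit_rasch_cml(matrix(2, 3, 3)), "binary")
})

test_that("Rasch CML recovers generating state values (J=20, N=1000)", {
  v_true <- stats::setNames(seq(-3, 3, length.out = 20), paste0("s", 1:20))
  set.seed(2024)
  theta <- rnorm(1000)
  X <- simulate_rasch_matrix(v_true, theta, seed = 2024)
  fit <- fit_rasch_cml(X, constraint = "sumzero")
  centered <- v_true - mean(v_true)
  expect_gte(cor(fit$estimates, centered), 0.98)
  expect_lte(sqrt(mean((fit$estimates - centered)^2)), 0.15)
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-8)
})

test_that("CML recovery error shrinks with the sample size", {
  v_true <- stats::setNames(seq(-2, 2, length.out = 12), paste0("s", 1:12))
  rmse_at <- function(N, seed) {
    set.seed(seed)
    X <- simulate_rasch_matrix(v_true, rnorm(N), seed = seed)
    fit <- fit_rasch_cml(X, constraint = "sumzero")
    sqrt(mean((fit$estimates - (v_true - mean(v_true)))^2))
  }
  r200 <- rmse_at(200, 51)
  r1000 <- rmse_at(1000, 52)
  r5000 <- rmse_at(5000, 53)
  expect_gt(r200, r1000)
  expect_gt(r200, r5000)
  expect_lte(r5000, r1000 * 1.25)  # allows simulation noise at the tail
})

test_that("JML and CML state estimates agree on well-conditioned data", {
  v_true <- stats::setNames(seq(-2, 2, length.out = 10), paste0("s", 1:10))
  set.seed(77)
  X <- simulate_rasch_matrix(v_true, rnorm(500), seed = 77)
  fc <- fit_rasch_cml(X, constraint = "sumzero")
  fj <- suppressWarnings(fit_rasch_jml(X, constraint = "sumzero"))
  expect_gt(cor(fc$estimates, fj$estimates), 0.99)
})

test_that("CML estimates are invariant to a shifted respondent sample", {
  v_true <- stats::setNames(seq(-2, 2, length.out = 10), paste0("s", 1:10))
  fit_from <- function(mu, seed) {
    set.seed(seed)
    X <- simulate_rasch_matrix(v_true, rnorm(800, mean = mu), seed = seed)
    fit_rasch_cml(X, constraint = "sumzero")
  }
  fa <- fit_from(-1, 61)
  fb <- fit_from(+1, 62)
  rep <- invariance_check(fa, fb)
  expect_lt(rep$mean_abs_diff, 0.2)
  expect_gte(rep$prop_z_within_3, 0.9)
})

test_that("MAPR structured fit equals the logistic regression on design differences", {
  dat <- make_pivot_dataset(150, seed = 301)
  fit <- fit_mapr(dat$tab, dat$system, theta_mode = "structured")
  # independent route: glm on z_s - z_own
  Z <- t(vapply(dat$tab$state_code, function(cd) encode_profile(cd, dat$system),
                numeric(10)))
  Zo <- t(vapply(dat$tab$own_code, function(cd) encode_profile(cd, dat$system),
                 numeric(10)))
  g <- stats::glm.fit(Z - Zo, dat$tab$response,
                      family = stats::binomial())
  expect_equal(unname(fit$estimates), unname(g$coefficients),
               tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("MAPR recovers the generating attribute weights from pivot data", {
  dat <- make_pivot_dataset(800, seed = 302)
  fit <- fit_mapr(dat$tab, dat$system, theta_mode = "structured")
  expect_lt(sqrt(mean((fit$estimates - dat$gamma)^2)), 0.15)
  z <- abs(fit$estimates - dat$gamma) / fit$se
  expect_gte(mean(z < 3), 0.9)
})

test_that("free-theta MAPR excludes degenerate respondents and converges", {
  dat <- make_pivot_dataset(250, seed = 303)
  fit <- suppressWarnings(fit_mapr(dat$tab, dat$system, theta_mode = "free"))
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-8)
  # excluded = respondents answering all 0 or all 1
  agg <- tapply(dat$tab$response, dat$tab$respondent_id, mean)
  degenerate <- names(agg)[agg %in% c(0, 1)]
  expect_setequal(fit$excluded, degenerate)
  expect_true(all(is.finite(fit$theta[setdiff(names(fit$theta),
                                              degenerate)])))
})

test_that("MAPR degenerate and rank-deficient inputs error informatively", {
  sys <- make_eq5d_system()
  tab <- data.frame(respondent_id = 1:4, own_code = "21111",
                    state_code = "22111", role = "hypothetical",
                    response = 1)
  expect_error(fit_mapr(tab, sys, theta_mode = "structured"),
               "non-estimable|separation")
  expect_error(suppressWarnings(fit_mapr(tab, sys, theta_mode = "free")),
               "separation")
  # MO never varies between own and presented -> MO columns collinear (zero)
  tab2 <- data.frame(
    respondent_id = rep(1:30, each = 2),
    own_code = "12222",
    state_code = rep(c("12122", "13222"), 30),
    role = "hypothetical",
    response = rep(c(1, 0), 30)
  )
  expect_error(fit_mapr(tab2, sys, theta_mode = "structured"), "MO")
})

test_that("a dead pseudo-state is estimated when mixed into the choice sets", {
  sys <- make_eq5d_system()
  vf <- value_function(make_gamma(), sys)
  dead_true <- -3.5
  vals <- vapply(enumerate_states(sys), state_value, numeric(1), vf = vf)
  pop <- sample_population(400, list(family = "uniform",
                                     min = min(vals), max = max(vals)),
                           seed = 71, system = sys, vf = vf,
                           snap_theta = TRUE)
  design <- unlist(lapply(seq_along(pop$id), function(r) {
    own <- state_profile(pop$own_code[r], sys)
    sets <- pivot_design(own, sys, pivot_config(1), respondent = pop$id[r])
    # mix the state dead in as one more presented health state
    sets[[length(sets) + 1]] <- choice_set(
      list(own, state_profile("33333", sys)), c("own", "dead"),
      "mapr-binary", respondent = pop$id[r], id = length(sets) + 1)
    sets
  }), recursive = FALSE)
  tab <- simulate_mapr_responses(pop, design, vf, seed = 72,
                                 dead_value = dead_true)
  fit <- fit_mapr(tab, sys, theta_mode = "structured")
  expect_lt(abs(fit$dead_value - dead_true), 3 * fit$se["dead"])
})

test_that("analytic gradients match finite differences for all models", {
  set.seed(88)
  # conditional logit
  pd <- data.frame(s = c("a", "a", "b"), t = c("b", "c", "c"),
                   n_st = c(5, 7, 3), n_ts = c(4, 2, 6))
  vp <- stats::setNames(rnorm(3), c("a", "b", "c"))
  g <- loglik_and_gradient(vp, pd, "clogit_pairs")
  gn <- numeric_gradient(function(p) {
    names(p) <- names(vp)
    loglik_and_gradient(p, pd, "clogit_pairs")$loglik
  }, vp)
  expect_lt(max(abs(g$gradient - gn) / pmax(abs(gn), 1)), 1e-6)
  # Rasch CML
  v_true <- stats::setNames(seq(-1, 1, length.out = 6), paste0("s", 1:6))
  X <- simulate_rasch_matrix(v_true, rnorm(80), seed = 88)
  vpt <- rnorm(6, sd = 0.5)
  g2 <- loglik_and_gradient(vpt, X, "rasch_cml")
  gn2 <- numeric_gradient(function(p)
    loglik_and_gradient(p, X, "rasch_cml")$loglik, vpt)
  expect_lt(max(abs(g2$gradient - gn2) / pmax(abs(gn2), 1)), 1e-6)
  # MAPR, both modes
  dat <- make_pivot_dataset(40, seed = 304)
  data_s <- list(responses = dat$tab, system = dat$system,
                 theta_mode = "structured")
  gp <- rnorm(10, sd = 0.3)
  g3 <- loglik_and_gradient(gp, data_s, "mapr")
  gn3 <- numeric_gradient(function(p)
    loglik_and_gradient(p, data_s, "mapr")$loglik, gp)
  expect_lt(max(abs(g3$gradient - gn3) / pmax(abs(gn3), 1)), 1e-6)
  data_f <- list(responses = dat$tab, system = dat$system,
                 theta_mode = "free")
  n_r <- length(unique(dat$tab$respondent_id))
  pf <- rnorm(10 + n_r, sd = 0.3)
  g4 <- loglik_and_gradient(pf, data_f, "mapr")
  gn4 <- numeric_gradient(function(p)
    loglik_and_gradient(p, data_f, "mapr")$loglik, pf)
  expect_lt(max(abs(g4$gradient - gn4) / pmax(abs(gn4), 1)), 1e-6)
})

test_that("fitted optima dominate the truth and satisfy first-order conditions", {
  dat <- make_pivot_dataset(120, seed = 305)
  fit <- fit_mapr(dat$tab, dat$system, theta_mode = "structured")
  data_s <- list(responses = dat$tab, system = dat$system,
                 theta_mode = "structured")
  ll_hat <- loglik_and_gradient(unname(fit$estimates), data_s, "mapr")
  ll_true <- loglik_and_gradient(dat$gamma, data_s, "mapr")
  expect_gte(ll_hat$loglik, ll_true$loglik)
  expect_lt(max(abs(ll_hat$gradient)), 1e-6)
})
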