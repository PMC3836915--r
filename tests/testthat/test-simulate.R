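test_that("population sampling is seeded and matches its distribution spec", {
  empty <- sample_population(0, seed = 1)
  expect_length(empty$theta, 0)
  p1 <- sample_population(50, seed = 9)
  p2 <- sample_population(50, seed = 9)
  expect_identical(p1$theta, p2$theta)
  big <- sample_population(1e5, list(family = "normal", mean = 0, sd = 1),
                           seed = 17)
  expect_lt(abs(mean(big$theta)), 0.02)  # 3 sd / sqrt(n) window
  u <- sample_population(1e4, list(family = "uniform", min = -2, max = 2),
                         seed = 3)
  expect_true(all(u$theta >= -2 & u$theta <= 2))
  expect_error(sample_population(5, list(family = "cauchy"), seed = 1),
               "unknown theta distribution")
  expect_error(sample_population(5, list(family = "normal", sd = 0),
                                 seed = 1), "positive")
})

test_that("own-state assignment picks the nearest-valued state", {
  sys <- make_eq5d_system()
  vf <- value_function(make_gamma(), sys)
  pop <- sample_population(200, list(family = "uniform", min = -4.5, max = 0),
                           seed = 21, system = sys, vf = vf)
  vals <- vapply(enumerate_states(sys), state_value, numeric(1), vf = vf)
  own_vals <- vapply(pop$own_code, function(cd) state_value(cd, vf),
                     numeric(1), USE.NAMES = FALSE)
  expect_equal(abs(own_vals[1:50] - pop$theta[1:50]),
               vapply(pop$theta[1:50], function(th) min(abs(vals - th)),
                      numeric(1)))
  snapped <- sample_population(20, list(family = "uniform", min = -4, max = 0),
                               seed = 4, system = sys, vf = vf,
                               snap_theta = TRUE)
  expect_equal(snapped$theta,
               vapply(snapped$own_code, function(cd) state_value(cd, vf),
                      numeric(1), USE.NAMES = FALSE))
})

test_that("MAPR response simulation follows the kernel and the seed", {
  sys <- make_eq5d_system()
  vf <- value_function(make_gamma(), sys)
  pop <- structure(list(id = 1:3, theta = c(-10, 10, 0),
                        own_code = rep("22222", 3)),
                   class = "population")
  design <- unlist(lapply(1:3, function(r) {
    pivot_design("22222", sys, pivot_config(1), respondent = r)
  }), recursive = FALSE)
  tab <- simulate_mapr_responses(pop, design, vf, seed = 5)
  # theta far below every state value: presented always judged better
  expect_true(all(tab$response[tab$respondent_id == 1] == 1))
  expect_true(all(tab$response[tab$respondent_id == 2] == 0))
  tab2 <- simulate_mapr_responses(pop, design, vf, seed = 5)
  expect_identical(tab, tab2)
  # respondent substreams survive design reordering
  tab3 <- simulate_mapr_responses(pop, rev(design), vf, seed = 5)
  tab3 <- tab3[order(tab3$respondent_id, tab3$choice_set_id), ]
  rownames(tab3) <- NULL
  expect_equal(tab3, tab[order(tab$respondent_id, tab$choice_set_id), ])
  # unknown respondent rejected
  orphan <- pivot_design("22222", sys, pivot_config(1), respondent = 99)
  expect_error(simulate_mapr_responses(pop, orphan, vf, seed = 1),
               "absent from the population")
})

test_that("indifferent pairs answer 1 about half the time", {
  sys <- make_eq5d_system()
  vf <- value_function(make_gamma(), sys)
  # own value exactly equals presented value -> p = 0.5 per judgment
  own <- "21111"
  pop <- structure(list(id = 1:400,
                        theta = rep(state_value(own, vf), 400),
                        own_code = rep(own, 400)),
                   class = "population")
  design <- unlist(lapply(1:400, function(r) {
    list(choice_set(list(state_profile(own, sys),
                         state_profile(own, sys)),
                    c("own", "hypothetical"), "mapr-binary",
                    respondent = r, id = 1))
  }), recursive = FALSE)
  tab <- simulate_mapr_responses(pop, design, vf, seed = 31)
  # 3 binomial SEs around 0.5 at n = 400
  expect_lt(abs(mean(tab$response) - 0.5), 3 * 0.5 / sqrt(400))
})

test_that("RUM choice frequencies converge to the closed-form kernels", {
  # zero-variance limit: deterministic maximization
  f0 <- simulate_rum_choices(c(0.3, 1.2, -1), "gumbel", 100, seed = 1,
                             scale = 0)
  expect_equal(unname(f0), c(0, 1, 0))
  # Gumbel errors -> conditional logit
  fg <- simulate_rum_choices(c(1, 0), "gumbel", 1e5, seed = 2)
  expect_lt(abs(fg[1] - plogis(1)), 3 * sqrt(plogis(1) * (1 - plogis(1)) / 1e5))
  # IID normal errors, pairwise -> Thurstone with sqrt(2) dispersion
  fn <- simulate_rum_choices(c(1, 0), "normal", 1e5, seed = 3)
  p <- pnorm(1 / sqrt(2))
  expect_lt(abs(fn[1] - p), 3 * sqrt(p * (1 - p) / 1e5))
  expect_error(simulate_rum_choices(c(1, 0), "laplace", 10, seed = 1))
  expect_error(simulate_rum_choices(1, "gumbel", 10, seed = 1), "at least 2")
})

test_that("deterministic Guttman data form a perfect scalogram", {
  sys <- make_eq5d_system()
  vf <- value_function(make_gamma(), sys)
  states <- lapply(c("11111", "21111", "22111", "22211", "22221", "22222",
                     "32222", "33222"), state_profile, system = sys)
  pop <- sample_population(7, list(family = "uniform", min = -3, max = 0),
                           seed = 13)
  m <- simulate_guttman_deterministic(pop, states, vf)
  expect_equal(dim(m), c(7, 8))
  expect_equal(guttman_sort(m)$misfit_count, 0)
  # single respondent: responses are a step function of state order
  one <- structure(list(id = 1, theta = -1.05, own_code = NULL),
                   class = "population")
  row <- drop(simulate_guttman_deterministic(one, states, vf))
  vals <- vapply(states, state_value, numeric(1), vf = vf)
  expect_equal(unname(row), as.integer(vals > -1.05))
  ord <- order(vals, decreasing = TRUE)
  expect_true(all(diff(row[ord]) <= 0))
})
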