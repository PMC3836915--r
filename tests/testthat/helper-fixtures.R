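# Shared fixtures: all synthetic, built in code.

# EQ-5D-like 5-attribute x 3-level system with terse level labels.
make_eq5d_system <- function() {
  attribute_system(list(
    MO = c("none", "some", "severe"),
    SC = c("none", "some", "severe"),
    UA = c("none", "some", "severe"),
    PD = c("none", "some", "severe"),
    AD = c("none", "some", "severe")
  ))
}

# Generating attribute decrements, design-vector order.
make_gamma <- function() {
  c(-0.30, -0.90, -0.25, -0.80, -0.20, -0.70, -0.40, -1.10, -0.35, -1.00)
}

# Random attribute system for property tests (2-4 attributes, 2-4 levels).
random_system <- function() {
  n_attr <- sample(2:4, 1)
  lv <- lapply(seq_len(n_attr), function(i) {
    paste0("l", seq_len(sample(2:4, 1)))
  })
  names(lv) <- paste0("A", seq_len(n_attr))
  attribute_system(lv)
}

# Binary Rasch response matrix from known values and locations.
simulate_rasch_matrix <- function(v, theta, seed) {
  set.seed(seed)
  N <- length(theta)
  J <- length(v)
  m <- matrix(rbinom(N * J, 1, plogis(outer(-theta, v, "+"))), N, J)
  colnames(m) <- names(v) %||% paste0("s", seq_len(J))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pivot-design MAPR dataset: population spread uniformly over the whole
# value continuum (the data condition Rasch-type estimation needs), own
# states snapped to the nearest enumerated state, radius-1 judgments.
make_pivot_dataset <- function(N, seed, system = make_eq5d_system(),
                               gamma = make_gamma()) {
  vf <- value_function(gamma, system)
  vals <- vapply(enumerate_states(system), state_value, numeric(1), vf = vf)
  pop <- sample_population(
    N, list(family = "uniform", min = min(vals), max = max(vals)),
    seed = seed, system = system, vf = vf, snap_theta = TRUE
  )
  design <- unlist(lapply(seq_along(pop$id), function(r) {
    pivot_design(pop$own_code[r], system, pivot_config(radius = 1),
                 respondent = pop$id[r])
  }), recursive = FALSE)
  tab <- simulate_mapr_responses(pop, design, vf, seed = seed + 1)
  list(tab = tab, pop = pop, vf = vf, system = system, gamma = gamma)
}
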