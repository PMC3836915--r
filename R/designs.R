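# Judgment-task designs: full pairwise comparisons, own-state pivot
# neighborhoods, partial-profile attribute subsets, and adaptive
# (maximum-information) item selection.

#' Construct a choice set
#'
#' A choice set is one judgment task: at least two alternatives, each a
#' `state_profile` tagged with a role (`"own"`, `"hypothetical"` or
#' `"dead"`).  The `mapr-binary` task pairs the respondent's own state with
#' exactly one hypothetical state; `paired` tasks compare two hypothetical
#' states.
#'
#' @param alternatives List of `state_profile` objects.
#' @param roles Character vector of roles, one per alternative.
#' @param type Task type: `"paired"`, `"rank"` or `"mapr-binary"`.
#' @param respondent Respondent identifier.
#' @param id Choice-set identifier.
#' @return An object of class `choice_set`.
#' @export
choice_set <- function(alternatives, roles, type = "paired",
                       respondent = NA, id = NA) {
  if (length(alternatives) < 2) stop("a choice set needs K >= 2 alternatives")
  if (length(roles) != length(alternatives)) {
    stop("one role per alternative required")
  }
  if (!all(roles %in% c("own", "hypothetical", "dead"))) {
    stop("roles must be 'own', 'hypothetical' or 'dead'")
  }
  if (sum(roles == "own") > 1) stop("at most one 'own' alternative")
  if (sum(roles == "dead") > 1) stop("at most one 'dead' alternative")
  if (!type %in% c("paired", "rank", "mapr-binary")) {
    stop("unknown task type: ", type)
  }
  if (type == "mapr-binary" &&
      !(length(alternatives) == 2 && sum(roles == "own") == 1)) {
    stop("a mapr-binary set pairs one 'own' state with one presented ",
         "('hypothetical' or 'dead') state")
  }
  structure(list(alternatives = alternatives, roles = roles, type = type,
                 respondent = respondent, id = id),
            class = "choice_set")
}

#' @export
print.choice_set <- function(x, ...) {
  codes <- vapply(x$alternatives, function(p) p$code, character(1))
  cat("Choice set", if (!is.na(x$id)) x$id else "", "(", x$type, "): ",
      paste(paste0(codes, "[", x$roles, "]"), collapse = " vs "), "\n")
  invisible(x)
}

#' Full pairwise comparison design
#'
#' All unordered pairs of the given states, each once, as `paired` choice
#' sets in deterministic order (pairs (i, j), i < j, in input order).
#'
#' @param states List of `state_profile` objects with distinct codes.
#' @param respondent Respondent identifier attached to every set.
#' @return List of `choice_set` objects of length n(n-1)/2.
#' @export
full_pairwise_design <- function(states, respondent = NA) {
  n <- length(states)
  if (n < 2) stop("need at least 2 states")
  codes <- vapply(states, function(p) p$code, character(1))
  if (anyDuplicated(codes)) {
    stop("duplicate states in design: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  }
  sets <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      k <- k + 1L
      sets[[k]] <- choice_set(list(states[[i]], states[[j]]),
                              c("hypothetical", "hypothetical"),
                              type = "paired", respondent = respondent,
                              id = k)
    }
  }
  sets
}

#' Pivot design configuration
#'
#' @param radius Maximum per-attribute level deviation from the own state
#'   (non-negative integer).  Radius 1 presents states that deviate slightly
#'   from the respondent's own levels.
#' @param n_alternatives Optional cap on the number of presented states
#'   (first states in deterministic order are kept).
#' @param multi_attribute If `TRUE`, alternatives may deviate in several
#'   attributes at once (all combinations within the radius); default is
#'   single-attribute deviations only.
#' @return An object of class `pivot_config`.
#' @export
pivot_config <- function(radius = 1L, n_alternatives = NULL,
                         multi_attribute = FALSE) {
  radius <- as.integer(radius)
  if (radius < 0) stop("radius must be >= 0")
  structure(list(radius = radius, n_alternatives = n_alternatives,
                 multi_attribute = multi_attribute),
            class = "pivot_config")
}

#' Own-state pivot design
#'
#' Builds the respondent-specific judgment tasks of the two-stage response
#' mechanism: after the respondent classifies their own state, they are
#' shown hypothetical states whose attribute levels deviate at most
#' `cfg$radius` levels per attribute from their own levels (by default one
#' attribute at a time).  The own state itself is excluded from the
#' hypothetical pool.  Each task is a `mapr-binary` choice set: own state
#' versus one neighbor.
#'
#' @param own The respondent's own `state_profile` (or code string).
#' @param system An `attribute_system`.
#' @param cfg A `pivot_config`.
#' @param respondent Respondent identifier.
#' @return List of `choice_set` objects (empty, with a warning, if
#'   `radius = 0`).
#' @export
pivot_design <- function(own, system, cfg = pivot_config(),
                         respondent = NA) {
  stopifnot(inherits(system, "attribute_system"),
            inherits(cfg, "pivot_config"))
  if (!inherits(own, "state_profile")) own <- state_profile(own, system)
  if (cfg$radius == 0L) {
    warning("pivot radius 0 generates no alternatives")
    return(list())
  }
  neighbors <- pivot_neighbors(own, system, cfg)
  if (!is.null(cfg$n_alternatives)) {
    neighbors <- neighbors[seq_len(min(length(neighbors),
                                       cfg$n_alternatives))]
  }
  lapply(seq_along(neighbors), function(k) {
    choice_set(list(own, neighbors[[k]]), c("own", "hypothetical"),
               type = "mapr-binary", respondent = respondent, id = k)
  })
}

# States within the pivot radius of `own`, own state excluded.
# Single-attribute mode: attribute order, then increasing level.
# Multi-attribute mode: lexicographic code order.
pivot_neighbors <- function(own, system, cfg) {
  n_attr <- length(system$attributes)
  if (!cfg$multi_attribute) {
    out <- list()
    for (i in seq_len(n_attr)) {
      lo <- max(1L, own$levels[i] - cfg$radius)
      hi <- min(system$n_levels[i], own$levels[i] + cfg$radius)
      for (l in seq(lo, hi)) {
        if (l == own$levels[i]) next
        lv <- own$levels
        lv[i] <- l
        out[[length(out) + 1L]] <- state_profile(lv, system)
      }
    }
    return(out)
  }
  ranges <- lapply(seq_len(n_attr), function(i) {
    seq(max(1L, own$levels[i] - cfg$radius),
        min(system$n_levels[i], own$levels[i] + cfg$radius))
  })
  grid <- rev(expand.grid(rev(ranges), KEEP.OUT.ATTRS = FALSE))
  out <- list()
  for (r in seq_len(nrow(grid))) {
    lv <- as.integer(grid[r, ])
    if (all(lv == own$levels)) next
    out[[length(out) + 1L]] <- state_profile(lv, system)
  }
  out
}

#' Select a personal subset of candidate health domains
#'
#' For the partial-profile extension a patient selects a few most relevant
#' domains from a large candidate pool; all unselected domains contribute
#' no value (their dummies are zero).  The selection here is a reproducible
#' random draw standing in for the patient's choice.
#'
#' @param candidate_domains Character vector of candidate domain names.
#' @param k Number of domains to select (`k <=` number of candidates).
#' @param seed Integer seed making the draw reproducible.
#' @return Character vector of `k` selected domains, in candidate order.
#' @export
partial_profile_select <- function(candidate_domains, k, seed) {
  n <- length(candidate_domains)
  if (k > n) stop("cannot select ", k, " domains from ", n, " candidates")
  if (k == n) return(candidate_domains)
  idx <- with_seed(seed, sort(sample.int(n, k)))
  candidate_domains[idx]
}

#' Adaptive next-state selection by Fisher information
#'
#' A binary item is most informative about a respondent when its value is
#' close to the respondent's location: the Fisher information of the MAPR
#' kernel is \eqn{p(1-p)}, maximal (0.25) where the state value equals
#' \eqn{\hat\theta}.  Returns the candidate maximizing the information at
#' the current location estimate; ties go to the lowest candidate index.
#'
#' @param theta_hat Current location estimate.
#' @param candidates Non-empty list of `state_profile` objects.
#' @param vf A `value_function`.
#' @return The selected `state_profile`.
#' @export
adaptive_next_state <- function(theta_hat, candidates, vf) {
  if (length(candidates) == 0) stop("no candidate states")
  values <- vapply(candidates, state_value, numeric(1), vf = vf)
  # p(1-p) is monotone decreasing in |v - theta|, so the argmax of the
  # information is the argmin of the distance; which.min takes the first
  # (lowest-index) candidate on ties without floating-point ambiguity.
  candidates[[which.min(abs(values - theta_hat))]]
}

#' Serialize a design to a long-format table
#'
#' One row per (respondent, choice set, alternative) with the role and
#' state code; round-trippable with [design_from_table()].
#'
#' @param design List of `choice_set` objects.
#' @return A data.frame with columns `respondent_id`, `choice_set_id`,
#'   `alternative_id`, `role`, `state_code`, `task_type`.
#' @export
design_table <- function(design) {
  rows <- lapply(design, function(cs) {
    data.frame(
      respondent_id = rep(cs$respondent, length(cs$alternatives)),
      choice_set_id = rep(cs$id, length(cs$alternatives)),
      alternative_id = seq_along(cs$alternatives),
      role = cs$roles,
      state_code = vapply(cs$alternatives, function(p) p$code, character(1)),
      task_type = rep(cs$type, length(cs$alternatives)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Rebuild a design from its long-format table
#'
#' @param tab A data.frame as produced by [design_table()].
#' @param system The `attribute_system` resolving the state codes.
#' @return List of `choice_set` objects.
#' @export
design_from_table <- function(tab, system) {
  needed <- c("respondent_id", "choice_set_id", "alternative_id", "role",
              "state_code", "task_type")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("design table lacks columns: ", paste(missing, collapse = ", "))
  }
  keys <- unique(tab[, c("respondent_id", "choice_set_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- tab[tab$respondent_id == keys$respondent_id[i] &
                 tab$choice_set_id == keys$choice_set_id[i], ]
    sub <- sub[order(sub$alternative_id), ]
    choice_set(lapply(sub$state_code, state_profile, system = system),
               roles = sub$role, type = sub$task_type[1],
               respondent = keys$respondent_id[i],
               id = keys$choice_set_id[i])
  })
}
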