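# Multi-attribute health-state descriptive systems, state profiles and
# their dummy-coded design vectors.

#' Define a multi-attribute health-state descriptive system
#'
#' An attribute system is an ordered set of health attributes (e.g. mobility,
#' self-care, pain), each with ordered severity levels.  Level index 1 is the
#' best level of an attribute; higher indices are worse.  States are coded as
#' digit strings, one digit per attribute (`"11111"` = best state of a
#' five-attribute system), mirroring the EQ-5D-style convention.
#'
#' The system fixes the dummy coding used throughout the package: each
#' non-reference level (levels 2, 3, ...) of each attribute contributes one
#' 0/1 design-vector entry, with the best level as reference, so the
#' design-vector length is \eqn{\sum_a (L_a - 1)} and the best state maps to
#' the zero vector.  This pins the best state at value 0 and identifies the
#' value scale.
#'
#' @param attributes Named list; one element per attribute, each a character
#'   vector of level labels ordered best to worst (at least two levels).
#' @return An object of class `attribute_system`.
#' @examples
#' sys <- attribute_system(list(
#'   MO = c("no problems", "some problems", "confined to bed"),
#'   SC = c("no problems", "some problems", "unable")
#' ))
#' sys$z_length  # 4
#' @export
attribute_system <- function(attributes) {
  if (!is.list(attributes) || is.null(names(attributes)) ||
      any(!nzchar(names(attributes)))) {
    stop("'attributes' must be a named list of level-label vectors")
  }
  n_levels <- vapply(attributes, length, integer(1))
  if (any(n_levels < 2)) {
    stop("every attribute needs at least 2 levels; offending: ",
         paste(names(attributes)[n_levels < 2], collapse = ", "))
  }
  if (any(n_levels > 9)) {
    stop("digit-string state codes support at most 9 levels per attribute")
  }
  attrs <- names(attributes)
  z_names <- unlist(lapply(attrs, function(a) {
    paste0(a, seq(2, n_levels[[a]]))
  }), use.names = FALSE)
  structure(
    list(
      attributes = attrs,
      levels = lapply(attributes, as.character),
      n_levels = n_levels,
      z_length = sum(n_levels - 1L),
      z_names = z_names
    ),
    class = "attribute_system"
  )
}

#' @export
print.attribute_system <- function(x, ...) {
  cat("Attribute system:", length(x$attributes), "attributes,",
      prod(x$n_levels), "states,", x$z_length, "design-vector entries\n")
  for (a in x$attributes) {
    cat("  ", a, ": ", paste(x$levels[[a]], collapse = " < "), "\n", sep = "")
  }
  invisible(x)
}

#' Read an attribute system from a YAML or JSON config file
#'
#' The config holds a top-level `attributes` mapping from attribute name to
#' the ordered list of level labels (best first).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `attribute_system`.
#' @export
read_attribute_system <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$attributes)) {
    stop("config must contain an 'attributes' mapping: ", path)
  }
  attribute_system(lapply(cfg$attributes, as.character))
}

#' Construct a health-state profile
#'
#' @param code Either a digit string (one digit per attribute, e.g.
#'   `"21121"`) or an integer vector of 1-based level indices.
#' @param system An `attribute_system`.
#' @return An object of class `state_profile` with fields `code`, `levels`
#'   and the dummy design vector `z`.
#' @export
state_profile <- function(code, system) {
  stopifnot(inherits(system, "attribute_system"))
  n_attr <- length(system$attributes)
  if (is.character(code)) {
    stopifnot(length(code) == 1L)
    if (nchar(code) != n_attr || !grepl("^[0-9]+$", code)) {
      stop("state code '", code, "' must be ", n_attr, " digits")
    }
    levels <- as.integer(strsplit(code, "")[[1]])
  } else {
    levels <- as.integer(code)
    if (length(levels) != n_attr) {
      stop("level vector has length ", length(levels), ", expected ", n_attr)
    }
    code <- paste(levels, collapse = "")
  }
  for (i in seq_len(n_attr)) {
    if (levels[i] < 1L || levels[i] > system$n_levels[i]) {
      stop("level ", levels[i], " out of range for attribute '",
           system$attributes[i], "' (1..", system$n_levels[i], ")")
    }
  }
  prof <- structure(list(code = code, levels = levels, z = NULL),
                    class = "state_profile")
  prof$z <- encode_profile(prof, system)
  prof
}

#' @export
print.state_profile <- function(x, ...) {
  cat("State profile ", x$code, " (z: ",
      paste(x$z, collapse = ""), ")\n", sep = "")
  invisible(x)
}

#' Dummy-encode a state profile against its attribute system
#'
#' Returns the 0/1 design vector `z` of the profile: one entry per
#' non-reference level of each attribute, 1 where the profile sits at that
#' level.  Reference (best) levels contribute no entries, so the best state
#' encodes to the zero vector.
#'
#' @param profile A `state_profile`, a digit-string code, or an integer
#'   level vector.
#' @param system An `attribute_system`.
#' @return A named numeric 0/1 vector of length `system$z_length`.
#' @export
encode_profile <- function(profile, system) {
  stopifnot(inherits(system, "attribute_system"))
  levels <- if (inherits(profile, "state_profile")) {
    profile$levels
  } else {
    state_profile(profile, system)$levels
  }
  z <- numeric(system$z_length)
  names(z) <- system$z_names
  pos <- 0L
  for (i in seq_along(system$attributes)) {
    L <- system$n_levels[i]
    if (levels[i] > 1L) z[pos + levels[i] - 1L] <- 1
    pos <- pos + (L - 1L)
  }
  z
}

#' Attribute-level value function
#'
#' Holds the coefficient vector gamma aligned with the design-vector layout
#' of an attribute system.  A state's value is the inner product of its
#' design vector with gamma (additive main-effects value function), so
#' coefficients are the decrements (usually negative) attached to each
#' non-reference attribute level and the best state has value 0.
#'
#' @param gamma Numeric coefficient vector of length `system$z_length`;
#'   names, if present, must match `system$z_names`.
#' @param system An `attribute_system`.
#' @return An object of class `value_function`.
#' @export
value_function <- function(gamma, system) {
  stopifnot(inherits(system, "attribute_system"))
  gamma <- as.numeric(gamma)
  if (length(gamma) != system$z_length) {
    stop("gamma has length ", length(gamma), ", design vector needs ",
         system$z_length)
  }
  names(gamma) <- system$z_names
  structure(list(gamma = gamma, system = system), class = "value_function")
}

#' @export
print.value_function <- function(x, ...) {
  cat("Value function over", length(x$gamma), "attribute-level dummies\n")
  print(round(x$gamma, 4))
  invisible(x)
}

#' Value of a health state under an additive value function
#'
#' Computes \eqn{v_s = z_s \cdot \gamma}: the sum of the coefficients of the
#' non-reference levels the state occupies.
#'
#' @param profile A `state_profile` (or code string, resolved against the
#'   value function's system).
#' @param vf A `value_function`.
#' @return A scalar value.
#' @export
state_value <- function(profile, vf) {
  stopifnot(inherits(vf, "value_function"))
  z <- if (inherits(profile, "state_profile")) {
    profile$z
  } else {
    encode_profile(profile, vf$system)
  }
  if (length(z) != length(vf$gamma)) {
    stop("design vector length ", length(z), " does not match gamma length ",
         length(vf$gamma))
  }
  sum(z * vf$gamma)
}

#' Enumerate every state of an attribute system
#'
#' @param system An `attribute_system`.
#' @return A list of `state_profile` objects covering all
#'   \eqn{\prod_a L_a} states, in lexicographic code order.
#' @export
enumerate_states <- function(system) {
  stopifnot(inherits(system, "attribute_system"))
  grids <- lapply(rev(system$n_levels), seq_len)
  grid <- rev(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  lapply(seq_len(nrow(grid)), function(i) {
    state_profile(as.integer(grid[i, ]), system)
  })
}
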