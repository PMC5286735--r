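#' Specify a synthetic cohort
#'
#' Describes a cohort with planted latent structure: a global patient-level
#' class with `G` classes, per-domain categorical structure derived from the
#' global class through a coupling, and mixed-type indicator variables drawn
#' from category-conditional distributions whose distance from the common
#' marginal is controlled by a separation parameter.
#'
#' @param n Cohort size.
#' @param domains Named list; each entry describes one health domain with
#'   fields `n_categories` (planted domain-level categories), `nominal`,
#'   `ordinal`, `continuous` (variable counts by kind), `nominal_levels`
#'   and `ordinal_levels` (category counts per variable).
#' @param G Number of planted patient-level classes.
#' @param weights Mixing weights (length `G`, summing to 1).
#' @param delta Separation in [0, 1]: 0 makes every variable independent of
#'   the planted structure (parameters equal the shared marginal), 1 puts
#'   each category-conditional distribution at its extreme.
#' @param missing_rate Per-cell MCAR masking probability in [0, 1).
#' @param coupling How a patient's domain category relates to their global
#'   class: `"identity"` (category = class; requires `n_categories >= G`),
#'   `"noisy"` (category = class with probability `1 - coupling_noise`,
#'   otherwise uniform) or `"independent"` (uniform, no shared structure).
#' @param coupling_noise Noise probability for `coupling = "noisy"`.
#' @param seed Integer seed; the whole cohort (generator parameters and
#'   draws) is a pure function of the spec including this seed.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n = 928L, domains = default_domain_template(),
                        G = 3L, weights = rep(1 / G, G), delta = 0.85,
                        missing_rate = 0.05,
                        coupling = c("identity", "noisy", "independent"),
                        coupling_noise = 0.2, seed = 1L) {
  coupling <- match.arg(coupling)
  G <- as.integer(G)
  n <- as.integer(n)
  if (n < G) stop("n must be at least G", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0))
    stop("weights must be nonnegative and sum to 1", call. = FALSE)
  if (length(weights) != G) stop("weights must have length G", call. = FALSE)
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  for (d in names(domains)) {
    dm <- domains[[d]]
    if (dm$n_categories < 2L)
      stop(sprintf("domain '%s': n_categories must be >= 2", d), call. = FALSE)
    if (coupling == "identity" && dm$n_categories < G)
      stop(sprintf("domain '%s': identity coupling needs n_categories >= G", d),
           call. = FALSE)
    if ((dm$nominal %||% 0) + (dm$ordinal %||% 0) + (dm$continuous %||% 0) < 1L)
      stop(sprintf("domain '%s' has no variables", d), call. = FALSE)
    if (!is.null(dm$nominal_levels) && dm$nominal_levels < 2L)
      stop(sprintf("domain '%s': nominal_levels must be >= 2", d), call. = FALSE)
    if (!is.null(dm$ordinal_levels) && dm$ordinal_levels < 2L)
      stop(sprintf("domain '%s': ordinal_levels must be >= 2", d), call. = FALSE)
  }
  structure(list(n = n, domains = domains, G = G, weights = weights,
                 delta = delta, missing_rate = missing_rate,
                 coupling = coupling, coupling_noise = coupling_noise,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# The six-domain, 112-variable template: category counts per domain follow
# the published second-stage variable characteristics (activity 7,
# contextual 7, pain 7, participation 7, physical impairment 6,
# psychology 8); the variable-kind apportionment mirrors the questionnaire
# inventory (clinician-reported physical tests mostly dichotomous, patient
# scales mostly ordinal, plus a few continuous measures such as age or BMI).
default_domain_template <- function() {
  list(
    activity = list(n_categories = 7L, nominal = 12L, nominal_levels = 2L,
                    ordinal = 6L, ordinal_levels = 5L, continuous = 2L),
    contextual = list(n_categories = 7L, nominal = 10L, nominal_levels = 2L,
                      ordinal = 3L, ordinal_levels = 5L, continuous = 2L),
    pain = list(n_categories = 7L, nominal = 12L, nominal_levels = 2L,
                ordinal = 6L, ordinal_levels = 5L, continuous = 2L),
    participation = list(n_categories = 7L, nominal = 10L, nominal_levels = 2L,
                         ordinal = 4L, ordinal_levels = 5L, continuous = 1L),
    physical_impairment = list(n_categories = 6L, nominal = 22L,
                               nominal_levels = 2L, ordinal = 3L,
                               ordinal_levels = 5L, continuous = 0L),
    psychology = list(n_categories = 8L, nominal = 9L, nominal_levels = 2L,
                      ordinal = 6L, ordinal_levels = 5L, continuous = 2L))
}

#' Default synthetic cohort specification
#'
#' The study-scale template: 928 patients, six health domains, 112 mixed
#' nominal/ordinal/continuous variables, domain category counts
#' (7, 7, 7, 7, 6, 8), three planted patient-level classes with equal
#' weights, separation 0.85, and 5% MCAR cell missingness (under which at
#' least 95% of rows have more than 86% complete data).
#'
#' @param ... Overrides passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(...) {
  cohort_spec(...)
}

#' @export
print.cohort_spec <- function(x, ...) {
  nv <- sum(vapply(x$domains, function(d)
    (d$nominal %||% 0) + (d$ordinal %||% 0) + (d$continuous %||% 0), numeric(1)))
  cat(sprintf("<cohort_spec> n = %d, %d domains, %d variables, G = %d, delta = %.2f, %s coupling, %.0f%% missing\n",
              x$n, length(x$domains), nv, x$G, x$delta, x$coupling,
              100 * x$missing_rate))
  invisible(x)
}

# Deterministic codebook implied by a cohort spec.
spec_codebook <- function(spec) {
  specs <- list()
  for (d in names(spec$domains)) {
    dm <- spec$domains[[d]]
    dom <- if (d %in% c("activity", "contextual", "pain", "participation",
                        "physical_impairment", "psychology")) d else "other"
    for (i in seq_len(dm$nominal %||% 0)) {
      L <- dm$nominal_levels %||% 2L
      lev <- as.character(seq_len(L) - 1L)
      specs[[length(specs) + 1L]] <-
        variable_spec(sprintf("%s_nom%02d", d, i), "nominal", dom,
                      levels = lev, severe_level = lev[L])
    }
    for (i in seq_len(dm$ordinal %||% 0)) {
      L <- dm$ordinal_levels %||% 5L
      specs[[length(specs) + 1L]] <-
        variable_spec(sprintf("%s_ord%02d", d, i), "ordinal", dom,
                      levels = as.character(seq_len(L)),
                      severity_direction = "higher_worse")
    }
    for (i in seq_len(dm$continuous %||% 0)) {
      specs[[length(specs) + 1L]] <-
        variable_spec(sprintf("%s_con%02d", d, i), "continuous", dom,
                      range = c(-15, 15),
                      severity_direction = "higher_worse")
    }
  }
  codebook(specs)
}

#' Generate a synthetic cohort with known latent structure
#'
#' Draws each patient's global class from the spec's mixing weights, derives
#' their category in every domain through the spec's coupling, then draws
#' each variable from its category-conditional distribution:
#' * categorical: `theta(delta) = (1 - delta) * uniform + delta * extreme`,
#'   where each (variable, category) pair has a randomly anchored extreme
#'   (a point mass on one level);
#' * continuous: Normal with unit variance and mean `delta * offset_c`,
#'   the offsets being a per-variable random permutation of equally spaced
#'   anchors centered at zero.
#'
#' MCAR missingness at the spec's rate is applied last (rows that would
#' become all-missing are re-drawn). The result is a pure function of the
#' spec, including its seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `data` (an `lca_dataset`), `codebook`, and `truth`
#'   (class `"synthetic_truth"`: per-patient global `class`, per-domain
#'   `domain_category` matrix, and the generator `params`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cb <- spec_codebook(spec)
  withr::with_seed(spec$seed, {
    params <- draw_generator_params(spec, cb)
    cls <- sample.int(spec$G, spec$n, replace = TRUE, prob = spec$weights)
    domains <- names(spec$domains)
    domcat <- matrix(NA_integer_, spec$n, length(domains),
                     dimnames = list(NULL, domains))
    for (d in domains) {
      C <- spec$domains[[d]]$n_categories
      domcat[, d] <- switch(spec$coupling,
        identity = cls,
        noisy = {
          flip <- stats::runif(spec$n) < spec$coupling_noise
          out <- cls
          out[flip] <- sample.int(C, sum(flip), replace = TRUE)
          out
        },
        independent = sample.int(C, spec$n, replace = TRUE))
    }
    df <- draw_variables(spec, cb, domcat, params)
    if (spec$missing_rate > 0)
      df <- mask_cells(df, spec$missing_rate)
    ds <- lca_dataset(df, cb)
    truth <- structure(list(class = cls, domain_category = domcat,
                            params = params),
                       class = "synthetic_truth")
    list(data = ds, codebook = cb, truth = truth)
  })
}

# Category-conditional parameters for every variable, drawn once per cohort.
draw_generator_params <- function(spec, cb) {
  params <- list()
  for (nm in variable_names(cb)) {
    vs <- cb$variables[[nm]]
    d <- sub("_(nom|ord|con)[0-9]+$", "", nm)
    C <- spec$domains[[d]]$n_categories
    if (is_categorical(vs)) {
      L <- n_levels(vs)
      anchors <- sample.int(L, C, replace = TRUE)
      theta <- matrix((1 - spec$delta) / L, C, L)
      theta[cbind(seq_len(C), anchors)] <-
        theta[cbind(seq_len(C), anchors)] + spec$delta
      params[[nm]] <- list(domain = d, theta = theta)
    } else {
      spacing <- 1.5
      offsets <- spacing * (seq_len(C) - (C + 1) / 2)
      offsets <- sample(offsets)
      params[[nm]] <- list(domain = d, mu = spec$delta * offsets, sd = 1)
    }
  }
  params
}

draw_variables <- function(spec, cb, domcat, params) {
  n <- spec$n
  df <- vector("list", length(cb$variables))
  names(df) <- variable_names(cb)
  for (nm in variable_names(cb)) {
    vs <- cb$variables[[nm]]
    p <- params[[nm]]
    cat_i <- domcat[, p$domain]
    if (is_categorical(vs)) {
      L <- n_levels(vs)
      u <- stats::runif(n)
      cum <- t(apply(p$theta, 1L, cumsum))      # C x L
      idx <- rowSums(u > cum[cat_i, , drop = FALSE]) + 1L
      df[[nm]] <- vs$levels[pmin(idx, L)]
    } else {
      y <- stats::rnorm(n, mean = p$mu[cat_i], sd = p$sd)
      df[[nm]] <- pmin(pmax(y, vs$range[1]), vs$range[2])
    }
  }
  as.data.frame(df, stringsAsFactors = FALSE)
}

# MCAR cell masking on a raw data.frame; rows that would become all-missing
# have their mask re-drawn.
mask_cells <- function(df, rate) {
  n <- nrow(df)
  p <- ncol(df)
  mask <- matrix(stats::runif(n * p) < rate, n, p)
  bad <- which(rowSums(mask) == p)
  while (length(bad)) {
    mask[bad, ] <- matrix(stats::runif(length(bad) * p) < rate,
                          length(bad), p)
    bad <- bad[rowSums(mask[bad, , drop = FALSE]) == p]
  }
  for (j in seq_len(p)) df[[j]][mask[, j]] <- NA
  df
}

#' Apply MCAR missingness to an existing dataset
#'
#' Masks each cell independently with probability `rate`; rows that would
#' become entirely missing are re-drawn so the dataset invariant holds.
#'
#' @param data An `lca_dataset`.
#' @param rate Masking probability in [0, 1).
#' @param seed Integer seed.
#' @return An `lca_dataset`.
#' @export
inject_missing <- function(data, rate, seed = 1L) {
  stopifnot(inherits(data, "lca_dataset"))
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)", call. = FALSE)
  if (rate == 0) return(data)
  df <- withr::with_seed(seed, mask_cells(data$data, rate))
  lca_dataset(df, data$codebook, ids = data$ids)
}
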