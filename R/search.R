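#' Retention rule for a set of restarted fits
#'
#' Operationalizes "use the model with the most consistent BIC": BIC values
#' are rounded to 2 decimals and tallied; if a unique modal value with
#' multiplicity >= 2 exists, the best-log-likelihood fit attaining it is
#' retained; otherwise (all values distinct, or several values tied at the
#' maximal multiplicity) the fit with the minimal BIC is retained.
#'
#' @param bic_values Numeric vector of per-restart BIC values.
#' @param logliks Optional per-restart log-likelihoods used to break ties
#'   among fits sharing the modal rounded BIC; defaults to `-bic_values`.
#' @return The integer index of the retained restart.
#' @export
choose_consistent_bic <- function(bic_values, logliks = -bic_values) {
  stopifnot(length(bic_values) >= 1L, length(logliks) == length(bic_values))
  r <- round(bic_values, 2)
  tab <- table(r)
  top <- max(tab)
  modal <- names(tab)[tab == top]
  if (top >= 2 && length(modal) == 1L) {
    cand <- which(r == as.numeric(modal))
    return(cand[which.max(logliks[cand])])
  }
  which.min(bic_values)
}

#' Fit one class count with seeded random restarts
#'
#' Runs [fit_em()] `n_restarts` times with restart seeds
#' `base_seed + 1, ..., base_seed + n_restarts` and retains one fit by the
#' most-consistent-BIC rule of [choose_consistent_bic()].
#'
#' @param data An `lca_dataset`.
#' @param K Class count.
#' @param n_restarts Number of restarts (default 10).
#' @param base_seed Integer; restart seeds are derived from it.
#' @param ... Passed to [fit_em()] (`tol`, `max_iter`, `variance_mode`).
#' @return An object of class `"lca_restarts"`: `K`, list of `fits`,
#'   `bic_values`, index `chosen`, the retained `fit`, and
#'   `any_converged`.
#' @export
fit_with_restarts <- function(data, K, n_restarts = 10L, base_seed = 1L, ...) {
  stopifnot(n_restarts >= 1L)
  seeds <- as.integer(base_seed) + seq_len(n_restarts)
  fits <- lapply(seeds, function(s) fit_em(data, K, seed = s, ...))
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  chosen <- choose_consistent_bic(bics, lls)
  any_conv <- any(vapply(fits, `[[`, logical(1), "converged"))
  if (!any_conv)
    warning(sprintf("no restart converged at K = %d", K), call. = FALSE)
  structure(list(K = K, fits = fits, bic_values = bics, chosen = chosen,
                 fit = fits[[chosen]], any_converged = any_conv),
            class = "lca_restarts")
}

#' @export
print.lca_restarts <- function(x, ...) {
  cat(sprintf("<lca_restarts> K = %d, %d restarts; retained restart %d (BIC %.2f)\n",
              x$K, length(x$fits), x$chosen, x$bic_values[x$chosen]))
  invisible(x)
}

#' Starting-model rule on a BIC table
#'
#' Walks class counts upward from K = 1 and continues while adding a class
#' decreases BIC by at least 1% (`BIC(K) <= 0.99 BIC(K-1)`). The starting
#' model is the last class count reached, capped at the global BIC argmin
#' should the walk overshoot it (possible only with non-monotone tables).
#'
#' @param bic_table Named numeric vector of retained BICs for consecutive
#'   class counts starting at 1 (names "1", "2", ...; unnamed vectors are
#'   taken in order).
#' @return The starting-model class count (integer).
#' @export
select_starting_model <- function(bic_table) {
  if (length(bic_table) == 0L) stop("empty BIC table", call. = FALSE)
  b <- as.numeric(bic_table)
  if (!is.null(names(bic_table))) {
    ks <- as.integer(names(bic_table))
    if (any(is.na(ks)) || !identical(ks, seq_along(b)))
      stop("bic_table must cover consecutive K starting at 1", call. = FALSE)
  }
  k <- 1L
  while (k < length(b) && b[k + 1L] <= 0.99 * b[k]) k <- k + 1L
  min(k, which.min(b))
}

#' Search class counts 1..K_max
#'
#' Fits every class count with restarts, tabulates the retained BICs and
#' applies the starting-model rule. The preferred model is deliberately left
#' undesignated: choosing it is a human consensus step informed by the
#' diagnostics, not an automated rule.
#'
#' @param data An `lca_dataset`.
#' @param K_max Largest class count (default 12).
#' @param n_restarts Restarts per class count (default 10).
#' @param base_seed Integer seed; each class count K uses restart base
#'   `base_seed + (K - 1) * n_restarts` so all restart seeds in the search
#'   are distinct. The whole search is a pure function of
#'   (data, settings, `base_seed`).
#' @param ... Passed to [fit_em()].
#' @return An object of class `"lca_search"`: `per_K` (list of
#'   `lca_restarts`), `bic_table` (named numeric), `starting_K`,
#'   `preferred_K` (NA until set by the analyst) and `errors` (per-K error
#'   messages, if any class count failed).
#' @export
run_search <- function(data, K_max = 12L, n_restarts = 10L, base_seed = 1L, ...) {
  stopifnot(K_max >= 1L)
  per_K <- vector("list", K_max)
  errors <- character(0)
  for (K in seq_len(K_max)) {
    res <- tryCatch(
      fit_with_restarts(data, K, n_restarts = n_restarts,
                        base_seed = as.integer(base_seed) + (K - 1L) * n_restarts,
                        ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[as.character(K)] <- conditionMessage(res)
      warning(sprintf("K = %d failed: %s", K, conditionMessage(res)),
              call. = FALSE)
    } else {
      per_K[[K]] <- res
    }
  }
  fitted_K <- which(!vapply(per_K, is.null, logical(1)))
  if (!length(fitted_K)) stop("every class count failed", call. = FALSE)
  bic_table <- vapply(per_K[fitted_K],
                      function(r) r$bic_values[r$chosen], numeric(1))
  names(bic_table) <- as.character(fitted_K)
  prefix <- 0L
  while (prefix + 1L <= K_max && !is.null(per_K[[prefix + 1L]]))
    prefix <- prefix + 1L
  if (prefix >= 1L) {
    starting_K <- select_starting_model(bic_table[as.character(seq_len(prefix))])
  } else {
    warning("K = 1 failed; starting model undetermined", call. = FALSE)
    starting_K <- NA_integer_
  }
  structure(list(per_K = per_K, bic_table = bic_table,
                 starting_K = starting_K, preferred_K = NA_integer_,
                 errors = errors),
            class = "lca_search")
}

#' @export
print.lca_search <- function(x, ...) {
  cat("<lca_search>\n  K   BIC\n")
  for (k in names(x$bic_table))
    cat(sprintf("  %-3s %.2f%s\n", k, x$bic_table[[k]],
                if (as.integer(k) == x$starting_K) "  <- starting model" else ""))
  invisible(x)
}

#' Retained fit for a class count of a search
#'
#' @param search An `lca_search`.
#' @param K Class count; defaults to the starting model.
#' @return An `lca_fit`.
#' @export
search_fit <- function(search, K = search$starting_K) {
  stopifnot(inherits(search, "lca_search"))
  r <- search$per_K[[K]]
  if (is.null(r)) stop(sprintf("no fit available at K = %d", K), call. = FALSE)
  r$fit
}

#' Variable-subgroup association ("loadings")
#'
#' Scale-free association between each variable and the modal class
#' membership of a fit: Cramer's V for nominal variables, the correlation
#' ratio (eta) for ordinal (integer-scored) and continuous variables. All
#' values lie in [0, 1]; a constant variable scores 0 with a warning.
#'
#' @param fit An `lca_fit`.
#' @param data The `lca_dataset` the fit was estimated on.
#' @return A data.frame with columns `variable`, `kind`, `statistic`
#'   (`"cramers_v"` or `"eta"`) and `association`.
#' @export
loadings <- function(fit, data) {
  stopifnot(inherits(fit, "lca_fit"), inherits(data, "lca_dataset"))
  if (length(fit$assignments) != data$n)
    stop("fit and dataset have different numbers of patients", call. = FALSE)
  cls <- fit$assignments
  out <- lapply(variable_names(data$codebook), function(nm) {
    spec <- data$codebook$variables[[nm]]
    x <- data$data[[nm]]
    obs <- !is.na(x)
    if (spec$kind == "nominal") {
      stat <- "cramers_v"
      a <- cramers_v(x[obs], cls[obs])
    } else {
      stat <- "eta"
      sc <- if (spec$kind == "ordinal") match(x, spec$levels) else x
      a <- correlation_ratio(sc[obs], cls[obs])
    }
    data.frame(variable = nm, kind = spec$kind, statistic = stat,
               association = a)
  })
  do.call(rbind, out)
}

cramers_v <- function(x, g) {
  if (length(unique(x)) < 2L || length(unique(g)) < 2L) {
    warning("constant variable or single class: association set to 0",
            call. = FALSE)
    return(0)
  }
  tab <- table(x, g)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  v <- sqrt(as.numeric(chi2) / (sum(tab) * (min(dim(tab)) - 1L)))
  min(max(v, 0), 1)
}

correlation_ratio <- function(y, g) {
  if (stats::var(y) == 0 || length(unique(g)) < 2L) {
    if (stats::var(y) == 0)
      warning("constant variable: association set to 0", call. = FALSE)
    return(0)
  }
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ss_between <- sum(ns * (means - mean(y))^2)
  ss_total <- sum((y - mean(y))^2)
  min(max(sqrt(ss_between / ss_total), 0), 1)
}
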