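# Internal numeric encoding of a dataset against its codebook.
# Categorical variables become integer codes plus an n x C indicator matrix
# whose missing rows are all-zero, so that a single matrix product gives each
# variable's log-density contribution and its weighted category counts.
encode_dataset <- function(data) {
  stopifnot(inherits(data, "lca_dataset"))
  cb <- data$codebook
  cat_enc <- list()
  cont_enc <- list()
  for (nm in variable_names(cb)) {
    spec <- cb$variables[[nm]]
    x <- data$data[[nm]]
    if (is_categorical(spec)) {
      codes <- match(x, spec$levels)
      C <- n_levels(spec)
      obs <- !is.na(codes)
      ind <- matrix(0, nrow = length(codes), ncol = C)
      if (any(obs)) ind[cbind(which(obs), codes[obs])] <- 1
      cat_enc[[nm]] <- list(codes = codes, C = C, ind = ind,
                            obs = as.numeric(obs))
    } else {
      obs <- !is.na(x)
      y0 <- ifelse(obs, x, 0)
      sv <- if (sum(obs) > 0L)
        sum((y0[obs] - mean(y0[obs]))^2) / sum(obs) else 1
      cont_enc[[nm]] <- list(y = x, y0 = y0, obs = as.numeric(obs),
                             sample_var = sv)
    }
  }
  list(cat = cat_enc, cont = cont_enc, n = data$n)
}

check_model_data <- function(model, data) {
  mvars <- c(names(model$theta), rownames(model$mu))
  dvars <- variable_names(data$codebook)
  if (!setequal(mvars, dvars))
    stop("model and dataset codebooks declare different variables", call. = FALSE)
  for (nm in names(model$theta)) {
    C <- n_levels(data$codebook$variables[[nm]])
    if (ncol(model$theta[[nm]]) != C)
      stop(sprintf("variable '%s': model has %d categories, codebook %d",
                   nm, ncol(model$theta[[nm]]), C), call. = FALSE)
  }
  invisible(TRUE)
}

# n x K matrix of per-row log conditional densities log prod_j f_j(y_ij | k),
# skipping missing entries.
log_density_matrix <- function(model, enc) {
  n <- enc$n
  K <- model$K
  logf <- matrix(0, n, K)
  for (nm in names(enc$cat)) {
    th <- model$theta[[nm]]                     # K x C
    logf <- logf + enc$cat[[nm]]$ind %*% t(log(th))
  }
  for (nm in names(enc$cont)) {
    e <- enc$cont[[nm]]
    mu <- model$mu[nm, ]                        # length K
    s2 <- if (model$variance_mode == "pooled")
      rep(model$sigma2[nm], K) else model$sigma2[nm, ]
    for (k in seq_len(K)) {
      logf[, k] <- logf[, k] +
        e$obs * (-0.5 * (log(2 * pi * s2[k]) + (e$y0 - mu[k])^2 / s2[k]))
    }
  }
  logf
}

posterior_from_logf <- function(logf, pi) {
  a <- sweep(logf, 2L, log(pmax(pi, 1e-300)), `+`)
  m <- apply(a, 1L, max)
  bad <- !is.finite(m)
  if (any(bad))
    stop(sprintf("row(s) %s have zero likelihood under every class",
                 paste(utils::head(which(bad), 5), collapse = ", ")),
         call. = FALSE)
  e <- exp(a - m)
  s <- rowSums(e)
  list(posteriors = e / s, loglik = sum(m + log(s)))
}

#' Mixture log-likelihood of a latent class model
#'
#' Total log-likelihood of the data under the model, with missing entries
#' skipped (each row contributes the mixture density of its observed
#' variables only, the ignorable-missingness likelihood).
#'
#' @param model An `lca_model`.
#' @param data An `lca_dataset` whose codebook matches the model.
#' @return A scalar.
#' @export
loglikelihood <- function(model, data) {
  check_model_data(model, data)
  enc <- encode_dataset(data)
  posterior_from_logf(log_density_matrix(model, enc), model$pi)$loglik
}

#' Posterior class-membership probabilities (E step)
#'
#' Bayes' rule over the model's classes, computed in the log domain to avoid
#' underflow: `p_ik = pi_k prod_j f_j(y_ij|k) / sum_m pi_m prod_j f_j(y_ij|m)`.
#' Each returned row sums to 1.
#'
#' @inheritParams loglikelihood
#' @return An `n x K` posterior matrix.
#' @export
e_step <- function(model, data) {
  check_model_data(model, data)
  enc <- encode_dataset(data)
  posterior_from_logf(log_density_matrix(model, enc), model$pi)$posteriors
}

new_lca_model <- function(K, pi, theta, mu, sigma2, variance_mode, codebook) {
  structure(list(K = K, pi = pi, theta = theta, mu = mu, sigma2 = sigma2,
                 variance_mode = variance_mode, codebook = codebook),
            class = "lca_model")
}

#' @export
print.lca_model <- function(x, ...) {
  cat(sprintf("<lca_model> K = %d classes, %d categorical + %d continuous variables\n",
              x$K, length(x$theta), NROW(x$mu)))
  cat("class weights:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

#' Parameter update (M step)
#'
#' Weighted maximum-likelihood update of all model parameters given
#' responsibilities: class weights are mean responsibilities; conditional
#' category probabilities are responsibility-weighted relative frequencies
#' among rows observed on the variable (floored at 1e-6 and renormalized);
#' class means are weighted means; variances are weighted variances, pooled
#' across classes per variable by default, floored at 1e-6 times the
#' variable's sample variance. A class whose total responsibility falls
#' below `collapse_eps` raises a warning of class `"lcasub_class_collapse"`
#' (a restart is advisable) rather than being silently renormalized.
#'
#' @param posteriors `n x K` matrix with rows summing to 1.
#' @param data An `lca_dataset`.
#' @param codebook Codebook to fit against (defaults to the dataset's).
#' @param variance_mode `"pooled"` (one variance per continuous variable) or
#'   `"class_specific"`.
#' @param collapse_eps Total-responsibility threshold below which a class is
#'   reported as collapsed.
#' @return An `lca_model`.
#' @export
m_step <- function(posteriors, data, codebook = data$codebook,
                   variance_mode = c("pooled", "class_specific"),
                   collapse_eps = 1e-6) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(inherits(data, "lca_dataset"))
  posteriors <- as.matrix(posteriors)
  if (nrow(posteriors) != data$n)
    stop("posterior rows must match the number of patients", call. = FALSE)
  enc <- encode_dataset(data)
  m_step_enc(posteriors, enc, codebook, variance_mode, collapse_eps)
}

m_step_enc <- function(posteriors, enc, codebook, variance_mode,
                       collapse_eps = 1e-6) {
  n <- enc$n
  K <- ncol(posteriors)
  Nk <- colSums(posteriors)
  if (any(Nk < collapse_eps))
    warning(structure(class = c("lcasub_class_collapse", "warning", "condition"),
                      list(message = sprintf(
                        "class(es) %s collapsed (total responsibility < %g); consider restarting",
                        paste(which(Nk < collapse_eps), collapse = ", "),
                        collapse_eps),
                        call = NULL)))
  pi <- Nk / n

  theta <- list()
  for (nm in names(enc$cat)) {
    e <- enc$cat[[nm]]
    counts <- crossprod(e$ind, posteriors)          # C x K
    denom <- pmax(colSums(posteriors * e$obs), 1e-12)
    th <- t(counts) / denom                          # K x C
    th <- pmax(th, 1e-6)
    th <- th / rowSums(th)
    theta[[nm]] <- th
  }

  cont_names <- names(enc$cont)
  mu <- matrix(NA_real_, length(cont_names), K,
               dimnames = list(cont_names, NULL))
  if (variance_mode == "pooled") {
    sigma2 <- stats::setNames(numeric(length(cont_names)), cont_names)
  } else {
    sigma2 <- matrix(NA_real_, length(cont_names), K,
                     dimnames = list(cont_names, NULL))
  }
  for (nm in cont_names) {
    e <- enc$cont[[nm]]
    w <- posteriors * e$obs                          # n x K
    sw <- pmax(colSums(w), 1e-12)
    swy <- colSums(w * e$y0)
    swy2 <- colSums(w * e$y0^2)
    mu_k <- swy / sw
    ss_k <- pmax(swy2 - sw * mu_k^2, 0)
    floor_j <- max(1e-6 * e$sample_var, 1e-12)
    mu[nm, ] <- mu_k
    if (variance_mode == "pooled") {
      sigma2[nm] <- max(sum(ss_k) / sum(sw), floor_j)
    } else {
      sigma2[nm, ] <- pmax(ss_k / sw, floor_j)
    }
  }
  new_lca_model(K, pi, theta, mu, sigma2, variance_mode, codebook)
}

reorder_classes <- function(model, perm) {
  model$pi <- model$pi[perm]
  model$theta <- lapply(model$theta, function(th) th[perm, , drop = FALSE])
  if (NROW(model$mu) > 0) model$mu <- model$mu[, perm, drop = FALSE]
  if (model$variance_mode == "class_specific" && NROW(model$sigma2) > 0)
    model$sigma2 <- model$sigma2[, perm, drop = FALSE]
  model
}

#' Count free parameters of a latent class model
#'
#' `(K - 1)` class weights, `K (C_j - 1)` conditional probabilities per
#' categorical variable with `C_j` categories, and per continuous variable
#' `K` means plus one pooled variance (or `K` class-specific variances).
#'
#' @param codebook An `lca_codebook`.
#' @param K Class count (>= 1).
#' @param variance_mode `"pooled"` or `"class_specific"`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(codebook, K,
                         variance_mode = c("pooled", "class_specific")) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(inherits(codebook, "lca_codebook"), K >= 1)
  p <- K - 1
  for (spec in codebook$variables) {
    if (is_categorical(spec)) {
      p <- p + K * (n_levels(spec) - 1L)
    } else {
      p <- p + if (variance_mode == "pooled") K + 1L else 2L * K
    }
  }
  as.integer(p)
}

#' Bayesian Information Criterion
#'
#' `BIC = -2 loglik + p log(n)`; lower is better, balancing model fit and
#' parsimony.
#'
#' @param loglik Total log-likelihood.
#' @param n_params Free-parameter count.
#' @param n_obs Number of observations (>= 1).
#' @return A scalar.
#' @export
bic <- function(loglik, n_params, n_obs) {
  if (n_obs < 1) stop("n_obs must be >= 1", call. = FALSE)
  -2 * loglik + n_params * log(n_obs)
}

#' Modal class assignment
#'
#' Assigns each row to the class with the largest posterior probability;
#' ties break toward the lowest class index.
#'
#' @param posteriors Posterior matrix with rows summing to 1.
#' @return Integer vector of class indices.
#' @export
modal_assign <- function(posteriors) {
  max.col(as.matrix(posteriors), ties.method = "first")
}

#' Fit a latent class model by EM
#'
#' Alternates the E and M steps from a seed-determined random start
#' (per-row responsibilities drawn from a symmetric Dirichlet(1), followed
#' by an M step) until the relative log-likelihood change drops below `tol`
#' or `max_iter` iterations. The log-likelihood is non-decreasing across
#' iterations. On return, classes are relabelled in descending class-weight
#' order so that restarts reaching the same optimum agree up to numerics.
#'
#' @param data An `lca_dataset`.
#' @param K Number of classes (`1 <= K <= n`).
#' @param seed Integer seed controlling the random start; the same data,
#'   `K` and seed give an identical fit.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap; hitting it returns `converged = FALSE`
#'   with a warning.
#' @param variance_mode Passed to [m_step()].
#' @return An object of class `"lca_fit"`: the fitted `model`, `loglik`,
#'   `n_params`, `n_obs`, `bic`, posterior matrix `posteriors`, modal
#'   `assignments`, `converged`, `n_iter`, the iteration `loglik_path`,
#'   `collapsed` flag and the `seed`.
#' @export
fit_em <- function(data, K, seed = 1L, tol = 1e-8, max_iter = 1000L,
                   variance_mode = c("pooled", "class_specific")) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(inherits(data, "lca_dataset"))
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K > data$n) stop(sprintf("K = %d exceeds n = %d", K, data$n), call. = FALSE)
  cb <- data$codebook
  enc <- encode_dataset(data)
  n <- data$n

  resp <- withr::with_seed(seed, {
    g <- matrix(stats::rexp(n * K), n, K)
    g / rowSums(g)
  })

  collapsed <- FALSE
  record_collapse <- function(w) {
    if (inherits(w, "lcasub_class_collapse")) {
      collapsed <<- TRUE
      invokeRestart("muffleWarning")
    }
  }

  model <- withCallingHandlers(
    m_step_enc(resp, enc, cb, variance_mode),
    warning = record_collapse)

  loglik_path <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    es <- posterior_from_logf(log_density_matrix(model, enc), model$pi)
    ll <- es$loglik
    loglik_path <- c(loglik_path, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    model <- withCallingHandlers(
      m_step_enc(es$posteriors, enc, cb, variance_mode),
      warning = record_collapse)
    ll_prev <- ll
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations (K = %d, seed = %d)",
                    max_iter, K, seed), call. = FALSE)

  perm <- order(model$pi, decreasing = TRUE)
  model <- reorder_classes(model, perm)
  es <- posterior_from_logf(log_density_matrix(model, enc), model$pi)
  p <- n_parameters(cb, K, variance_mode)
  structure(list(model = model,
                 loglik = es$loglik,
                 n_params = p,
                 n_obs = n,
                 bic = bic(es$loglik, p, n),
                 posteriors = es$posteriors,
                 assignments = modal_assign(es$posteriors),
                 converged = converged,
                 n_iter = iter,
                 loglik_path = loglik_path,
                 collapsed = collapsed,
                 seed = as.integer(seed)),
            class = "lca_fit")
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("<lca_fit> K = %d  loglik = %.3f  BIC = %.3f  (%s in %d iterations)\n",
              x$model$K, x$loglik, x$bic,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("class shares (modal):",
      paste(sprintf("%.3f", tabulate(x$assignments, x$model$K) / x$n_obs),
            collapse = " "), "\n")
  invisible(x)
}

#' Export fitted parameters in long format
#'
#' One row per (variable, class, category) for conditional probabilities,
#' per (variable, class) for means and variances, and per class for weights.
#'
#' @param fit An `lca_fit`.
#' @return A data.frame with columns `variable`, `class`, `category`,
#'   `parameter`, `value`.
#' @export
fit_parameters <- function(fit) {
  stopifnot(inherits(fit, "lca_fit"))
  m <- fit$model
  rows <- list(data.frame(variable = "", class = seq_len(m$K), category = "",
                          parameter = "class_weight", value = m$pi))
  for (nm in names(m$theta)) {
    th <- m$theta[[nm]]
    lev <- m$codebook$variables[[nm]]$levels
    rows[[length(rows) + 1L]] <- data.frame(
      variable = nm,
      class = rep(seq_len(m$K), times = ncol(th)),
      category = rep(lev, each = m$K),
      parameter = "conditional_prob",
      value = as.vector(th))
  }
  for (nm in rownames(m$mu)) {
    rows[[length(rows) + 1L]] <- data.frame(
      variable = nm, class = seq_len(m$K), category = "",
      parameter = "mean", value = m$mu[nm, ])
    v <- if (m$variance_mode == "pooled") rep(m$sigma2[nm], m$K) else m$sigma2[nm, ]
    rows[[length(rows) + 1L]] <- data.frame(
      variable = nm, class = seq_len(m$K), category = "",
      parameter = "variance", value = v)
  }
  do.call(rbind, rows)
}
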