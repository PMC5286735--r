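# Shared fixtures: tiny codebooks, hand-built models, and a reduced
# six-domain cohort spec used by the recovery suites.

binary_codebook <- function(name = "y") {
  codebook(variable_spec(name, "nominal", levels = c("0", "1"),
                         severe_level = "1"))
}

# K-class model over a single binary variable: P(y = "1" | class k) = p1[k].
binary_model <- function(pi, p1, cb = binary_codebook()) {
  K <- length(pi)
  theta <- list(y = cbind(1 - p1, p1))
  lcasub:::new_lca_model(K = K, pi = pi, theta = theta,
                         mu = matrix(numeric(0), 0, K),
                         sigma2 = stats::setNames(numeric(0), character(0)),
                         variance_mode = "pooled", codebook = cb)
}

binary_dataset <- function(values, cb = binary_codebook()) {
  lca_dataset(data.frame(y = as.character(values)), cb)
}

# Mixed three-variable codebook for oracle tests: one 3-level nominal, one
# 2-level nominal, one continuous.
mixed_codebook <- function() {
  codebook(
    variable_spec("a", "nominal", levels = c("1", "2", "3")),
    variable_spec("b", "nominal", levels = c("0", "1")),
    variable_spec("z", "continuous", range = c(-10, 10)))
}

# Random valid model over mixed_codebook(), drawn under a seed.
random_mixed_model <- function(K, seed) {
  cb <- mixed_codebook()
  withr::with_seed(seed, {
    pi <- stats::rexp(K); pi <- pi / sum(pi)
    th_a <- matrix(stats::rexp(K * 3), K); th_a <- th_a / rowSums(th_a)
    th_b <- matrix(stats::rexp(K * 2), K); th_b <- th_b / rowSums(th_b)
    mu <- matrix(stats::rnorm(K, sd = 2), 1, K, dimnames = list("z", NULL))
    sigma2 <- stats::setNames(stats::runif(1, 0.5, 2), "z")
    lcasub:::new_lca_model(K, pi, list(a = th_a, b = th_b), mu, sigma2,
                           "pooled", cb)
  })
}

# Random small dataset over mixed_codebook() with some missing cells.
random_mixed_dataset <- function(n, seed, missing_rate = 0.15) {
  cb <- mixed_codebook()
  withr::with_seed(seed, {
    df <- data.frame(
      a = sample(c("1", "2", "3"), n, replace = TRUE),
      b = sample(c("0", "1"), n, replace = TRUE),
      z = round(stats::rnorm(n, sd = 2), 3))
    for (j in seq_along(df)) {
      mask <- stats::runif(n) < missing_rate
      df[[j]][mask] <- NA
    }
    keep <- rowSums(!is.na(df)) > 0
    lca_dataset(df[keep, , drop = FALSE], cb)
  })
}

# Brute-force posterior oracle: direct products of densities, no log-space
# computation, independent of the package's E-step path.
oracle_posteriors <- function(model, data) {
  n <- data$n
  K <- model$K
  post <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    dens <- numeric(K)
    for (k in seq_len(K)) {
      p <- model$pi[k]
      for (nm in names(model$theta)) {
        x <- data$data[[nm]][i]
        if (!is.na(x)) {
          lev <- match(x, model$codebook$variables[[nm]]$levels)
          p <- p * model$theta[[nm]][k, lev]
        }
      }
      for (nm in rownames(model$mu)) {
        y <- data$data[[nm]][i]
        if (!is.na(y)) {
          s2 <- if (model$variance_mode == "pooled") model$sigma2[[nm]]
                else model$sigma2[nm, k]
          p <- p * stats::dnorm(y, model$mu[nm, k], sqrt(s2))
        }
      }
      dens[k] <- p
    }
    post[i, ] <- dens / sum(dens)
  }
  post
}

# Saturated-marginal log-likelihood: per-variable multinomial / Gaussian MLE
# over observed rows, the closed form a 1-class model must attain.
marginal_loglik <- function(data) {
  cb <- data$codebook
  ll <- 0
  for (nm in names(cb$variables)) {
    spec <- cb$variables[[nm]]
    x <- data$data[[nm]]
    x <- x[!is.na(x)]
    m <- length(x)
    if (m == 0) next
    if (spec$kind %in% c("nominal", "ordinal")) {
      tab <- table(factor(x, levels = spec$levels))
      tab <- tab[tab > 0]
      ll <- ll + sum(tab * log(tab / m))
    } else {
      v <- sum((x - mean(x))^2) / m
      ll <- ll - m / 2 * (log(2 * pi * v) + 1)
    }
  }
  ll
}

# Reduced six-domain cohort for recovery suites: 20 mixed variables,
# three planted categories per domain, identity coupling.
small_domains <- function() {
  base <- list(n_categories = 3L, nominal = 2L, nominal_levels = 3L,
               ordinal = 1L, ordinal_levels = 4L, continuous = 0L)
  out <- list(activity = base, contextual = base, pain = base,
              participation = base, physical_impairment = base,
              psychology = base)
  out$activity$continuous <- 1L
  out$psychology$continuous <- 1L
  out
}

small_cohort_spec <- function(seed, n = 1000L, delta = 0.85,
                              missing_rate = 0.03, ...) {
  cohort_spec(n = n, domains = small_domains(), G = 3L, delta = delta,
              missing_rate = missing_rate, seed = seed, ...)
}

# Best class-permutation match of estimated against true labels (small K).
best_permutation <- function(est, truth, K) {
  perms <- all_perms(K)
  overlaps <- vapply(perms, function(p) sum(p[est] == truth), numeric(1))
  perms[[which.max(overlaps)]]
}

all_perms <- function(K) {
  if (K == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(K)) {
    rest <- all_perms(K - 1L)
    for (r in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(K), i)[r])
  }
  out
}

# Minimal hand-built lca_fit for rule-level diagnostics tests.
fake_fit <- function(assignments, K, posteriors = NULL, model = NULL) {
  n <- length(assignments)
  if (is.null(posteriors)) {
    posteriors <- matrix(0, n, K)
    posteriors[cbind(seq_len(n), assignments)] <- 1
  }
  structure(list(model = model %||% list(K = K), posteriors = posteriors,
                 assignments = assignments, n_obs = n,
                 loglik = NA_real_, bic = NA_real_),
            class = "lca_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
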