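test_that("log-likelihood matches closed forms on single-variable models", {
  # K = 1 with a binary variable at its sample MLE: binomial closed form
  ds <- binary_dataset(c(1, 1, 1, 0, 1, 0, 1, 1, 0, 1))
  n1 <- 7; n0 <- 3; phat <- 0.7
  model <- binary_model(pi = 1, p1 = phat)
  expect_equal(loglikelihood(model, ds),
               n1 * log(phat) + n0 * log(1 - phat), tolerance = 1e-12)

  # hand-evaluated two-class mixture density for a single observed row
  m2 <- binary_model(pi = c(0.6, 0.4), p1 = c(0.9, 0.2))
  expect_equal(loglikelihood(m2, binary_dataset("1")), log(0.62),
               tolerance = 1e-12)
})

test_that("missing entries are skipped: a column's removal removes exactly its contribution", {
  cb <- codebook(
    variable_spec("a", "nominal", levels = c("0", "1")),
    variable_spec("b", "nominal", levels = c("1", "2", "3")))
  df <- data.frame(a = c("1", "0", "1", "1"), b = c("1", "2", NA, "3"))
  ds <- lca_dataset(df, cb)
  f <- fit_em(ds, K = 1, seed = 1)

  # with `b` entirely deleted, the K=1 loglik drops by b's marginal part
  ds_a <- subset_variables(ds, "a")
  f_a <- fit_em(ds_a, K = 1, seed = 1)
  expect_equal(f$loglik - f_a$loglik, marginal_loglik(ds) - marginal_loglik(ds_a),
               tolerance = 1e-8)

  # a row missing on one variable scores as if that cell never existed
  m <- binary_model(pi = c(0.6, 0.4), p1 = c(0.9, 0.2))
  cb2 <- codebook(variable_spec("y", "nominal", levels = c("0", "1")),
                  variable_spec("w", "nominal", levels = c("0", "1")))
  m2 <- lcasub:::new_lca_model(2, c(0.6, 0.4),
                               list(y = cbind(c(0.1, 0.8), c(0.9, 0.2)),
                                    w = cbind(c(0.5, 0.5), c(0.5, 0.5))),
                               matrix(numeric(0), 0, 2),
                               stats::setNames(numeric(0), character(0)),
                               "pooled", cb2)
  ds2 <- lca_dataset(data.frame(y = "1", w = NA_character_), cb2,
                     allow_all_missing = FALSE)
  expect_equal(loglikelihood(m2, ds2), log(0.62), tolerance = 1e-12)
})

test_that("E-step reproduces Bayes' rule", {
  # single class: certainty
  expect_equal(e_step(binary_model(1, 0.3), binary_dataset(c(0, 1, 1))),
               matrix(1, 3, 1))
  # hand computation: P(class 1 | y = 1) = 0.54 / 0.62
  m <- binary_model(c(0.6, 0.4), c(0.9, 0.2))
  p <- e_step(m, binary_dataset("1"))
  expect_equal(p[1, 1], 0.54 / 0.62, tolerance = 1e-12)
  expect_equal(rowSums(p), 1, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("log-domain E-step agrees with the brute-force oracle", {
  for (seed in 1:8) {
    K <- 1 + seed %% 2  # K in {1, 2}
    model <- random_mixed_model(K, seed)
    ds <- random_mixed_dataset(n = 15, seed = seed + 100)
    expect_equal(e_step(model, ds), oracle_posteriors(model, ds),
                 tolerance = 1e-10)
  }
})

test_that("M-step computes weighted frequencies, means and class weights", {
  ds <- binary_dataset(c("1", "0"))
  post <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  m <- m_step(post, ds)
  expect_equal(m$pi, c(0.6, 0.4), tolerance = 1e-12)
  expect_equal(m$theta$y[1, 2], 0.8 / 1.2, tolerance = 1e-9)

  # hard posteriors: per-class sample frequencies
  hard <- rbind(c(1, 0), c(0, 1))
  mh <- m_step(hard, ds)
  expect_equal(mh$theta$y[1, 2], 1, tolerance = 1e-5)
  expect_equal(mh$theta$y[2, 2], 0, tolerance = 1e-5)

  # uniform posteriors: both classes equal the marginal fit
  unif <- matrix(0.5, 2, 2)
  mu <- m_step(unif, ds)
  expect_equal(mu$theta$y[1, ], mu$theta$y[2, ], tolerance = 1e-12)
  expect_equal(mu$theta$y[1, 2], 0.5, tolerance = 1e-9)

  # continuous update
  cb <- codebook(variable_spec("z", "continuous", range = c(-10, 10)))
  dz <- lca_dataset(data.frame(z = c(0, 2, 4)), cb)
  mz <- m_step(matrix(1, 3, 1), dz)
  expect_equal(unname(mz$mu["z", 1]), 2)
  expect_equal(unname(mz$sigma2["z"]), 8 / 3, tolerance = 1e-12)
})

test_that("a collapsing class is signalled, not silently renormalized", {
  ds <- binary_dataset(c("1", "0", "1"))
  post <- cbind(rep(1, 3), rep(0, 3))
  expect_warning(m_step(post, ds), class = "lcasub_class_collapse")
})

test_that("fit_em is deterministic and honours its contracts", {
  ds <- random_mixed_dataset(n = 60, seed = 42)
  # over-parameterized fits on tiny noisy data may drift along a likelihood
  # ridge past the iteration cap; the contract is warn-and-return
  f1 <- suppressWarnings(fit_em(ds, K = 2, seed = 7))
  f2 <- suppressWarnings(fit_em(ds, K = 2, seed = 7))
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$model$pi, f2$model$pi)
  expect_identical(f1$posteriors, f2$posteriors)

  # K = 1 reaches the closed-form marginal fit almost immediately
  fm <- fit_em(ds, K = 1, seed = 3)
  expect_lte(fm$n_iter, 2L)
  expect_equal(fm$loglik, marginal_loglik(ds), tolerance = 1e-8)

  expect_error(fit_em(ds, K = 1000), "exceeds")
  expect_error(fit_em(ds, K = 0), ">= 1")
})

test_that("fit invariants hold: normalization, BIC identity, modal assignment, monotone loglik", {
  ds <- random_mixed_dataset(n = 80, seed = 5)
  for (K in 1:3) {
    f <- fit_em(ds, K = K, seed = K)
    expect_equal(sum(f$model$pi), 1, tolerance = 1e-9)
    for (th in f$model$theta)
      expect_equal(rowSums(th), rep(1, K), tolerance = 1e-9,
                   ignore_attr = TRUE)
    expect_equal(rowSums(f$posteriors), rep(1, ds$n), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(f$bic, -2 * f$loglik + f$n_params * log(f$n_obs))
    expect_equal(f$assignments, apply(f$posteriors, 1, which.max))
    expect_true(all(diff(f$loglik_path) >= -1e-8 * abs(f$loglik_path[-1])))
    expect_equal(f$model$pi, sort(f$model$pi, decreasing = TRUE))
  }
})

test_that("permuting class labels leaves loglik and BIC unchanged", {
  model <- random_mixed_model(2, seed = 9)
  ds <- random_mixed_dataset(n = 30, seed = 10)
  permuted <- lcasub:::reorder_classes(model, c(2, 1))
  expect_equal(loglikelihood(model, ds), loglikelihood(permuted, ds),
               tolerance = 1e-12)
})

test_that("two planted classes are recovered from a binary indicator", {
  # n=500, pi=(0.5,0.5), P(y=1|class) = 0.9 vs 0.1
  cbm <- codebook(
    variable_spec("y1", "nominal", levels = c("0", "1")),
    variable_spec("y2", "nominal", levels = c("0", "1")),
    variable_spec("y3", "nominal", levels = c("0", "1")))
  df <- withr::with_seed(31, {
    cls <- sample(1:2, 500, replace = TRUE)
    p <- c(0.9, 0.1)[cls]
    data.frame(y1 = as.character(rbinom(500, 1, p)),
               y2 = as.character(rbinom(500, 1, p)),
               y3 = as.character(rbinom(500, 1, p)))
  })
  f <- fit_em(lca_dataset(df, cbm), K = 2, seed = 2)
  expect_lt(max(abs(sort(f$model$pi) - c(0.5, 0.5))), 0.05)
  th <- sort(f$model$theta$y1[, 2])
  expect_lt(abs(th[1] - 0.1), 0.05)
  expect_lt(abs(th[2] - 0.9), 0.05)
})

test_that("free-parameter counts follow the mixed-indicator formula", {
  cb1 <- binary_codebook()
  expect_equal(n_parameters(cb1, K = 1), 1L)

  cb2 <- codebook(
    variable_spec("a", "nominal", levels = as.character(1:4)),
    variable_spec("b", "nominal", levels = c("0", "1")),
    variable_spec("z", "continuous", range = c(0, 1)))
  expect_equal(n_parameters(cb2, K = 3), 18L)  # 2 + 9 + 3 + (3+1)
  expect_equal(n_parameters(cb2, K = 3, variance_mode = "class_specific"),
               20L)                            # continuous part 2K = 6
  expect_error(codebook(list()), "at least one")
})

test_that("bic follows its formula", {
  expect_equal(bic(0, 0, 50), 0)
  expect_equal(bic(-500, 10, 100), 1000 + 10 * log(100))
  expect_equal(bic(-500, 11, 100) - bic(-500, 10, 100), log(100))
  expect_error(bic(-1, 1, 0), ">= 1")
})

test_that("modal assignment breaks ties toward the lowest class", {
  expect_equal(modal_assign(rbind(c(0.7, 0.3))), 1L)
  expect_equal(modal_assign(rbind(c(0.5, 0.5))), 1L)
  expect_equal(modal_assign(rbind(c(0.2, 0.3, 0.5), c(0.6, 0.3, 0.1))),
               c(3L, 1L))
})
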