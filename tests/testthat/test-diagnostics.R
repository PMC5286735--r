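test_that("posterior certainty summary counts strict threshold crossings", {
  # one-hot rows: full certainty
  ph <- diag(3)[c(1, 2, 3, 1), ]
  s <- posterior_summary(ph)
  expect_equal(s$median_max_posterior, 1)
  expect_equal(s$n_below_070, 0L)
  expect_equal(s$n_multi_033, 0L)

  # hand-evaluated example
  p <- rbind(c(0.5, 0.5), c(0.8, 0.2), c(0.65, 0.35))
  s2 <- posterior_summary(p)
  expect_equal(s2$median_max_posterior, 0.65)
  expect_equal(s2$n_below_070, 2L)
  expect_equal(s2$n_multi_033, 2L)

  # uniform over K = 3: all below 0.70, none strictly above one third
  pu <- matrix(1 / 3, 5, 3)
  s3 <- posterior_summary(pu)
  expect_equal(s3$n_below_070, 5L)
  expect_equal(s3$n_multi_033, 0L)
  expect_equal(sum(s3$below_070_by_class), 5L)
})

test_that("profiles are range-normalized and severity-reversed", {
  cb <- codebook(
    variable_spec("pain_intensity", "continuous", range = c(0, 10),
                  severity_direction = "higher_worse"),
    variable_spec("wellbeing", "continuous", range = c(0, 10),
                  severity_direction = "lower_worse"),
    variable_spec("legpain", "nominal", levels = c("0", "1"),
                  severe_level = "1"))
  model <- lcasub:::new_lca_model(
    K = 2, pi = c(0.5, 0.5),
    theta = list(legpain = cbind(c(0.1, 0.8), c(0.9, 0.2))),
    mu = rbind(pain_intensity = c(7, 2), wellbeing = c(7, 2)),
    sigma2 = c(pain_intensity = 1, wellbeing = 1),
    variance_mode = "pooled", codebook = cb)
  fit <- fake_fit(c(1L, 2L), K = 2, model = model)
  prof <- normalized_profile(fit, cb)
  expect_equal(prof$scores["pain_intensity", ], c(0.7, 0.2),
               ignore_attr = TRUE)
  expect_equal(prof$scores["wellbeing", ], c(0.3, 0.8), ignore_attr = TRUE)
  expect_equal(prof$scores["legpain", ], c(0.9, 0.2), ignore_attr = TRUE)
  expect_true(all(prof$scores >= 0 & prof$scores <= 1))
  expect_true(prof$reversed["wellbeing"])

  # reversal is an involution: flipping the declaration restores the values
  cb2 <- codebook(
    variable_spec("pain_intensity", "continuous", range = c(0, 10),
                  severity_direction = "higher_worse"),
    variable_spec("wellbeing", "continuous", range = c(0, 10),
                  severity_direction = "higher_worse"),
    variable_spec("legpain", "nominal", levels = c("0", "1"),
                  severe_level = "1"))
  model2 <- model
  model2$codebook <- cb2
  prof2 <- normalized_profile(fake_fit(c(1L, 2L), K = 2, model = model2), cb2)
  expect_equal(prof2$scores["wellbeing", ], 1 - prof$scores["wellbeing", ])

  # a nominal variable without severity information is excluded, with warning
  cb3 <- codebook(
    variable_spec("pain_intensity", "continuous", range = c(0, 10)),
    variable_spec("occupation", "nominal", levels = c("a", "b", "c")))
  model3 <- lcasub:::new_lca_model(
    K = 2, pi = c(0.5, 0.5),
    theta = list(occupation = matrix(1 / 3, 2, 3)),
    mu = rbind(pain_intensity = c(7, 2)),
    sigma2 = c(pain_intensity = 1),
    variance_mode = "pooled", codebook = cb3)
  expect_warning(p3 <- normalized_profile(fake_fit(c(1L, 2L), 2,
                                                   model = model3), cb3),
                 "excluded")
  expect_equal(rownames(p3$scores), "pain_intensity")
})

test_that("ordinal profile scores use equidistant integer scoring", {
  cb <- codebook(variable_spec("disability", "ordinal",
                               levels = c("1", "2", "3"),
                               severity_direction = "higher_worse"))
  model <- lcasub:::new_lca_model(
    K = 2, pi = c(0.5, 0.5),
    theta = list(disability = rbind(c(0, 0, 1), c(1, 0, 0))),
    mu = matrix(numeric(0), 0, 2),
    sigma2 = stats::setNames(numeric(0), character(0)),
    variance_mode = "pooled", codebook = cb)
  prof <- normalized_profile(fake_fit(c(1L, 2L), 2, model = model), cb)
  expect_equal(prof$scores["disability", ], c(1, 0), ignore_attr = TRUE)
})

test_that("feature detection groups concordant high-spread variables", {
  mk_prof <- function(scores) structure(
    list(scores = scores,
         method = stats::setNames(rep("scaled_mean", nrow(scores)),
                                  rownames(scores)),
         reversed = stats::setNames(rep(FALSE, nrow(scores)),
                                    rownames(scores))),
    class = "profile_matrix")
  prof <- mk_prof(rbind(v1 = c(0.9, 0.2), v2 = c(0.8, 0.3), v3 = c(0.2, 0.9)))
  feats <- detect_features(prof)
  expect_length(feats, 2L)
  expect_equal(feats[[1]]$members, c("v1", "v2"))
  expect_equal(feats[[1]]$spread, 0.5)           # min member spread
  expect_equal(feats[[1]]$concordance, 1)
  expect_equal(feats[[1]]$classification, "quantitative")
  expect_equal(feats[[2]]$members, "v3")

  # spreads below 30%: no features
  low <- mk_prof(rbind(v1 = c(0.55, 0.45), v2 = c(0.5, 0.6)))
  expect_length(detect_features(low), 0L)

  # single-class profile: no features
  one <- mk_prof(rbind(v1 = matrix(0.9, 1, 1)))
  expect_length(detect_features(one), 0L)

  # a crossing inside a tolerated group marks it qualitative
  cross <- mk_prof(rbind(v1 = c(0.9, 0.5, 0.1), v2 = c(0.7, 0.9, 0.2)))
  f2 <- detect_features(cross, concordance_min = 0.5)
  expect_length(f2, 1L)
  expect_equal(f2[[1]]$classification, "qualitative")
})

test_that("profile differences classify as quantitative or qualitative", {
  expect_equal(classify_difference(c(0.8, 0.8), c(0.3, 0.3)), "quantitative")
  expect_equal(classify_difference(c(0.8, 0.2), c(0.2, 0.8)), "qualitative")
  expect_equal(classify_difference(c(0.5, 0.5), c(0.5, 0.5)), "quantitative")
})

test_that("subgroup-size rules flag small classes with the 3-5% relaxation", {
  cb <- codebook(variable_spec("sev", "continuous", range = c(0, 10),
                               severity_direction = "higher_worse"))
  model <- lcasub:::new_lca_model(
    K = 3, pi = c(0.5, 0.46, 0.04),
    theta = list(),
    mu = rbind(sev = c(2, 3, 9)),
    sigma2 = c(sev = 1), variance_mode = "pooled", codebook = cb)
  assign1 <- rep(1:3, times = c(50, 46, 4))
  fit <- fake_fit(assign1, K = 3, model = model)

  # class 3 (4%) is conditionally acceptable: its distinguishing feature
  # variable is in the relaxed list
  r <- subgroup_size_check(fit, relaxed_variables = "sev")
  expect_equal(r$status, c("ok", "ok", "conditional"))
  # without a qualifying variable it is flagged
  r2 <- subgroup_size_check(fit, relaxed_variables = "other_var")
  expect_equal(r2$status, c("ok", "ok", "flagged"))
  # below 3% it is always flagged
  fit3 <- fake_fit(rep(1:3, times = c(50, 48, 2)), K = 3, model = model)
  r3 <- subgroup_size_check(fit3, relaxed_variables = "sev")
  expect_equal(r3$status, c("ok", "ok", "flagged"))
  # nothing to flag
  r4 <- subgroup_size_check(fake_fit(rep(1:2, c(60, 40)), 2))
  expect_equal(r4$status, c("ok", "ok"))
})

test_that("crosstab computes counts, margins and exclusive flags", {
  ct <- crosstab(rep(1:2, c(10, 10)),
                 c(rep(1, 8), rep(2, 2), rep(1, 1), rep(2, 9)))
  expect_equal(unname(ct$counts), rbind(c(8, 2), c(1, 9)))
  expect_equal(unname(ct$row_totals), c(10, 10))
  expect_equal(unname(ct$col_totals), c(9, 11))
  expect_equal(ct$total, 20)
  expect_equal(unname(diag(ct$flags)), c("a", "a"))
  expect_equal(ct$flags[1, 2], "c")    # 2 is 20% of its row
  expect_equal(ct$flags[2, 1], "d")    # 1 is >10% of its column only

  # identical assignments: diagonal, all flagged a, no c/d
  a <- rep(1:3, times = c(5, 7, 9))
  ct2 <- crosstab(a, a)
  expect_true(all(diag(ct2$counts) == c(5, 7, 9)))
  expect_equal(sort(unique(as.vector(ct2$flags))), c("", "a"))

  expect_error(crosstab(1:5, 1:4), "different lengths")
})

test_that("the published 7x9 membership table reproduces its printed arithmetic", {
  ct <- published_crosstab()
  expect_equal(ct$total, 928)
  expect_equal(unname(ct$row_totals), c(192, 154, 136, 132, 130, 109, 75))
  expect_equal(unname(ct$col_totals),
               c(219, 161, 127, 113, 71, 69, 74, 45, 49))
  # SS3 x TS1 = 113 is the largest cell in its row
  expect_equal(ct$counts["SS3", "TS1"], 113)
  expect_equal(ct$flags["SS3", "TS1"], "a")
  # 79 is SS1's largest; 44 is SS5's largest
  expect_equal(ct$flags["SS1", "TS2"], "a")
  expect_equal(ct$flags["SS5", "TS3"], "a")
  # 36 at SS1 x TS4 is TS4's column maximum but not SS1's row maximum
  expect_equal(ct$flags["SS1", "TS4"], "b")

  agr <- crosstab_agreement(ct)
  expect_equal(agr$row_summary$share_largest[3], 113 / 136, tolerance = 1e-12)
  # flags are a pure function of the counts
  ct2 <- crosstab(ct$counts)
  expect_identical(ct2$flags, ct$flags)
})

test_that("agreement diagnostics behave at the extremes and match the oracle", {
  a <- rep(1:3, times = c(5, 7, 9))
  ct <- crosstab(a, a)
  agr <- crosstab_agreement(ct)
  expect_equal(agr$ari, 1)
  expect_equal(agr$percent_agreement, 100)
  expect_true(all(agr$row_summary$nonzero_cells == 1))

  # independence: ARI near zero at n = 5000
  ab <- withr::with_seed(99, list(a = sample(1:4, 5000, replace = TRUE),
                                  b = sample(1:5, 5000, replace = TRUE)))
  ari0 <- adjusted_rand_index(ab$a, ab$b)
  expect_lt(abs(ari0), 0.02)

  # dual route: the table-based ARI equals mclust's vector-based ARI
  skip_if_not_installed("mclust")
  for (seed in 1:5) {
    ab <- withr::with_seed(seed, list(
      a = sample(1:3, 200, replace = TRUE),
      b = sample(1:4, 200, replace = TRUE)))
    expect_equal(adjusted_rand_index(ab$a, ab$b),
                 unname(mclust::adjustedRandIndex(ab$a, ab$b)),
                 tolerance = 1e-12)
  }
})

test_that("prevalences round half away from zero to integer percent", {
  expect_equal(percent_round(219 / 928), 24L)
  expect_equal(percent_round(154 / 928), 17L)
  expect_equal(percent_round(0.125), 13L)
  expect_equal(percent_round(0.004), 0L)
  expect_equal(percent_round(0.005), 1L)
})
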