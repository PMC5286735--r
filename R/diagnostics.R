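#' Posterior-certainty summary
#'
#' Summarizes how confidently patients are assigned: the median and
#' interquartile range of each patient's maximum posterior probability
#' (1.00 would mean no uncertainty at all), the number of patients whose
#' maximum posterior is below 0.70 for any subgroup, and the number with a
#' posterior above 0.33 (one third) for more than one subgroup. Both
#' thresholds are strict inequalities, so boundary rows (maximum exactly
#' 0.70, or rows exactly uniform over three classes) are excluded from both
#' counts.
#'
#' @param posteriors Posterior matrix (or an `lca_fit`).
#' @return An object of class `"posterior_summary"`: `median_max_posterior`,
#'   `iqr_max_posterior` (length-2, the 25% and 75% quantiles),
#'   `n_below_070`, `n_multi_033`, `n`, and `below_070_by_class` (counts of
#'   low-certainty patients per modal class).
#' @export
posterior_summary <- function(posteriors) {
  if (inherits(posteriors, "lca_fit")) posteriors <- posteriors$posteriors
  p <- as.matrix(posteriors)
  maxp <- apply(p, 1L, max)
  cls <- modal_assign(p)
  below <- maxp < 0.70
  multi <- rowSums(p > 1 / 3) > 1L
  structure(list(
    median_max_posterior = stats::median(maxp),
    iqr_max_posterior = unname(stats::quantile(maxp, c(0.25, 0.75))),
    n_below_070 = sum(below),
    n_multi_033 = sum(multi),
    n = nrow(p),
    below_070_by_class = tabulate(cls[below], ncol(p))),
    class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> n = %d\n", x$n))
  cat(sprintf(" median max posterior: %.2f (IQR %.2f-%.2f)\n",
              x$median_max_posterior, x$iqr_max_posterior[1],
              x$iqr_max_posterior[2]))
  cat(sprintf(" max posterior < 0.70: %d (%d%%)\n", x$n_below_070,
              percent_round(x$n_below_070 / x$n)))
  cat(sprintf(" posterior > 0.33 for more than one subgroup: %d (%d%%)\n",
              x$n_multi_033, percent_round(x$n_multi_033 / x$n)))
  invisible(x)
}

#' Normalized severity profile of a fitted model
#'
#' One row per variable, one column per class, all entries scaled to
#' [0, 1] so profiles are comparable across variables, with higher always
#' meaning a more severe condition:
#' * continuous variables: class-conditional mean, min-max scaled by the
#'   declared range;
#' * ordinal variables: class-conditional mean of equidistant integer
#'   scores 1..C, scaled by the score range;
#' * nominal variables: when the `recode_map` declares a numeric severity
#'   score per level, the score-weighted class mean (min-max scaled);
#'   otherwise the conditional probability of the declared `severe_level`.
#'   Nominal variables with neither are excluded with a warning.
#'
#' Variables declared `lower_worse` are reverse scored (`1 - value`).
#'
#' @param fit An `lca_fit`.
#' @param codebook Codebook (defaults to the model's).
#' @return An object of class `"profile_matrix"`: `scores` (variables x
#'   classes, in [0, 1]), `method` (per-variable normalization tag) and
#'   `reversed` (logical per variable).
#' @export
normalized_profile <- function(fit, codebook = fit$model$codebook) {
  stopifnot(inherits(fit, "lca_fit"))
  m <- fit$model
  rows <- list()
  method <- character(0)
  reversed <- logical(0)
  for (nm in variable_names(codebook)) {
    spec <- codebook$variables[[nm]]
    if (spec$kind == "continuous") {
      val <- (m$mu[nm, ] - spec$range[1]) / diff(spec$range)
      meth <- "scaled_mean"
    } else if (spec$kind == "ordinal") {
      scores <- seq_len(n_levels(spec))
      val <- as.vector(m$theta[[nm]] %*% scores)
      val <- (val - 1) / (n_levels(spec) - 1)
      meth <- "scored_mean"
    } else {
      sev_scores <- severity_scores(spec)
      if (!is.null(sev_scores)) {
        val <- as.vector(m$theta[[nm]] %*% sev_scores)
        rng <- range(sev_scores)
        val <- (val - rng[1]) / diff(rng)
        meth <- "scored_mean"
      } else if (!is.null(spec$severe_level)) {
        val <- m$theta[[nm]][, match(spec$severe_level, spec$levels)]
        meth <- "prob_severe_level"
      } else {
        warning(sprintf("nominal variable '%s' has no severity ordering or severe_level; excluded from profile",
                        nm), call. = FALSE)
        next
      }
    }
    val <- pmin(pmax(val, 0), 1)
    rev <- spec$severity_direction == "lower_worse"
    if (rev) val <- 1 - val
    rows[[nm]] <- val
    method[nm] <- meth
    reversed[nm] <- rev
  }
  if (!length(rows)) stop("no variables could be profiled", call. = FALSE)
  scores <- do.call(rbind, rows)
  colnames(scores) <- paste0("class", seq_len(m$K))
  structure(list(scores = scores, method = method, reversed = reversed),
            class = "profile_matrix")
}

# A nominal variable's recode_map may carry numeric severity scores
# (level -> score); returns the per-level scores in level order, or NULL.
severity_scores <- function(spec) {
  map <- spec$recode_map
  if (is.null(map)) return(NULL)
  vals <- suppressWarnings(as.numeric(unlist(map)))
  if (any(is.na(vals))) return(NULL)
  if (!all(spec$levels %in% names(map))) return(NULL)
  vals[match(spec$levels, names(map))]
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d variables x %d classes\n",
              nrow(x$scores), ncol(x$scores)))
  print(round(x$scores, 3))
  invisible(x)
}

#' Detect subgroup features in a profile matrix
#'
#' A feature is a group of variables that (i) show concordant scoring
#' patterns across the subgroups (rank correlation of their class-score
#' vectors at least `concordance_min`, tolerating minor profile crossings)
#' and (ii) each spread at least `min_spread` between the highest- and
#' lowest-scoring subgroup. Grouping is greedy in profile order: a variable
#' joins the first existing group with which every member is sufficiently
#' concordant, otherwise it seeds a new (possibly singleton) group.
#'
#' @param profile A `profile_matrix`.
#' @param min_spread Minimum max-min class-score difference (default 0.30).
#' @param concordance_min Minimum pairwise Spearman correlation for two
#'   variables to share a group (default 0.6).
#' @return A list of `feature_group` objects, each with `members`, `spread`
#'   (the minimum member spread), `concordance` (minimum pairwise rank
#'   correlation; `NA` for singletons) and `classification`
#'   (`"quantitative"` if every pair of classes is ordered the same way by
#'   all members, else `"qualitative"`).
#' @export
detect_features <- function(profile, min_spread = 0.30, concordance_min = 0.6) {
  stopifnot(inherits(profile, "profile_matrix"))
  sc <- profile$scores
  if (ncol(sc) < 2L) return(list())
  spreads <- apply(sc, 1L, function(v) max(v) - min(v))
  eligible <- rownames(sc)[spreads >= min_spread]
  if (!length(eligible)) return(list())
  groups <- list()
  for (nm in eligible) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      cors <- vapply(groups[[gi]], function(other)
        suppressWarnings(stats::cor(sc[nm, ], sc[other, ],
                                    method = "spearman")), numeric(1))
      if (all(!is.na(cors)) && all(cors >= concordance_min)) {
        groups[[gi]] <- c(groups[[gi]], nm)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- nm
  }
  lapply(groups, function(members) {
    sub <- sc[members, , drop = FALSE]
    conc <- NA_real_
    if (length(members) > 1L) {
      pairs <- utils::combn(length(members), 2L)
      conc <- min(apply(pairs, 2L, function(ij)
        suppressWarnings(stats::cor(sub[ij[1], ], sub[ij[2], ],
                                    method = "spearman"))))
    }
    quant <- TRUE
    cls_pairs <- utils::combn(ncol(sub), 2L)
    for (j in seq_len(ncol(cls_pairs))) {
      if (classify_difference(sub[, cls_pairs[1, j]],
                              sub[, cls_pairs[2, j]]) == "qualitative") {
        quant <- FALSE
        break
      }
    }
    structure(list(members = members,
                   spread = min(apply(sub, 1L, function(v) max(v) - min(v))),
                   concordance = conc,
                   classification = if (quant) "quantitative" else "qualitative"),
              class = "feature_group")
  })
}

#' @export
print.feature_group <- function(x, ...) {
  cat(sprintf("<feature_group> %d variable(s), spread >= %.2f, %s\n",
              length(x$members), x$spread, x$classification))
  cat(" ", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' Classify the difference between two class profiles
#'
#' Two subgroups differ *qualitatively* when their profile lines cross:
#' some variables score higher in one subgroup and some in the other.
#' They differ *quantitatively* when one profile dominates -- every
#' per-variable difference has the same sign (or is zero), indicating a
#' severity continuum rather than a distinct scoring pattern.
#'
#' @param profileA,profileB Numeric class-score vectors over the same
#'   variables.
#' @return `"quantitative"` or `"qualitative"`.
#' @export
classify_difference <- function(profileA, profileB) {
  stopifnot(length(profileA) == length(profileB))
  d <- profileA - profileB
  if (any(d > 0) && any(d < 0)) "qualitative" else "quantitative"
}

#' Subgroup-size check
#'
#' Flags small subgroups by their modal-assignment share of the cohort:
#' shares of at least `threshold` (default 5%) pass; shares in
#' `[relaxed, threshold)` (default 3--5%) are conditionally acceptable when
#' the subgroup's distinguishing feature variables include any of
#' `relaxed_variables` (characteristics known to be under-represented in
#' the sampled population); smaller subgroups are always flagged.
#'
#' A subgroup's distinguishing variables are the feature members (from
#' [detect_features()]) on which that subgroup attains the extreme
#' (highest or lowest) normalized score.
#'
#' @param fit An `lca_fit`.
#' @param threshold Full acceptance threshold (default 0.05).
#' @param relaxed Conditional acceptance threshold (default 0.03).
#' @param relaxed_variables Character vector of variable names that justify
#'   conditional acceptance.
#' @param codebook Codebook for profiling (defaults to the model's).
#' @return A data.frame with columns `class`, `n`, `share` and `status`
#'   (`"ok"`, `"conditional"` or `"flagged"`).
#' @export
subgroup_size_check <- function(fit, threshold = 0.05, relaxed = 0.03,
                                relaxed_variables = character(0),
                                codebook = fit$model$codebook) {
  stopifnot(inherits(fit, "lca_fit"))
  K <- fit$model$K
  counts <- tabulate(fit$assignments, K)
  shares <- counts / fit$n_obs
  status <- rep("ok", K)
  small <- which(shares < threshold)
  if (length(small)) {
    distinguishing <- vector("list", K)
    if (length(relaxed_variables)) {
      prof <- tryCatch(normalized_profile(fit, codebook), error = function(e) NULL)
      if (!is.null(prof)) {
        feats <- detect_features(prof)
        for (fg in feats) {
          for (nm in fg$members) {
            v <- prof$scores[nm, ]
            ext <- c(which.max(v), which.min(v))
            for (k in ext)
              distinguishing[[k]] <- union(distinguishing[[k]], nm)
          }
        }
      }
    }
    for (k in small) {
      if (shares[k] >= relaxed &&
          length(intersect(distinguishing[[k]], relaxed_variables))) {
        status[k] <- "conditional"
      } else {
        status[k] <- "flagged"
      }
    }
  }
  data.frame(class = seq_len(K), n = counts, share = shares, status = status)
}

#' Cross-tabulate two subgroup solutions
#'
#' Joint modal-membership counts of two solutions over the same patients,
#' with margins, grand total and per-cell flags:
#' * `a` -- the cell is the largest in its row;
#' * `b` -- the largest in its column (when not already `a`);
#' * `c` -- more than 10% of its row total (but not the largest);
#' * `d` -- more than 10% of its column total only (but not the largest).
#'
#' Flags are mutually exclusive with precedence `a > b > c > d` and are a
#' pure function of the counts.
#'
#' @param assignA,assignB Equal-length assignment vectors (or a pre-built
#'   count matrix passed as `assignA` with `assignB` missing).
#' @param labelsA,labelsB Optional dimension labels.
#' @return An object of class `"lca_crosstab"`: `counts`, `flags`
#'   (character matrix), `row_totals`, `col_totals`, `total`.
#' @export
crosstab <- function(assignA, assignB = NULL, labelsA = NULL, labelsB = NULL) {
  if (is.null(assignB)) {
    counts <- as.matrix(assignA)
  } else {
    if (length(assignA) != length(assignB))
      stop("assignment vectors have different lengths", call. = FALSE)
    a <- as.integer(assignA)
    b <- as.integer(assignB)
    counts <- as.matrix(table(factor(a, levels = seq_len(max(a))),
                              factor(b, levels = seq_len(max(b)))))
    dimnames(counts) <- NULL
  }
  storage.mode(counts) <- "double"
  if (!is.null(labelsA)) rownames(counts) <- labelsA
  if (!is.null(labelsB)) colnames(counts) <- labelsB
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("A", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("B", seq_len(ncol(counts)))
  rt <- rowSums(counts)
  ct <- colSums(counts)
  flags <- matrix("", nrow(counts), ncol(counts),
                  dimnames = dimnames(counts))
  row_max <- apply(counts, 1L, max)
  col_max <- apply(counts, 2L, max)
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      x <- counts[i, j]
      if (x <= 0) next
      if (x == row_max[i]) {
        flags[i, j] <- "a"
      } else if (x == col_max[j]) {
        flags[i, j] <- "b"
      } else if (x > 0.10 * rt[i]) {
        flags[i, j] <- "c"
      } else if (x > 0.10 * ct[j]) {
        flags[i, j] <- "d"
      }
    }
  }
  structure(list(counts = counts, flags = flags, row_totals = rt,
                 col_totals = ct, total = sum(counts)),
            class = "lca_crosstab")
}

#' @export
print.lca_crosstab <- function(x, ...) {
  disp <- matrix(paste0(x$counts, ifelse(x$flags == "", "", paste0("^", x$flags))),
                 nrow(x$counts), dimnames = dimnames(x$counts))
  disp <- cbind(disp, Total = as.character(x$row_totals))
  disp <- rbind(disp, Total = c(as.character(x$col_totals),
                                as.character(x$total)))
  print(as.data.frame(disp), right = TRUE)
  cat("flags: a largest in row; b largest in column; c >10% of row; d >10% of column\n")
  invisible(x)
}

#' Agreement diagnostics for a membership cross-tabulation
#'
#' How much one subgroup solution's members spread over the other's:
#' per row/column the number of nonzero cells and the share held by the
#' largest cell; overall the percent agreement under a greedy one-to-one
#' matching of largest cells, and the adjusted Rand index (computed from
#' the contingency table).
#'
#' @param ct An `lca_crosstab`.
#' @return A list with `row_summary`, `col_summary` (data.frames),
#'   `percent_agreement` and `ari`.
#' @export
crosstab_agreement <- function(ct) {
  stopifnot(inherits(ct, "lca_crosstab"))
  counts <- ct$counts
  row_summary <- data.frame(
    subgroup = rownames(counts),
    n = ct$row_totals,
    nonzero_cells = apply(counts, 1L, function(v) sum(v > 0)),
    share_largest = apply(counts, 1L, max) / pmax(ct$row_totals, 1))
  col_summary <- data.frame(
    subgroup = colnames(counts),
    n = ct$col_totals,
    nonzero_cells = apply(counts, 2L, function(v) sum(v > 0)),
    share_largest = apply(counts, 2L, max) / pmax(ct$col_totals, 1))
  # greedy 1-1 matching of largest cells
  m <- counts
  matched <- 0
  repeat {
    if (all(m < 0) || max(m) <= 0) break
    ij <- which(m == max(m), arr.ind = TRUE)[1, ]
    matched <- matched + m[ij[1], ij[2]]
    m[ij[1], ] <- -1
    m[, ij[2]] <- -1
  }
  list(row_summary = row_summary, col_summary = col_summary,
       percent_agreement = 100 * matched / ct$total,
       ari = ari_from_table(counts))
}

# Adjusted Rand index from a contingency table (Hubert & Arabie form).
ari_from_table <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  ch2 <- function(x) x * (x - 1) / 2
  sum_cells <- sum(ch2(counts))
  sum_rows <- sum(ch2(rowSums(counts)))
  sum_cols <- sum(ch2(colSums(counts)))
  expected <- sum_rows * sum_cols / ch2(n)
  max_index <- (sum_rows + sum_cols) / 2
  if (max_index == expected) return(0)
  (sum_cells - expected) / (max_index - expected)
}

#' Adjusted Rand index between two assignment vectors
#'
#' Chance-corrected agreement between two partitions of the same patients.
#'
#' @param assignA,assignB Equal-length assignment vectors.
#' @return A scalar in [-1, 1]; 1 for identical partitions, about 0 for
#'   independent ones.
#' @export
adjusted_rand_index <- function(assignA, assignB) {
  if (length(assignA) != length(assignB))
    stop("assignment vectors have different lengths", call. = FALSE)
  ari_from_table(as.matrix(table(assignA, assignB)))
}

#' Round a proportion to an integer percentage
#'
#' Half-away-from-zero rounding, matching the prevalence arithmetic of
#' descriptive reports (e.g. 219/928 -> 24%).
#'
#' @param p Proportion(s) in [0, 1].
#' @return Integer percent.
#' @export
percent_round <- function(p) {
  as.integer(sign(p) * floor(abs(p) * 100 + 0.5))
}
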