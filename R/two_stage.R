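#' First-stage latent class models within health domains
#'
#' Fits one latent class model per health domain of the codebook, restricted
#' to that domain's variables, and assigns each patient to the domain
#' category with the largest posterior probability (modal assignment).
#'
#' @param data An `lca_dataset` whose codebook partitions its variables
#'   into domains.
#' @param domain_Ks Either a named integer vector/list giving the class
#'   count per domain, or the string `"search"` to select each domain's
#'   class count by [run_search()] + the starting-model rule.
#' @param n_restarts Restarts per fit (default 10).
#' @param base_seed Integer seed; domain d (in codebook order) uses restart
#'   base `base_seed + (d - 1) * 1000`.
#' @param K_max Search bound per domain when `domain_Ks = "search"`.
#' @param ... Passed to [fit_em()].
#' @return A list with `fits` (named list of `lca_fit` per domain),
#'   `membership` (see [domain_membership()]) and `searches` (per-domain
#'   `lca_search` when searching).
#' @export
fit_first_stage <- function(data, domain_Ks = "search", n_restarts = 10L,
                            base_seed = 1L, K_max = 12L, ...) {
  stopifnot(inherits(data, "lca_dataset"))
  partition <- data$codebook$domain_partition
  if (length(partition) == 0L)
    stop("the codebook declares no domain partition", call. = FALSE)
  domains <- names(partition)
  searching <- identical(domain_Ks, "search")
  if (!searching) {
    domain_Ks <- unlist(domain_Ks)
    missing_d <- setdiff(domains, names(domain_Ks))
    if (length(missing_d))
      stop(sprintf("domain_Ks lacks domain(s): %s",
                   paste(missing_d, collapse = ", ")), call. = FALSE)
  }
  fits <- list()
  searches <- list()
  for (i in seq_along(domains)) {
    d <- domains[i]
    if (length(partition[[d]]) == 0L)
      stop(sprintf("domain '%s' has no variables", d), call. = FALSE)
    dat_d <- subset_variables(data, partition[[d]])
    seed_d <- as.integer(base_seed) + (i - 1L) * 1000L
    if (searching) {
      s <- run_search(dat_d, K_max = K_max, n_restarts = n_restarts,
                      base_seed = seed_d, ...)
      searches[[d]] <- s
      fits[[d]] <- search_fit(s)
    } else {
      fits[[d]] <- fit_with_restarts(dat_d, K = as.integer(domain_Ks[[d]]),
                                     n_restarts = n_restarts,
                                     base_seed = seed_d, ...)$fit
    }
  }
  list(fits = fits, membership = domain_membership(fits, data$ids),
       searches = if (searching) searches else NULL)
}

#' Domain membership table from first-stage fits
#'
#' @param fits Named list of per-domain `lca_fit` objects.
#' @param ids Patient identifiers.
#' @return An object of class `"domain_membership"`: `assignments` (patients
#'   x domains integer matrix), `posterior` (maximum posterior backing each
#'   assignment), `K` (categories per domain), `prevalence` (per domain, the
#'   modal-assignment category shares, summing to 1) and `ids`.
#' @export
domain_membership <- function(fits, ids = NULL) {
  stopifnot(length(fits) >= 1L, !is.null(names(fits)))
  n <- fits[[1]]$n_obs
  domains <- names(fits)
  assignments <- matrix(NA_integer_, n, length(domains),
                        dimnames = list(NULL, domains))
  post <- matrix(NA_real_, n, length(domains),
                 dimnames = list(NULL, domains))
  K <- stats::setNames(integer(length(domains)), domains)
  for (d in domains) {
    f <- fits[[d]]
    if (f$n_obs != n) stop("domain fits disagree on patient count", call. = FALSE)
    assignments[, d] <- f$assignments
    post[, d] <- f$posteriors[cbind(seq_len(n), f$assignments)]
    K[d] <- f$model$K
  }
  prevalence <- lapply(domains, function(d)
    tabulate(assignments[, d], K[d]) / n)
  names(prevalence) <- domains
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(assignments = assignments, posterior = post, K = K,
                 prevalence = prevalence, ids = ids),
            class = "domain_membership")
}

#' Build the second-stage dataset from domain memberships
#'
#' One nominal variable per domain whose values are the assigned category
#' indices. The posterior certainty of the first-stage assignment is
#' deliberately not carried forward -- the hard assignment between stages is
#' the information loss inherent to the two-stage design. Categories never
#' assigned to any patient are retained as declared levels (with a message),
#' so the second-stage codebook always has `C = K_d` levels per domain.
#'
#' @param membership A `domain_membership`.
#' @return A list with `data` (an `lca_dataset`, complete by construction)
#'   and `codebook`.
#' @export
build_second_stage_dataset <- function(membership) {
  stopifnot(inherits(membership, "domain_membership"))
  domains <- colnames(membership$assignments)
  specs <- lapply(domains, function(d)
    variable_spec(name = d, kind = "nominal", domain = "other",
                  levels = as.character(seq_len(membership$K[[d]]))))
  cb <- codebook(specs)
  df <- as.data.frame(lapply(domains, function(d)
    as.character(membership$assignments[, d])))
  names(df) <- domains
  for (d in domains) {
    empty <- setdiff(seq_len(membership$K[[d]]),
                     unique(membership$assignments[, d]))
    if (length(empty))
      message(sprintf("domain '%s': category(ies) %s never assigned; level retained",
                      d, paste(empty, collapse = ", ")))
  }
  ds <- lca_dataset(df, cb, ids = membership$ids)
  list(data = ds, codebook = cb)
}

#' Run the full two-stage pipeline
#'
#' First-stage latent class models within each health domain, modal
#' assignment of every patient to a domain category, then a second-stage
#' class-count search over the resulting all-categorical dataset (one
#' nominal variable per domain).
#'
#' @inheritParams fit_first_stage
#' @param K_max Largest class count searched in the second stage.
#' @param second_stage_restarts Restarts per class count in the second
#'   stage (defaults to `n_restarts`).
#' @return An object of class `"lca_two_stage"`: `first_stage` (the
#'   [fit_first_stage()] result), `membership`, `second_stage_data` and
#'   `second_stage` (an `lca_search`).
#' @export
run_two_stage <- function(data, domain_Ks = "search", K_max = 12L,
                          n_restarts = 10L, base_seed = 1L,
                          second_stage_restarts = n_restarts, ...) {
  first <- fit_first_stage(data, domain_Ks = domain_Ks,
                           n_restarts = n_restarts, base_seed = base_seed,
                           K_max = K_max, ...)
  built <- build_second_stage_dataset(first$membership)
  second <- run_search(built$data, K_max = K_max,
                       n_restarts = second_stage_restarts,
                       base_seed = as.integer(base_seed) + 100000L, ...)
  structure(list(first_stage = first, membership = first$membership,
                 second_stage_data = built$data, second_stage = second),
            class = "lca_two_stage")
}

#' @export
print.lca_two_stage <- function(x, ...) {
  cat("<lca_two_stage>\n first stage domain categories:",
      paste(sprintf("%s=%d", names(x$membership$K), x$membership$K),
            collapse = " "), "\n")
  cat(sprintf(" second stage: starting model K = %d\n",
              x$second_stage$starting_K))
  invisible(x)
}

#' Export a domain membership table
#'
#' Long-format table (patient, domain, category, posterior) as written by
#' the pipeline.
#'
#' @param membership A `domain_membership`.
#' @return A data.frame.
#' @export
membership_table <- function(membership) {
  stopifnot(inherits(membership, "domain_membership"))
  domains <- colnames(membership$assignments)
  do.call(rbind, lapply(domains, function(d)
    data.frame(patient = membership$ids, domain = d,
               category = membership$assignments[, d],
               posterior = membership$posterior[, d])))
}
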