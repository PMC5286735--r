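#' Run a configured analysis pipeline
#'
#' Chains the package's stages from a single configuration: simulate (or
#' load) a cohort, screen and preprocess, search class counts single-stage,
#' run the two-stage pipeline, and export diagnostics. Every file written
#' is listed in a manifest with its MD5 hash, and the log records the seeds
#' and rule decisions, so a run is reproducible from its configuration
#' alone.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `stages` (character subset of `"simulate"`, `"preprocess"`, `"search"`,
#'   `"two_stage"`, `"diagnose"`), `out_dir`, `seed`, and optionally
#'   `data`/`codebook` paths (when not simulating), `K_max` (default 12),
#'   `n_restarts` (default 10), `tol`, `domain_Ks`, and a `cohort` list of
#'   [cohort_spec()] overrides.
#' @return Invisibly, a list with the artifacts produced and `manifest`
#'   (data.frame of file, md5).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("simulate", "search", "diagnose")
  out_dir <- config$out_dir %||% stop("config needs `out_dir`", call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  K_max <- as.integer(config$K_max %||% 12L)
  n_restarts <- as.integer(config$n_restarts %||% 10L)
  tol <- config$tol %||% 1e-8
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  emit <- function(obj, fname, writer) {
    path <- file.path(out_dir, fname)
    writer(obj, path)
    written <<- c(written, path)
    logf("wrote %s", fname)
    path
  }
  write_csv <- function(obj, path)
    utils::write.csv(obj, path, row.names = FALSE, quote = FALSE)

  cat("", file = log_path)
  logf("pipeline started; seed = %d; stages: %s", seed,
       paste(stages, collapse = ", "))
  artifacts <- list()

  if ("simulate" %in% stages) {
    spec_args <- config$cohort %||% list()
    spec_args$seed <- spec_args$seed %||% seed
    spec <- do.call(cohort_spec, spec_args)
    cohort <- generate_cohort(spec)
    data <- cohort$data
    emit(data, "cohort.csv", write_lca_dataset)
    emit(cohort$codebook, "codebook.yml",
         function(obj, path) write_codebook(obj, path))
    emit(data.frame(patient = data$ids, class = cohort$truth$class,
                    cohort$truth$domain_category),
         "truth.csv", write_csv)
    artifacts$cohort <- cohort
    logf("simulated cohort: n = %d, G = %d, delta = %.2f, coupling = %s",
         spec$n, spec$G, spec$delta, spec$coupling)
  } else {
    cb <- read_codebook(config$codebook %||%
                          stop("config needs `codebook`", call. = FALSE))
    data <- read_lca_dataset(config$data %||%
                               stop("config needs `data`", call. = FALSE), cb)
    logf("loaded %d patients x %d variables", data$n, ncol(data$data))
  }

  if ("preprocess" %in% stages) {
    screen <- rare_category_screen(data,
                                   threshold = config$rare_threshold %||% 0.85)
    emit(screen, "rare_category_screen.csv", write_csv)
    flagged <- screen$variable[screen$flagged]
    logf("rare-category screen: %d variable(s) flagged%s", length(flagged),
         if (length(flagged)) paste0(" (", paste(flagged, collapse = ", "), ")")
         else "")
    if (isTRUE(config$drop_flagged) && length(flagged)) {
      data <- drop_variables(data, flagged)
      logf("dropped flagged variables (confirmed by config)")
    }
    artifacts$screen <- screen
  }

  if ("search" %in% stages) {
    search <- run_search(data, K_max = K_max, n_restarts = n_restarts,
                         base_seed = seed, tol = tol)
    emit(data.frame(K = as.integer(names(search$bic_table)),
                    bic = unname(search$bic_table)),
         "bic_table.csv", write_csv)
    emit(fit_parameters(search_fit(search)), "starting_model_parameters.csv",
         write_csv)
    logf("single-stage search: starting model K = %d (1%%-rule walk over BIC table)",
         search$starting_K)
    artifacts$search <- search
  }

  if ("two_stage" %in% stages) {
    ts <- run_two_stage(data, domain_Ks = config$domain_Ks %||% "search",
                        K_max = K_max, n_restarts = n_restarts,
                        base_seed = seed, tol = tol)
    emit(membership_table(ts$membership), "domain_membership.csv", write_csv)
    emit(data.frame(K = as.integer(names(ts$second_stage$bic_table)),
                    bic = unname(ts$second_stage$bic_table)),
         "second_stage_bic_table.csv", write_csv)
    logf("two-stage: domain Ks = %s; second-stage starting model K = %d",
         paste(ts$membership$K, collapse = ","), ts$second_stage$starting_K)
    artifacts$two_stage <- ts
  }

  if ("diagnose" %in% stages) {
    fit <- if (!is.null(artifacts$search)) search_fit(artifacts$search)
           else stop("diagnose stage requires the search stage", call. = FALSE)
    ps <- posterior_summary(fit)
    emit(data.frame(metric = c("median_max_posterior", "q25", "q75",
                               "n_below_070", "n_multi_033", "n"),
                    value = c(ps$median_max_posterior, ps$iqr_max_posterior,
                              ps$n_below_070, ps$n_multi_033, ps$n)),
         "posterior_summary.csv", write_csv)
    prof <- suppressWarnings(normalized_profile(fit))
    emit(data.frame(variable = rownames(prof$scores), prof$scores),
         "profile_matrix.csv", write_csv)
    emit(loadings(fit, data), "loadings.csv", write_csv)
    emit(subgroup_size_check(fit), "subgroup_sizes.csv", write_csv)
    if (!is.null(artifacts$two_stage)) {
      ss_fit <- fit
      ts_fit <- search_fit(artifacts$two_stage$second_stage)
      ctab <- crosstab(ss_fit$assignments, ts_fit$assignments)
      emit(as.data.frame(ctab$counts), "membership_crosstab.csv",
           function(obj, path) utils::write.csv(obj, path, row.names = TRUE))
      emit(as.data.frame(ctab$flags), "membership_crosstab_flags.csv",
           function(obj, path) utils::write.csv(obj, path, row.names = TRUE))
      logf("crosstab ARI = %.3f", crosstab_agreement(ctab)$ari)
    }
    logf("diagnostics written")
    artifacts$posterior_summary <- ps
  }

  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  logf("pipeline finished: %d file(s)", length(written))
  invisible(c(artifacts, list(manifest = manifest)))
}
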