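#' Screen for rare-category (near-constant) variables
#'
#' For every nominal/ordinal variable, computes the share of non-missing
#' responses falling in the modal category and flags variables whose share
#' strictly exceeds the threshold (default 85%) as candidates for
#' exclusion. The screen only reports; dropping variables is a separate,
#' explicit transformation ([drop_variables()]), since such exclusions are
#' substantive decisions.
#'
#' @param data An `lca_dataset`.
#' @param threshold Modal-share threshold (default 0.85; strict inequality).
#' @return A data.frame with columns `variable`, `modal_category`,
#'   `modal_share`, `n_obs` and `flagged`.
#' @export
rare_category_screen <- function(data, threshold = 0.85) {
  stopifnot(inherits(data, "lca_dataset"))
  cb <- data$codebook
  rows <- list()
  for (nm in variable_names(cb)) {
    spec <- cb$variables[[nm]]
    if (!is_categorical(spec)) next
    x <- data$data[[nm]]
    x <- x[!is.na(x)]
    if (!length(x)) {
      rows[[nm]] <- data.frame(variable = nm, modal_category = NA_character_,
                               modal_share = NA_real_, n_obs = 0L,
                               flagged = FALSE)
      next
    }
    tab <- table(x)
    share <- max(tab) / length(x)
    rows[[nm]] <- data.frame(variable = nm,
                             modal_category = names(tab)[which.max(tab)],
                             modal_share = share, n_obs = length(x),
                             flagged = share > threshold)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Drop variables from a dataset
#'
#' The explicit exclusion step following [rare_category_screen()]; logs
#' what was removed.
#'
#' @param data An `lca_dataset`.
#' @param vars Variable names to drop.
#' @return An `lca_dataset` over the reduced codebook.
#' @export
drop_variables <- function(data, vars) {
  stopifnot(inherits(data, "lca_dataset"))
  keep <- setdiff(variable_names(data$codebook), vars)
  if (!length(keep)) stop("cannot drop every variable", call. = FALSE)
  message(sprintf("dropping %d variable(s): %s", length(vars),
                  paste(vars, collapse = ", ")))
  subset_variables(data, keep)
}

#' Apply declarative recodes and pooling
#'
#' Applies each variable's `recode_map` (raw value to analysis value) and
#' any declared pooling: a pooled variable replaces its source variables
#' with their cell-wise maximum (for dichotomous 0/1 items this is the
#' logical OR -- e.g. pooling side-specific test results into "positive
#' unilaterally or bilaterally"). Pooling is declarative; nothing is pooled
#' automatically.
#'
#' @param data An `lca_dataset`.
#' @param pools Optional named list; each entry is
#'   `list(members = c(...), spec = variable_spec(...))` describing the
#'   pooled variable that replaces its members.
#' @return A list with `data` (the transformed `lca_dataset`) and
#'   `codebook`.
#' @export
apply_recode <- function(data, pools = NULL) {
  stopifnot(inherits(data, "lca_dataset"))
  cb <- data$codebook
  df <- data$data
  # recode maps (values may already be recoded if read via read_lca_dataset;
  # applying an identity or idempotent map again is harmless for values
  # already in the target space, and required for raw in-memory data)
  for (nm in variable_names(cb)) {
    spec <- cb$variables[[nm]]
    map <- spec$recode_map
    if (is.null(map) || !is_categorical(spec)) next
    x <- as.character(df[[nm]])
    hit <- !is.na(x) & x %in% names(map)
    x[hit] <- as.character(unlist(map))[match(x[hit], names(map))]
    bad <- !is.na(x) & !(x %in% spec$levels)
    if (any(bad))
      stop(sprintf("variable '%s': recode leaves value(s) outside levels", nm),
           call. = FALSE)
    df[[nm]] <- x
  }
  specs <- cb$variables
  if (!is.null(pools)) {
    for (newname in names(pools)) {
      pool <- pools[[newname]]
      members <- pool$members
      missing_m <- setdiff(members, names(df))
      if (length(missing_m))
        stop(sprintf("pool '%s': unknown member(s) %s", newname,
                     paste(missing_m, collapse = ", ")), call. = FALSE)
      if (newname %in% setdiff(names(specs), members))
        stop(sprintf("pool '%s' collides with an existing variable", newname),
             call. = FALSE)
      vals <- do.call(cbind, lapply(members, function(m)
        suppressWarnings(as.numeric(df[[m]]))))
      pooled <- apply(vals, 1L, function(v)
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
      spec_new <- pool$spec
      df[[newname]] <- as.character(pooled)
      for (m in members) df[[m]] <- NULL
      specs[members] <- NULL
      specs[[newname]] <- spec_new
      message(sprintf("pooled %s -> %s (cell-wise maximum)",
                      paste(members, collapse = " + "), newname))
    }
  }
  cb2 <- codebook(specs[names(df)])
  list(data = lca_dataset(df, cb2, ids = data$ids), codebook = cb2)
}

#' Reverse score lower-is-worse variables
#'
#' Recodes ordinal variables (level index `i` becomes `C + 1 - i`) and
#' reflects continuous variables about their range midpoint for variables
#' declared `lower_worse`, so that afterwards higher scores indicate a more
#' severe condition everywhere. The transformation is an involution applied
#' twice returns the original data up to the severity flag.
#'
#' @param data An `lca_dataset`.
#' @return A list with `data` and `codebook` (severity directions updated
#'   to `higher_worse`).
#' @export
reverse_score <- function(data) {
  stopifnot(inherits(data, "lca_dataset"))
  cb <- data$codebook
  df <- data$data
  specs <- cb$variables
  for (nm in variable_names(cb)) {
    spec <- specs[[nm]]
    if (spec$severity_direction != "lower_worse") next
    if (spec$kind == "ordinal") {
      idx <- match(df[[nm]], spec$levels)
      df[[nm]] <- spec$levels[length(spec$levels) + 1L - idx]
    } else if (spec$kind == "continuous") {
      df[[nm]] <- spec$range[1] + spec$range[2] - df[[nm]]
    } else {
      next  # nominal variables carry no scale to reverse
    }
    spec$severity_direction <- "higher_worse"
    specs[[nm]] <- spec
  }
  cb2 <- codebook(specs)
  list(data = lca_dataset(df, cb2, ids = data$ids), codebook = cb2)
}
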