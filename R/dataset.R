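#' Construct a validated patient dataset
#'
#' Wraps a rectangular table of patient responses and validates it against a
#' codebook: every non-missing nominal/ordinal value must be a declared
#' level, every continuous value must fall inside the declared range, and no
#' row may be entirely missing (patients with completely missing data are
#' invalid input and must be excluded before construction; see
#' [read_lca_dataset()], which drops them with a message).
#'
#' @param df A data.frame with one row per patient and one column per
#'   codebook variable (extra columns are an error). Missing entries are
#'   `NA` (empty strings are converted to `NA`).
#' @param codebook An [codebook()] object.
#' @param ids Optional row identifiers; defaults to existing row names or
#'   `1:n`.
#' @param allow_all_missing Permit rows with no observed value. Off by
#'   default (a patient with completely missing data is invalid input); used
#'   internally for per-domain restrictions of a wider dataset, where a
#'   patient may be unobserved within one domain yet observed elsewhere.
#'
#' @return An object of class `"lca_dataset"`: a list with `data` (a
#'   data.frame of character categorical columns and numeric continuous
#'   columns, in codebook order), `codebook`, `ids` and `n`.
#' @export
lca_dataset <- function(df, codebook, ids = NULL, allow_all_missing = FALSE) {
  stopifnot(is.data.frame(df), inherits(codebook, "lca_codebook"))
  nms <- variable_names(codebook)
  missing_cols <- setdiff(nms, names(df))
  if (length(missing_cols))
    stop(sprintf("dataset lacks codebook columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  unknown <- setdiff(names(df), nms)
  if (length(unknown))
    stop(sprintf("unknown columns not in codebook: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (is.null(ids)) {
    ids <- if (!is.null(attr(df, "row.names")) &&
               !is.integer(attr(df, "row.names"))) rownames(df)
           else as.character(seq_len(nrow(df)))
  }
  ids <- as.character(ids)
  if (length(ids) != nrow(df))
    stop("`ids` length must equal the number of rows", call. = FALSE)

  out <- df[nms]
  for (nm in nms) {
    spec <- codebook$variables[[nm]]
    x <- out[[nm]]
    if (is_categorical(spec)) {
      x <- as.character(x)
      x[!is.na(x) & x == ""] <- NA_character_
      bad <- !is.na(x) & !(x %in% spec$levels)
      if (any(bad))
        stop(sprintf("variable '%s': value(s) outside declared levels in row(s) %s (e.g. '%s')",
                     nm, paste(utils::head(ids[bad], 5), collapse = ", "),
                     x[which(bad)[1]]), call. = FALSE)
    } else {
      if (is.character(x)) x[!is.na(x) & x == ""] <- NA_character_
      xn <- suppressWarnings(as.numeric(x))
      bad_parse <- !is.na(x) & is.na(xn)
      if (any(bad_parse))
        stop(sprintf("variable '%s': non-numeric value in row(s) %s",
                     nm, paste(utils::head(ids[bad_parse], 5), collapse = ", ")),
             call. = FALSE)
      if (!is.null(spec$range)) {
        outside <- !is.na(xn) & (xn < spec$range[1] | xn > spec$range[2])
        if (any(outside))
          stop(sprintf("variable '%s': value outside range [%g, %g] in row(s) %s",
                       nm, spec$range[1], spec$range[2],
                       paste(utils::head(ids[outside], 5), collapse = ", ")),
               call. = FALSE)
      }
      x <- xn
    }
    out[[nm]] <- x
  }
  all_missing <- rowSums(!is.na(out)) == 0L
  if (any(all_missing) && !allow_all_missing)
    stop(sprintf("%d row(s) entirely missing (ids: %s); exclude them before construction",
                 sum(all_missing),
                 paste(utils::head(ids[all_missing], 10), collapse = ", ")),
         call. = FALSE)
  rownames(out) <- NULL
  structure(list(data = out, codebook = codebook, ids = ids, n = nrow(out)),
            class = "lca_dataset")
}

#' @export
print.lca_dataset <- function(x, ...) {
  miss <- mean(is.na(as.matrix(x$data)))
  cat(sprintf("<lca_dataset> %d patients x %d variables (%.1f%% cells missing)\n",
              x$n, ncol(x$data), 100 * miss))
  invisible(x)
}

#' Read a patient dataset from CSV
#'
#' Reads a comma-separated table (header row of variable names, one row per
#' patient, empty cells meaning missing), applies any `recode_map` declared
#' in the codebook, validates against the codebook, and drops rows that are
#' missing on every variable -- reporting how many were excluded, since
#' completely missing patients carry no information for the likelihood.
#'
#' @param path CSV file path.
#' @param codebook An [codebook()] object.
#' @param id_column Optional name of a column holding patient identifiers.
#' @param apply_recodes Apply declared `recode_map`s (default `TRUE`).
#' @return An `lca_dataset`. The number of dropped all-missing rows is
#'   available as `attr(x, "n_dropped_all_missing")`.
#' @export
read_lca_dataset <- function(path, codebook, id_column = NULL,
                             apply_recodes = TRUE) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = "")
  ids <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(df))
      stop(sprintf("id column '%s' not found", id_column), call. = FALSE)
    ids <- df[[id_column]]
    df[[id_column]] <- NULL
  }
  nms <- variable_names(codebook)
  missing_cols <- setdiff(nms, names(df))
  if (length(missing_cols))
    stop(sprintf("CSV lacks codebook columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  unknown <- setdiff(names(df), nms)
  if (length(unknown))
    stop(sprintf("unknown CSV columns: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  df <- df[nms]
  if (apply_recodes) {
    for (nm in nms) {
      map <- codebook$variables[[nm]]$recode_map
      if (is.null(map)) next
      x <- df[[nm]]
      hit <- !is.na(x) & x %in% names(map)
      x[hit] <- as.character(unlist(map))[match(x[hit], names(map))]
      df[[nm]] <- x
    }
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(df)))
  all_missing <- rowSums(!is.na(df) & df != "") == 0L
  n_dropped <- sum(all_missing)
  if (n_dropped > 0L) {
    message(sprintf("excluded %d patient(s) with completely missing data (ids: %s)",
                    n_dropped,
                    paste(utils::head(ids[all_missing], 10), collapse = ", ")))
    df <- df[!all_missing, , drop = FALSE]
    ids <- ids[!all_missing]
  }
  ds <- lca_dataset(df, codebook, ids = ids)
  attr(ds, "n_dropped_all_missing") <- n_dropped
  ds
}

#' Write a dataset to CSV
#'
#' Inverse of [read_lca_dataset()]: header row of variable names, empty cell
#' for missing. An optional leading `id` column carries the row identifiers.
#'
#' @param data An `lca_dataset`.
#' @param path Output path.
#' @param include_ids Write the `id` column (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_lca_dataset <- function(data, path, include_ids = FALSE) {
  stopifnot(inherits(data, "lca_dataset"))
  df <- data$data
  for (j in seq_along(df)) {
    x <- df[[j]]
    df[[j]] <- ifelse(is.na(x), "", as.character(x))
  }
  if (include_ids) df <- cbind(id = data$ids, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a dataset to a subset of variables
#'
#' @param data An `lca_dataset`.
#' @param vars Character vector of variable names to keep.
#' @return An `lca_dataset` over the reduced codebook. Rows entirely missing
#'   on the kept variables are retained (the row still belongs to the
#'   cohort; its likelihood contribution reduces to the class weights).
#' @export
subset_variables <- function(data, vars) {
  stopifnot(inherits(data, "lca_dataset"))
  vars <- intersect(variable_names(data$codebook), vars)
  if (!length(vars)) stop("no matching variables to keep", call. = FALSE)
  cb <- codebook(data$codebook$variables[vars])
  lca_dataset(data$data[vars], cb, ids = data$ids, allow_all_missing = TRUE)
}
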