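#' Declare a single questionnaire variable
#'
#' A variable specification records everything the model and the diagnostics
#' need to know about one column of a patient dataset: its measurement kind,
#' its health domain, the admissible values, and which direction of the scale
#' indicates a more severe condition.
#'
#' @param name Variable name (unique within a codebook).
#' @param kind One of `"nominal"`, `"ordinal"`, `"continuous"`.
#' @param domain Health domain; one of `"activity"`, `"contextual"`, `"pain"`,
#'   `"participation"`, `"physical_impairment"`, `"psychology"`, `"other"`.
#' @param levels Ordered character vector of category codes. Required for
#'   nominal and ordinal variables; must be non-empty and unique.
#' @param range Numeric length-2 vector `c(min, max)` of scale bounds.
#'   Required for continuous variables (used for profile normalization);
#'   optional for ordinal variables (defaults to score range `c(1, C)`).
#' @param severity_direction `"higher_worse"`, `"lower_worse"` or `"none"`.
#'   Profiles reverse-score `lower_worse` variables so that higher always
#'   means more severe.
#' @param recode_map Optional named list mapping raw values (names) to
#'   analysis values; applied when reading data. For nominal variables the
#'   map targets must be declared levels.
#' @param severe_level Optional: for a nominal variable without a natural
#'   ordering, the single level regarded as the severe response. Used by
#'   [normalized_profile()].
#'
#' @return An object of class `"variable_spec"`.
#' @seealso [codebook()]
#' @export
variable_spec <- function(name, kind, domain = "other", levels = NULL,
                          range = NULL, severity_direction = "none",
                          recode_map = NULL, severe_level = NULL) {
  kind <- match.arg(kind, c("nominal", "ordinal", "continuous"))
  domain <- match.arg(domain, c("activity", "contextual", "pain",
                                "participation", "physical_impairment",
                                "psychology", "other"))
  severity_direction <- match.arg(severity_direction,
                                  c("higher_worse", "lower_worse", "none"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string", call. = FALSE)
  if (kind %in% c("nominal", "ordinal")) {
    if (is.null(levels) || length(levels) == 0L)
      stop(sprintf("variable '%s': %s variables need non-empty `levels`",
                   name, kind), call. = FALSE)
    levels <- as.character(levels)
    if (anyDuplicated(levels))
      stop(sprintf("variable '%s': duplicated levels", name), call. = FALSE)
  } else {
    levels <- NULL
  }
  if (kind == "continuous" && is.null(range))
    stop(sprintf("variable '%s': continuous variables need `range`", name),
         call. = FALSE)
  if (kind == "ordinal" && is.null(range))
    range <- c(1, length(levels))
  if (!is.null(range)) {
    range <- as.numeric(range)
    if (length(range) != 2L || !all(is.finite(range)) || range[1] >= range[2])
      stop(sprintf("variable '%s': `range` must be finite c(min, max) with min < max",
                   name), call. = FALSE)
  }
  if (!is.null(recode_map)) {
    if (is.null(names(recode_map)) || any(!nzchar(names(recode_map))))
      stop(sprintf("variable '%s': recode_map must be a fully named list", name),
           call. = FALSE)
    if (kind %in% c("nominal", "ordinal")) {
      targets <- as.character(unlist(recode_map, use.names = FALSE))
      bad <- setdiff(targets, levels)
      if (length(bad))
        stop(sprintf("variable '%s': recode_map targets not in levels: %s",
                     name, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (!is.null(severe_level)) {
    severe_level <- as.character(severe_level)
    if (is.null(levels) || !severe_level %in% levels)
      stop(sprintf("variable '%s': severe_level must be one of the declared levels",
                   name), call. = FALSE)
  }
  structure(list(name = name, kind = kind, domain = domain, levels = levels,
                 range = range, severity_direction = severity_direction,
                 recode_map = recode_map, severe_level = severe_level),
            class = "variable_spec")
}

#' Assemble a codebook from variable specifications
#'
#' A codebook is the ordered collection of [variable_spec()] declarations that
#' a dataset is validated against, together with the partition of variables
#' into health domains (derived from each variable's `domain` field).
#'
#' @param ... `variable_spec` objects, or a single list of them.
#'
#' @return An object of class `"lca_codebook"` with elements `variables`
#'   (named list of specs) and `domain_partition` (named list mapping each
#'   occurring domain to its variable names).
#' @export
codebook <- function(...) {
  vars <- list(...)
  if (length(vars) == 1L && is.list(vars[[1]]) &&
      !inherits(vars[[1]], "variable_spec"))
    vars <- vars[[1]]
  if (length(vars) == 0L)
    stop("a codebook needs at least one variable", call. = FALSE)
  ok <- vapply(vars, inherits, logical(1), what = "variable_spec")
  if (!all(ok))
    stop("all arguments must be variable_spec objects", call. = FALSE)
  nms <- vapply(vars, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop(sprintf("duplicated variable names: %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")),
         call. = FALSE)
  names(vars) <- nms
  doms <- vapply(vars, `[[`, character(1), "domain")
  partition <- split(nms, doms)
  structure(list(variables = vars, domain_partition = partition),
            class = "lca_codebook")
}

#' @export
print.lca_codebook <- function(x, ...) {
  kinds <- vapply(x$variables, `[[`, character(1), "kind")
  cat(sprintf("<lca_codebook> %d variables (%d nominal, %d ordinal, %d continuous)\n",
              length(x$variables), sum(kinds == "nominal"),
              sum(kinds == "ordinal"), sum(kinds == "continuous")))
  for (d in names(x$domain_partition))
    cat(sprintf("  %-20s %d variables\n", d, length(x$domain_partition[[d]])))
  invisible(x)
}

variable_names <- function(codebook) names(codebook$variables)

is_categorical <- function(spec) spec$kind %in% c("nominal", "ordinal")

n_levels <- function(spec) length(spec$levels)

#' Read or write a codebook as a YAML document
#'
#' The on-disk codebook is a key-value document with one entry per variable
#' carrying `kind`, `domain`, `levels`, `range`, `severity_direction`,
#' `recode_map` and `severe_level` fields, mirroring [variable_spec()].
#'
#' @param path File path.
#' @param codebook An `lca_codebook`.
#' @return `read_codebook()` returns an `lca_codebook`; `write_codebook()`
#'   returns `path` invisibly.
#' @export
read_codebook <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$variables))
    stop("codebook file must have a top-level `variables` entry", call. = FALSE)
  vars <- lapply(names(doc$variables), function(nm) {
    e <- doc$variables[[nm]]
    variable_spec(name = nm, kind = e$kind,
                  domain = e$domain %||% "other",
                  levels = e$levels, range = e$range,
                  severity_direction = e$severity_direction %||% "none",
                  recode_map = e$recode_map, severe_level = e$severe_level)
  })
  codebook(vars)
}

#' @rdname read_codebook
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "lca_codebook"))
  vars <- lapply(codebook$variables, function(v) {
    e <- list(kind = v$kind, domain = v$domain)
    if (!is.null(v$levels)) e$levels <- v$levels
    if (!is.null(v$range)) e$range <- v$range
    if (v$severity_direction != "none") e$severity_direction <- v$severity_direction
    if (!is.null(v$recode_map)) e$recode_map <- v$recode_map
    if (!is.null(v$severe_level)) e$severe_level <- v$severe_level
    e
  })
  yaml::write_yaml(list(variables = vars), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
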