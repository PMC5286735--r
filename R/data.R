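#' Published 7 x 9 subgroup membership comparison
#'
#' The cross-tabulation of modal subgroup memberships between a published
#' seven-subgroup single-stage solution (rows SS1--SS7) and a nine-subgroup
#' two-stage solution (columns TS1--TS9) on a cohort of 928 low back pain
#' patients. This is the one fully printed data object from the study the
#' package's methodology derives from, shipped as a worked example for the
#' cross-tabulation diagnostics; the original patient-level cohort was
#' never deposited.
#'
#' @return An `lca_crosstab` (counts, margins, grand total 928, and flags
#'   recomputed from the counts).
#' @examples
#' ct <- published_crosstab()
#' ct$total                      # 928
#' crosstab_agreement(ct)$ari
#' @export
published_crosstab <- function() {
  path <- system.file("extdata", "subgroup_crosstab_7x9.csv",
                      package = "lcasub", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  counts <- as.matrix(df[, -1])
  rownames(counts) <- df[[1]]
  crosstab(counts)
}

#' Expand a count matrix into paired assignment vectors
#'
#' Reconstructs two modal-assignment vectors whose cross-tabulation equals
#' the given counts (patient order is row-major over cells; any order
#' yields the same table and the same agreement statistics).
#'
#' @param counts Nonnegative integer matrix.
#' @return A list with vectors `a` (row solution) and `b` (column
#'   solution), each of length `sum(counts)`.
#' @export
expand_crosstab <- function(counts) {
  counts <- as.matrix(counts)
  a <- integer(0)
  b <- integer(0)
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      k <- counts[i, j]
      if (k > 0) {
        a <- c(a, rep.int(i, k))
        b <- c(b, rep.int(j, k))
      }
    }
  }
  list(a = a, b = b)
}
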