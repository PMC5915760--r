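#' Log2 expression matrix with missingness provenance
#'
#' The working container of the pipeline: a proteins x samples matrix of log2
#' LFQ intensities together with a per-cell record of whether each value was
#' measured, is still missing, or was filled in by imputation. Created by
#' [to_log2()] and completed by [impute_downshift()].
#'
#' @param values numeric matrix of log2 intensities (NA where missing).
#' @param observed logical matrix, `TRUE` where the value was measured.
#' @param provenance character matrix with entries `"observed"`, `"missing"`
#'   or `"imputed"`.
#' @param proteins tibble of row metadata with at least columns `protein_ids`
#'   and `gene_name`; one row per matrix row.
#'
#' @return An object of class `expr_matrix`.
#' @export
new_expr_matrix <- function(values, observed, provenance, proteins) {
  stopifnot(is.matrix(values), is.matrix(observed), is.matrix(provenance))
  if (!identical(dim(values), dim(observed)) ||
      !identical(dim(values), dim(provenance))) {
    abort("values, observed and provenance must share dimensions")
  }
  if (nrow(proteins) != nrow(values)) {
    abort("proteins metadata must have one row per matrix row")
  }
  if (anyDuplicated(colnames(values))) {
    abort("sample names must be unique")
  }
  rownames(values) <- rownames(observed) <- rownames(provenance) <-
    proteins$protein_ids
  structure(
    list(
      values = values,
      observed = observed,
      provenance = provenance,
      proteins = as_tibble(proteins)
    ),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  n_missing <- sum(!x$observed)
  n_imputed <- sum(x$provenance == "imputed")
  cat(sprintf(
    "<expr_matrix> %d proteins x %d samples; %d cells not measured (%d imputed)\n",
    nrow(x$values), ncol(x$values), n_missing, n_imputed
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Sample names of an expression matrix
#' @param x an `expr_matrix`.
#' @return Character vector of sample names.
#' @export
sample_names <- function(x) colnames(x$values)

is_complete <- function(x) !anyNA(x$values)

#' Subset an expression matrix
#'
#' @param x an `expr_matrix`.
#' @param i row (protein) index, logical or integer.
#' @param j column (sample) index, logical, integer or sample names.
#' @param ... unused.
#' @return An `expr_matrix` restricted to the requested rows/columns.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  new_expr_matrix(
    x$values[i, j, drop = FALSE],
    x$observed[i, j, drop = FALSE],
    x$provenance[i, j, drop = FALSE],
    x$proteins[i, , drop = FALSE]
  )
}

#' @export
as_tibble.expr_matrix <- function(x, ...) {
  wide <- bind_cols_safe(x$proteins, as_tibble(x$values, .name_repair = "minimal"))
  wide
}

bind_cols_safe <- function(a, b) {
  out <- a
  for (nm in names(b)) out[[nm]] <- b[[nm]]
  out
}

#' Tidy an expression matrix into long form
#'
#' @param x an `expr_matrix`.
#' @param ... unused.
#' @return A tibble with one row per protein/sample cell: `protein_ids`,
#'   `gene_name`, `sample`, `log2_intensity`, `observed`, `provenance`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  samples <- sample_names(x)
  tibble(
    protein_ids = rep(x$proteins$protein_ids, times = length(samples)),
    gene_name = rep(x$proteins$gene_name, times = length(samples)),
    sample = rep(samples, each = nrow(x$values)),
    log2_intensity = as.vector(x$values),
    observed = as.vector(x$observed),
    provenance = as.vector(x$provenance)
  )
}
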