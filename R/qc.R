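#' Inter-sample Pearson correlation report
#'
#' Pairwise Pearson correlation of log2 expression profiles, either on the
#' imputed complete matrix (the post-processing view used for heatmaps) or on
#' cells observed in both samples of a pair (`observed_pairwise`, which is
#' deterministic because it ignores imputed noise).
#'
#' @param x an `expr_matrix`.
#' @param use `"imputed_complete"` (default; requires a complete matrix) or
#'   `"observed_pairwise"`.
#' @return An object of class `correlation_report`: list with the samples x
#'   samples `matrix` and the `use` mode. `tidy()` gives the long pair table.
#' @export
correlation_report <- function(x, use = c("imputed_complete",
                                          "observed_pairwise")) {
  use <- match.arg(use)
  if (ncol(x$values) < 2) {
    abort("need at least 2 samples", class = "progmarker_validation_error")
  }
  if (use == "imputed_complete") {
    if (!is_complete(x)) {
      abort("matrix has missing values; impute first or use observed_pairwise",
            class = "progmarker_validation_error")
    }
    cc <- cor(x$values)
  } else {
    v <- x$values
    v[!x$observed] <- NA_real_
    shared <- crossprod(!is.na(v))
    if (any(shared < 3)) {
      bad <- which(shared < 3 & upper.tri(shared), arr.ind = TRUE)[1, ]
      abort(sprintf(
        "samples %s and %s share fewer than 3 observed proteins",
        colnames(v)[bad[1]], colnames(v)[bad[2]]),
        class = "progmarker_validation_error")
    }
    cc <- cor(v, use = "pairwise.complete.obs")
    diag(cc) <- 1
  }
  structure(list(matrix = cc, use = use), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  cat(sprintf(
    "<correlation_report> %d samples (%s); off-diagonal PCC range [%.3f, %.3f]\n",
    ncol(x$matrix), x$use, min(off), max(off)))
  invisible(x)
}

#' @export
tidy.correlation_report <- function(x, ...) {
  m <- x$matrix
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(
    sample_a = rownames(m)[idx[, 1]],
    sample_b = colnames(m)[idx[, 2]],
    pcc = m[idx]
  )
}

#' Flag cohort outliers by within-cohort correlation
#'
#' A sample is flagged when its best (maximum) Pearson correlation with any
#' other sample of the same cohort falls strictly below `threshold` — the rule
#' that singles out an atypical patient such as one whose profile no longer
#' matches its histological cohort. Cohorts of size 1 are never flagged.
#'
#' @param report a [correlation_report()].
#' @param annotation sample/cohort tibble covering every sample.
#' @param threshold flagging threshold on the max within-cohort PCC
#'   (default 0.75).
#' @return Tibble with `sample`, `cohort`, `max_within_cohort_pcc`, `flagged`.
#' @export
flag_outliers <- function(report, annotation, threshold = 0.75) {
  m <- report$matrix
  samples <- colnames(m)
  missing_ann <- setdiff(samples, annotation$sample)
  if (length(missing_ann)) {
    abort(paste0("samples missing from annotation: ",
                 paste(missing_ann, collapse = ", ")),
          class = "progmarker_validation_error")
  }
  cohort <- annotation$cohort[match(samples, annotation$sample)]
  max_pcc <- vapply(seq_along(samples), function(i) {
    mates <- which(cohort == cohort[i])
    mates <- setdiff(mates, i)
    if (!length(mates)) NA_real_ else max(m[i, mates])
  }, 0)
  tibble(
    sample = samples,
    cohort = cohort,
    max_within_cohort_pcc = max_pcc,
    flagged = !is.na(max_pcc) & max_pcc < threshold
  )
}

#' Housekeeping-protein stability report
#'
#' For each requested protein: the coefficient of variation of the
#' linear-scale (2^log2) values and the sample SD of the log2 values across
#' all samples — low values certify that presumed-stable proteins behave as
#' such in the dataset.
#'
#' @param x a complete `expr_matrix`.
#' @param housekeeping_ids protein ids expected to be stable.
#' @return Tibble with `protein_ids`, `gene_name`, `cv_linear`, `sd_log2`,
#'   `range_log2`.
#' @export
housekeeping_report <- function(x, housekeeping_ids) {
  missing_ids <- setdiff(housekeeping_ids, x$proteins$protein_ids)
  if (length(missing_ids)) {
    abort(paste0("unknown protein id(s): ",
                 paste(head(missing_ids, 10), collapse = ", ")),
          class = "progmarker_validation_error")
  }
  rows <- match(housekeeping_ids, x$proteins$protein_ids)
  v <- x$values[rows, , drop = FALSE]
  lin <- 2^v
  tibble(
    protein_ids = housekeeping_ids,
    gene_name = x$proteins$gene_name[rows],
    cv_linear = unname(apply(lin, 1, function(r) sd(r) / mean(r))),
    sd_log2 = unname(apply(v, 1, sd)),
    range_log2 = unname(apply(v, 1, function(r) diff(range(r))))
  )
}
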