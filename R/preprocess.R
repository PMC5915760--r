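#' Filter protein groups before quantification
#'
#' Removes decoy (reverse) hits, potential contaminants and groups identified
#' by fewer than `min_unique_peptides` unique peptides. Survivor order is
#' preserved; the per-criterion removal counts are attached as
#' `attr(, "filter_report")`.
#'
#' @param x a `protein_groups` tibble.
#' @param min_unique_peptides minimum unique-peptide count (default 2).
#' @param drop_reverse,drop_contaminant whether to drop flagged rows.
#' @return The filtered `protein_groups` tibble.
#' @export
filter_protein_groups <- function(x, min_unique_peptides = 2,
                                  drop_reverse = TRUE,
                                  drop_contaminant = TRUE) {
  bad_rev <- if (drop_reverse) x$is_reverse else rep(FALSE, nrow(x))
  bad_con <- if (drop_contaminant) x$is_contaminant else rep(FALSE, nrow(x))
  bad_pep <- !is.na(x$unique_peptides) & x$unique_peptides < min_unique_peptides
  keep <- !(bad_rev | bad_con | bad_pep)
  report <- tibble(
    criterion = c("reverse", "contaminant",
                  paste0("unique_peptides<", min_unique_peptides), "total"),
    removed = c(sum(bad_rev), sum(bad_con), sum(bad_pep), sum(!keep))
  )
  out <- x[keep, , drop = FALSE]
  attr(out, "samples") <- pg_samples(x)
  attr(out, "filter_report") <- report
  if (!inherits(out, "protein_groups")) {
    class(out) <- c("protein_groups", class(out))
  }
  out
}

#' Log2-transform LFQ intensities
#'
#' Zero intensities (MaxQuant's "not quantified") become missing cells;
#' positive intensities become log2 values. No imputation happens here.
#'
#' @param x a `protein_groups` tibble.
#' @return An [new_expr_matrix()] with `NA` at missing cells and provenance
#'   `"observed"` / `"missing"`.
#' @export
to_log2 <- function(x) {
  samples <- pg_samples(x)
  m <- as.matrix(as.data.frame(x)[, samples, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) {
    abort("negative intensities cannot be log-transformed",
          class = "progmarker_validation_error")
  }
  observed <- is.finite(m) & m > 0
  vals <- ifelse(observed, log2(m), NA_real_)
  colnames(vals) <- colnames(observed) <- samples
  prov <- ifelse(observed, "observed", "missing")
  new_expr_matrix(vals, observed, prov,
                  x[, c("protein_ids", "gene_name"), drop = FALSE])
}

#' Impute missing values by per-sample Gaussian down-shift
#'
#' Perseus-style missing-not-at-random imputation: within each sample column,
#' missing cells are drawn from a Gaussian centred `downshift` observed
#' standard deviations below the observed mean, with width `width` times the
#' observed standard deviation — emulating the distribution of signals below
#' the detection limit. Observed cells are never altered.
#'
#' @param x an `expr_matrix` from [to_log2()].
#' @param width imputation SD as a fraction of the observed SD (default 0.3).
#' @param downshift number of observed SDs subtracted from the observed mean
#'   (default 1.0).
#' @param seed optional RNG seed (consumed as a dedicated substream so other
#'   stages' draws are unaffected).
#' @return The completed `expr_matrix`, with imputed cells marked in the
#'   provenance matrix.
#' @export
impute_downshift <- function(x, width = 0.3, downshift = 1.0, seed = NULL) {
  stopifnot(width > 0, downshift >= 0)
  n_obs <- colSums(x$observed)
  if (any(n_obs < 2)) {
    abort(paste0("cannot estimate imputation parameters for sample(s) with ",
                 "fewer than 2 observed values: ",
                 paste(sample_names(x)[n_obs < 2], collapse = ", ")),
          class = "progmarker_validation_error")
  }
  vals <- x$values
  prov <- x$provenance
  with_stage_seed(seed, "impute", {
    for (j in seq_len(ncol(vals))) {
      obs <- x$observed[, j]
      if (all(obs)) next
      mu <- mean(vals[obs, j])
      sigma <- sd(vals[obs, j])
      miss <- which(!obs)
      vals[miss, j] <- rnorm(length(miss), mu - downshift * sigma,
                             width * sigma)
      prov[miss, j] <- "imputed"
    }
  })
  new_expr_matrix(vals, x$observed, prov, x$proteins)
}

#' Z-score each protein across samples
#'
#' Standardises every row to mean 0, SD 1 — the normalisation used ahead of
#' Euclidean-distance hierarchical clustering and heatmaps.
#'
#' @param x a complete `expr_matrix`.
#' @param sd_type `"population"` (divide by n, the common heatmap-tooling
#'   convention; default) or `"sample"` (divide by n-1).
#' @return The standardised `expr_matrix`.
#' @export
zscore_rows <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!is_complete(x)) {
    abort("matrix has missing values; run impute_downshift() first",
          class = "progmarker_validation_error")
  }
  v <- x$values
  mu <- rowMeans(v)
  centred <- v - mu
  n <- ncol(v)
  ss <- rowSums(centred^2)
  s <- if (sd_type == "population") sqrt(ss / n) else sqrt(ss / (n - 1))
  if (any(s == 0)) {
    abort(paste0("constant rows cannot be z-scored: ",
                 paste(head(x$proteins$protein_ids[s == 0], 5), collapse = ", ")),
          class = "progmarker_validation_error")
  }
  new_expr_matrix(centred / s, x$observed, x$provenance, x$proteins)
}
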