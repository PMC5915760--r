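# Builders shared across test files. All fixtures are constructed in code.

# protein-groups tibble from an intensity matrix (proteins x samples)
make_pg <- function(intensities, peptides = NULL, reverse = FALSE,
                    contaminant = FALSE, genes = NULL) {
  n <- nrow(intensities)
  samples <- colnames(intensities)
  stopifnot(!is.null(samples))
  pg <- tibble::tibble(
    protein_ids = sprintf("P%03d", seq_len(n)),
    gene_name = genes %||% sprintf("G%03d", seq_len(n)),
    unique_peptides = as.integer(peptides %||% rep(5L, n)),
    is_reverse = rep_len(reverse, n),
    is_contaminant = rep_len(contaminant, n)
  )
  for (k in seq_along(samples)) pg[[samples[k]]] <- intensities[, k]
  attr(pg, "samples") <- samples
  class(pg) <- c("protein_groups", class(pg))
  pg
}

# complete expr_matrix straight from a log2 matrix
make_em <- function(values, genes = NULL) {
  n <- nrow(values)
  stopifnot(!is.null(colnames(values)))
  obs <- matrix(TRUE, n, ncol(values), dimnames = dimnames(values))
  prov <- matrix("observed", n, ncol(values), dimnames = dimnames(values))
  new_expr_matrix(values, obs, prov,
                  tibble::tibble(protein_ids = sprintf("P%03d", seq_len(n)),
                                 gene_name = genes %||% sprintf("G%03d", seq_len(n))))
}

# annotation for a named cohort-size vector, sample names <cohort>_<i>
make_annotation <- function(sizes) {
  tibble::tibble(
    sample = unlist(lapply(names(sizes), function(g) paste0(g, "_", seq_len(sizes[[g]])))),
    cohort = rep(names(sizes), times = unlist(sizes)),
    batch = NA_character_
  )
}

# write a proteinGroups-dialect file and return its path
write_pg_fixture <- function(pg, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "proteinGroups.txt")
  write_protein_groups(pg, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
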