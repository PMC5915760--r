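map_symbols <- function(x, symbols) {
  # case-insensitive exact symbol match; multi-mapping resolved to the protein
  # group with the highest mean log2 intensity
  tbl_genes <- toupper(x$proteins$gene_name)
  row_mean <- rowMeans(x$values, na.rm = TRUE)
  vapply(toupper(symbols), function(s) {
    hits <- which(tbl_genes == s & tbl_genes != "")
    if (!length(hits)) NA_integer_
    else hits[which.max(row_mean[hits])]
  }, 1L, USE.NAMES = FALSE)
}

#' Extract an IHC-style marker matrix
#'
#' Pulls the per-sample log2 values for a list of marker gene symbols together
#' with detection flags. "Detected" means observed before imputation: imputed
#' cells are noise fill and do not count as expression evidence.
#'
#' @param x an `expr_matrix`.
#' @param markers character vector of gene symbols.
#' @return Tibble in long form: `gene`, `mapped`, `protein_ids`, `sample`,
#'   `log2_intensity`, `detected`. Unmapped symbols are retained with
#'   `mapped = FALSE` and NA values.
#' @export
extract_marker_matrix <- function(x, markers) {
  rows <- map_symbols(x, markers)
  samples <- sample_names(x)
  out <- purrr::map2_dfr(markers, rows, function(g, r) {
    if (is.na(r)) {
      tibble(gene = g, mapped = FALSE, protein_ids = NA_character_,
             sample = samples, log2_intensity = NA_real_, detected = FALSE)
    } else {
      tibble(gene = g, mapped = TRUE,
             protein_ids = x$proteins$protein_ids[r],
             sample = samples,
             log2_intensity = x$values[r, ],
             detected = x$observed[r, ])
    }
  })
  out
}

#' Concordance of a directional gene signature with the proteome
#'
#' For each signature gene: maps it to a protein group, computes the log2
#' difference of cohort means (cancer minus comparator), calls the gene
#' concordant when the sign of that difference matches the signature's
#' expected direction, and flags S0-volcano significance. Summary counts
#' (concordant-up / total-up etc.) are attached as `attr(, "summary")`.
#'
#' @param signature a `signature_set` from [read_signature()] (columns
#'   `gene`, `direction`).
#' @param x a complete `expr_matrix`.
#' @param annotation sample/cohort tibble.
#' @param cancer cancer cohort (e.g. "CC").
#' @param comparator comparator cohort (default "EMT").
#' @param fdr,s0 volcano parameters for the significance flag.
#' @return Tibble with per-gene `mapped`, `logfc`, `protein_direction`,
#'   `concordant`, `significant`.
#' @export
signature_concordance <- function(signature, x, annotation, cancer,
                                  comparator = "EMT", fdr = 0.05, s0 = 1) {
  idx <- match_groups(x, annotation, c(cancer, comparator))
  if (any(lengths(idx) < 2)) {
    abort("both cohorts need at least 2 samples",
          class = "progmarker_validation_error")
  }
  dt <- moderated_t(x, annotation, contrast = c(cancer, comparator))
  sig_flags <- s0_significance(dt$logfc, dt$se, dt$df_total,
                               fdr = fdr, s0 = s0)$significant
  rows <- map_symbols(x, signature$gene)
  logfc <- ifelse(is.na(rows), NA_real_, dt$logfc[rows])
  prot_dir <- dplyr::case_when(
    is.na(logfc) ~ NA_character_,
    logfc > 0 ~ "up",
    logfc < 0 ~ "down",
    TRUE ~ "flat"
  )
  out <- tibble(
    gene = signature$gene,
    direction = signature$direction,
    mapped = !is.na(rows),
    protein_ids = ifelse(is.na(rows), NA_character_,
                         x$proteins$protein_ids[rows]),
    logfc = logfc,
    protein_direction = prot_dir,
    concordant = !is.na(prot_dir) & prot_dir == signature$direction,
    significant = ifelse(is.na(rows), FALSE, sig_flags[rows])
  )
  up <- out$direction == "up"
  attr(out, "summary") <- tibble(
    concordant_up = sum(out$concordant & up),
    total_up = sum(up),
    concordant_down = sum(out$concordant & !up),
    total_down = sum(!up),
    significant_and_concordant = sum(out$concordant & out$significant)
  )
  out
}

#' Can a signature's sub-matrix separate cohorts?
#'
#' Clusters samples on the z-scored sub-matrix of the signature's mapped
#' proteins (Euclidean, average linkage, 2-group cut) and scores the
#' agreement with each requested binary labelling by the adjusted Rand
#' index — high for partitions the signature can reconstruct, near zero for
#' those it cannot.
#'
#' @param x a complete `expr_matrix`.
#' @param annotation sample/cohort tibble.
#' @param signature a `signature_set` or plain character vector of symbols.
#' @param partitions named list of binary labelings; each element is a
#'   character vector of the cohorts forming one side (the rest of the
#'   samples form the other), e.g.
#'   `list(cancer_vs_control = c("CC", "EC"), emt_vs_end = "EMT")`. For a
#'   partition naming only some cohorts' samples (e.g. EMT vs END), samples
#'   outside those cohorts are dropped before clustering.
#' @param restrict named list (same names) of cohort subsets to restrict each
#'   comparison to, or `NULL` to use all samples.
#' @return Tibble with `partition` and `ari`.
#' @export
signature_discrimination <- function(x, annotation, signature, partitions,
                                     restrict = NULL) {
  symbols <- if (is.data.frame(signature)) signature$gene else signature
  rows <- map_symbols(x, symbols)
  rows <- rows[!is.na(rows)]
  if (length(rows) < 2) {
    abort("signature maps to fewer than 2 proteins",
          class = "progmarker_validation_error")
  }
  sub <- x[unique(rows), ]
  cohort <- annotation$cohort[match(sample_names(x), annotation$sample)]
  res <- imap(partitions, function(side, nm) {
    keep <- seq_along(cohort)
    if (!is.null(restrict) && !is.null(restrict[[nm]])) {
      keep <- which(cohort %in% restrict[[nm]])
    }
    subk <- sub[, keep]
    # drop proteins constant across the retained samples
    s <- apply(subk$values, 1, sd)
    subk <- subk[s > 0, ]
    if (nrow(subk$values) < 2 || ncol(subk$values) < 3) {
      return(tibble(partition = nm, ari = NA_real_))
    }
    cl <- hierarchical_cluster(zscore_rows(subk), axis = "samples")
    assign <- cut_clusters(cl, 2)
    labels <- ifelse(cohort[keep] %in% side, "in", "out")
    tibble(partition = nm, ari = label_agreement(assign, labels))
  })
  bind_rows(res)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set: the upper-tail hypergeometric probability
#' `P(X >= overlap)` of drawing at least the observed overlap when `|query|`
#' genes are sampled without replacement from the background, with BH
#' adjustment across sets. Membership is case-insensitive.
#'
#' @param query character vector of gene symbols (must be contained in
#'   `background`).
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param background character vector: the symbol universe.
#' @return Tibble with per-set `overlap`, `set_size` (after intersection with
#'   the background), `query_size`, `background_size`, `p`, `q`.
#' @export
ora_hypergeometric <- function(query, sets, background) {
  query <- unique(toupper(query))
  background <- unique(toupper(background))
  stray <- setdiff(query, background)
  if (length(stray)) {
    abort(paste0("query genes outside the background: ",
                 paste(head(stray, 10), collapse = ", ")),
          class = "progmarker_validation_error")
  }
  n_bg <- length(background)
  n_q <- length(query)
  res <- imap(sets, function(genes, nm) {
    genes <- intersect(unique(toupper(genes)), background)
    k <- length(intersect(genes, query))
    p <- phyper(k - 1, length(genes), n_bg - length(genes), n_q,
                lower.tail = FALSE)
    tibble(set = nm, overlap = k, set_size = length(genes),
           query_size = n_q, background_size = n_bg, p = p)
  })
  out <- bind_rows(res)
  out$q <- p.adjust(out$p, method = "BH")
  out
}
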