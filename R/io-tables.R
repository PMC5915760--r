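#' Read a MaxQuant-style proteinGroups table
#'
#' Parses the tab-separated `proteinGroups.txt` dialect: one row per protein
#' group, identifier and peptide-count columns, `"+"`-coded Reverse /
#' Potential contaminant flags, and one `"LFQ intensity <sample>"` column per
#' sample. Zero intensities are preserved as zeros; their interpretation as
#' missing values is deferred to [to_log2()]. Both the full MaxQuant header
#' set and a minimal five-column dialect are accepted; LFQ columns are
#' recognised solely by the `"LFQ intensity "` prefix.
#'
#' @param path path to a tab-separated protein-groups file.
#' @return A tibble of class `protein_groups` with columns `protein_ids`,
#'   `gene_name` (first symbol when several are concatenated with `";"`),
#'   `unique_peptides`, `is_reverse`, `is_contaminant`, and one numeric column
#'   per sample (prefix stripped, file order preserved). Sample names are
#'   stored in `attr(, "samples")`.
#' @export
read_protein_groups <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(decimal_mark = "."),
    progress = FALSE,
    name_repair = "minimal"
  )
  lfq_prefix <- "LFQ intensity "
  lfq_cols <- names(raw)[startsWith(names(raw), lfq_prefix)]
  if (length(lfq_cols) == 0) {
    abort(
      paste0("no quantification columns found; expected columns with the '",
             lfq_prefix, "' prefix"),
      class = "progmarker_format_error"
    )
  }
  samples <- substring(lfq_cols, nchar(lfq_prefix) + 1L)
  if (anyDuplicated(samples)) {
    abort(
      paste0("duplicate sample names: ",
             paste(unique(samples[duplicated(samples)]), collapse = ", ")),
      class = "progmarker_format_error"
    )
  }

  pick <- function(...) {
    cand <- c(...)
    hit <- cand[cand %in% names(raw)]
    if (length(hit)) hit[[1]] else NA_character_
  }
  id_col <- pick("Majority protein IDs", "Protein IDs", "protein_ids")
  if (is.na(id_col)) {
    abort("no protein identifier column (expected 'Majority protein IDs' or 'Protein IDs')",
          class = "progmarker_format_error")
  }
  gene_col <- pick("Gene names", "gene_name")
  pep_col <- pick("Unique peptides", "unique_peptides")
  rev_col <- pick("Reverse", "is_reverse")
  con_col <- pick("Potential contaminant", "Contaminant", "is_contaminant")

  lfq <- matrix(NA_real_, nrow = nrow(raw), ncol = length(lfq_cols),
                dimnames = list(NULL, samples))
  for (k in seq_along(lfq_cols)) {
    v <- suppressWarnings(as.numeric(raw[[lfq_cols[k]]]))
    bad <- which(is.na(v) & !is.na(raw[[lfq_cols[k]]]) &
                   trimws(raw[[lfq_cols[k]]]) != "")
    if (length(bad)) {
      abort(sprintf("non-numeric intensity in column '%s', row %d: '%s'",
                    lfq_cols[k], bad[1], raw[[lfq_cols[k]]][bad[1]]),
            class = "progmarker_format_error")
    }
    v[is.na(v)] <- 0
    lfq[, k] <- v
  }
  if (any(lfq < 0)) {
    abort("negative LFQ intensity encountered", class = "progmarker_format_error")
  }

  plus_flag <- function(col) {
    if (is.na(col)) rep(FALSE, nrow(raw))
    else !is.na(raw[[col]]) & trimws(raw[[col]]) == "+"
  }
  gene <- if (is.na(gene_col)) rep("", nrow(raw)) else {
    g <- raw[[gene_col]]
    g[is.na(g)] <- ""
    stringr::str_split_fixed(g, ";", 2)[, 1]
  }
  pep <- if (is.na(pep_col)) rep(NA_integer_, nrow(raw)) else {
    suppressWarnings(as.integer(raw[[pep_col]]))
  }

  out <- tibble(
    protein_ids = raw[[id_col]],
    gene_name = gene,
    unique_peptides = pep,
    is_reverse = plus_flag(rev_col),
    is_contaminant = plus_flag(con_col)
  )
  if (any(is.na(out$protein_ids) | out$protein_ids == "")) {
    abort("every protein group needs at least one protein id",
          class = "progmarker_format_error")
  }
  for (s in samples) out[[s]] <- lfq[, s]
  attr(out, "samples") <- samples
  class(out) <- c("protein_groups", class(out))
  out
}

#' Write a protein-groups table in the proteinGroups dialect
#'
#' Inverse of [read_protein_groups()]: emits MaxQuant-style column headers and
#' `"+"`-coded flags so the written file round-trips through the reader.
#'
#' @param x a `protein_groups` tibble.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(x, path) {
  samples <- pg_samples(x)
  out <- tibble(
    `Majority protein IDs` = x$protein_ids,
    `Gene names` = x$gene_name,
    `Unique peptides` = x$unique_peptides,
    Reverse = ifelse(x$is_reverse, "+", ""),
    `Potential contaminant` = ifelse(x$is_contaminant, "+", "")
  )
  for (s in samples) out[[paste0("LFQ intensity ", s)]] <- x[[s]]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

pg_samples <- function(x) {
  s <- attr(x, "samples")
  if (is.null(s)) {
    meta <- c("protein_ids", "gene_name", "unique_peptides",
              "is_reverse", "is_contaminant")
    s <- setdiff(names(x), meta)
  }
  s
}

#' Read a sample-to-cohort annotation table
#'
#' @param path delimited file (tab or comma) with header columns `sample` and
#'   `cohort` (case-insensitive), and an optional `batch` column.
#' @return A tibble with columns `sample`, `cohort` (one of CC, EC, EMT, END)
#'   and `batch` (NA when absent).
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_delim(
    path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  names(raw) <- tolower(names(raw))
  if (!all(c("sample", "cohort") %in% names(raw))) {
    abort("annotation needs 'sample' and 'cohort' columns",
          class = "progmarker_format_error")
  }
  bad <- setdiff(unique(raw$cohort), cohort_levels())
  if (length(bad)) {
    abort(paste0("unknown cohort label(s): ", paste(bad, collapse = ", "),
                 "; allowed: ", paste(cohort_levels(), collapse = ", ")),
          class = "progmarker_validation_error")
  }
  tibble(
    sample = raw$sample,
    cohort = raw$cohort,
    batch = if ("batch" %in% names(raw)) raw$batch else NA_character_
  )
}

#' Read a direction-annotated gene signature
#'
#' @param path delimited file with a gene-symbol column (`gene` or `symbol`)
#'   and a `direction` column; `up`/`+`/`1` map to "up", `down`/`-`/`-1` to
#'   "down".
#' @param name signature name; defaults to the file name.
#' @return A tibble of class `signature_set` with columns `gene` and
#'   `direction`, and the name in `attr(, "name")`.
#' @export
read_signature <- function(path, name = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_delim(
    path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  names(raw) <- tolower(names(raw))
  gene_col <- intersect(c("gene", "symbol", "gene_name"), names(raw))
  if (!length(gene_col) || !"direction" %in% names(raw)) {
    abort("signature needs a gene/symbol column and a direction column",
          class = "progmarker_format_error")
  }
  dir <- normalize_direction(raw$direction)
  out <- tibble(gene = raw[[gene_col[1]]], direction = dir)
  if (any(is.na(out$gene) | out$gene == "")) {
    abort("empty gene symbol in signature", class = "progmarker_validation_error")
  }
  attr(out, "name") <- name %||% basename(path)
  class(out) <- c("signature_set", class(out))
  out
}

normalize_direction <- function(x) {
  x0 <- tolower(trimws(x))
  out <- rep(NA_character_, length(x0))
  out[x0 %in% c("up", "+", "1", "increased")] <- "up"
  out[x0 %in% c("down", "-", "-1", "decreased")] <- "down"
  if (anyNA(out) && length(x0)) {
    abort(paste0("unrecognised direction value(s): ",
                 paste(unique(x0[is.na(out)]), collapse = ", "),
                 "; allowed: up, down, +, -"),
          class = "progmarker_validation_error")
  }
  out
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return A named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort("GMT line needs name, description and at least one gene",
            class = "progmarker_format_error")
    }
    unique(parts[-c(1, 2)][nzchar(parts[-c(1, 2)])])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write result tables as tab-separated files
#'
#' @param tables named list of data frames.
#' @param out_dir output directory, created if needed.
#' @return Tibble with columns `name` and `path` of the written files.
#' @export
write_result_tables <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(paste0("cannot create output directory: ", out_dir))
  }
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(as_tibble(tables[[nm]]), p, progress = FALSE)
    p
  }, "")
  tibble(name = names(tables), path = unname(paths))
}
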