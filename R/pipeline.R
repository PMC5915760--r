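default_pipeline_params <- function() {
  list(
    min_unique_peptides = 2,
    impute = list(width = 0.3, downshift = 1.0),
    correlation_on = "imputed_complete",
    outlier_threshold = 0.75,
    exclude_outliers = FALSE,
    anova_alpha = 0.01,
    volcano = list(fdr = 0.05, s0 = 1),
    cancer_cohort = "CC",
    comparator = "EMT",
    tau = 0.9,
    gamma = 0.25,
    null = "theoretical",
    k_clusters = 2
  )
}

#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates every stage end to end: read (or simulate) the protein-group
#' table and annotation; filter; log2-transform; pre-imputation QC in
#' observed-pairwise mode; impute; post-imputation QC and outlier flagging;
#' PCA and hierarchical clustering; one-way ANOVA of cancer vs EMT vs END;
#' moderated t for the cancer-vs-comparator contrast with the S0 volcano
#' rule; transition posteriors and progressive-pattern marker calls; optional
#' signature concordance and over-representation analysis. All result tables
#' are written as TSV under `out_dir` and listed in a JSON manifest; the same
#' config and seed reproduce identical numbers.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Must contain exactly one of `input` (list with `protein_groups` and
#'   `annotation` paths) or `simulation` (arguments for [sim_config()]);
#'   optional elements `params` (overrides of the defaults, see
#'   `progmarker:::default_pipeline_params()`), `signature` (path),
#'   `gene_sets` (GMT path), `seed` and `out_dir`.
#' @return The manifest (list with `outputs`, `parameters`, `seed`,
#'   `version`, `stages`), invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulation)
  if (has_input == has_sim) {
    abort("config must contain exactly one of 'input' or 'simulation'",
          class = "progmarker_config_error")
  }
  params <- modifyList(default_pipeline_params(), config$params %||% list())
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% "progmarker_output"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  tables <- list()
  note <- function(s) stages <<- c(stages, s)

  if (has_sim) {
    note("simulate")
    cfg <- do.call(sim_config, modifyList(config$simulation,
                                          list(seed = seed)))
    sim <- generate_lfq_dataset(cfg)
    pg <- sim$protein_groups
    annotation <- sim$annotation
    tables$truth <- sim$truth
  } else {
    note("read")
    for (f in c("protein_groups", "annotation")) {
      if (is.null(config$input[[f]]) || !file.exists(config$input[[f]])) {
        abort(paste0("input file missing: ", f),
              class = "progmarker_config_error")
      }
    }
    pg <- read_protein_groups(config$input$protein_groups)
    annotation <- read_sample_annotation(config$input$annotation)
  }

  note("filter")
  pg <- filter_protein_groups(pg, params$min_unique_peptides)
  tables$filter_report <- attr(pg, "filter_report")

  note("log2")
  em_raw <- to_log2(pg)

  note("qc_pre")
  qc_pre <- correlation_report(em_raw, use = "observed_pairwise")
  tables$correlation_pre_imputation <- tidy(qc_pre)

  note("impute")
  em <- impute_downshift(em_raw, width = params$impute$width,
                         downshift = params$impute$downshift, seed = seed)

  note("qc_post")
  qc_post <- correlation_report(em, use = "imputed_complete")
  tables$correlation_post_imputation <- tidy(qc_post)
  qc_for_flags <- if (params$correlation_on == "observed_pairwise") qc_pre else qc_post
  flags <- flag_outliers(qc_for_flags, annotation, params$outlier_threshold)
  tables$outlier_flags <- flags
  if (isTRUE(params$exclude_outliers) && any(flags$flagged)) {
    note("exclude_outliers")
    keep <- !sample_names(em) %in% flags$sample[flags$flagged]
    em <- em[, keep]
    annotation <- annotation[annotation$sample %in% sample_names(em), ]
  }

  note("pca")
  pca <- lfq_pca(em)
  tables$pca_scores <- tidy(pca)
  tables$pca_variance <- tibble(component = seq_along(pca$explained_variance),
                                explained_variance = pca$explained_variance)

  note("cluster")
  cl <- hierarchical_cluster(zscore_rows(em), axis = "samples")
  tables$cluster_merges <- tidy(cl)
  tables$cluster_assignments <- cut_clusters(cl, params$k_clusters)

  cancer <- params$cancer_cohort
  note("anova")
  anova_groups <- intersect(c(cancer, "EMT", "END"), unique(annotation$cohort))
  tables$anova <- anova_scan(em, annotation, groups = anova_groups,
                             alpha = params$anova_alpha)

  note("moderated_t")
  dt <- moderated_t(em, annotation, contrast = c(cancer, params$comparator))
  vol <- s0_significance(dt$logfc, dt$se, dt$df_total,
                         fdr = params$volcano$fdr, s0 = params$volcano$s0)
  dt$t_s0 <- vol$t_s0
  dt$q_s0 <- vol$q
  dt$significant_s0 <- vol$significant
  tables$differential <- dt

  note("markers")
  post <- transition_posteriors(em, annotation,
                                ordered_groups = c("END", "EMT", cancer),
                                gamma = params$gamma, null = params$null)
  calls <- classify_patterns(post, tau = params$tau)
  tables$transition_posteriors <- as_tibble(as.data.frame(post))
  tables$marker_calls <- as_tibble(as.data.frame(calls))
  tables$markers <- as_tibble(as.data.frame(calls[calls$is_marker, ]))

  if (!is.null(config$signature)) {
    note("signatures")
    sig <- read_signature(config$signature)
    conc <- signature_concordance(sig, em, annotation, cancer = cancer,
                                  comparator = params$comparator,
                                  fdr = params$volcano$fdr,
                                  s0 = params$volcano$s0)
    tables$signature_concordance <- conc
    tables$signature_concordance_summary <- attr(conc, "summary")
  }
  if (!is.null(config$gene_sets)) {
    note("enrichment")
    sets <- read_gmt(config$gene_sets)
    background <- unique(em$proteins$gene_name)
    query <- unique(tables$markers$gene_name)
    query <- intersect(toupper(query), toupper(background))
    tables$enrichment <- ora_hypergeometric(query, sets, background)
  }

  note("write")
  written <- write_result_tables(tables, out_dir)
  manifest <- list(
    version = as.character(utils::packageVersion("progmarker")),
    seed = seed,
    parameters = params,
    stages = stages,
    outputs = setNames(as.list(written$path), written$name)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
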