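#' Simulation configuration for synthetic LFQ datasets
#'
#' Defines the statistical regime the generator emulates: a tissue cohort of
#' 21 unbalanced samples (CC/EC/EMT/END), log-normal protein intensities,
#' subsets of proteins with progressive cohort effects, housekeeping proteins
#' with equal means everywhere, and intensity-dependent (missing-not-at-random)
#' dropout encoded as zero intensities.
#'
#' Progressive patterns shift cohort means in log2 units relative to the END
#' baseline: pattern A rises at both transitions (`+effect_size` at EMT,
#' `+2*effect_size` in the carcinoma cohorts), pattern B rises only from END
#' to EMT (carcinoma stays at the EMT level), pattern C rises only from EMT
#' to carcinoma (`+effect_size` in carcinoma, EMT = END). Both carcinoma
#' cohorts (CC and EC) receive the same shift.
#'
#' A cell with realized log2 value `x` is set missing with probability
#' `plogis(mnar_alpha - mnar_beta * x)`, mimicking an instrument detection
#' limit acting on the noisy value rather than the true mean.
#'
#' @param n_proteins number of protein groups.
#' @param cohort_sizes named counts for CC, EC, EMT, END.
#' @param baseline_mean,baseline_sd log2-intensity distribution of per-protein
#'   baselines.
#' @param effect_size log2-unit step per perturbed transition.
#' @param pattern_fractions named fractions of proteins assigned patterns
#'   A, B, C; the remainder (beyond housekeeping) is unperturbed.
#' @param n_housekeeping number of dedicated housekeeping proteins (equal
#'   means in all cohorts, labelled in the truth table).
#' @param mnar_alpha,mnar_beta missingness-logistic parameters; `mnar_beta = 0`
#'   gives intensity-independent dropout, `mnar_alpha = -Inf` none at all.
#' @param noise_sd within-cohort residual SD in log2 units.
#' @param single_peptide_fraction fraction of rows drawn with a single unique
#'   peptide (removed by the default filter).
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 5000,
                       cohort_sizes = c(CC = 6, EC = 7, EMT = 3, END = 5),
                       baseline_mean = 25,
                       baseline_sd = 2,
                       effect_size = 2,
                       pattern_fractions = c(A = 0.02, B = 0.02, C = 0.02),
                       n_housekeeping = 50,
                       mnar_alpha = 10.4,
                       mnar_beta = 0.5,
                       noise_sd = 0.7,
                       single_peptide_fraction = 0.05,
                       seed = 1L) {
  cohort_sizes <- unlist(cohort_sizes)[cohort_levels()]
  pattern_fractions <- unlist(pattern_fractions)
  names(cohort_sizes) <- cohort_levels()
  pf <- c(A = 0, B = 0, C = 0)
  pf[names(pattern_fractions)] <- pattern_fractions
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    cohort_sizes = cohort_sizes,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    effect_size = effect_size,
    pattern_fractions = pf,
    n_housekeeping = as.integer(n_housekeeping),
    mnar_alpha = mnar_alpha,
    mnar_beta = mnar_beta,
    noise_sd = noise_sd,
    single_peptide_fraction = single_peptide_fraction,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (sum(cfg$pattern_fractions) > 1) {
    abort("pattern fractions must sum to at most 1",
          class = "progmarker_config_error")
  }
  if (any(is.na(cfg$cohort_sizes)) || any(cfg$cohort_sizes < 0)) {
    abort("cohort sizes must be non-negative counts",
          class = "progmarker_config_error")
  }
  if (cfg$n_proteins < 0 || cfg$n_housekeeping < 0) {
    abort("counts must be non-negative", class = "progmarker_config_error")
  }
  if (cfg$n_housekeeping + sum(round(cfg$pattern_fractions * cfg$n_proteins)) >
        cfg$n_proteins) {
    abort("housekeeping plus pattern proteins exceed n_proteins",
          class = "progmarker_config_error")
  }
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0) {
    abort("noise_sd must be positive", class = "progmarker_config_error")
  }
  invisible(cfg)
}

#' Dropout probability at a given log2 intensity
#'
#' @param x log2 intensity (vectorised).
#' @param config a [sim_config()].
#' @return `plogis(mnar_alpha - mnar_beta * x)`, in `[0, 1]` and monotone
#'   non-increasing in `x` when `mnar_beta >= 0`.
#' @export
missingness_probability <- function(x, config) {
  stats::plogis(config$mnar_alpha - config$mnar_beta * x)
}

#' Generate a synthetic LFQ dataset with ground truth
#'
#' Draws per-protein baselines, applies the configured progressive cohort
#' shifts, adds within-cohort noise, applies intensity-dependent dropout, and
#' exports the result on the raw intensity scale (`2^x`, zeros for missing) in
#' the same proteinGroups dialect the reader consumes, so the full
#' preprocessing path is exercised.
#'
#' @param config a [sim_config()].
#' @return A list with elements `protein_groups` (a `protein_groups` tibble),
#'   `annotation` (sample/cohort tibble) and `truth` (per-protein pattern and
#'   true cohort means; the per-cell dropout probability matrix is in
#'   `attr(truth, "miss_prob")`).
#' @export
generate_lfq_dataset <- function(config) {
  validate_sim_config(config)
  with_stage_seed(config$seed, "simulate", {
    n <- config$n_proteins
    sizes <- config$cohort_sizes
    cohorts <- rep(names(sizes), times = sizes)
    samples <- unlist(lapply(names(sizes), function(g) {
      if (sizes[[g]] == 0) character(0) else paste0(g, "_", seq_len(sizes[[g]]))
    }))

    n_pat <- round(config$pattern_fractions * n)
    pattern <- rep("none", n)
    idx <- seq_len(n)
    hk_idx <- head(idx, config$n_housekeeping)
    pattern[hk_idx] <- "housekeeping"
    free <- setdiff(idx, hk_idx)
    take <- function(k) {
      got <- head(free, k)
      free <<- setdiff(free, got)
      got
    }
    pattern[take(n_pat[["A"]])] <- "A"
    pattern[take(n_pat[["B"]])] <- "B"
    pattern[take(n_pat[["C"]])] <- "C"

    e <- config$effect_size
    shift <- cbind(
      CC = ifelse(pattern == "A", 2 * e, ifelse(pattern %in% c("B", "C"), e, 0)),
      EC = ifelse(pattern == "A", 2 * e, ifelse(pattern %in% c("B", "C"), e, 0)),
      EMT = ifelse(pattern %in% c("A", "B"), e, 0),
      END = 0
    )
    baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
    true_means <- baseline + shift           # n x 4, recycled by column

    mean_mat <- true_means[, cohorts, drop = FALSE]
    x <- mean_mat + matrix(rnorm(n * length(samples), 0, config$noise_sd),
                           nrow = n)
    colnames(x) <- samples

    p_miss <- missingness_probability(x, config)
    miss <- matrix(runif(length(x)) < p_miss, nrow = n)
    intensity <- ifelse(miss, 0, 2^x)

    single <- runif(n) < config$single_peptide_fraction
    peptides <- ifelse(single, 1L, 2L + stats::rpois(n, 6))

    pg <- tibble(
      protein_ids = sprintf("SIMP%05d", seq_len(n)),
      gene_name = sprintf("SIMG%05d", seq_len(n)),
      unique_peptides = as.integer(peptides),
      is_reverse = FALSE,
      is_contaminant = FALSE
    )
    for (k in seq_along(samples)) pg[[samples[k]]] <- intensity[, k]
    attr(pg, "samples") <- samples
    class(pg) <- c("protein_groups", class(pg))

    annotation <- tibble(sample = samples, cohort = cohorts,
                         batch = NA_character_)

    truth <- tibble(
      protein_ids = pg$protein_ids,
      gene_name = pg$gene_name,
      pattern = pattern,
      mean_CC = true_means[, "CC"],
      mean_EC = true_means[, "EC"],
      mean_EMT = true_means[, "EMT"],
      mean_END = true_means[, "END"]
    )
    attr(truth, "miss_prob") <- p_miss

    list(protein_groups = pg, annotation = annotation, truth = truth)
  })
}
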