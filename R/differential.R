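match_groups <- function(x, annotation, groups) {
  samples <- sample_names(x)
  missing_ann <- setdiff(samples, annotation$sample)
  if (length(missing_ann)) {
    abort(paste0("samples missing from annotation: ",
                 paste(missing_ann, collapse = ", ")),
          class = "progmarker_validation_error")
  }
  cohort <- annotation$cohort[match(samples, annotation$sample)]
  lapply(setNames(groups, groups), function(g) which(cohort == g))
}

#' Per-protein one-way ANOVA across cohorts
#'
#' Fixed-effects one-way F test per protein over the named cohorts, with
#' Benjamini-Hochberg adjustment across all proteins — the screen used to
#' enrich for proteins with the strongest between-cohort differences.
#' Proteins with identical values in all samples get `F = 0`, `p = 1`.
#'
#' @param x a complete `expr_matrix`.
#' @param annotation sample/cohort tibble.
#' @param groups cohorts to compare (default: all cohorts present); each
#'   needs at least 2 samples.
#' @param alpha BH significance level for the `significant` flag
#'   (default 0.01).
#' @return Tibble with per-protein group means, `f`, `p`, `q`, `significant`.
#' @export
anova_scan <- function(x, annotation, groups = NULL, alpha = 0.01) {
  if (!is_complete(x)) {
    abort("matrix has missing values; run impute_downshift() first",
          class = "progmarker_validation_error")
  }
  samples <- sample_names(x)
  cohort <- annotation$cohort[match(samples, annotation$sample)]
  groups <- groups %||% intersect(cohort_levels(), unique(cohort))
  idx <- match_groups(x, annotation, groups)
  sizes <- lengths(idx)
  if (length(groups) < 2) {
    abort("need at least 2 groups", class = "progmarker_validation_error")
  }
  if (any(sizes < 2)) {
    abort(paste0("groups with fewer than 2 samples: ",
                 paste(groups[sizes < 2], collapse = ", ")),
          class = "progmarker_validation_error")
  }
  v <- x$values[, unlist(idx), drop = FALSE]
  n <- ncol(v)
  k <- length(groups)
  gmeans <- vapply(idx, function(cols) rowMeans(x$values[, cols, drop = FALSE]),
                   numeric(nrow(v)))
  if (nrow(v) == 1) gmeans <- matrix(gmeans, nrow = 1, dimnames = list(NULL, groups))
  grand <- rowSums(sweep(gmeans, 2, sizes, `*`)) / n
  ssb <- rowSums(sweep((gmeans - grand)^2, 2, sizes, `*`))
  ssw <- numeric(nrow(v))
  for (g in seq_along(idx)) {
    block <- x$values[, idx[[g]], drop = FALSE]
    ssw <- ssw + rowSums((block - gmeans[, g])^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  degen <- ssw <= .Machine$double.eps * n & ssb <= .Machine$double.eps * n
  f[degen] <- 0
  p[degen] <- 1
  out <- tibble(
    protein_ids = x$proteins$protein_ids,
    gene_name = x$proteins$gene_name
  )
  for (g in groups) out[[paste0("mean_", g)]] <- unname(gmeans[, g])
  out$f <- unname(f)
  out$p <- unname(p)
  out$q <- p.adjust(p, method = "BH")
  out$significant <- out$q <= alpha
  out
}

#' Benjamini-Hochberg adjustment with rejection flags
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param level FDR level for the rejection flags (default 0.05).
#' @return Tibble with `p`, `q` (step-up adjusted) and `reject` (`q <= level`).
#' @export
bh_adjust <- function(p, level = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]", class = "progmarker_validation_error")
  }
  q <- p.adjust(p, method = "BH")
  tibble(p = p, q = q, reject = q <= level)
}

#' Fit the empirical-Bayes variance prior
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_sq`
#' of the scaled inverse-chi-square model for per-protein residual variances
#' (the moment estimator on log variances, with the trigamma equation solved
#' by Newton iteration). `d0 = Inf` is returned when the observed dispersion
#' of log variances does not exceed its sampling expectation.
#'
#' @param variances per-protein residual variances (at least 10 positive).
#' @param df residual degrees of freedom of each variance (scalar or vector).
#' @return Object of class `variance_prior`: list with `d0` and `s0_sq`.
#' @export
fit_variance_prior <- function(variances, df) {
  ok <- is.finite(variances) & variances > 0
  if (sum(ok) < 10) {
    abort("need at least 10 positive variances to fit the prior",
          class = "progmarker_validation_error")
  }
  fit <- limma::fitFDist(variances[ok], df1 = df)
  structure(list(d0 = fit$df2, s0_sq = fit$scale), class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("<variance_prior> d0 = %s, s0_sq = %.4g\n",
              format(x$d0), x$s0_sq))
  invisible(x)
}

#' Moderated two-group t statistics
#'
#' Empirical-Bayes moderated t test of `group` against `reference`: the
#' per-protein pooled variance is shrunk toward the prior,
#' `s2_tilde = (d0 * s0_sq + df * s2) / (d0 + df)`, and the statistic
#' `t = (mean_group - mean_reference) / (s_tilde * sqrt(1/n1 + 1/n2))` is
#' referred to a t distribution on `d0 + df` degrees of freedom. `d0 = 0`
#' reduces to the ordinary pooled t; `d0 = Inf` fixes the variance at
#' `s0_sq`.
#'
#' @param x a complete `expr_matrix`.
#' @param annotation sample/cohort tibble.
#' @param contrast length-2 character vector `c(group, reference)`.
#' @param prior a [fit_variance_prior()] result, or `NULL` to fit it from
#'   this contrast's pooled variances.
#' @return Tibble with per-protein means, `logfc`, variances, `se`, `t`,
#'   `df_total`, two-sided `p`, one-sided `p_elevated`
#'   (`P(T >= t)`, elevation in `group`), and BH `q` on the two-sided p.
#' @export
moderated_t <- function(x, annotation, contrast, prior = NULL) {
  stopifnot(length(contrast) == 2)
  if (!is_complete(x)) {
    abort("matrix has missing values; run impute_downshift() first",
          class = "progmarker_validation_error")
  }
  idx <- match_groups(x, annotation, contrast)
  n1 <- length(idx[[1]]); n2 <- length(idx[[2]])
  if (n1 < 2 || n2 < 2) {
    abort("both contrast groups need at least 2 samples",
          class = "progmarker_validation_error")
  }
  g1 <- x$values[, idx[[1]], drop = FALSE]
  g2 <- x$values[, idx[[2]], drop = FALSE]
  m1 <- unname(rowMeans(g1)); m2 <- unname(rowMeans(g2))
  df_resid <- n1 + n2 - 2
  s2 <- unname(rowSums((g1 - m1)^2) + rowSums((g2 - m2)^2)) / df_resid
  if (is.null(prior)) prior <- fit_variance_prior(s2, df_resid)
  mod <- moderate_variance(s2, df_resid, prior)
  se <- sqrt(mod$s2_tilde * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  tibble(
    protein_ids = x$proteins$protein_ids,
    gene_name = x$proteins$gene_name,
    mean_group = m1,
    mean_reference = m2,
    logfc = m1 - m2,
    s2 = s2,
    s2_moderated = mod$s2_tilde,
    se = se,
    t = tt,
    df_total = mod$df_total,
    p = 2 * pt(-abs(tt), df = mod$df_total),
    p_elevated = pt(tt, df = mod$df_total, lower.tail = FALSE),
    q = p.adjust(2 * pt(-abs(tt), df = mod$df_total), method = "BH")
  )
}

moderate_variance <- function(s2, df_resid, prior) {
  d0 <- prior$d0
  if (is.infinite(d0)) {
    list(s2_tilde = rep(prior$s0_sq, length(s2)), df_total = 1e6,
         effective_df = 1e6)
  } else if (d0 <= 0) {
    list(s2_tilde = s2, df_total = df_resid, effective_df = df_resid)
  } else {
    list(s2_tilde = (d0 * prior$s0_sq + df_resid * s2) / (d0 + df_resid),
         df_total = d0 + df_resid, effective_df = d0 + df_resid)
  }
}

#' S0-modified volcano significance
#'
#' The volcano-plot rule with fudge factor S0: the ordinary t statistic's
#' denominator is inflated by a constant, `t_s0 = logfc / (se + s0)`, which
#' de-prioritises proteins whose significance rests on a tiny fold change
#' with near-zero variance. P-values come from the t distribution on the
#' unmodified degrees of freedom; flags are BH at `fdr`. `s0 = 0` reduces to
#' plain BH on the ordinary t.
#'
#' @param logfc per-protein log2 fold changes.
#' @param se per-protein standard errors of `logfc`.
#' @param df t degrees of freedom (scalar or vector).
#' @param fdr BH level (default 0.05).
#' @param s0 fudge factor (default 1).
#' @return Tibble with `logfc`, `se`, `t_s0`, `p`, `q`, `significant`.
#' @export
s0_significance <- function(logfc, se, df, fdr = 0.05, s0 = 1) {
  stopifnot(length(logfc) == length(se), fdr > 0, fdr < 1, s0 >= 0)
  t_s0 <- logfc / (se + s0)
  p <- 2 * pt(-abs(t_s0), df = df)
  q <- p.adjust(p, method = "BH")
  tibble(logfc = logfc, se = se, t_s0 = t_s0, p = p, q = q,
         significant = q <= fdr)
}
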