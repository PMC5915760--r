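#' Estimate the true-null proportion by the right-boundary rule
#'
#' Histogram-based choice of the tail threshold for the classical tail
#' estimator `pi0(lambda) = #(p > lambda) / (m * (1 - lambda))`: the p-value
#' histogram is scanned left to right and the first bin whose height does not
#' exceed the tail estimate computed over everything to its right sets
#' `lambda*` at its right boundary. On an equal-width histogram that tail
#' estimate equals the mean height of the remaining bins, so the rule picks
#' the point where the histogram has flattened to its null plateau.
#'
#' @param p p-values in `[0, 1]`, at least 50 of them.
#' @param bins number of equal-width histogram bins (default 20, giving
#'   candidate boundaries 0.05, 0.10, ..., 0.95).
#' @return The estimate `pi0(lambda*)`, clipped to `[0, 1]`.
#' @export
estimate_pi0_right_boundary <- function(p, bins = 20) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]", class = "progmarker_validation_error")
  }
  m <- length(p)
  if (m < 50) {
    abort("need at least 50 p-values for a stable pi0 estimate",
          class = "progmarker_validation_error")
  }
  w <- 1 / bins
  edges <- seq(0, 1, by = w)
  counts <- tabulate(pmin(pmax(ceiling(p / w), 1L), bins), nbins = bins)
  heights <- counts / (m * w)
  # candidate boundaries exclude 1 (the tail estimator is undefined there)
  lambda_star <- edges[bins]               # fallback: last interior boundary
  for (j in seq_len(bins - 1)) {
    r <- edges[j + 1]
    tail_est <- sum(p > r) / (m * (1 - r))
    if (heights[j] <= tail_est) {
      lambda_star <- r
      break
    }
  }
  pi0 <- sum(p > lambda_star) / (m * (1 - lambda_star))
  min(max(pi0, 0), 1)
}

#' Fit the two-group model and local false discovery rate
#'
#' Converts one-sided p-values to z-scores `z = qnorm(1 - p)`, estimates the
#' marginal density f by a Gaussian-kernel smoother with Silverman's
#' bandwidth, and computes the local false discovery rate
#' `lfdr(z) = pi0 * f0(z) / f(z)` (clipped to `[0, 1]`), with the null
#' density f0 either the theoretical standard normal or a normal fitted to
#' the central half of the z sample (median and IQR/1.349). The posterior
#' probability of elevation is `1 - lfdr` for `z > 0` and 0 otherwise.
#'
#' @param p_one_sided one-sided p-values; values of exactly 0 or 1 are
#'   clamped to `1/(m+1)` / `m/(m+1)` with a warning.
#' @param pi0 true-null proportion, e.g. from
#'   [estimate_pi0_right_boundary()].
#' @param null `"theoretical"` (standard normal; default) or `"empirical"`.
#' @return Object of class `two_group_fit`: per-protein tibble (`z`, `lfdr`,
#'   `posterior_elevated`) plus `pi0`, the density grid, and the fitted null
#'   parameters. `tidy()` returns the per-protein table.
#' @export
fit_two_group <- function(p_one_sided, pi0,
                          null = c("theoretical", "empirical")) {
  null <- match.arg(null)
  stopifnot(pi0 >= 0, pi0 <= 1)
  p <- p_one_sided
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]", class = "progmarker_validation_error")
  }
  m <- length(p)
  if (any(p == 0 | p == 1)) {
    warn("p-values of exactly 0 or 1 clamped to (0, 1)")
    p <- pmin(pmax(p, 1 / (m + 1)), m / (m + 1))
  }
  z <- unname(qnorm(1 - p))
  dens <- density(z, bw = "nrd0", n = 1024)
  f_hat <- approx(dens$x, dens$y, xout = z, rule = 2)$y
  f_hat <- pmax(f_hat, .Machine$double.eps)
  if (null == "theoretical") {
    mu0 <- 0; sd0 <- 1
  } else {
    mu0 <- median(z)
    sd0 <- (quantile(z, 0.75) - quantile(z, 0.25)) / 1.349
    sd0 <- unname(max(sd0, .Machine$double.eps))
  }
  f0 <- dnorm(z, mu0, sd0)
  lfdr <- pmin(pmax(pi0 * f0 / f_hat, 0), 1)
  posterior <- ifelse(z > 0, 1 - lfdr, 0)
  structure(
    list(
      table = tibble(z = z, lfdr = lfdr, posterior_elevated = posterior),
      pi0 = pi0,
      null = null,
      null_mean = mu0,
      null_sd = sd0,
      grid = tibble(z = dens$x, f_hat = dens$y,
                    f0 = dnorm(dens$x, mu0, sd0)),
      bandwidth = dens$bw
    ),
    class = "two_group_fit"
  )
}

#' @export
print.two_group_fit <- function(x, ...) {
  cat(sprintf(
    "<two_group_fit> m = %d, pi0 = %.3f, %s null; %d proteins with posterior >= 0.9\n",
    nrow(x$table), x$pi0, x$null, sum(x$table$posterior_elevated >= 0.9)))
  invisible(x)
}

#' @export
tidy.two_group_fit <- function(x, ...) x$table

#' @export
glance.two_group_fit <- function(x, ...) {
  tibble(
    m = nrow(x$table),
    pi0 = x$pi0,
    null = x$null,
    null_mean = x$null_mean,
    null_sd = x$null_sd,
    bandwidth = x$bandwidth
  )
}

#' Conservative normal model of a control cohort
#'
#' Models each protein's level in a control cohort as normal, with the mean
#' estimated by the sample mean and the variance inflated to the upper bound
#' of its chi-square confidence interval,
#' `(n - 1) * s2 / qchisq(gamma, n - 1)` — a deliberately pessimistic scale
#' so that apparent elevation over the control is not driven by an
#' underestimated control variance.
#'
#' @param x a complete `expr_matrix`.
#' @param annotation sample/cohort tibble.
#' @param control_group cohort to model (needs at least 2 samples).
#' @param gamma lower chi-square tail level (default 0.25); smaller gamma is
#'   more conservative.
#' @return Tibble with `protein_ids`, `n`, `mean`, `var_sample`,
#'   `var_conservative`, `degenerate` (TRUE where the sample variance is 0).
#' @export
conservative_control_fit <- function(x, annotation, control_group,
                                     gamma = 0.25) {
  stopifnot(gamma > 0, gamma < 1)
  idx <- match_groups(x, annotation, control_group)[[1]]
  n <- length(idx)
  if (n < 2) {
    abort("control group needs at least 2 samples",
          class = "progmarker_validation_error")
  }
  v <- x$values[, idx, drop = FALSE]
  mu <- unname(rowMeans(v))
  s2 <- unname(rowSums((v - mu)^2)) / (n - 1)
  infl <- (n - 1) / qchisq(gamma, df = n - 1)
  tibble(
    protein_ids = x$proteins$protein_ids,
    n = n,
    mean = mu,
    var_sample = s2,
    var_conservative = s2 * infl,
    degenerate = s2 == 0
  )
}

#' Posterior probabilities of elevation for both disease transitions
#'
#' The marker engine: for each adjacent transition of the ordered cohorts
#' (END to EMT, EMT to carcinoma) it runs a one-sided moderated test of
#' elevation in the later group in which the control (earlier) group's
#' variance contribution is conservatively inflated, estimates the true-null
#' proportion of the resulting one-sided p-values by the right-boundary rule,
#' fits the two-group model, and returns the per-protein posterior
#' probability of elevation.
#'
#' The conservative chi-square upper-bound inflation is applied to the
#' moderated variance at its effective degrees of freedom (`d0 + df`), i.e.
#' the inflation factor is `nu / qchisq(gamma, nu)` with `nu = d0 + df`:
#' the bound is placed on the variance estimate the test actually uses, and
#' vanishes as the prior becomes certain.
#'
#' @param x a complete `expr_matrix`.
#' @param annotation sample/cohort tibble.
#' @param ordered_groups length-3 character vector, earliest first, e.g.
#'   `c("END", "EMT", "CC")`.
#' @param prior a [fit_variance_prior()] result, or `NULL` to fit one from
#'   the residual variances of the three ordered cohorts.
#' @param gamma conservative tail level passed to the variance inflation
#'   (default 0.25).
#' @param null null-density mode for [fit_two_group()].
#' @return Object of class `transition_posteriors`: tibble with per-protein
#'   `posterior_1` (first transition), `posterior_2` (second), the underlying
#'   z-scores, plus the two `two_group_fit`s in attributes `fit_1`, `fit_2`.
#' @export
transition_posteriors <- function(x, annotation,
                                  ordered_groups = c("END", "EMT", "CC"),
                                  prior = NULL, gamma = 0.25,
                                  null = c("theoretical", "empirical")) {
  null <- match.arg(null)
  stopifnot(length(ordered_groups) == 3)
  if (!is_complete(x)) {
    abort("matrix has missing values; run impute_downshift() first",
          class = "progmarker_validation_error")
  }
  idx <- match_groups(x, annotation, ordered_groups)
  sizes <- lengths(idx)
  if (any(sizes < 2)) {
    abort(paste0("cohorts with fewer than 2 samples: ",
                 paste(ordered_groups[sizes < 2], collapse = ", ")),
          class = "progmarker_validation_error")
  }
  if (is.null(prior)) {
    # residual variance pooled across the three ordered cohorts
    df_resid <- sum(sizes) - 3
    ssw <- numeric(nrow(x$values))
    for (g in seq_along(idx)) {
      block <- x$values[, idx[[g]], drop = FALSE]
      ssw <- ssw + rowSums((block - rowMeans(block))^2)
    }
    prior <- fit_variance_prior(ssw / df_resid, df_resid)
  }

  one_transition <- function(ctrl, case) {
    n1 <- length(ctrl); n2 <- length(case)
    g1 <- x$values[, ctrl, drop = FALSE]
    g2 <- x$values[, case, drop = FALSE]
    m1 <- unname(rowMeans(g1)); m2 <- unname(rowMeans(g2))
    df_resid <- n1 + n2 - 2
    s2 <- unname(rowSums((g1 - m1)^2) + rowSums((g2 - m2)^2)) / df_resid
    mod <- moderate_variance(s2, df_resid, prior)
    nu <- mod$effective_df
    infl <- nu / qchisq(gamma, df = nu)
    se <- sqrt(mod$s2_tilde * (infl / n1 + 1 / n2))
    tt <- (m2 - m1) / se
    p_one <- pt(tt, df = mod$df_total, lower.tail = FALSE)
    pi0 <- estimate_pi0_right_boundary(p_one)
    fit <- fit_two_group(p_one, pi0, null = null)
    list(fit = fit, p = p_one, delta = m2 - m1)
  }

  t1 <- one_transition(idx[[1]], idx[[2]])
  t2 <- one_transition(idx[[2]], idx[[3]])
  out <- tibble(
    protein_ids = x$proteins$protein_ids,
    gene_name = x$proteins$gene_name,
    delta_1 = t1$delta,
    z_1 = t1$fit$table$z,
    posterior_1 = t1$fit$table$posterior_elevated,
    delta_2 = t2$delta,
    z_2 = t2$fit$table$z,
    posterior_2 = t2$fit$table$posterior_elevated
  )
  attr(out, "fit_1") <- t1$fit
  attr(out, "fit_2") <- t2$fit
  attr(out, "ordered_groups") <- ordered_groups
  attr(out, "prior") <- prior
  class(out) <- c("transition_posteriors", class(out))
  out
}

#' Classify proteins into progressive disease patterns
#'
#' Applies the progressive-expression criteria at posterior threshold `tau`:
#' pattern A — elevated at both transitions (progressive increase from END
#' through EMT to carcinoma); pattern B — elevated only from END to EMT;
#' pattern C — elevated only from EMT to carcinoma. The disease-marker set is
#' the union of the three patterns.
#'
#' @param posteriors a [transition_posteriors()] tibble, or `NULL` if
#'   `posterior_1`/`posterior_2` are given directly.
#' @param posterior_1,posterior_2 numeric vectors of posteriors, used when
#'   `posteriors` is `NULL`.
#' @param tau posterior threshold in (0, 1) (default 0.9).
#' @return Tibble with per-protein `posterior_1`, `posterior_2`, `pattern`
#'   (`"A"`, `"B"`, `"C"` or `"none"`) and `is_marker`.
#' @export
classify_patterns <- function(posteriors = NULL, posterior_1 = NULL,
                              posterior_2 = NULL, tau = 0.9) {
  stopifnot(tau > 0, tau < 1)
  if (!is.null(posteriors)) {
    ids <- posteriors$protein_ids
    genes <- posteriors$gene_name
    posterior_1 <- posteriors$posterior_1
    posterior_2 <- posteriors$posterior_2
  } else {
    ids <- NULL; genes <- NULL
  }
  if (length(posterior_1) != length(posterior_2)) {
    abort("posterior vectors must have equal length",
          class = "progmarker_validation_error")
  }
  up1 <- posterior_1 >= tau
  up2 <- posterior_2 >= tau
  pattern <- dplyr::case_when(
    up1 & up2 ~ "A",
    up1 & !up2 ~ "B",
    !up1 & up2 ~ "C",
    TRUE ~ "none"
  )
  out <- tibble(
    posterior_1 = posterior_1,
    posterior_2 = posterior_2,
    pattern = pattern,
    is_marker = pattern != "none"
  )
  if (!is.null(ids)) {
    out <- bind_cols_safe(tibble(protein_ids = ids, gene_name = genes), out)
  }
  attr(out, "tau") <- tau
  class(out) <- c("marker_call", class(out))
  out
}

#' @export
print.marker_call <- function(x, ...) {
  tab <- table(factor(x$pattern, levels = c("A", "B", "C", "none")))
  cat(sprintf(
    "<marker_call> %d proteins at tau = %.2f: A=%d B=%d C=%d none=%d (%d markers)\n",
    nrow(x), attr(x, "tau") %||% NA, tab["A"], tab["B"], tab["C"],
    tab["none"], sum(x$is_marker)))
  invisible(x)
}
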