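ann3 <- make_annotation(c(CC = 3, EMT = 3, END = 3))

test_that("one-way F matches brute-force sums of squares and aov", {
  v <- rbind(
    c(1, 2, 3, 2, 3, 4, 10, 11, 12),
    c(5, 5, 5, 5, 5, 5, 5, 5, 5)
  )
  colnames(v) <- ann3$sample
  em <- make_em(v)
  res <- anova_scan(em, ann3, groups = c("CC", "EMT", "END"))

  # brute-force SS decomposition for the toy row
  y <- v[1, ]; g <- ann3$cohort
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(y, g, function(x) sum((x - mean(x))^2)))
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$f[1], f_hand, tolerance = 1e-10)
  expect_equal(res$p[1], pf(f_hand, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # cross-check against the stock linear-model ANOVA
  a <- anova(lm(y ~ factor(g)))
  expect_equal(res$f[1], a$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p[1], a$`Pr(>F)`[1], tolerance = 1e-10)

  # constant protein: degenerate convention
  expect_equal(res$f[2], 0)
  expect_equal(res$p[2], 1)
})

test_that("two-group F equals the square of the pooled t", {
  set.seed(33)
  ann2 <- make_annotation(c(CC = 4, EMT = 5))
  for (rep_i in 1:5) {
    v <- matrix(rnorm(20 * 9, 20), 20, 9, dimnames = list(NULL, ann2$sample))
    em <- make_em(v)
    res <- anova_scan(em, ann2, groups = c("CC", "EMT"))
    tt <- apply(v, 1, function(y) {
      t.test(y[1:4], y[5:9], var.equal = TRUE)$statistic
    })
    expect_equal(res$f, unname(tt^2), tolerance = 1e-10)
  }
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  bh_brute <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m); out[o] <- q; out
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04))$q, rep(0.04, 4))
  expect_equal(bh_adjust(0.37)$q, 0.37)
  all1 <- bh_adjust(rep(1, 5), level = 0.05)
  expect_true(all(all1$q == 1) && !any(all1$reject))
  set.seed(41)
  for (rep_i in 1:50) {
    p <- runif(sample(1:10, 1))
    expect_equal(bh_adjust(p)$q, bh_brute(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "progmarker_validation_error")
})

test_that("variance prior handles degenerate and minimal inputs", {
  expect_equal(fit_variance_prior(rep(0.25, 50), df = 4)$d0, Inf)
  tiny <- fit_variance_prior(c(0.1, 0.2, 0.15, 0.3, 0.25, 0.12, 0.18,
                               0.22, 0.28, 0.16), df = 4)
  expect_true(is.infinite(tiny$d0) || tiny$d0 > 0)
  expect_gt(tiny$s0_sq, 0)
  expect_error(fit_variance_prior(rep(0.2, 9), df = 4),
               class = "progmarker_validation_error")
})

test_that("moderated t reduces to the pooled t at d0 = 0 and to the prior at
           d0 = Inf, and matches the hand formula", {
  ann2 <- make_annotation(c(CC = 3, EMT = 3))
  v <- matrix(c(1, 2, 3, 3, 4, 5), 1, 6, dimnames = list(NULL, ann2$sample))
  em <- make_em(v)

  prior0 <- structure(list(d0 = 0, s0_sq = 1), class = "variance_prior")
  t0 <- moderated_t(em, ann2, c("CC", "EMT"), prior = prior0)
  plain <- t.test(v[1, 1:3], v[1, 4:6], var.equal = TRUE)
  expect_equal(t0$t[1], unname(plain$statistic), tolerance = 1e-12)
  expect_equal(t0$p[1], plain$p.value, tolerance = 1e-12)

  priorI <- structure(list(d0 = Inf, s0_sq = 0.123), class = "variance_prior")
  tI <- moderated_t(em, ann2, c("CC", "EMT"), prior = priorI)
  expect_equal(tI$s2_moderated[1], 0.123)

  # hand evaluation at d0 = 2, s0_sq = 1: s2 = 1, s2_tilde = (2 + 4)/6 = 1
  prior2 <- structure(list(d0 = 2, s0_sq = 1), class = "variance_prior")
  t2 <- moderated_t(em, ann2, c("CC", "EMT"), prior = prior2)
  expect_equal(t2$logfc[1], -2)
  expect_equal(t2$t[1], -2 / sqrt(1 * (1 / 3 + 1 / 3)), tolerance = 1e-12)
  expect_equal(t2$df_total[1], 6)
  expect_equal(t2$p_elevated[1], pt(t2$t[1], 6, lower.tail = FALSE))
})

test_that("moderated t agrees with limma's empirical-Bayes pipeline", {
  set.seed(55)
  ann2 <- make_annotation(c(CC = 4, EMT = 4))
  v <- matrix(rnorm(200 * 8, 20, 1), 200, 8, dimnames = list(NULL, ann2$sample))
  v[1:10, 1:4] <- v[1:10, 1:4] + 2
  em <- make_em(v)
  design <- cbind(intercept = 1, cc = rep(c(1, 0), each = 4))
  lfit <- limma::eBayes(limma::lmFit(v, design))
  prior <- structure(list(d0 = lfit$df.prior, s0_sq = lfit$s2.prior),
                     class = "variance_prior")
  mine <- moderated_t(em, ann2, c("CC", "EMT"), prior = prior)
  expect_equal(mine$t, lfit$t[, "cc"], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(mine$p, lfit$p.value[, "cc"], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("moderated-t p-values are uniform under a correctly specified null", {
  set.seed(66)
  ann2 <- make_annotation(c(CC = 4, EMT = 4))
  m <- 10000; d0 <- 4; s0 <- 0.25
  sigma2 <- s0 * d0 / rchisq(m, d0)
  v <- matrix(rnorm(m * 8, 20, rep(sqrt(sigma2), 8)), m, 8,
              dimnames = list(NULL, ann2$sample))
  em <- make_em(v)
  prior <- structure(list(d0 = d0, s0_sq = s0), class = "variance_prior")
  res <- moderated_t(em, ann2, c("CC", "EMT"), prior = prior)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("S0 significance reduces to plain BH at s0 = 0 and dies at s0 large", {
  set.seed(77)
  logfc <- c(rnorm(95, 0, 0.3), rnorm(5, 10, 0.3))
  se <- runif(100, 0.2, 0.5)
  df <- 20
  plain <- s0_significance(logfc, se, df, s0 = 0)
  t_ref <- logfc / se
  ref <- bh_adjust(2 * pt(-abs(t_ref), df), level = 0.05)
  expect_equal(plain$significant, ref$reject)
  expect_equal(plain$q, ref$q, tolerance = 1e-12)

  none <- s0_significance(logfc, se, df, s0 = 1e6)
  expect_false(any(none$significant))

  # brute-force recomputation of the s0-modified rule
  s1 <- s0_significance(logfc, se, df, fdr = 0.05, s0 = 1)
  t_s0 <- logfc / (se + 1)
  p_b <- 2 * pt(-abs(t_s0), df)
  q_b <- p.adjust(p_b, "BH")
  expect_equal(s1$significant, q_b <= 0.05)
  expect_true(all(s1$significant == (s1$q <= 0.05)))
  expect_gte(sum(s1$significant), 5)
})
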