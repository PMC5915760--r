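test_that("right-boundary pi0 estimator handles canonical inputs", {
  m <- 1000
  p_uniform <- (seq_len(m) - 0.5) / m
  pi0_u <- estimate_pi0_right_boundary(p_uniform)
  expect_gte(pi0_u, 0.95)
  expect_lte(pi0_u, 1)

  p_all_small <- runif(1000, 0, 0.001)
  expect_equal(estimate_pi0_right_boundary(p_all_small), 0)

  expect_error(estimate_pi0_right_boundary(runif(49)),
               class = "progmarker_validation_error")
  expect_error(estimate_pi0_right_boundary(c(runif(60), 1.5)),
               class = "progmarker_validation_error")
})

test_that("pi0 estimate responds monotonically to added signal", {
  set.seed(101)
  pi0_null <- replicate(20, estimate_pi0_right_boundary(runif(500)))
  pi0_sig <- replicate(20, estimate_pi0_right_boundary(
    c(runif(400), rbeta(100, 0.1, 10))))
  expect_gte(mean(pi0_null), 0.9)
  expect_lt(mean(pi0_sig), mean(pi0_null))
})

test_that("two-group fit: degenerate pi0 limits and spiked alternatives", {
  set.seed(102)
  p <- runif(500)
  fit0 <- fit_two_group(p, pi0 = 0)
  expect_true(all(fit0$table$lfdr == 0))
  expect_true(all(fit0$table$posterior_elevated[fit0$table$z > 0] == 1))
  expect_true(all(fit0$table$posterior_elevated[fit0$table$z <= 0] == 0))

  # pure null at pi0 = 1: elevation posteriors stay low
  z_null <- rnorm(10000)
  fit1 <- fit_two_group(pnorm(z_null, lower.tail = FALSE), pi0 = 1)
  expect_lte(median(fit1$table$posterior_elevated), 0.1)

  # single strong spike among nulls is called with near certainty
  p_spike <- c(pnorm(6, lower.tail = FALSE), runif(2000))
  fit_s <- fit_two_group(p_spike, pi0 = 0.95)
  expect_gte(fit_s$table$posterior_elevated[1], 0.99)

  expect_warning(fit_two_group(c(0, runif(100)), pi0 = 0.9), "clamped")
})

test_that("empirical null recentres the null density on the z sample", {
  set.seed(103)
  z <- rnorm(5000, mean = -0.5, sd = 0.8)   # deflated, shifted null
  fit <- fit_two_group(pnorm(z, lower.tail = FALSE), pi0 = 1,
                       null = "empirical")
  expect_equal(fit$null_mean, -0.5, tolerance = 0.1)
  expect_equal(fit$null_sd, 0.8, tolerance = 0.1)
  expect_lte(median(fit$table$posterior_elevated), 0.2)
})

test_that("conservative control variance equals the chi-square upper bound", {
  ann <- make_annotation(c(END = 3, EMT = 2))
  v <- matrix(c(0, 1, 2, 7, 7), 1, 5, dimnames = list(NULL, ann$sample))
  em <- make_em(v)
  fitc <- conservative_control_fit(em, ann, "END", gamma = 0.25)
  expect_equal(fitc$var_sample[1], 1)        # s2 of {0,1,2}
  expect_equal(fitc$var_conservative[1], 2 / qchisq(0.25, 2),
               tolerance = 1e-12)            # = 3.476052 from the quantile
  expect_gte(fitc$var_conservative[1], fitc$var_sample[1])

  # constant control values: degenerate, variance 0
  fitd <- conservative_control_fit(em, ann, "EMT", gamma = 0.25)
  expect_true(fitd$degenerate[1])
  expect_equal(fitd$var_conservative[1], 0)

  # gamma -> 0.5 with large n: inflation factor -> 1
  ann_big <- make_annotation(c(END = 100))
  set.seed(104)
  v_big <- matrix(rnorm(100), 1, 100, dimnames = list(NULL, ann_big$sample))
  fitb <- conservative_control_fit(make_em(v_big), ann_big, "END",
                                   gamma = 0.4999)
  expect_equal(fitb$var_conservative[1] / fitb$var_sample[1], 1,
               tolerance = 0.02)

  expect_error(conservative_control_fit(em, make_annotation(c(END = 1, EMT = 4)),
                                        "END"),
               class = "progmarker_validation_error")
})

sim_marker_run <- function(seed, fractions, effect = 2, n = 1500,
                           gamma = 0.25, prior = NULL) {
  cfg <- sim_config(n_proteins = n, cohort_sizes = c(CC = 6, EC = 0, EMT = 3,
                                                     END = 5),
                    pattern_fractions = fractions, effect_size = effect,
                    noise_sd = 0.7, mnar_alpha = -Inf, mnar_beta = 0,
                    n_housekeeping = 0, single_peptide_fraction = 0,
                    seed = seed)
  sim <- generate_lfq_dataset(cfg)
  em <- to_log2(sim$protein_groups)
  post <- transition_posteriors(em, sim$annotation, c("END", "EMT", "CC"),
                                gamma = gamma, prior = prior)
  list(sim = sim, post = post)
}

test_that("transition posteriors stay low on effect-free data", {
  run <- sim_marker_run(105, c(A = 0, B = 0, C = 0))
  expect_lte(mean(run$post$posterior_1 >= 0.9), 0.10)
  expect_lte(mean(run$post$posterior_2 >= 0.9), 0.10)
})

test_that("elevated posteriors concentrate on the perturbed transition", {
  # pattern B only: signal in END->EMT, none in EMT->cancer
  run <- sim_marker_run(106, c(A = 0, B = 0.05, C = 0))
  b_rows <- run$sim$truth$pattern == "B"
  expect_gt(median(run$post$posterior_1[b_rows]), 0.8)
  expect_lte(mean(run$post$posterior_2 >= 0.9), 0.05)

  # pattern C only: signal confined to EMT->cancer
  run2 <- sim_marker_run(107, c(A = 0, B = 0, C = 0.05))
  c_rows <- run2$sim$truth$pattern == "C"
  expect_gt(median(run2$post$posterior_2[c_rows]), 0.8)
  expect_lte(mean(run2$post$posterior_1 >= 0.9), 0.05)
})

test_that("marker recovery is sensitive and specific at strong effects", {
  run <- sim_marker_run(108, c(A = 0.02, B = 0.02, C = 0.02), effect = 3,
                        n = 2000)
  calls <- classify_patterns(run$post, tau = 0.9)
  truth <- run$sim$truth$pattern %in% c("A", "B", "C")
  expect_gte(mean(calls$is_marker[truth]), 0.85)
  expect_lte(mean(!truth[calls$is_marker]), 0.15)
})

test_that("conservative inflation suppresses null false positives", {
  # small prior df makes the inflation factor substantial; compare the
  # right-tail mass of null z-scores with and without meaningful inflation
  prior <- structure(list(d0 = 4, s0_sq = 0.49), class = "variance_prior")
  run_tight <- sim_marker_run(109, c(A = 0, B = 0, C = 0), gamma = 0.25,
                              prior = prior)
  run_loose <- sim_marker_run(109, c(A = 0, B = 0, C = 0), gamma = 0.4999,
                              prior = prior)
  expect_lt(sum(run_tight$post$z_1 > 1.64), sum(run_loose$post$z_1 > 1.64))
  expect_lt(sum(run_tight$post$z_2 > 1.64), sum(run_loose$post$z_2 > 1.64))
})

test_that("pattern classification applies the A/B/C rules", {
  calls <- classify_patterns(posterior_1 = c(0.95, 0.95, 0.10, 0.10, 0.90),
                             posterior_2 = c(0.95, 0.10, 0.95, 0.10, 0.89),
                             tau = 0.9)
  expect_equal(calls$pattern, c("A", "B", "C", "none", "B"))
  expect_equal(calls$is_marker, c(TRUE, TRUE, TRUE, FALSE, TRUE))

  empty <- classify_patterns(posterior_1 = rep(0, 5), posterior_2 = rep(0, 5))
  expect_false(any(empty$is_marker))
  expect_error(classify_patterns(posterior_1 = 1:3 / 10,
                                 posterior_2 = 1:4 / 10),
               class = "progmarker_validation_error")
})

test_that("lfdr decreases with z on the right tail of a spiked fit", {
  set.seed(110)
  p <- c(pnorm(rnorm(200, 4), lower.tail = FALSE), runif(4000))
  fit <- fit_two_group(p, pi0 = 0.95)
  tbl <- fit$table[order(fit$table$z), ]
  right <- tbl[tbl$z > 2 & tbl$z < 5, ]
  expect_lt(cor(right$z, right$lfdr, method = "spearman"), -0.8)
})
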