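test_that("per-probe OLS equals the textbook one-probe-at-a-time fit", {
  set.seed(22)
  n <- 16
  M <- matrix(rnorm(200 * n), 200, n, dimnames = list(paste0("p", 1:200),
                                                      NULL))
  grp <- rep(c(1, 0), each = n / 2)
  covar <- rnorm(n)
  design <- cbind(intercept = 1, group = grp, covar = covar)
  fit <- fit_probe_models(M, design)
  for (i in c(1, 57, 200)) {
    lm_i <- lm(M[i, ] ~ grp + covar)
    expect_equal(fit$coef[i], unname(coef(lm_i)["grp"]), tolerance = 1e-10)
    expect_equal(fit$s2[i], summary(lm_i)$sigma^2, tolerance = 1e-10)
  }
  expect_identical(fit$df, as.integer(n) - 3L)

  # two groups, no covariates: coef is the difference of group means
  d2 <- cbind(intercept = 1, group = grp)
  f2 <- fit_probe_models(M, d2)
  expect_equal(f2$coef,
               unname(rowMeans(M[, grp == 1]) - rowMeans(M[, grp == 0])),
               tolerance = 1e-12)

  # a covariate orthogonal to group leaves the group effect unchanged
  orth <- rep(c(-1, 1), n / 2)  # balanced within both groups
  f3 <- fit_probe_models(M, cbind(intercept = 1, group = grp, orth = orth))
  expect_equal(f3$coef, f2$coef, tolerance = 1e-10)

  expect_error(fit_probe_models(M, cbind(intercept = 1, group = grp,
                                         dup = grp)),
               "collinear.*dup")
})

test_that("variance moderation matches the empirical-Bayes oracle", {
  set.seed(23)
  sds <- sqrt(1 / rgamma(2000, shape = 2, rate = 2))
  M <- matrix(rnorm(2000 * 12), 2000, 12) * sds
  rownames(M) <- paste0("p", 1:2000)
  design <- cbind(intercept = 1, group = rep(c(1, 0), each = 6))
  fit <- fit_probe_models(M, design)
  mod <- moderate_variances(fit)
  le <- limma::eBayes(limma::lmFit(M, design))
  expect_equal(mod$prior$d0, unname(le$df.prior), tolerance = 1e-6)
  expect_equal(mod$prior$s0_sq, unname(le$s2.prior), tolerance = 1e-6)
  expect_equal(mod$t_mod, unname(le$t[, "group"]), tolerance = 1e-8)
  expect_equal(mod$p, unname(le$p.value[, "group"]), tolerance = 1e-8)

  # shrinkage direction: small variances shrink t towards the ordinary t
  ord_t <- fit$coef / (fit$stdev_unscaled * sqrt(fit$s2))
  lo <- fit$s2 < mod$prior$s0_sq
  expect_true(all(abs(mod$t_mod[lo]) <= abs(ord_t[lo]) + 1e-12))
  expect_true(all(abs(mod$t_mod[!lo]) >= abs(ord_t[!lo]) - 1e-12))
})

test_that("identical residual variances reproduce the ordinary t", {
  set.seed(24)
  n <- 10
  base <- rnorm(n)
  M <- outer(rnorm(50), rep(1, n)) + outer(rep(1, 50), base)
  rownames(M) <- paste0("p", 1:50)
  design <- cbind(intercept = 1, group = rep(c(1, 0), each = 5))
  fit <- fit_probe_models(M, design)
  expect_lt(diff(range(fit$s2)), 1e-10)
  mod <- moderate_variances(fit)
  expect_identical(mod$prior$d0, Inf)
  ord_t <- fit$coef / (fit$stdev_unscaled * sqrt(fit$s2))
  expect_equal(mod$t_mod, ord_t, tolerance = 1e-10)
})

test_that("moderated p-values are calibrated under the null", {
  set.seed(25)
  M <- matrix(rnorm(5000 * 20), 5000, 20)
  rownames(M) <- paste0("p", 1:5000)
  design <- cbind(intercept = 1, group = rep(c(1, 0), each = 10))
  mod <- moderate_variances(fit_probe_models(M, design))
  frac <- mean(mod$p < 0.05)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.7), 0.7)
  set.seed(26)
  p <- runif(20)
  expect_equal(adjust_bh(p), bh_oracle(p))
  p2 <- c(runif(15), rep(0.2, 5))  # ties
  expect_equal(adjust_bh(p2), bh_oracle(p2))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("signature selection applies both thresholds strictly", {
  res <- data.frame(probe_id = c("a", "b", "c", "d"),
                    delta_beta = c(0.15, 0.05, -0.2, 0.12),
                    q = c(0.001, 1e-9, 0.005, 0.01))
  expect_identical(select_signature_probes(res), c("c", "a"))
  expect_identical(select_signature_probes(res[0, ]), character(0))
})

test_that("the planted epi-signature is recovered with high sensitivity", {
  man <- tiny_manifest()
  ref <- make_cell_reference(probes_per_type = 50,
                             probe_ids = man$probe_id[!man$is_sex_chrom][1:300],
                             seed = 2)
  des <- cohort_design(n_signal_probes = 300, delta_beta = 0.15,
                       cell_reference = ref, seed = 7)
  ds <- simulate_cohort(man, des)
  fp <- filter_probes(ds)
  props <- estimate_cell_proportions(ds$beta, ref)
  res <- run_differential(fp$dataset, cell_props = props)
  sel <- select_signature_probes(res)
  truth <- intersect(ds$truth$signal_probes, fp$dataset$manifest$probe_id)
  expect_gte(mean(truth %in% sel), 0.8)
  expect_lte(mean(!(sel %in% truth)), 0.05)
})

test_that("cell-proportion covariates absorb composition confounding", {
  man <- tiny_manifest()
  ref <- make_cell_reference(probes_per_type = 50,
                             probe_ids = man$probe_id[!man$is_sex_chrom][1:300],
                             seed = 2)
  des <- cohort_design(n_signal_probes = 0, delta_beta = 0.15,
                       cell_reference = ref,
                       case_cell_alpha = c(40, 4, 4, 4, 4, 4),
                       control_cell_alpha = rep(10, 6), seed = 19)
  ds <- simulate_cohort(man, des)
  fp <- filter_probes(ds)
  props <- estimate_cell_proportions(ds$beta, ref)
  with_cov <- select_signature_probes(run_differential(fp$dataset,
                                                       cell_props = props))
  without <- select_signature_probes(run_differential(fp$dataset))
  expect_lte(length(with_cov), 5)
  expect_gte(length(without), 10 * max(length(with_cov), 1))
})
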