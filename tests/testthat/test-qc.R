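test_that("beta computation follows the intensity-ratio definition", {
  expect_equal(compute_beta(600, 400, 0), 0.6)
  expect_equal(suppressWarnings(compute_beta(0, 0, 100)), 0)
  expect_equal(compute_beta(300, 100, 100), 0.6)
  expect_warning(compute_beta(0, 0, 0), "zero total")
  expect_error(compute_beta(-1, 5), "non-negative")
})

test_that("M-value transform is the clipped logit and invertible", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  b <- seq(0.01, 0.99, by = 0.007)
  expect_lt(max(abs(m_to_beta(beta_to_m(b)) - b)), 1e-12)
  expect_equal(beta_to_m(1 - b), -beta_to_m(b))
})

test_that("probe filtering removes each flag class once, idempotently", {
  man <- as_probe_manifest(data.frame(
    probe_id = sprintf("p%02d", 1:10),
    chrom = c(rep("chr1", 7), "chrX", "chrX", "chr2"),
    pos = c(1:7 * 100, 100, 200, 100)))
  man$flag_snp[1] <- TRUE
  man$flag_cross_reactive[2] <- TRUE
  n <- 4
  beta <- matrix(0.5, 10, n, dimnames = list(man$probe_id, NULL))
  det <- matrix(0.001, 10, n)
  det[3, 2] <- 0.5  # detection failure
  samples <- data.frame(sample_id = paste0("s", 1:n), age = 10,
                        sex = "female", batch = "b", cohort = "control")
  ds <- methylation_dataset(man, beta = beta, detection_p = det,
                            samples = samples)
  fp <- filter_probes(ds)
  expect_identical(nrow(fp$dataset$manifest), 5L)
  expect_setequal(fp$report$reason[!fp$report$pass],
                  c("snp", "cross_reactive", "detection", "sex_chromosome"))
  expect_identical(sum(fp$report$reason == "sex_chromosome"), 2L)
  # idempotence
  fp2 <- filter_probes(fp$dataset)
  expect_identical(fp2$dataset$manifest, fp$dataset$manifest)
  # nothing to remove -> identity
  ds_clean <- methylation_dataset(man[man$chrom == "chr1" &
                                        !man$flag_snp &
                                        !man$flag_cross_reactive, ],
                                  beta = beta[3:7, ],
                                  detection_p = matrix(0.001, 5, n),
                                  samples = samples)
  expect_identical(nrow(filter_probes(ds_clean)$dataset$manifest), 5L)
})

test_that("sample QC applies the strict 5% failed-probe rule", {
  man <- as_probe_manifest(data.frame(probe_id = sprintf("p%03d", 1:100),
                                      chrom = "chr1", pos = 1:100 * 100))
  beta <- matrix(rep(c(0.05, 0.95), each = 50), 100, 3)
  rownames(beta) <- man$probe_id
  det <- matrix(0.001, 100, 3)
  det[1:6, 2] <- 0.5   # 6% failures
  det[1:5, 3] <- 0.5   # exactly 5%
  samples <- data.frame(sample_id = c("ok", "bad", "edge"), age = 10,
                        sex = "female", batch = "b", cohort = "control")
  ds <- methylation_dataset(man, beta = beta, detection_p = det,
                            samples = samples)
  rep <- sample_qc(ds, max_fail_rate = 0.05)
  expect_identical(rep$excluded, c(FALSE, TRUE, FALSE))
  expect_true(all(rep$bimodal_pass))
})

test_that("sex prediction recovers generator truth and flags discordance", {
  man <- tiny_manifest()
  ds <- simulate_cohort(man, cohort_design(n_cases = 6, n_controls = 12,
                                           n_signal_probes = 0, seed = 17))
  pred <- predict_sex(ds)
  expect_identical(unname(pred), ds$samples$sex)
  ds$samples$sex[1] <- setdiff(c("male", "female"), pred[1])
  rep <- sample_qc(ds)
  expect_true(rep$sex_discordant[1])
  expect_false(any(rep$sex_discordant[-1]))
  man_auto <- make_probe_manifest(100, c(chr1 = 100), seed = 1)
  ds_auto <- simulate_cohort(man_auto,
                             cohort_design(n_cases = 2, n_controls = 4,
                                           n_signal_probes = 0, seed = 1))
  expect_error(predict_sex(ds_auto), "sex-chromosome")
})

test_that("bimodality check separates bimodal from flat beta profiles", {
  set.seed(31)
  bimodal <- c(rbeta(1000, 1, 20), rbeta(1000, 20, 1))
  expect_true(check_bimodality(bimodal))
  expect_false(check_bimodality(runif(2000)))
  expect_false(check_bimodality(rep(0.5, 200)))
  expect_error(check_bimodality(rep(0.5, 10)), "100 probes")
})

test_that("PCA scores reflect rank and duplicate samples", {
  set.seed(12)
  base <- matrix(rnorm(4 * 30), 4, 30)
  x <- rbind(base[1, ], base[1, ], base[2:4, ])
  sc <- pca_scores(x, k = 2)$scores
  expect_equal(sc[1, ], sc[2, ])
  # exact rank 2 -> third component has no variance
  y <- cbind(rnorm(10), rnorm(10)) %*% matrix(rnorm(2 * 20), 2, 20)
  expect_warning(s3 <- pca_scores(y, k = 5), "truncating")
  expect_lte(ncol(s3$scores), 2)
  # scores are uncorrelated across components
  z <- matrix(rnorm(40 * 15), 40, 15)
  sz <- pca_scores(z, k = 3)$scores
  cv <- crossprod(scale(sz, scale = FALSE))
  expect_lt(max(abs(cv[upper.tri(cv)])) / max(diag(cv)), 1e-10)
})

test_that("matched-control selection honours strata, ratio and clones", {
  cases <- data.frame(sample_id = paste0("case", 1:3),
                      age = c(5, 10, 15), sex = c("male", "female", "male"),
                      batch = "b1", stringsAsFactors = FALSE)
  clones <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(sample_id = paste0("clone", i, "_", 1:4),
               age = cases$age[i], sex = cases$sex[i], batch = "b1",
               stringsAsFactors = FALSE)
  }))
  decoys <- data.frame(sample_id = paste0("decoy", 1:20),
                       age = rep(c(40, 50), 10),
                       sex = rep(c("male", "female"), each = 10),
                       batch = "b1", stringsAsFactors = FALSE)
  pool <- rbind(decoys, clones)  # clones last: distance must drive choice
  sel <- match_controls(cases, pool, ratio = 4)
  expect_length(sel, 12)
  expect_setequal(sel, clones$sample_id)
  expect_length(intersect(sel, cases$sample_id), 0)

  # 11 cases at ratio 4 -> 44 controls
  cases11 <- data.frame(sample_id = paste0("c", 1:11), age = 10,
                        sex = "male", batch = "b1")
  pool11 <- data.frame(sample_id = paste0("p", 1:60),
                       age = rnorm(60, 10), sex = "male", batch = "b1")
  expect_length(match_controls(cases11, pool11, ratio = 4), 44)

  # stratum exhaustion errors with the stratum named
  expect_error(match_controls(cases, pool[pool$sex == "male", ], ratio = 4),
               "sex=female")
})

test_that("a gross PCA outlier among matched controls is replaced", {
  set.seed(8)
  cases <- data.frame(sample_id = paste0("case", 1:4), age = c(4, 8, 12, 16),
                      sex = "male", batch = "b1", stringsAsFactors = FALSE)
  pool <- data.frame(sample_id = paste0("p", 1:40),
                     age = rep(c(4, 8, 12, 16), 10), sex = "male",
                     batch = "b1", stringsAsFactors = FALSE)
  pm <- matrix(rnorm(40 * 50), 40, 50, dimnames = list(pool$sample_id, NULL))
  pm["p1", ] <- pm["p1", ] + 50   # age-4 exact match, gross outlier
  sel <- match_controls(cases, pool, pool_m = pm, ratio = 4)
  expect_length(sel, 16)
  expect_false("p1" %in% sel)
  # without the outlier column p1 would be picked (zero age distance)
  sel0 <- match_controls(cases, pool, ratio = 4)
  expect_true("p1" %in% sel0)
})
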