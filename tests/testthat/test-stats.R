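test_that("one-tailed paired t test matches the closed-form df = 2 oracle", {
  pre <- c(10, 10, 10)
  post <- c(11, 12, 13)           # differences 1, 2, 3
  res <- paired_t_one_tailed(pre, post, "greater")
  expect_equal(res$t, sqrt(12), tolerance = 1e-4)   # 3.4641
  # closed form for the t CDF at df = 2: P(T <= t) = 1/2 + t/(2 sqrt(2+t^2))
  p_oracle <- 1 - (0.5 + res$t / (2 * sqrt(2 + res$t^2)))
  expect_equal(res$p, p_oracle, tolerance = 1e-10)
  expect_equal(res$p, 0.0371, tolerance = 1e-3)
  # tail symmetry under negation of the differences
  res2 <- paired_t_one_tailed(post, pre, "greater")
  expect_equal(res2$p, 1 - res$p)
  # null: identical pairs
  res0 <- paired_t_one_tailed(pre, pre, "greater")
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 0.5)
  # listwise deletion of incomplete pairs
  res3 <- paired_t_one_tailed(c(pre, NA), c(post, 5), "greater")
  expect_equal(res3$n, 3)
  expect_error(paired_t_one_tailed(1, 2, "greater"),
               class = "vldlkin_validation_error")
})

test_that("Pearson correlation matches hand computation and permutations", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1)$r, 1)
  res <- pearson(c(1, 2, 3), c(1, 2, 2))
  expect_equal(res$r, sqrt(3) / 2, tolerance = 1e-12)
  # joint permutation invariance
  set.seed(3)
  x <- rnorm(15); y <- rnorm(15) + 0.5 * x
  perm <- sample(15)
  expect_equal(pearson(x[perm], y[perm])$r, pearson(x, y)$r)
  # zero variance is undefined
  expect_true(is.na(pearson(rep(1, 5), rnorm(5))$r))
  # t-transform p agrees with a permutation null within Monte-Carlo error
  set.seed(9)
  x <- rnorm(20); y <- rnorm(20)
  p_t <- pearson(x, y)$p
  p_perm <- vldlkin:::pearson_perm_p(x, y, n_perm = 4000, seed = 2)
  expect_lt(abs(p_t - p_perm), 3 * sqrt(p_t * (1 - p_t) / 4000) + 0.01)
})

test_that("cohort tables flag configured contrasts and handle null cohorts", {
  cohort <- cached("stats_cohort",
                   generate_cohort(cohort_config(n_patients = 24, seed = 2,
                                                 with_clamp = TRUE)))
  summaries <- do.call(rbind, lapply(names(cohort$datasets), function(k)
    true_kinetics(cohort$truth[[k]], cohort$datasets[[k]])))
  clamp_sums <- do.call(rbind, lapply(cohort$datasets, clamp_summary))
  tabs <- build_cohort_tables(summaries, clamp_sums)

  t2 <- tabs$table2
  row <- function(v) t2[t2$variable == v, ]
  # configured production decrease is detected at n = 24
  expect_identical(row("P_B1")$direction, "less")
  expect_lt(row("P_B1")$p, 0.05)
  expect_lt(row("P_T1")$p, 0.05)
  # configured increases
  expect_identical(row("k_FCR_T2")$direction, "greater")
  expect_lt(row("k_FCR_T2")$p, 0.05)
  expect_lt(row("ISI")$p, 0.05)
  expect_true(all(t2$p >= 0 & t2$p <= 1, na.rm = TRUE))

  # combined correlations use 2n points
  comb <- tabs$correlations[tabs$correlations$subset == "combined", ]
  expect_true(all(comb$n == 48))
  expect_true(all(abs(tabs$correlations$r) <= 1, na.rm = TRUE))
  # ISI vs normalised lipolysis suppression is positive post surgery
  isi_cor <- tabs$correlations[
    tabs$correlations$panel == "ISI_vs_lipolysis_suppression_norm", ]
  expect_gt(isi_cor$r, 0)
  expect_lt(isi_cor$p, 0.05)

  # null cohort: identical pre/post
  null_sum <- summaries[summaries$condition == "pre", ]
  null_post <- null_sum
  null_post$condition <- "post"
  ntabs <- suppressWarnings(build_cohort_tables(rbind(null_sum, null_post)))
  expect_true(all(abs(ntabs$table2$pre_mean - ntabs$table2$post_mean) < 1e-12))
  expect_true(all(ntabs$table2$p == 0.5 | is.na(ntabs$table2$p)))

  # unpaired patients are excluded with a warning
  expect_warning(build_cohort_tables(summaries[-1, ]), "unpaired")
})

test_that("table export writes the four CSV artefacts", {
  cohort <- cached("stats_cohort",
                   generate_cohort(cohort_config(n_patients = 24, seed = 2,
                                                 with_clamp = TRUE)))
  summaries <- do.call(rbind, lapply(names(cohort$datasets), function(k)
    true_kinetics(cohort$truth[[k]], cohort$datasets[[k]])))
  dir <- withr::local_tempdir()
  build_cohort_tables(summaries, out_dir = dir)
  expect_setequal(list.files(dir), c("table2.csv", "correlations.csv",
                                     "fig1_auc.csv", "fig4_isi.csv"))
  expect_gt(nrow(read.csv(file.path(dir, "table2.csv"))), 10)
})
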