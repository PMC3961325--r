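toy_matrix <- function() {
  m <- matrix(c(1, 2, 3,
                2, 4, 6,
                3, 6, 9), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
  m
}

test_that("normalisation mean-centres each sample and is idempotent", {
  norm <- normalize_expression(toy_matrix())
  expect_equal(unname(colMeans(norm)), rep(0, 3), tolerance = 1e-9)
  expect_equal(normalize_expression(norm), norm)
  logged <- normalize_expression(toy_matrix(), log2_transform = TRUE)
  expect_equal(unname(colMeans(logged)), rep(0, 3), tolerance = 1e-9)
  bad <- toy_matrix(); bad[1, 1] <- 0
  expect_error(normalize_expression(bad, log2_transform = TRUE), "positive")
})

test_that("signature scores average the present signature rows", {
  m <- toy_matrix()
  expect_equal(signature_score(m, c("g1", "g2", "g3"))$score,
               unname(colMeans(m)))
  expect_equal(signature_score(m, "g2")$score, unname(m["g2", ]))
  expect_warning(sc <- signature_score(m, c("g1", "absent")), "dropped")
  expect_equal(sc$score, unname(m["g1", ]))
  expect_error(signature_score(m, "nope"), "no signature gene")
})

test_that("the median split sends ties to the low group", {
  sc <- tibble::tibble(sample = paste0("s", 1:4), score = c(1, 2, 3, 4))
  split <- median_split(sc)  # median 2.5
  expect_equal(as.character(split$group), c("low", "low", "high", "high"))
  sc2 <- tibble::tibble(sample = paste0("s", 1:4), score = c(1, 2, 2, 4))
  split2 <- median_split(sc2)  # median 2.0; both 2.0 samples are low
  expect_equal(sum(split2$group == "low"), 3L)
  expect_error(median_split(tibble::tibble(sample = c("a", "b"), score = c(1, 1))),
               "degenerate")
})

test_that("the product-limit estimate matches hand calculation", {
  km <- km_estimate(tibble::tibble(time = c(1, 2), event = c(1, 1)))
  expect_equal(km$survival, c(0.5, 0))           # (1-1/2), then (1-1/1)
  cens <- km_estimate(tibble::tibble(time = c(1, 2, 3), event = 0))
  expect_equal(cens$survival, rep(1, 3))
  expect_error(km_estimate(tibble::tibble(time = -1, event = 1)), "non-negative")
})

test_that("KM is the empirical survival function without censoring and scale-invariant", {
  set.seed(61)
  times <- round(rexp(40, 0.2), 2)
  rec <- tibble::tibble(time = times, event = 1)
  km <- km_estimate(rec)
  ecdf_surv <- vapply(km$time, function(t) mean(times > t), 0)
  expect_equal(km$survival, ecdf_surv, tolerance = 1e-12)
  doubled <- km_estimate(dplyr::bind_rows(rec, rec))
  expect_equal(doubled$survival, km$survival, tolerance = 1e-12)
})

test_that("the log-rank statistic matches the hand-tabulated 2x2 table sum", {
  high <- tibble::tibble(time = c(1, 2), event = 1)
  low <- tibble::tibble(time = c(3, 4), event = 1)
  # by hand over event times 1..4: O_high = 2, E_high = 1/2 + 1/3 = 5/6,
  # V = 1/4 + 2/9 = 17/36, chisq = (2 - 5/6)^2 / (17/36) = 2.882353
  res <- log_rank_test(high, low)
  expect_equal(res$chisq, (2 - 5/6)^2 / (17/36), tolerance = 1e-6)
  expect_equal(res$p_value, pchisq(res$chisq, 1, lower.tail = FALSE))
  expect_equal(sum(res$groups$observed), 4)
  # swapping group labels leaves the statistic unchanged
  expect_equal(log_rank_test(low, high)$chisq, res$chisq, tolerance = 1e-12)
  # identical groups: no evidence
  res0 <- log_rank_test(high, high)
  expect_equal(res0$chisq, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)
  expect_error(log_rank_test(tibble::tibble(time = 1, event = 0),
                             tibble::tibble(time = 2, event = 0)), "at least one event")
})

test_that("stratified survival composes the pipeline and ignores sample order", {
  set.seed(62)
  cohort <- simulate_cohort(sim_config(cohort_n = 60L), sprintf("G%04d", 1:20))
  res <- stratified_survival(cohort$matrix, sprintf("G%04d", 1:20), cohort$clinical)
  expect_s3_class(res$test, "logrank_result")
  expect_equal(nrow(res$scores), 60L)
  perm <- sample(ncol(cohort$matrix))
  res2 <- stratified_survival(cohort$matrix[, perm], sprintf("G%04d", 1:20),
                              cohort$clinical)
  expect_equal(glance(res2), glance(res))
  expect_equal(dplyr::arrange(res2$scores, sample), dplyr::arrange(res$scores, sample))
  expect_s3_class(autoplot(res), "ggplot")
  # mismatched ids are rejected
  expect_error(stratified_survival(cohort$matrix[, 1:59], sprintf("G%04d", 1:20),
                                   cohort$clinical), "one-to-one")
})

test_that("the score split recovers the planted cohort groups", {
  set.seed(63)
  sig <- sprintf("G%04d", 1:40)
  cohort <- simulate_cohort(sim_config(), sig)
  res <- stratified_survival(cohort$matrix, sig, cohort$clinical)
  agree <- mean((res$scores$group == "high") ==
                  (cohort$group$true_group == "high"))
  expect_gt(max(agree, 1 - agree), 0.95)
  # planted hazard ratio 2 on 232 samples is detectable
  expect_lt(res$test$p_value, 0.05)
})
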