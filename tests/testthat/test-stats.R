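test_that("log transform: closed form, monotone, elementwise log1p", {
  m <- matrix(c(0, 1, 4, NA), 2, 2)
  lt <- log_transform(m)
  expect_equal(lt[1, 1], 0)
  expect_true(is.na(lt[2, 2]))
  expect_error(log_transform(matrix(-1)), ">= 0")
  set.seed(2)
  r <- matrix(runif(60, 0, 50), 10, 6)
  expect_equal(log_transform(r), log1p(r))
  expect_identical(order(r[, 3]), order(log_transform(r)[, 3]))
})

test_that("ICC: perfect agreement, ANOVA-oracle equivalence,
           reordering invariance, validation", {
  m <- matrix(rep(c(3, 7, 12, 20), 3), 4, 3)
  expect_equal(icc(m)$value, 1, tolerance = 1e-12)

  hand <- matrix(c(9, 2, 5, 8,
                   6, 1, 3, 2,
                   8, 4, 6, 8), 4, 3)
  expect_equal(icc(hand)$value, brute_icc21(hand), tolerance = 1e-10)
  set.seed(7)
  for (i in 1:20) {
    r <- matrix(rnorm(28, 10, 3), 7, 4)
    res <- icc(r)
    expect_equal(res$value, brute_icc21(r), tolerance = 1e-10)
    expect_true(res$ci[1] <= res$value && res$value <= res$ci[2])
    perm <- r[sample(7), sample(4)]
    expect_equal(icc(perm)$value, res$value, tolerance = 1e-10)
  }
  expect_error(icc(matrix(1:4, 4, 1)), "2")
  withna <- rbind(hand, c(NA, 1, 2))
  expect_equal(icc(withna)$n_dropped, 1L)
})

test_that("ICC single-rater forms match their k-rater Spearman-Brown
           counterparts", {
  set.seed(11)
  m <- matrix(rnorm(50, 20, 5), 10, 5)
  f <- icc(m)$forms
  k <- 5
  sb <- function(x) k * x / (1 + (k - 1) * x)
  expect_equal(f$value[f$form == "ICC3k"], sb(f$value[f$form == "ICC3"]),
               tolerance = 1e-10)
  expect_equal(f$value[f$form == "ICC1k"], sb(f$value[f$form == "ICC1"]),
               tolerance = 1e-10)
})

test_that("Kendall W: unanimity, antisymmetry, tied-rank formula,
           reference-implementation agreement", {
  un <- matrix(rep(c(1, 3, 2, 1, 2, 3), 4), 6, 4)
  expect_equal(kendall_w(un)$value, 1)
  rev2 <- cbind(1:5, 5:1)
  expect_equal(kendall_w(rev2)$value, 0)
  expect_error(kendall_w(matrix(2, 4, 3)), "constant")
  set.seed(10)
  for (i in 1:25) {
    m <- matrix(sample(1:3, 24, TRUE), 6, 4)
    ok <- tryCatch({
      w <- kendall_w(m)$value
      expect_equal(w, brute_kendall_w(m), tolerance = 1e-10)
      if (requireNamespace("vegan", quietly = TRUE)) {
        wv <- unname(vegan::kendall.global(m)$Concordance_analysis[1, 1])
        expect_equal(w, wv, tolerance = 1e-10)
      }
      TRUE
    }, error = function(e) grepl("constant", conditionMessage(e)))
    expect_true(ok)
  }
})

test_that("reliability bands follow the printed intervals", {
  expect_equal(classify_reliability(0.94), "excellent")
  expect_equal(classify_reliability(0.60), "moderate")
  expect_equal(classify_reliability(0.44), "moderate")
  expect_equal(classify_reliability(0.75), "good")
  expect_equal(classify_reliability(0.805), "excellent")
  expect_equal(classify_reliability(0.2), "poor")
  expect_error(classify_reliability(1.4), "<= 1")
})

test_that("coefficient of variation: hand value, zero-mean case,
           scale invariance", {
  m <- rbind(c(1, 2, 3), c(5, 5, 5), c(0, 0, 0))
  cv <- coefficient_of_variation(m)
  expect_equal(unname(cv$cv[1]), 0.5)
  expect_equal(unname(cv$cv[2]), 0)
  expect_true(is.na(cv$cv[3]))
  expect_equal(unname(coefficient_of_variation(7 * m)$cv[1]), 0.5)
})

test_that("log-rank: identical groups give chi-square 0; hand-worked
           risk-table arithmetic matches", {
  rec <- data.frame(time_months = rep(c(3, 6, 9, 12), 2),
                    event = rep(c(1, 0, 1, 1), 2),
                    group = rep(c("low", "high"), each = 4))
  r <- km_logrank(rec)
  expect_equal(r$chisq, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)

  rec2 <- data.frame(time_months = c(2, 4, 7, 3, 6, 9),
                     event = c(1, 1, 0, 1, 0, 1),
                     group = rep(c("low", "high"), each = 3))
  r2 <- km_logrank(rec2)
  expect_equal(r2$chisq,
               brute_logrank(rec2$time_months, rec2$event, rec2$group),
               tolerance = 1e-9)
  expect_equal(r2$p, pchisq(r2$chisq, 1, lower.tail = FALSE))
  expect_error(km_logrank(rec[rec$group == "low", ]), "2")
})

test_that("Cox: Efron duplication invariance, sign agrees with log-rank,
           adjusted model uses stage I reference", {
  co <- simulate_survival_cohort(sim_config(seed = 61))
  f1 <- cox_fit(co)
  dup <- rbind(co, co)
  # exact invariance under Breslow (risk-set sums just double);
  # Efron's within-tie correction makes it approximate
  fb1 <- cox_fit(co, ties = "breslow")
  fb2 <- cox_fit(dup, ties = "breslow")
  expect_equal(fb2$hr, fb1$hr, tolerance = 1e-8)
  f2 <- cox_fit(dup)
  expect_equal(f2$hr, f1$hr, tolerance = 0.02)
  lr <- km_logrank(co)
  expect_equal(sign(f1$coef),
               sign((lr$observed - lr$expected)[2]))
  fm <- cox_fit(co, c("group", "sex", "age", "stage"))
  expect_true(all(c("stageII", "stageIII", "stageIV") %in% fm$term))
  expect_false("stageI" %in% fm$term)
  expect_error(cox_fit(transform(co, group = "high")), "constant")
})

test_that("Schoenfeld residuals sum to zero; sign-flip effects are
           detected; validation", {
  co <- simulate_survival_cohort(sim_config(seed = 63))
  f <- cox_fit(co, c("group", "age"))
  resid <- residuals(attr(f, "fit"), type = "schoenfeld")
  expect_true(all(abs(colSums(resid)) < 1e-8))
  z <- schoenfeld_test(f)
  expect_true("GLOBAL" %in% z$term)
  set.seed(8)
  flip <- sim_flip_cohort(2000)
  zf <- schoenfeld_test(cox_fit(flip))
  expect_lt(zf$p[zf$term == "group"], 0.01)
  tiny <- data.frame(time_months = c(2, 4, 6, 8), event = c(1, 1, 0, 0),
                     group = c("low", "high", "low", "high"))
  expect_error(schoenfeld_test(cox_fit(tiny)), "3 events")
})
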