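test_that("Lambert volume arithmetic", {
  expect_equal(lambert_volume(4, 3, 2.5), 21.3)
  expect_equal(lambert_volume(1, 1, 1), 0.71)
  expect_equal(lambert_volume(2, 3, 2.5), 2 * lambert_volume(1, 3, 2.5))
  expect_error(lambert_volume(0, 1, 1), "> 0")
})

test_that("group comparison: identical groups, label antisymmetry", {
  rec <- tibble::tibble(group = rep(c("NOA", "OA"), each = 4),
                        x = rep(c(1, 2, 3, 4), 2))
  gc <- group_compare(rec, "x")
  expect_equal(gc$t, 0)
  expect_equal(gc$p_value, 1, tolerance = 1e-9)

  rec2 <- tibble::tibble(group = rep(c("NOA", "OA"), each = 5),
                         x = c(1:5, 3:7))
  g1 <- group_compare(rec2, "x")
  rec3 <- dplyr::mutate(rec2, group = ifelse(group == "NOA", "OA", "NOA"))
  g2 <- group_compare(rec3, "x")
  expect_equal(g1$t, -g2$t, tolerance = 1e-12)
  expect_equal(g1$p_value, g2$p_value, tolerance = 1e-12)
  expect_error(group_compare(rec2[c(1, 6:10), ], "x"), "2 patients")
})

test_that("pearson matrix: unit diagonal, symmetry, affine invariance", {
  withr::with_seed(41, {
    rec <- tibble::tibble(a = rnorm(40), b = rnorm(40))
    rec$c <- rec$a + rnorm(40, sd = 0.3)
    rec$group <- rep(c("NOA", "OA"), 20)
    pm <- pearson_matrix(rec, c("a", "b", "c"))
    expect_equal(diag(pm$r), c(a = 1, b = 1, c = 1))
    expect_equal(pm$r, t(pm$r))
    ct <- cor.test(rec$a, rec$c)
    expect_equal(pm$r["a", "c"], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(pm$p["a", "c"], ct$p.value, tolerance = 1e-12)
    # positive affine rescaling leaves r unchanged
    rec2 <- dplyr::mutate(rec, a = 7 * a + 100)
    pm2 <- pearson_matrix(rec2, c("a", "b", "c"))
    expect_equal(pm2$r, pm$r, tolerance = 1e-12)
    # assumption report carries Shapiro-Wilk and Levene columns
    expect_true(all(c("shapiro_p", "levene_p") %in% names(pm$assumptions)))
    # zero-variance variable reported missing
    rec$z <- 1
    pm3 <- pearson_matrix(rec, c("a", "z"))
    expect_true(is.na(pm3$r["a", "z"]))
  })
})

test_that("pearson estimate covers the true rho at the Figure-7 operating point", {
  # bivariate normal, rho = 0.757, n = 94 (FSH-LH scale): the exact CI covers
  # rho in >= 93% of replicates
  withr::with_seed(42, {
    rho <- 0.757; n <- 94; hits <- 0; reps <- 150
    for (i in seq_len(reps)) {
      x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
      ci <- cor.test(x, y)$conf.int
      if (rho >= ci[1] && rho <= ci[2]) hits <- hits + 1
    }
    expect_gte(hits / reps, 0.93)
  })
})

test_that("ROC: perfect separation, trapezoid = rank U equivalence, Youden cutoff", {
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12), rep(c("NOA", "OA"), each = 3))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  withr::with_seed(43, {
    for (i in 1:30) {
      n1 <- sample(3:25, 1); n0 <- sample(3:25, 1)
      sc <- round(c(rnorm(n0), rnorm(n1, mean = runif(1, 0, 2))), 1) # ties
      lab <- rep(c("NOA", "OA"), c(n0, n1))
      r <- roc_analysis(sc, lab)
      u <- unname(wilcox.test(sc[lab == "OA"], sc[lab == "NOA"],
                              exact = FALSE)$statistic)
      expect_equal(r$auc, u / (n1 * n0), tolerance = 1e-10)
    }
  })

  # labels independent of scores -> AUC near 1/2
  withr::with_seed(44, {
    sc <- rnorm(4000); lab <- sample(rep(c("NOA", "OA"), 2000))
    expect_lt(abs(roc_analysis(sc, lab)$auc - 0.5), 0.03)
  })

  # Youden cutoff: J maximized, tie broken toward specificity
  r2 <- roc_analysis(c(1, 2, 3, 4), c("NOA", "NOA", "OA", "OA"))
  expect_equal(r2$sensitivity + r2$specificity - 1, 1)
  expect_error(roc_analysis(1:4, rep("OA", 4)), "both classes")
})

test_that("DeLong CI agrees with pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(45, {
    sc <- c(rnorm(40), rnorm(50, 1))
    lab <- rep(c("NOA", "OA"), c(40, 50))
    r <- roc_analysis(sc, lab)
    pr <- pROC::roc(lab, sc, levels = c("NOA", "OA"), direction = "<",
                    quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(unname(r$auc_ci), ci[c(1, 3)], tolerance = 1e-6)
  })
})

test_that("logistic model: OR = exp(beta), Table-2 arithmetic, VIF, errors", {
  expect_equal(round(exp(-0.833), 3), 0.435)  # printed OR check
  withr::with_seed(46, {
    n <- 300
    fsh <- rgamma(n, 9, 1); dia <- rnorm(n, 160, 35)
    lp <- -6 - 0.8 * fsh + 0.07 * dia
    y <- rbinom(n, 1, plogis(lp))
    rec <- tibble::tibble(group = ifelse(y == 1, "OA", "NOA"),
                          fsh = fsh, mean_diameter = dia)
    m <- fit_logistic(rec)
    td <- tidy(m)
    expect_equal(td$odds_ratio, exp(td$beta), tolerance = 1e-12)
    expect_equal(td$or_ci_lower, exp(td$beta - 1.96 * td$se),
                 tolerance = 1e-12)
    ref <- glm(y ~ fsh + dia, family = binomial())
    expect_equal(unname(sort(td$beta)), sort(unname(coef(ref))),
                 tolerance = 1e-8)
    expect_true(all(m$vif >= 1))
    gl <- glance(m)
    expect_true(gl$pseudo_r2 > 0 && gl$pseudo_r2 < 1)

    # constant covariate is inestimable
    rec$flat <- 5
    expect_error(fit_logistic(rec, c("fsh", "flat")), "flat")
    # perfect separation is reported
    rec$sep <- ifelse(rec$group == "OA", 10, -10)
    expect_error(fit_logistic(rec, "sep"), "separation")
  })
})

test_that("logistic recovery: 95% CIs cover the truth in most replicates", {
  withr::with_seed(47, {
    b <- c(-1, 0.8, -0.5)
    reps <- 60; n <- 1500; hits <- matrix(0, reps, 3)
    for (r in seq_len(reps)) {
      x1 <- rnorm(n); x2 <- rnorm(n)
      y <- rbinom(n, 1, plogis(b[1] + b[2] * x1 + b[3] * x2))
      rec <- tibble::tibble(group = ifelse(y == 1, "OA", "NOA"),
                            x1 = x1, x2 = x2)
      td <- tidy(fit_logistic(rec, c("x1", "x2")))
      hits[r, ] <- as.integer(b >= td$ci_lower & b <= td$ci_upper)
    }
    expect_gte(min(colMeans(hits)), 0.93)
  })
})

test_that("classification report reproduces published-table arithmetic and edge cases", {
  cm <- matrix(c(31, 5, 2, 56), 2, 2, byrow = TRUE)
  rep1 <- classification_report(cm)
  expect_equal(round(rep1$sensitivity, 1), 96.6)
  expect_equal(round(rep1$specificity, 1), 86.1)
  expect_equal(round(rep1$accuracy, 1), 92.6)
  expect_equal(round(rep1$npv, 1), 93.9)
  expect_equal(round(rep1$ppv, 1), 91.8)

  all_right <- classification_report(matrix(c(10, 0, 0, 20), 2, 2))
  expect_true(all(unlist(all_right[c("sensitivity", "specificity", "ppv",
                                     "npv", "accuracy")]) == 100))

  withr::with_seed(48, {
    rec <- tibble::tibble(group = rep(c("NOA", "OA"), each = 30),
                          fsh = c(rnorm(30, 12, 3), rnorm(30, 5, 2)),
                          mean_diameter = c(rnorm(30, 140, 30),
                                            rnorm(30, 185, 30)))
    m <- fit_logistic(rec)
    r0 <- classification_report(m, rec, cutoff = 0)
    expect_equal(r0$sensitivity, 100)
    expect_equal(r0$specificity, 0)
    r5 <- classification_report(m, rec, cutoff = 0.5)
    expect_equal(r5$tp + r5$fn, 30)
    expect_error(classification_report(m, rec[0, ]), "non-empty")
  })
})

test_that("t-test power at the diameter operating point (n = 36/58) is near 1", {
  # diameter group parameters, pooled t-test: p < 0.001 in >= 95% of reps
  withr::with_seed(49, {
    reps <- 100; hit <- 0
    for (i in seq_len(reps)) {
      noa <- rnorm(36, 143.1, 31.3); oa <- rnorm(58, 183.6, 37.1)
      if (t.test(noa, oa, var.equal = TRUE)$p.value < 0.001) hit <- hit + 1
    }
    expect_gte(hit / reps, 0.95)
  })
})
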