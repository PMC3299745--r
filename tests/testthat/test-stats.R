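test_that("Box-Cox transforms match closed forms and select sensible lambda", {
  expect_equal(box_cox(c(1, 2, 3), lambda = 1)$values, c(0, 1, 2))
  expect_equal(box_cox(c(1, exp(1), exp(2)), lambda = 0)$values, c(0, 1, 2),
               tolerance = 1e-12)
  # log-normal data: the stabilising exponent is 0
  x <- withr::with_seed(31, exp(stats::rnorm(200, 1, 0.6)))
  fit <- box_cox(x, lambda = "auto")
  expect_gte(fit$lambda, -0.3)
  expect_lte(fit$lambda, 0.3)
  # agreement with the standard profile-likelihood implementation
  skip_if_not_installed("MASS")
  prof <- MASS::boxcox(x ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  expect_equal(fit$lambda, prof$x[which.max(prof$y)], tolerance = 0.02)
})

test_that("Box-Cox auto recovers the generating exponent within 0.25", {
  # Gaussian on the transformed scale, with enough spread relative to the
  # mean that the exponent is identifiable
  for (lambda_true in c(0, 0.5, 1)) {
    x <- withr::with_seed(100 + round(10 * lambda_true), {
      y <- pmax(stats::rnorm(1000, 4, 1.2), 0.2)
      if (lambda_true == 0) exp(y) else (y * lambda_true + 1)^(1 / lambda_true)
    })
    fit <- box_cox(x, lambda = "auto")
    expect_lt(abs(fit$lambda - lambda_true), 0.25)
  }
})

test_that("Box-Cox shifts zero-containing data and records it", {
  fit <- box_cox(c(0, 2, 4), lambda = 1)
  expect_equal(fit$shift, 1)  # half the smallest positive value
  expect_equal(fit$values, c(0, 2, 4) + 1 - 1)
  expect_error(box_cox(c(-1, 2)), class = "copediv_domain_error")
  expect_named(glance(fit), c("lambda", "shift", "log_lik", "n"))
  expect_equal(tidy(fit)$original, c(0, 2, 4))
})

test_that("pooled t-test reproduces study and hand values and its conventions", {
  d <- tibble::tibble(
    h_b = c(1.15055, 1.00991, 0.88865, 0.59314, 0.84244, 0.73034),
    arm = rep(c("control", "antibiotic"), each = 3)
  )
  tt <- t_test_unpaired(d, h_b, arm)
  expect_equal(round(abs(tt$statistic), 2), 2.82)
  expect_equal(tt$df, 4)
  d2 <- tibble::tibble(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  tt2 <- t_test_unpaired(d2, v, g)
  expect_equal(abs(tt2$statistic), 3.6742346141747673, tolerance = 1e-12)
  expect_equal(tt2$df, 4)
  # identical groups
  same <- tibble::tibble(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_equal(t_test_unpaired(same, v, g)$statistic, 0)
  expect_equal(t_test_unpaired(same, v, g)$p_value, 1)
  # zero variance, unequal means
  deg <- tibble::tibble(v = c(1, 1, 2, 2), g = c("a", "a", "b", "b"))
  expect_identical(t_test_unpaired(deg, v, g)$statistic, -Inf)
  expect_equal(t_test_unpaired(deg, v, g)$p_value, 0)
})

test_that("t statistic is antisymmetric and affine-invariant", {
  withr::with_seed(13, {
    for (i in 1:20) {
      a <- stats::rnorm(sample(3:6, 1))
      b <- stats::rnorm(sample(3:6, 1), mean = 1)
      d <- tibble::tibble(v = c(a, b),
                          g = rep(c("a", "b"), c(length(a), length(b))))
      dswap <- d[rev(seq_len(nrow(d))), ]  # group "b" now appears first
      t1 <- t_test_unpaired(d, v, g)$statistic
      expect_equal(t_test_unpaired(dswap, v, g)$statistic, -t1,
                   tolerance = 1e-10)
      daff <- dplyr::mutate(d, v = 3.7 * v - 11)
      expect_equal(t_test_unpaired(daff, v, g)$statistic, t1,
                   tolerance = 1e-10)
    }
  })
})

test_that("one-way ANOVA matches hand computation and F = t^2 for two groups", {
  d0 <- tibble::tibble(v = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  an0 <- one_way_anova(d0, v, g)
  expect_equal(an0$statistic, 0)
  expect_identical(c(an0$df1, an0$df2), c(2, 6))
  # between-SS 42, within-SS 6 -> F = 21
  d1 <- tibble::tibble(v = c(1, 2, 3, 2, 3, 4, 6, 7, 8),
                       g = rep(c("a", "b", "c"), each = 3))
  an1 <- one_way_anova(d1, v, g)
  expect_equal(an1$statistic, 21, tolerance = 1e-12)
  expect_identical(c(an1$df1, an1$df2), c(2, 6))
  # hand formula as independent route
  ss_between <- function(groups) {
    gm <- mean(unlist(groups))
    sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  }
  withr::with_seed(17, {
    for (i in 1:10) {
      a <- stats::rnorm(4); b <- stats::rnorm(4, 1)
      d <- tibble::tibble(v = c(a, b), g = rep(c("a", "b"), each = 4))
      an <- one_way_anova(d, v, g)
      tt <- t_test_unpaired(d, v, g)
      expect_equal(an$statistic, tt$statistic^2, tolerance = 1e-10)
      groups <- list(a, b)
      msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / 6
      expect_equal(an$statistic, ss_between(groups) / 1 / msw, tolerance = 1e-10)
    }
  })
})

test_that("Tukey HSD orders pairwise p-values by mean gap and collapses to t for two groups", {
  d <- tibble::tibble(v = c(1, 2, 3, 2, 3, 4, 6, 7, 8),
                      g = rep(c("a", "b", "c"), each = 3))
  tk <- tukey_hsd(d, v, g)
  expect_identical(nrow(tk), 3L)
  p_ab <- tk$p_value[tk$group1 == "a" & tk$group2 == "b"]
  p_ac <- tk$p_value[tk$group1 == "a" & tk$group2 == "c"]
  expect_lt(p_ac, p_ab)
  same <- tibble::tibble(v = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  expect_true(all(tukey_hsd(same, v, g)$p_value == 1))
  # two groups: studentized range q = t * sqrt(2), so the p-values agree
  d2 <- tibble::tibble(v = c(1, 2, 3, 3, 5, 6), g = rep(c("a", "b"), each = 3))
  tk2 <- tukey_hsd(d2, v, g)
  tt2 <- t_test_unpaired(d2, v, g)
  # tolerance reflects ptukey's numerical-integration accuracy
  expect_equal(tk2$p_value, tt2$p_value, tolerance = 1e-5)
  expect_equal(tk2$p_value,
               stats::ptukey(abs(tt2$statistic) * sqrt(2), 2, 4,
                             lower.tail = FALSE),
               tolerance = 1e-5)
})

test_that("Spearman correlation matches rank-Pearson and exact enumeration", {
  inc <- tibble::tibble(x = 1:5, y = c(2, 4, 6, 8, 10))
  expect_equal(spearman_cor(inc, x, y)$estimate, 1)
  dec <- tibble::tibble(x = 1:5, y = 5:1)
  expect_equal(spearman_cor(dec, x, y)$estimate, -1)
  d <- tibble::tibble(x = 1:4, y = c(1, 3, 2, 4))
  expect_equal(spearman_cor(d, x, y)$estimate, 0.8)  # 1 - 6*2/(4*15)
  withr::with_seed(23, {
    for (i in 1:15) {
      n <- sample(4:9, 1)
      dd <- tibble::tibble(x = stats::rnorm(n),
                           y = sample(c(stats::rnorm(n - 1), stats::rnorm(1))))
      got <- spearman_cor(dd, x, y)$estimate
      expect_equal(got, stats::cor(dd$x, dd$y, method = "spearman"),
                   tolerance = 1e-12)
      expect_equal(got, stats::cor(rank(dd$x), rank(dd$y)), tolerance = 1e-12)
    }
  })
  # exact permutation p at n = 6 equals the reference exact distribution
  d6 <- tibble::tibble(x = c(0.2, 0.9, 1.1, 1.4, 1.5, 1.6),
                       y = c(0.73, 0.59, 0.84, 1.15, 0.89, 1.01))
  sp <- spearman_cor(d6, x, y, p_method = "exact")
  ref <- suppressWarnings(stats::cor.test(d6$x, d6$y, method = "spearman",
                                          exact = TRUE))
  expect_equal(sp$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(sp$p_value, ref$p.value, tolerance = 1e-12)
  # degenerate ranks
  flat <- tibble::tibble(x = c(1, 1, 1), y = c(1, 2, 3))
  expect_true(is.na(spearman_cor(flat, x, y)$estimate))
  expect_error(spearman_cor(tibble::tibble(x = 1:2, y = 1:2), x, y),
               class = "copediv_data_error")
})
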