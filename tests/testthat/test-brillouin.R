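test_that("log_factorial matches exact values and lgamma", {
  expect_identical(log_factorial(0), 0)
  expect_equal(log_factorial(2), log(2), tolerance = 1e-14)
  # frozen from exact big-integer 30! then log
  expect_equal(log_factorial(30), 74.65823634883016, tolerance = 1e-12)
  n <- c(1, 5, 171, 1000, 1e6)
  expect_equal(log_factorial(n), lgamma(n + 1), tolerance = 1e-10)
  expect_error(log_factorial(-1), class = "copediv_domain_error")
  expect_error(log_factorial(2.5), class = "copediv_domain_error")
})

test_that("Brillouin diversity reproduces printed library values and hand cases", {
  # six-library study values, printed at 2 dp
  printed <- c(Cipr = 0.59, Sulf = 0.84, Trim = 0.73,
               SS = 1.15, Ac = 1.01, DMSO = 0.89)
  got <- vapply(study_counts_list(), brillouin_diversity, numeric(1))
  expect_equal(round(got, 2), printed)
  # hand-derived values from exact factorials
  expect_equal(brillouin_diversity(30), 0)
  expect_equal(brillouin_diversity(c(1, 1)), 0.34657359027997264,
               tolerance = 1e-14)
  expect_equal(brillouin_diversity(c(2, 24, 2, 2)), 0.5931355136345999,
               tolerance = 1e-12)
  expect_error(brillouin_diversity(integer(0)), class = "copediv_domain_error")
  expect_error(brillouin_diversity(c(0, 0)), class = "copediv_domain_error")
})

test_that("diversity is permutation- and zero-count-invariant", {
  withr::with_seed(42, {
    for (i in 1:25) {
      counts <- random_counts()
      h <- brillouin_diversity(counts)
      expect_equal(brillouin_diversity(counts[sample.int(length(counts))]), h,
                   tolerance = 1e-14)
      expect_equal(brillouin_diversity(c(counts, 0L, 0L)), h, tolerance = 1e-14)
      expect_equal(h, brillouin_oracle(counts), tolerance = 1e-10)
    }
  })
})

test_that("min/max diversities match brute-force enumeration over all compositions (N <= 15)", {
  for (n in 2:15) {
    for (s in 1:n) {
      h <- apply(compositions(n, s), 1, brillouin_oracle)
      expect_equal(brillouin_min(n, s), min(h), tolerance = 1e-12)
      mx <- brillouin_max(n, s, partition = TRUE)
      expect_equal(mx$h_max, max(h), tolerance = 1e-12)
      expect_equal(sort(mx$partition$composition),
                   sort(compositions(n, s)[which.max(h), ]),
                   ignore_attr = TRUE)
    }
  }
})

test_that("min/max closed forms agree with frozen exact-arithmetic values", {
  expect_equal(brillouin_min(30, 4), 0.336689924060794, tolerance = 1e-12)
  expect_equal(brillouin_min(30, 1), 0)
  expect_equal(brillouin_min(3, 3), 0.5972531564093516, tolerance = 1e-12)
  expect_equal(brillouin_min(3, 3), brillouin_max(3, 3), tolerance = 1e-14)
  expect_equal(brillouin_max(30, 4), 1.213290260706961, tolerance = 1e-12)
  expect_equal(sort(brillouin_max(30, 4, partition = TRUE)$partition$composition),
               c(7, 7, 8, 8))
  expect_equal(brillouin_max(30, 5), 1.3920660096259885, tolerance = 1e-12)
  expect_equal(brillouin_max(30, 5, partition = TRUE)$partition$composition,
               rep(6, 5))
  expect_equal(brillouin_max(4, 2), 0.4479398673070138, tolerance = 1e-12)
  expect_error(brillouin_min(3, 4), class = "copediv_domain_error")
  expect_error(brillouin_max(3, 0), class = "copediv_domain_error")
})

test_that("maximal-evenness partition satisfies its arithmetic identities", {
  withr::with_seed(7, {
    for (i in 1:50) {
      s <- sample(30, 1)
      n <- s + sample(0:100, 1)
      p <- max_even_partition(n, s)
      expect_identical(p$y, p$x + 1L)
      expect_true(p$r >= 0 && p$r < s)
      expect_equal((s - p$r) * p$x + p$r * p$y, n)
      expect_equal(sum(p$composition), n)
      expect_true(all(p$composition >= 1))
    }
  })
})

test_that("H_min <= H_B <= H_max on random count vectors", {
  withr::with_seed(11, {
    for (i in 1:100) {
      counts <- random_counts()
      n <- sum(counts); s <- length(counts)
      h <- brillouin_diversity(counts)
      expect_gte(h, brillouin_min(n, s) - 1e-12)
      expect_lte(h, brillouin_max(n, s) + 1e-12)
    }
  })
})

test_that("evenness reproduces printed control-library values and handles S = 1", {
  expect_equal(round(brillouin_evenness(c(15, 6, 2, 3, 4))$v, 2), 0.74)
  expect_equal(round(brillouin_evenness(c(18, 3, 2, 2, 5))$v, 2), 0.60)
  expect_equal(brillouin_evenness(c(6, 6, 6, 6, 6))$v, 1, tolerance = 1e-12)
  res <- brillouin_evenness(30)
  expect_true(is.na(res$v))
  td <- tidy(brillouin_evenness(c(15, 6, 2, 3, 4)))
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("n", "s", "h_b", "h_min", "h_max", "v"))
  expect_identical(glance(brillouin_evenness(c(2, 1))),
                   tidy(brillouin_evenness(c(2, 1))))
})

test_that("V is invariant to the logarithm base", {
  withr::with_seed(3, {
    for (i in 1:20) {
      counts <- random_counts(80, 10)
      n <- sum(counts); s <- length(counts)
      if (s < 2) next
      v_nats <- brillouin_evenness(counts)$v
      # recompute every H in log10: the common scale factor cancels in V
      scale <- 1 / log(10)
      h10 <- brillouin_diversity(counts) * scale
      v10 <- (h10 - brillouin_min(n, s) * scale) /
        (brillouin_max(n, s) * scale - brillouin_min(n, s) * scale)
      expect_equal(v_nats, v10, tolerance = 1e-12)
    }
  })
})

test_that("Brillouin approaches Shannon for large censuses", {
  p <- c(0.5, 0.3, 0.2)
  counts <- round(p * 1e5)
  shannon <- -sum(p * log(p))
  expect_lt(abs(brillouin_diversity(counts) - shannon), 0.001)
})

test_that("diversity_table computes one row per library in input order", {
  tab <- read_count_table(copediv_example("table1_counts.tsv"))
  div <- diversity_table(tab)
  expect_identical(div$library, c("Cipr", "Sulf", "Trim", "SS", "Ac", "DMSO"))
  expect_identical(div$n, rep(30L, 6))
  expect_identical(div$s, c(4L, 4L, 4L, 5L, 5L, 4L))
  expect_equal(div$h_b[1], 0.5931355136345999, tolerance = 1e-12)
  # S = 4 evenness follows the standard min/max forms; the historical
  # printed values for those libraries are not reproducible from them
  expect_true(all(div$v > 0 & div$v < 1))
})
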