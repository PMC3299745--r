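#' Box-Cox power transformation
#'
#' Transforms positive data by `(x^lambda - 1) / lambda` (natural log at
#' `lambda = 0`), the variance-stabilising step applied to small-sample
#' endpoint data before t-tests and ANOVA. With `lambda = "auto"` the
#' exponent maximising the profile log-likelihood over `[-5, 5]` is used.
#' Data containing zeros are shifted by half the smallest positive value
#' first; the shift is recorded in the result.
#'
#' @param x Numeric vector, non-negative (zeros trigger the shift;
#'   negatives are an error).
#' @param lambda A number, or `"auto"` for maximum-likelihood selection.
#' @return An object of class `"box_cox"`: list with `values`
#'   (transformed data), `lambda`, `shift` and `log_lik`. `tidy()` returns
#'   the transformed values with the original, `glance()` the parameters.
#' @examples
#' box_cox(c(1, 2, 3), lambda = 1)$values
#' glance(box_cox(rlnorm(50), lambda = "auto"))
#' @export
box_cox <- function(x, lambda = "auto") {
  if (anyNA(x) || any(x < 0)) {
    abort("`x` must be non-negative and free of NA.",
          class = "copediv_domain_error")
  }
  shift <- 0
  if (any(x == 0)) {
    pos <- x[x > 0]
    if (length(pos) == 0) {
      abort("all values are zero; nothing to transform.",
            class = "copediv_domain_error")
    }
    shift <- min(pos) / 2
    x <- x + shift
  }
  if (identical(lambda, "auto")) {
    opt <- optimize(function(l) bc_log_lik(x, l), c(-5, 5), maximum = TRUE)
    lambda <- opt$maximum
    ll <- opt$objective
  } else {
    ll <- bc_log_lik(x, lambda)
  }
  structure(list(values = bc_transform(x, lambda), lambda = lambda,
                 shift = shift, log_lik = ll, original = x - shift),
            class = "box_cox")
}

bc_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-10) log(x) else (x^lambda - 1) / lambda
}

# profile log-likelihood of the Box-Cox model (Gaussian after transform)
bc_log_lik <- function(x, lambda) {
  n <- length(x)
  y <- bc_transform(x, lambda)
  s2 <- sum((y - mean(y))^2) / n
  -n / 2 * log(s2) + (lambda - 1) * sum(log(x))
}

#' @export
print.box_cox <- function(x, ...) {
  cat(sprintf("Box-Cox transform: lambda = %.4f, shift = %g, n = %d\n",
              x$lambda, x$shift, length(x$values)))
  invisible(x)
}

#' @rdname box_cox
#' @param ... Unused.
#' @method tidy box_cox
#' @export
tidy.box_cox <- function(x, ...) {
  tibble(original = x$original, transformed = x$values)
}

#' @rdname box_cox
#' @method glance box_cox
#' @export
glance.box_cox <- function(x, ...) {
  tibble(lambda = x$lambda, shift = x$shift, log_lik = x$log_lik,
         n = length(x$values))
}

two_group_values <- function(data, value, group) {
  value <- tidyselect_name(data, {{ value }})
  group <- tidyselect_name(data, {{ group }})
  g <- data[[group]]
  split(data[[value]], factor(g, levels = unique(g)))
}

#' Pooled-variance unpaired t-test
#'
#' Student's two-sample t-test with pooled variance — the classical form
#' whose degrees of freedom are `n1 + n2 - 2` (4 for the 3-vs-3 designs
#' this pipeline targets), not the Welch approximation. Two-sided p.
#' Degenerate inputs follow explicit conventions: zero pooled variance
#' with equal means gives `t = 0, p = 1`; with unequal means, an
#' infinite-t marker with `p = 0`.
#'
#' @param data Data frame with one row per replicate.
#' @param value,group Columns holding the measured value and the
#'   two-level group label.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `method`,
#'   `group1`, `group2`, `mean1`, `mean2`.
#' @examples
#' d <- tibble::tibble(h_b = c(1.15, 1.01, 0.89, 0.59, 0.84, 0.73),
#'                     arm = rep(c("control", "antibiotic"), each = 3))
#' t_test_unpaired(d, h_b, arm)
#' @export
t_test_unpaired <- function(data, value, group) {
  groups <- two_group_values(data, {{ value }}, {{ group }})
  if (length(groups) != 2) {
    abort("`group` must have exactly two levels.", class = "copediv_data_error")
  }
  a <- groups[[1]]; b <- groups[[2]]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs >= 2 values.", class = "copediv_data_error")
  }
  df <- length(a) + length(b) - 2
  pooled <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / df
  if (pooled == 0) {
    stat <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
    p <- if (is.finite(stat)) 1 else 0
  } else {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  tibble(statistic = stat, df = df, p_value = p,
         method = "pooled-variance unpaired t-test",
         group1 = names(groups)[1], group2 = names(groups)[2],
         mean1 = mean(a), mean2 = mean(b))
}

#' One-way analysis of variance
#'
#' Standard fixed-effects one-way ANOVA (`F` on `k - 1` and `N - k`
#' degrees of freedom), used for between-control comparisons. All values
#' identical yields `F = 0, p = 1`.
#'
#' @inheritParams t_test_unpaired
#' @param group Column holding the (>= 2 level) group label.
#' @return A one-row tibble: `statistic`, `df1`, `df2`, `p_value`,
#'   `method`.
#' @export
one_way_anova <- function(data, value, group) {
  groups <- two_group_values(data, {{ value }}, {{ group }})
  check_anova_groups(groups)
  k <- length(groups)
  n <- sum(lengths(groups))
  if (var(unlist(groups)) == 0) {
    return(tibble(statistic = 0, df1 = k - 1L, df2 = n - k, p_value = 1,
                  method = "one-way ANOVA"))
  }
  fit <- stats::aov(value ~ group,
                    data = data.frame(value = unlist(groups),
                                      group = rep(names(groups), lengths(groups))))
  tab <- summary(fit)[[1]]
  tibble(statistic = tab[["F value"]][1], df1 = tab[["Df"]][1],
         df2 = tab[["Df"]][2], p_value = tab[["Pr(>F)"]][1],
         method = "one-way ANOVA")
}

check_anova_groups <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    abort("need >= 2 groups with >= 2 values each.",
          class = "copediv_data_error")
  }
  invisible(groups)
}

#' Tukey honest significant difference test
#'
#' All pairwise group comparisons with studentized-range p-values at the
#' one-way ANOVA's error degrees of freedom — the paper-standard follow-up
#' to a significant between-control ANOVA.
#'
#' @inheritParams one_way_anova
#' @return A tibble with one row per group pair: `group1`, `group2`,
#'   `diff` (mean of `group2` minus `group1`), `lwr`, `upr` (95% family
#'   interval), `p_value`.
#' @export
tukey_hsd <- function(data, value, group) {
  groups <- two_group_values(data, {{ value }}, {{ group }})
  check_anova_groups(groups)
  fit <- stats::aov(value ~ group,
                    data = data.frame(value = unlist(groups),
                                      group = rep(names(groups), lengths(groups))))
  tk <- stats::TukeyHSD(fit)$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tibble(group1 = vapply(pairs, `[`, character(1), 2),
         group2 = vapply(pairs, `[`, character(1), 1),
         diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
         upr = unname(tk[, "upr"]),
         p_value = pmin(pmax(unname(tk[, "p adj"]), 0), 1))
}

#' Spearman rank correlation
#'
#' Spearman's r computed as the Pearson correlation of average (midrank)
#' ranks. For small samples (`n <= 8`, the regime of six-library designs)
#' the two-sided p-value is obtained by full permutation enumeration of
#' one variable's ranks; above that, the usual t approximation on
#' `r * sqrt((n-2)/(1-r^2))` is used.
#'
#' @param data Data frame with one row per paired observation.
#' @param x,y Columns holding the paired variables.
#' @param p_method `"auto"` (exact for `n <= 8`), `"exact"`, or
#'   `"approx"`.
#' @return A one-row tibble: `estimate`, `n`, `p_value`, `p_method`,
#'   `method`. Zero rank variance in either variable gives `NA` estimate
#'   and p.
#' @examples
#' d <- tibble::tibble(di = c(0.2, 0.9, 1.1, 1.4, 1.5, 1.6),
#'                     h_b = c(0.73, 0.59, 0.84, 1.15, 0.89, 1.01))
#' spearman_cor(d, di, h_b)
#' @export
spearman_cor <- function(data, x, y, p_method = c("auto", "exact", "approx")) {
  p_method <- match.arg(p_method)
  x <- data[[tidyselect_name(data, {{ x }})]]
  y <- data[[tidyselect_name(data, {{ y }})]]
  if (length(x) != length(y) || length(x) < 3) {
    abort("need paired vectors of equal length >= 3.",
          class = "copediv_data_error")
  }
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    return(tibble(estimate = NA_real_, n = n, p_value = NA_real_,
                  p_method = NA_character_, method = "Spearman rank correlation"))
  }
  r <- cor(rx, ry)
  if (p_method == "auto") p_method <- if (n <= 8) "exact" else "approx"
  p <- if (p_method == "exact") {
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
    mean(abs(r_perm) >= abs(r) - 1e-12)
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  tibble(estimate = r, n = n, p_value = p, p_method = p_method,
         method = "Spearman rank correlation")
}

# all permutations of 1..n as rows (n! x n); fine for n <= 8
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
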