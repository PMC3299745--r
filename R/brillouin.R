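#' Natural log of n factorial
#'
#' Exact at double precision for `n <= 170` (direct product), log-gamma
#' beyond. Every Brillouin quantity in the package funnels through this so
#' the small-N clone-library scale (N ~ 30) carries no accumulation error.
#'
#' @param n Vector of non-negative integers.
#' @return `log(n!)` as a double vector.
#' @examples
#' log_factorial(c(0, 2, 30))
#' @export
log_factorial <- function(n) {
  if (length(n) == 0) return(numeric(0))
  if (anyNA(n) || any(n < 0) || any(n != floor(n))) {
    abort("`n` must contain non-negative integers.", class = "copediv_domain_error")
  }
  out <- numeric(length(n))
  small <- n <= 170
  out[small] <- vapply(n[small], function(k) log(prod(seq_len(k))), numeric(1))
  out[!small] <- lgamma(n[!small] + 1)
  out
}

check_counts <- function(counts) {
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    abort("counts must be non-negative integers.", class = "copediv_domain_error")
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    abort("counts must contain at least one positive entry.",
          class = "copediv_domain_error")
  }
  counts
}

#' Brillouin diversity of a clone-count vector
#'
#' The Brillouin index for a fully censused collection,
#' \eqn{H_B = (\ln N! - \sum_i \ln N_i!)/N}, in nats per individual
#' (natural logarithm throughout). Preferred over Shannon when the sample
#' is not random — e.g. PCR/cloning selectivity in clone libraries.
#' Zero counts are dropped; the result is invariant to their presence and
#' to the ordering of `counts`.
#'
#' @param counts Non-negative integer vector of clones per phylotype.
#' @return Brillouin diversity in nats per individual.
#' @examples
#' brillouin_diversity(c(2, 24, 2, 2))   # strongly dominated library
#' brillouin_diversity(c(15, 6, 2, 3, 4))
#' @seealso [brillouin_evenness()], [diversity_table()]
#' @export
brillouin_diversity <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  (log_factorial(n) - sum(log_factorial(counts))) / n
}

#' Minimum Brillouin diversity at fixed N and S
#'
#' Diversity of the most uneven composition of `n` individuals into `s`
#' non-empty classes: one class holds `n - s + 1`, the rest one each, so
#' \eqn{H_{min} = (\ln N! - \ln (N-S+1)!)/N}.
#'
#' @param n Total individuals (N >= 1).
#' @param s Number of classes (1 <= S <= N).
#' @return Minimum attainable Brillouin diversity, nats per individual.
#' @export
brillouin_min <- function(n, s) {
  check_n_s(n, s)
  (log_factorial(n) - log_factorial(n - s + 1)) / n
}

#' Maximum Brillouin diversity at fixed N and S
#'
#' Diversity of the most even composition: with `X = floor(N/S)`,
#' `Y = X + 1` and remainder `r = N - S*X`, the maximal partition has
#' `S - r` classes of size X and `r` of size Y, giving
#' \eqn{H_{max} = (\ln N! - [(S-r)\ln X! + r\ln Y!])/N}.
#'
#' @inheritParams brillouin_min
#' @param partition Also return the achieving partition? If `TRUE` the
#'   result is a list with elements `h_max` and `partition` (a
#'   [max_even_partition()]).
#' @return The maximum Brillouin diversity, or a list when
#'   `partition = TRUE`.
#' @examples
#' brillouin_max(30, 4)
#' brillouin_max(30, 4, partition = TRUE)$partition
#' @export
brillouin_max <- function(n, s, partition = FALSE) {
  check_n_s(n, s)
  p <- max_even_partition(n, s)
  h <- (log_factorial(n) -
          ((s - p$r) * log_factorial(p$x) + p$r * log_factorial(p$y))) / n
  if (partition) list(h_max = h, partition = p) else h
}

#' Maximal-evenness partition of N individuals into S classes
#'
#' @inheritParams brillouin_min
#' @return A list with `x` (floor of N/S), `y` (`x + 1`), `r` (remainder
#'   `N - S*x`) and `composition`, the integer multiset with `S - r` parts
#'   equal to `x` and `r` parts equal to `y`.
#' @export
max_even_partition <- function(n, s) {
  check_n_s(n, s)
  x <- n %/% s
  r <- n - s * x
  list(x = x, y = x + 1L, r = r,
       composition = c(rep(x + 1L, r), rep(x, s - r)))
}

check_n_s <- function(n, s) {
  if (length(n) != 1 || length(s) != 1 || anyNA(c(n, s)) ||
      n != floor(n) || s != floor(s) || n < 1 || s < 1 || s > n) {
    abort("need integers 1 <= s <= n.", class = "copediv_domain_error")
  }
  invisible(NULL)
}

#' Brillouin diversity, bounds and relative evenness
#'
#' Bundles the Brillouin diversity of a count vector with its minimum and
#' maximum attainable values at the observed N and S, and the relative
#' evenness \eqn{V = (H_B - H_{min})/(H_{max} - H_{min})}. For a
#' single-phylotype library (S = 1) the bounds coincide and `v` is `NA`
#' rather than a silent 0/0: a defined-looking value there would corrupt
#' downstream rank correlations.
#'
#' @inheritParams brillouin_diversity
#' @return An object of class `"brillouin"`: a list with `n`, `s`, `h_b`,
#'   `h_min`, `h_max`, `v` and `partition` (the maximal-evenness
#'   partition). Use [tidy()] for a one-row tibble.
#' @examples
#' tidy(brillouin_evenness(c(15, 6, 2, 3, 4)))
#' @export
brillouin_evenness <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  s <- length(counts)
  h_b <- brillouin_diversity(counts)
  h_min <- brillouin_min(n, s)
  mx <- brillouin_max(n, s, partition = TRUE)
  v <- if (mx$h_max - h_min > 0) (h_b - h_min) / (mx$h_max - h_min) else NA_real_
  structure(
    list(n = n, s = s, h_b = h_b, h_min = h_min, h_max = mx$h_max,
         v = v, partition = mx$partition),
    class = "brillouin"
  )
}

#' @export
print.brillouin <- function(x, ...) {
  cat("Brillouin diversity (censored community)\n")
  cat(sprintf("  N = %d clones, S = %d phylotypes\n", x$n, x$s))
  cat(sprintf("  H_B = %.4f nats/individual  [H_min = %.4f, H_max = %.4f]\n",
              x$h_b, x$h_min, x$h_max))
  if (is.na(x$v)) {
    cat("  V undefined (single phylotype: H_max = H_min)\n")
  } else {
    cat(sprintf("  V = %.4f\n", x$v))
  }
  invisible(x)
}

#' @rdname brillouin_evenness
#' @param x A `"brillouin"` object.
#' @param ... Unused.
#' @method tidy brillouin
#' @export
tidy.brillouin <- function(x, ...) {
  tibble(n = x$n, s = x$s, h_b = x$h_b, h_min = x$h_min,
         h_max = x$h_max, v = x$v)
}

#' @rdname brillouin_evenness
#' @method glance brillouin
#' @export
glance.brillouin <- function(x, ...) tidy(x)

#' Per-library diversity table from clone counts
#'
#' The workhorse for Table-2-style reporting: takes a long count table and
#' returns one row per library with N, S, Brillouin diversity, its bounds
#' and relative evenness. Computation is at full precision; round only at
#' the reporting layer.
#'
#' @param data Data frame with one row per (phylotype, library) cell.
#' @param library,phylotype,count Column names (bare or character) holding
#'   the library label, phylotype label and clone count. Defaults match
#'   [read_count_table()] output.
#' @return A tibble with columns `library`, `n`, `s`, `h_b`, `h_min`,
#'   `h_max`, `v`, one row per library, in first-appearance order.
#' @examples
#' tab <- read_count_table(copediv_example("table1_counts.tsv"))
#' diversity_table(tab)
#' @export
diversity_table <- function(data, library = "library", phylotype = "phylotype",
                            count = "count") {
  library <- tidyselect_name(data, {{ library }})
  count <- tidyselect_name(data, {{ count }})
  data |>
    dplyr::rename(.library = dplyr::all_of(library),
                  .count = dplyr::all_of(count)) |>
    dplyr::mutate(.library = factor(.data$.library,
                                    levels = unique(.data$.library))) |>
    dplyr::group_by(.library) |>
    dplyr::summarise(res = list(tidy(brillouin_evenness(.data$.count))),
                     .groups = "drop") |>
    tidyr::unnest("res") |>
    dplyr::rename(library = ".library") |>
    dplyr::mutate(library = as.character(.data$library))
}

# resolve a column given bare name or string
tidyselect_name <- function(data, col) {
  nm <- rlang::as_name(rlang::enquo(col))
  if (!nm %in% names(data)) {
    # the quo may already hold a string
    val <- tryCatch(rlang::eval_tidy(rlang::enquo(col)), error = function(e) NULL)
    if (is.character(val) && length(val) == 1 && val %in% names(data)) return(val)
    abort(sprintf("column `%s` not found.", nm), class = "copediv_data_error")
  }
  nm
}
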