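#' Copepod development endpoints per replicate
#'
#' Scores each replicate well of a stage census with the three endpoint
#' metrics used in copepod ecotoxicology:
#'
#' * survivorship: `100 * (n_nauplii + n_copepodites) / n_start` (%);
#' * `%Copepodites`: `100 * n_copepodites / survivors` (%), `NA` when no
#'   animal survived;
#' * development index (DI): the stage-value mean over staged individuals,
#'   with nauplii scored 1 and copepodites 2. Under the default
#'   `"all_staged"` convention dead individuals are staged with value 0
#'   and the denominator is `n_start`, so DI folds survival and
#'   metamorphosis success into one number in `[0, 2]`; under
#'   `"survivors_only"` the dead are excluded and DI lies in `[1, 2]`
#'   (`NA` with no survivors).
#'
#' @param data Stage-census tibble with columns `n_start`, `n_nauplii`,
#'   `n_copepodites` (see [read_stage_census()]); other columns pass
#'   through.
#' @param di_convention How the development index treats dead individuals.
#' @return The input tibble with `survivorship`, `pct_copepodites` and
#'   `di` columns added.
#' @examples
#' census <- tibble::tibble(replicate = "r1", treatment = "control",
#'                          n_start = 50, n_nauplii = 20, n_copepodites = 20)
#' development_endpoints(census)
#' @export
development_endpoints <- function(data,
                                  di_convention = c("all_staged", "survivors_only")) {
  di_convention <- match.arg(di_convention)
  validate_census(data)
  dplyr::mutate(
    as_tibble(data),
    survivorship = survivorship(.data$n_start, .data$n_nauplii, .data$n_copepodites),
    pct_copepodites = percent_copepodites(.data$n_nauplii, .data$n_copepodites),
    di = development_index(.data$n_start, .data$n_nauplii, .data$n_copepodites,
                           convention = di_convention)
  )
}

#' @rdname development_endpoints
#' @param n_start,n_nauplii,n_copepodites Integer vectors: animals at the
#'   start, and nauplii / copepodites alive at termination.
#' @export
survivorship <- function(n_start, n_nauplii, n_copepodites) {
  if (any(n_start <= 0)) {
    abort("n_start must be positive.", class = "copediv_domain_error")
  }
  100 * (n_nauplii + n_copepodites) / n_start
}

#' @rdname development_endpoints
#' @export
percent_copepodites <- function(n_nauplii, n_copepodites) {
  survivors <- n_nauplii + n_copepodites
  ifelse(survivors > 0, 100 * n_copepodites / survivors, NA_real_)
}

#' @rdname development_endpoints
#' @param convention `"all_staged"` (dead staged at value 0, denominator
#'   `n_start`) or `"survivors_only"`.
#' @export
development_index <- function(n_start, n_nauplii, n_copepodites,
                              convention = c("all_staged", "survivors_only")) {
  convention <- match.arg(convention)
  if (any(n_start <= 0)) {
    abort("n_start must be positive.", class = "copediv_domain_error")
  }
  staged_sum <- 1 * n_nauplii + 2 * n_copepodites
  if (convention == "all_staged") {
    staged_sum / n_start
  } else {
    survivors <- n_nauplii + n_copepodites
    ifelse(survivors > 0, staged_sum / survivors, NA_real_)
  }
}

#' Per-treatment endpoint summary (median and range)
#'
#' The replicate-level endpoints condensed the way development figures
#' report them: median and observed range per treatment.
#'
#' @param data Output of [development_endpoints()] with a `treatment`
#'   column.
#' @return A tibble with one row per (treatment, endpoint): `median`,
#'   `min`, `max`, `n_replicates`.
#' @export
endpoint_summary <- function(data) {
  data |>
    tidyr::pivot_longer(c("survivorship", "pct_copepodites", "di"),
                        names_to = "endpoint", values_to = "value") |>
    dplyr::group_by(.data$treatment, .data$endpoint) |>
    dplyr::summarise(
      median = median(.data$value, na.rm = TRUE),
      min = suppressWarnings(min(.data$value, na.rm = TRUE)),
      max = suppressWarnings(max(.data$value, na.rm = TRUE)),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}
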