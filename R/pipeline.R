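#' Run configuration for the full analysis
#'
#' @param counts_path TSV count table (see [read_count_table()]); `NULL`
#'   to derive counts from clone FASTA input or a synthetic scenario.
#' @param clones_path Clone FASTA with `library|id` headers; binned at
#'   `threshold` when given.
#' @param references_path Optional reference FASTA for phylotype naming.
#' @param census_path Stage-census TSV; `NULL` to simulate from the
#'   scenario.
#' @param scenario A [synthetic_scenario()] used to synthesise any input
#'   not supplied as a file.
#' @param control_libraries,antibiotic_libraries Library labels of the two
#'   arms for the diversity t-tests (defaults: the study's solvent
#'   controls and antibiotic treatments).
#' @param threshold Identity threshold for binning.
#' @param di_convention Development-index convention, see
#'   [development_endpoints()].
#' @param box_cox_lambda Lambda policy for endpoint transforms (`"auto"`
#'   or a number).
#' @param out_dir Output directory; `NULL` suppresses file output.
#' @param seed Seed for any synthetic stage.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(counts_path = NULL, clones_path = NULL,
                       references_path = NULL, census_path = NULL,
                       scenario = synthetic_scenario(seed = seed),
                       control_libraries = c("SS", "Ac", "DMSO"),
                       antibiotic_libraries = c("Cipr", "Sulf", "Trim"),
                       threshold = 0.97,
                       di_convention = "all_staged",
                       box_cox_lambda = "auto",
                       out_dir = NULL, seed = 1L) {
  for (p in c(counts_path, clones_path, references_path, census_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("input path does not exist: %s", p),
            class = "copediv_config_error")
    }
  }
  if (threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1].", class = "copediv_config_error")
  }
  structure(list(counts_path = counts_path, clones_path = clones_path,
                 references_path = references_path, census_path = census_path,
                 scenario = scenario,
                 control_libraries = control_libraries,
                 antibiotic_libraries = antibiotic_libraries,
                 threshold = threshold, di_convention = di_convention,
                 box_cox_lambda = box_cox_lambda,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

provenance_header <- function(config) {
  fields <- c(config[c("threshold", "di_convention", "box_cox_lambda", "seed")],
              list(scenario_seed = config$scenario$seed))
  c(sprintf("copediv %s", as.character(utils::packageVersion("copediv"))),
    paste0(names(fields), " = ", vapply(fields, function(x)
      paste(format(x), collapse = ","), character(1))))
}

#' Run the full clone-library / development analysis
#'
#' Orchestrates every stage end to end and (optionally) writes the four
#' report tables:
#'
#' 1. `count_table.tsv` — phylotype-by-library counts and frequencies;
#' 2. `diversity_table.tsv` — per-library N, S, Brillouin diversity,
#'    bounds and evenness;
#' 3. `endpoint_table.tsv` — per-replicate survivorship, %Copepodites and
#'    DI, plus a per-treatment median/range summary;
#' 4. `stats_report.tsv` — control-vs-antibiotic pooled t-tests on H_B
#'    and V, Box-Cox-transformed endpoint comparisons, between-control
#'    ANOVA + Tukey HSD, and Spearman correlations of DI against H_B
#'    and V.
#'
#' Count input is resolved in precedence order: a counts TSV, a clone
#' FASTA (binned at the configured threshold), else a synthetic scenario.
#' Census input: a census TSV, else simulation from the scenario. With a
#' fixed seed the result is fully reproducible.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `counts`, `diversity`, `endpoints`,
#'   `endpoint_summary`, `stats`, and (when sequences were involved)
#'   `clones`.
#' @export
run_full_analysis <- function(config = run_config()) {
  clones <- NULL
  if (!is.null(config$counts_path)) {
    counts <- read_count_table(config$counts_path)
  } else {
    pcfg <- phylotyping_config(threshold = config$threshold)
    if (!is.null(config$clones_path)) {
      clones <- read_clone_fasta(config$clones_path)
    } else {
      sim <- simulate_clone_libraries(config$scenario)
      clones <- sim$clones
    }
    clones <- bin_phylotypes(clones, pcfg)
    refs <- if (!is.null(config$references_path)) {
      read_clone_fasta(config$references_path)
    } else if (is.null(config$clones_path)) {
      simulate_clone_libraries(config$scenario)$references
    }
    if (!is.null(refs)) clones <- assign_names(clones, refs, pcfg)
    counts <- count_table(clones)
  }

  diversity <- diversity_table(counts)

  census <- if (!is.null(config$census_path)) {
    read_stage_census(config$census_path)
  } else {
    simulate_experiment(config$scenario)
  }
  endpoints <- development_endpoints(census, di_convention = config$di_convention)
  summary_tbl <- endpoint_summary(endpoints)

  stats_tbl <- stats_report(diversity, endpoints,
                            control_libraries = config$control_libraries,
                            antibiotic_libraries = config$antibiotic_libraries,
                            box_cox_lambda = config$box_cox_lambda)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- provenance_header(config)
    write_count_table(counts, file.path(config$out_dir, "count_table.tsv"), hdr)
    write_tsv_with_header(diversity,
                          file.path(config$out_dir, "diversity_table.tsv"), hdr)
    write_tsv_with_header(endpoints,
                          file.path(config$out_dir, "endpoint_table.tsv"), hdr)
    write_tsv_with_header(summary_tbl,
                          file.path(config$out_dir, "endpoint_summary.tsv"), hdr)
    write_tsv_with_header(stats_tbl,
                          file.path(config$out_dir, "stats_report.tsv"), hdr)
  }
  invisible(list(counts = counts, diversity = diversity, clones = clones,
                 endpoints = endpoints, endpoint_summary = summary_tbl,
                 stats = stats_tbl))
}

#' Statistical report linking diversity and development
#'
#' The full statistical layer on computed tables: pooled-variance t-tests
#' of control vs antibiotic libraries on Brillouin diversity and evenness;
#' per-endpoint control-vs-antibiotic t-tests and the between-control
#' one-way ANOVA with Tukey HSD on Box-Cox transformed endpoints; and
#' Spearman rank correlations (non-transformed, per-treatment means) of
#' the development index against H_B and V. Comparisons that cannot run
#' (too few replicates, undefined evenness) come back as explicit
#' `skipped` rows rather than being dropped silently.
#'
#' @param diversity Output of [diversity_table()].
#' @param endpoints Output of [development_endpoints()]; `treatment`
#'   labels must match the diversity `library` labels for the
#'   correlations.
#' @param control_libraries,antibiotic_libraries Library labels of the two
#'   arms.
#' @param box_cox_lambda Lambda policy for endpoint transforms.
#' @return A tibble with columns `comparison`, `method`, `statistic`,
#'   `df`, `p_value`, `note`.
#' @export
stats_report <- function(diversity, endpoints,
                         control_libraries = c("SS", "Ac", "DMSO"),
                         antibiotic_libraries = c("Cipr", "Sulf", "Trim"),
                         box_cox_lambda = "auto") {
  rows <- list()
  add <- function(comparison, method, statistic = NA_real_, df = NA_character_,
                  p_value = NA_real_, note = "") {
    rows[[length(rows) + 1]] <<- tibble(
      comparison = comparison, method = method, statistic = statistic,
      df = df, p_value = p_value, note = note)
  }

  arm_tbl <- diversity |>
    dplyr::filter(.data$library %in% c(control_libraries, antibiotic_libraries)) |>
    dplyr::mutate(arm = ifelse(.data$library %in% control_libraries,
                               "control", "antibiotic"))
  for (idx in c("h_b", "v")) {
    d <- arm_tbl[!is.na(arm_tbl[[idx]]), ]
    if (length(unique(d$arm)) == 2 && all(table(d$arm) >= 2)) {
      tt <- t_test_unpaired(d, !!rlang::sym(idx), "arm")
      add(paste0("control vs antibiotic: ", idx), tt$method, tt$statistic,
          as.character(tt$df), tt$p_value)
    } else {
      add(paste0("control vs antibiotic: ", idx), "pooled-variance unpaired t-test",
          note = "skipped: fewer than 2 defined values per arm")
    }
  }

  trt_col <- endpoints$treatment
  for (ep in c("survivorship", "pct_copepodites", "di")) {
    vals <- endpoints[[ep]]
    ok <- !is.na(vals)
    d <- tibble(value = vals[ok], treatment = trt_col[ok]) |>
      dplyr::mutate(arm = dplyr::case_when(
        .data$treatment %in% control_libraries ~ "control",
        .data$treatment %in% antibiotic_libraries ~ "antibiotic",
        TRUE ~ NA_character_)) |>
      dplyr::filter(!is.na(.data$arm))
    if (length(unique(d$arm)) == 2 && all(table(d$arm) >= 2)) {
      bc <- box_cox(d$value, lambda = box_cox_lambda)
      d$transformed <- bc$values
      tt <- t_test_unpaired(d, "transformed", "arm")
      add(paste0("control vs antibiotic: ", ep),
          paste0(tt$method, " (Box-Cox, lambda = ", signif(bc$lambda, 3), ")"),
          tt$statistic, as.character(tt$df), tt$p_value)
    } else {
      add(paste0("control vs antibiotic: ", ep), "pooled-variance unpaired t-test",
          note = "skipped: fewer than 2 values per arm")
    }
    ctrl <- d[d$arm == "control", ]
    if (length(unique(ctrl$treatment)) >= 2 && all(table(ctrl$treatment) >= 2)) {
      bc <- box_cox(ctrl$value, lambda = box_cox_lambda)
      ctrl$transformed <- bc$values
      an <- one_way_anova(ctrl, "transformed", "treatment")
      add(paste0("between controls: ", ep),
          paste0(an$method, " (Box-Cox, lambda = ", signif(bc$lambda, 3), ")"),
          an$statistic, paste0(an$df1, ",", an$df2), an$p_value)
      tk <- tukey_hsd(ctrl, "transformed", "treatment")
      for (i in seq_len(nrow(tk))) {
        add(paste0("between controls: ", ep, ": ", tk$group2[i], " vs ",
                   tk$group1[i]),
            "Tukey HSD", tk$diff[i], paste0(an$df1, ",", an$df2), tk$p_value[i])
      }
    } else {
      add(paste0("between controls: ", ep), "one-way ANOVA",
          note = "skipped: fewer than 2 control groups with 2+ replicates")
    }
  }

  # Spearman: per-treatment mean DI against library diversity (non-transformed)
  di_means <- endpoints |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(di = mean(.data$di, na.rm = TRUE), .groups = "drop")
  joined <- dplyr::inner_join(di_means, diversity,
                              by = c(treatment = "library"))
  for (idx in c("h_b", "v")) {
    d <- joined[!is.na(joined[[idx]]) & !is.na(joined$di), ]
    if (nrow(d) >= 3) {
      sp <- spearman_cor(d, "di", idx)
      add(paste0("DI vs ", idx), paste0(sp$method, " (", sp$p_method, " p)"),
          sp$estimate, as.character(sp$n), sp$p_value)
    } else {
      add(paste0("DI vs ", idx), "Spearman rank correlation",
          note = "skipped: fewer than 3 paired treatments")
    }
  }
  dplyr::bind_rows(rows)
}
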