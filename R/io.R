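#' Read a phylotype-by-library count table
#'
#' Parses the wide TSV dialect used for clone-library count tables: first
#' column the phylotype name, one column per library, integer cells, with
#' `"nd"` (not detected) or `0` marking absence. Comment lines starting
#' with `#` are skipped.
#'
#' @param path Path to a TSV file.
#' @return A long tibble with columns `phylotype`, `library`, `count`
#'   (absences as 0), in file order.
#' @examples
#' read_count_table(copediv_example("table1_counts.tsv"))
#' @export
read_count_table <- function(path) {
  wide <- readr::read_tsv(path, comment = "#", col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  if (ncol(wide) < 2) {
    abort("count table needs a phylotype column plus >= 1 library column.",
          class = "copediv_data_error")
  }
  names(wide)[1] <- "phylotype"
  long <- tidyr::pivot_longer(wide, -"phylotype", names_to = "library",
                              values_to = "count",
                              values_transform = as.character)
  long$count[is.na(long$count) | tolower(long$count) == "nd"] <- "0"
  count <- suppressWarnings(as.numeric(long$count))
  if (anyNA(count) || any(count < 0) || any(count != floor(count))) {
    abort("count cells must be non-negative integers or 'nd'.",
          class = "copediv_data_error")
  }
  long$count <- as.integer(count)
  long |>
    dplyr::mutate(library = factor(.data$library, levels = unique(.data$library)),
                  phylotype = factor(.data$phylotype, levels = unique(.data$phylotype))) |>
    dplyr::arrange(.data$library, .data$phylotype) |>
    dplyr::mutate(dplyr::across(c("phylotype", "library"), as.character))
}

#' Write a long count table in the wide TSV dialect
#'
#' Inverse of [read_count_table()]: zero counts are rendered `"nd"`.
#'
#' @param data Long tibble with `phylotype`, `library`, `count` columns.
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed provenance
#'   lines written before the table.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(data, path, header = NULL) {
  wide <- data |>
    dplyr::select("phylotype", "library", "count") |>
    dplyr::mutate(count = ifelse(.data$count == 0, "nd",
                                 as.character(.data$count))) |>
    tidyr::pivot_wider(names_from = "library", values_from = "count",
                       values_fill = "nd")
  write_tsv_with_header(wide, path, header)
}

write_tsv_with_header <- function(data, path, header = NULL) {
  if (!is.null(header)) {
    writeLines(paste0("# ", header), path)
    readr::write_tsv(data, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_tsv(data, path, progress = FALSE)
  }
  invisible(path)
}

#' Read clone or reference sequences from FASTA
#'
#' Clone headers may carry a library prefix in the form
#' `library|clone_id`; anything without a `|` gets an `NA` library (fine
#' for reference sets). Sequences are uppercased.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A tibble with columns `id`, `library`, `residues`.
#' @export
read_clone_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  has_lib <- grepl("|", ids, fixed = TRUE)
  tibble(
    id = ifelse(has_lib, sub("^[^|]*\\|", "", ids), ids),
    library = ifelse(has_lib, sub("\\|.*$", "", ids), NA_character_),
    residues = toupper(as.character(set))
  )
}

#' Write sequences to FASTA
#'
#' @param data Tibble with `id`, `residues` and optionally `library`
#'   columns; a non-`NA` library becomes a `library|id` header prefix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clone_fasta <- function(data, path) {
  hdr <- if ("library" %in% names(data) && !all(is.na(data$library))) {
    ifelse(is.na(data$library), data$id, paste0(data$library, "|", data$id))
  } else data$id
  set <- Biostrings::DNAStringSet(data$residues)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a copepod stage-census table
#'
#' TSV with columns `replicate`, `treatment`, `n_start`, `n_nauplii`,
#' `n_copepodites` (one row per replicate well).
#'
#' @param path Path to a TSV file.
#' @return A tibble with the census columns, validated
#'   (`n_nauplii + n_copepodites <= n_start`, all non-negative).
#' @export
read_stage_census <- function(path) {
  census <- readr::read_tsv(path, comment = "#", col_types = readr::cols(),
                            progress = FALSE, show_col_types = FALSE)
  needed <- c("replicate", "treatment", "n_start", "n_nauplii", "n_copepodites")
  if (!all(needed %in% names(census))) {
    abort(paste("stage census needs columns:", paste(needed, collapse = ", ")),
          class = "copediv_data_error")
  }
  validate_census(census)
  as_tibble(census)
}

validate_census <- function(census) {
  num <- census[c("n_start", "n_nauplii", "n_copepodites")]
  if (anyNA(num) || any(num < 0) ||
      any(census$n_nauplii + census$n_copepodites > census$n_start)) {
    abort("invalid stage census: counts must be non-negative and survivors cannot exceed n_start.",
          class = "copediv_data_error")
  }
  invisible(census)
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata`; with no argument,
#'   lists the available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' copediv_example()
#' @export
copediv_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "copediv"))
  } else {
    path <- system.file("extdata", file, package = "copediv")
    if (!nzchar(path)) abort(sprintf("no packaged file '%s'.", file),
                             class = "copediv_data_error")
    path
  }
}
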