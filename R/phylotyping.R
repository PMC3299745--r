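#' Alignment scoring configuration for phylotype binning
#'
#' Scores for the global (Needleman-Wunsch, affine-gap) alignment behind
#' [pairwise_identity()]. Gap penalties are magnitudes. The ambiguity code
#' `N` scores — and counts — as a mismatch against everything, a
#' deliberately conservative choice for an identity threshold.
#'
#' @param threshold Identity fraction at or above which two sequences fall
#'   in one phylotype (default 0.97, the conventional 16S species-level
#'   cutoff).
#' @param match,mismatch,gap_open,gap_extend Alignment scores.
#' @return A list of class `"phylotyping_config"`.
#' @export
phylotyping_config <- function(threshold = 0.97, match = 1, mismatch = -1,
                               gap_open = 2, gap_extend = 0.5) {
  if (threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1].", class = "copediv_config_error")
  }
  structure(list(threshold = threshold, match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "phylotyping_config")
}

substitution_matrix <- function(config) {
  bases <- c("A", "C", "G", "T", "N")
  mat <- matrix(config$mismatch, 5, 5, dimnames = list(bases, bases))
  diag(mat) <- config$match
  mat["N", "N"] <- config$mismatch  # N never self-matches
  mat
}

align_pair <- function(a, b, config) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = substitution_matrix(config),
    gapOpening = config$gap_open, gapExtension = config$gap_extend
  )
}

#' Percent identity between two sequences
#'
#' Globally aligns two nucleotide sequences (affine gap penalties) and
#' returns the fraction of matching columns over all alignment columns,
#' excluding terminal-gap columns — clone inserts are partial genes with
#' ragged ends, which should not be charged as differences. `N` columns
#' count as mismatches. Symmetric in its arguments.
#'
#' @param a,b Nucleotide strings over `A`, `C`, `G`, `T`, `N`.
#' @param config A [phylotyping_config()].
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("ACGT", "ACGA")          # 0.75
#' pairwise_identity("ACGTACGT", "ACGACGT")   # one internal gap: 7/8
#' @export
pairwise_identity <- function(a, b, config = phylotyping_config()) {
  check_sequence(a)
  check_sequence(b)
  aln <- align_pair(a, b, config)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  aligned_identity(pa, pb)
}

aligned_identity <- function(pa, pb) {
  gap_a <- pa == "-"
  gap_b <- pb == "-"
  ngap <- !(gap_a | gap_b)
  # terminal gap columns: before the first / after the last column where
  # both sequences have residues
  inner <- which(ngap)
  if (length(inner) == 0) return(0)
  keep <- seq(min(inner), max(inner))
  matches <- sum(pa[keep] == pb[keep] & ngap[keep] & pa[keep] %in% c("A", "C", "G", "T"))
  matches / length(keep)
}

check_sequence <- function(x) {
  if (!is.character(x) || length(x) != 1 || !nzchar(x)) {
    abort("sequences must be non-empty strings.", class = "copediv_domain_error")
  }
  if (grepl("[^ACGTN]", x)) {
    abort("sequences may only contain A, C, G, T, N.",
          class = "copediv_domain_error")
  }
  invisible(x)
}

#' Bin clone sequences into phylotypes by greedy centroid clustering
#'
#' Sequences are processed in a deterministic order (descending length,
#' ties by id); each joins the first existing cluster whose representative
#' it matches at `>= threshold` identity, otherwise it founds a new
#' cluster and becomes its representative. The result is a partition of
#' the input and is reproducible for a fixed input.
#'
#' @param data Tibble of clones with columns `id`, `residues` and
#'   (optionally) `library`. Ids must be unique within a library.
#' @param config A [phylotyping_config()]; `config$threshold` is the
#'   identity cutoff.
#' @return The input tibble with two added columns: `phylotype_id`
#'   (`"pt1"`, `"pt2"`, ... in founding order) and `representative` (id of
#'   the cluster centroid). Zero-row input yields a zero-row tibble.
#' @examples
#' clones <- tibble::tibble(
#'   id = c("c1", "c2", "c3"),
#'   residues = c(strrep("ACGT", 25), strrep("ACGT", 25), strrep("TTGA", 25))
#' )
#' bin_phylotypes(clones)
#' @export
bin_phylotypes <- function(data, config = phylotyping_config()) {
  data <- as_tibble(data)
  if (!all(c("id", "residues") %in% names(data))) {
    abort("`data` needs `id` and `residues` columns.",
          class = "copediv_data_error")
  }
  if (!"library" %in% names(data)) data$library <- NA_character_
  if (anyDuplicated(data[c("library", "id")])) {
    abort("clone ids must be unique within a library.",
          class = "copediv_data_error")
  }
  if (nrow(data) == 0) {
    return(dplyr::mutate(data, phylotype_id = character(0),
                         representative = character(0)))
  }
  vapply(data$residues, check_sequence, character(1))
  ord <- order(-nchar(data$residues), data$id)
  reps <- character(0)      # representative residues, founding order
  rep_ids <- character(0)
  assignment <- integer(nrow(data))
  for (i in ord) {
    seq_i <- data$residues[i]
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (pairwise_identity(seq_i, reps[k], config) >= config$threshold) {
        assignment[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, seq_i)
      rep_ids <- c(rep_ids, data$id[i])
      assignment[i] <- length(reps)
    }
  }
  data$phylotype_id <- paste0("pt", assignment)
  data$representative <- rep_ids[assignment]
  data
}

#' Name phylotypes by their closest reference sequence
#'
#' Assigns each phylotype the label of the reference with highest identity
#' to its representative (ties broken lexicographically by reference id),
#' recording the identity so that below-threshold best hits — named only
#' at a coarser taxonomic level in practice — stay visible.
#'
#' @param data Clone tibble as returned by [bin_phylotypes()].
#' @param references Tibble of reference sequences with `id`, `residues`.
#' @param config A [phylotyping_config()].
#' @return `data` with added columns `name` and `name_identity`.
#' @export
assign_names <- function(data, references, config = phylotyping_config()) {
  if (is.null(references) || nrow(references) == 0) {
    abort("reference set must be non-empty.", class = "copediv_config_error")
  }
  refs <- references[order(references$id), ]
  rep_tbl <- data |>
    dplyr::distinct(.data$phylotype_id, .data$representative) |>
    dplyr::left_join(dplyr::select(data, "id", "residues") |> dplyr::distinct(),
                     by = c(representative = "id"))
  best <- purrr::map(rep_tbl$residues, function(seq_r) {
    ident <- vapply(refs$residues, function(ref)
      pairwise_identity(seq_r, ref, config), numeric(1))
    k <- which.max(ident)  # refs sorted by id, so first max = lexicographic tie-break
    list(name = refs$id[k], name_identity = ident[k])
  })
  rep_tbl$name <- vapply(best, `[[`, character(1), "name")
  rep_tbl$name_identity <- vapply(best, `[[`, numeric(1), "name_identity")
  dplyr::left_join(data,
                   dplyr::select(rep_tbl, "phylotype_id", "name", "name_identity"),
                   by = "phylotype_id")
}

#' Phylotype-by-library count and frequency table
#'
#' Tallies binned clones into a long count table with per-library
#' frequencies. Frequencies are `100 * count / library total`, rounded to
#' the nearest whole number (half away from zero) at the reporting layer;
#' zero counts render as `"nd"` in [write_count_table()] output.
#'
#' @param data Clone tibble from [bin_phylotypes()] (optionally through
#'   [assign_names()]); every clone must carry a `library` label.
#' @param libraries Optional character vector fixing the library order
#'   (and catching unknown labels); defaults to first-appearance order.
#' @return A tibble with `phylotype`, `library`, `count`, `frequency`,
#'   complete over all phylotype-library pairs. The `phylotype` column
#'   uses the assigned `name` when present, else `phylotype_id`.
#' @export
count_table <- function(data, libraries = NULL) {
  if (anyNA(data$library)) {
    abort("every clone needs a library label.", class = "copediv_data_error")
  }
  if (is.null(libraries)) libraries <- unique(data$library)
  if (!all(data$library %in% libraries)) {
    abort("unknown library label in data.", class = "copediv_data_error")
  }
  data$phylotype <- if ("name" %in% names(data)) data$name else data$phylotype_id
  counts <- data |>
    dplyr::count(.data$phylotype, .data$library, name = "count") |>
    tidyr::complete(phylotype = unique(data$phylotype),
                    library = libraries,
                    fill = list(count = 0L)) |>
    dplyr::mutate(library = factor(.data$library, levels = libraries)) |>
    dplyr::group_by(.data$library) |>
    dplyr::mutate(frequency = round_half_away(100 * .data$count /
                                                sum(.data$count))) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$library, .data$phylotype) |>
    dplyr::mutate(library = as.character(.data$library))
  counts
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
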