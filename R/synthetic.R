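#' Reconciled clone-library composition profiles
#'
#' The per-library phylotype compositions of the six-library copepod
#' study design (three antibiotic arms, three solvent controls, 30 clones
#' each), as clone-count vectors over the eight community members. These
#' are the packaged `table1_counts.tsv` counts in matrix form and serve as
#' the default `community_profiles` of [synthetic_scenario()].
#'
#' @return An 8 x 6 integer matrix (phylotype x library).
#' @export
study_count_matrix <- function() {
  m <- matrix(
    c( 2,  2,  3, 15, 18, 19,   # Hydrogenophaga
       0,  0,  0,  6,  3,  4,   # Acidovorax
       0,  0,  0,  2,  2,  2,   # Betaproteobacterium
       0,  0,  0,  3,  2,  0,   # Bacteroidetes
       0,  0,  0,  4,  5,  5,   # Cyanobacterium
      24, 20, 22,  0,  0,  0,   # Cardinium
       2,  4,  2,  0,  0,  0,   # Phyllobacteriaceae
       2,  4,  3,  0,  0,  0),  # Achromobacter
    nrow = 8, byrow = TRUE,
    dimnames = list(
      c("Hydrogenophaga", "Acidovorax", "Betaproteobacterium",
        "Bacteroidetes", "Cyanobacterium", "Cardinium",
        "Phyllobacteriaceae", "Achromobacter"),
      c("Cipr", "Sulf", "Trim", "SS", "Ac", "DMSO")
    )
  )
  storage.mode(m) <- "integer"
  m
}

default_stage_model <- function() {
  tibble(
    treatment = c("Cipr", "Sulf", "Trim", "SS", "Ac", "DMSO"),
    p_survive = c(0.85, 0.85, 0.50, 0.90, 0.90, 0.90),
    p_metamorphose = c(0.40, 0.60, 0.00, 0.65, 0.85, 0.45)
  )
}

#' Synthetic study scenario
#'
#' Bundles every knob of the synthetic-data generator: divergent reference
#' ribotypes, clone libraries with treatment-dependent composition and
#' per-base sequencing/cloning error, and replicate copepod stage censuses
#' with treatment-dependent survival and metamorphosis. Defaults emulate
#' the six-library, 30-clone, 3-replicate, 50-nauplii study design, with
#' community profiles taken from [study_count_matrix()] and a stage model
#' in which one antibiotic arm arrests metamorphosis completely.
#'
#' @param n_references Number of reference ribotypes (default 8).
#' @param min_divergence Minimum pairwise divergence between references as
#'   a fraction (default 0.04, i.e. all pairwise identities <= 0.96 —
#'   comfortably below a 0.97 binning threshold).
#' @param seq_length Reference length in bases (default 900, a partial
#'   16S fragment).
#' @param community_profiles Phylotype x library matrix of clone counts or
#'   proportions; column names are the library labels.
#' @param clones_per_library Clones drawn per library in multinomial mode
#'   (default 30).
#' @param per_base_error Per-base substitution probability applied to each
#'   clone (default 0.005). Must satisfy
#'   `min_divergence > 2 * per_base_error` or planted phylotypes may merge.
#' @param stage_model Tibble with `treatment`, `p_survive`,
#'   `p_metamorphose` columns.
#' @param replicates Replicate wells per treatment (default 3).
#' @param n_start Nauplii per well at the start (default 50).
#' @param seed Integer seed; all generator functions are deterministic
#'   given the scenario.
#' @return A list of class `"synthetic_scenario"`.
#' @export
synthetic_scenario <- function(n_references = 8,
                               min_divergence = 0.04,
                               seq_length = 900,
                               community_profiles = study_count_matrix(),
                               clones_per_library = 30,
                               per_base_error = 0.005,
                               stage_model = default_stage_model(),
                               replicates = 3,
                               n_start = 50,
                               seed = 1L) {
  if (min_divergence <= 2 * per_base_error) {
    abort("need min_divergence > 2 * per_base_error for recoverable phylotypes.",
          class = "copediv_config_error")
  }
  if (any(stage_model$p_survive < 0 | stage_model$p_survive > 1 |
          stage_model$p_metamorphose < 0 | stage_model$p_metamorphose > 1)) {
    abort("stage probabilities must be in [0, 1].",
          class = "copediv_config_error")
  }
  structure(list(n_references = n_references,
                 min_divergence = min_divergence,
                 seq_length = seq_length,
                 community_profiles = community_profiles,
                 clones_per_library = clones_per_library,
                 per_base_error = per_base_error,
                 stage_model = stage_model,
                 replicates = replicates,
                 n_start = n_start,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("Synthetic scenario: %d references (%d bp, divergence >= %g), %d libraries x %d clones, error %g/base, %d replicates x %d nauplii, seed %d\n",
              x$n_references, x$seq_length, x$min_divergence,
              ncol(x$community_profiles), x$clones_per_library,
              x$per_base_error, x$replicates, x$n_start, x$seed))
  invisible(x)
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_sequence <- function(seq, p_error) {
  if (p_error <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < p_error)
  if (length(hit) > 0) {
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  paste(chars, collapse = "")
}

# fast Hamming-based screen: iid random sequences differ at ~75% of sites,
# vastly above any realistic min_divergence, so rejection sampling on the
# Hamming identity is the operative check; the alignment-based identity of
# equal-length sequences can only be higher, so a final alignment check
# guards the contract on the first few pairs.
hamming_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}

#' Generate divergent reference ribotypes
#'
#' Draws `n_references` random sequences and rejection-checks that every
#' pair is at identity `<= 1 - min_divergence` (global-alignment identity,
#' the same measure the binning threshold uses). Deterministic for a fixed
#' scenario seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @param max_tries Attempts per reference before giving up.
#' @return A tibble with `id` (`"ref1"`, ...) and `residues`.
#' @export
make_references <- function(scenario, max_tries = 100) {
  withr::local_seed(scenario$seed)
  refs <- character(0)
  config <- phylotyping_config()
  for (i in seq_len(scenario$n_references)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- random_sequence(scenario$seq_length)
      if (length(refs) == 0 ||
          all(vapply(refs, function(r)
            pairwise_identity(cand, r, config), numeric(1)) <=
            1 - scenario$min_divergence)) {
        refs <- c(refs, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort("could not generate sufficiently divergent references.",
            class = "copediv_generation_error")
    }
  }
  tibble(id = paste0("ref", seq_along(refs)), residues = refs)
}

#' Simulate one clone library
#'
#' Clone counts per reference are either drawn multinomially from
#' `profile` (`counts = NULL`) or fixed exactly to a supplied count vector
#' — the fixed mode makes golden-path tests exact. Each clone is its
#' reference sequence with independent per-base substitutions at the
#' scenario's error rate.
#'
#' @param profile Composition vector over references (counts or
#'   proportions; normalised internally). Ignored when `counts` is given.
#' @param references Tibble from [make_references()].
#' @param scenario A [synthetic_scenario()].
#' @param library Library label stamped on the clones.
#' @param counts Optional integer vector (length = rows of `references`)
#'   of exact clone counts.
#' @param seed Seed for this library; defaults to the scenario seed.
#' @return A clone tibble (`id`, `library`, `residues`, `source_ref`).
#' @export
simulate_library <- function(profile, references, scenario,
                             library = "lib1", counts = NULL,
                             seed = scenario$seed) {
  withr::local_seed(seed)
  if (is.null(counts)) {
    p <- profile / sum(profile)
    counts <- as.integer(rmultinom(1, scenario$clones_per_library, p))
  }
  if (length(counts) != nrow(references)) {
    abort("`counts`/`profile` must have one entry per reference.",
          class = "copediv_config_error")
  }
  src <- rep(seq_len(nrow(references)), counts)
  residues <- vapply(references$residues[src], mutate_sequence,
                     character(1), p_error = scenario$per_base_error,
                     USE.NAMES = FALSE)
  tibble(
    id = sprintf("%s_clone%03d", library, seq_along(src)),
    library = library,
    residues = residues,
    source_ref = references$id[src]
  )
}

#' Simulate all clone libraries of a scenario
#'
#' One library per column of `community_profiles`, in fixed-count mode
#' when the profiles are integer counts summing to `clones_per_library`,
#' else multinomially. Library seeds are derived deterministically from
#' the scenario seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @param references Optional pre-built reference tibble (default:
#'   [make_references()] on the scenario).
#' @param fixed_counts Use the profile columns as exact clone counts
#'   (default: `TRUE` when they are integers summing to
#'   `clones_per_library`).
#' @return A list with `references` and `clones` (all libraries, row-bound).
#' @export
simulate_clone_libraries <- function(scenario, references = NULL,
                                     fixed_counts = NULL) {
  if (is.null(references)) references <- make_references(scenario)
  profiles <- scenario$community_profiles
  if (is.null(fixed_counts)) {
    fixed_counts <- all(profiles == floor(profiles)) &&
      all(colSums(profiles) == scenario$clones_per_library)
  }
  libs <- colnames(profiles) %||% paste0("lib", seq_len(ncol(profiles)))
  clones <- purrr::map2_dfr(seq_len(ncol(profiles)), libs, function(j, lab) {
    simulate_library(profiles[, j], references, scenario, library = lab,
                     counts = if (fixed_counts) as.integer(profiles[, j]),
                     seed = scenario$seed + j)
  })
  list(references = references, clones = clones)
}

#' Simulate replicate copepod stage censuses
#'
#' For each treatment and replicate: survivors are Binomial(`n_start`,
#' `p_survive`) and copepodites Binomial(survivors, `p_metamorphose`);
#' the remaining survivors are nauplii. Deterministic for a fixed
#' scenario seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A stage-census tibble (`replicate`, `treatment`, `n_start`,
#'   `n_nauplii`, `n_copepodites`).
#' @export
simulate_experiment <- function(scenario) {
  withr::local_seed(scenario$seed)
  sm <- scenario$stage_model
  purrr::map_dfr(seq_len(nrow(sm)), function(i) {
    survivors <- rbinom(scenario$replicates, scenario$n_start, sm$p_survive[i])
    copepodites <- rbinom(scenario$replicates, survivors, sm$p_metamorphose[i])
    tibble(
      replicate = paste0(sm$treatment[i], "_r", seq_len(scenario$replicates)),
      treatment = sm$treatment[i],
      n_start = scenario$n_start,
      n_nauplii = survivors - copepodites,
      n_copepodites = copepodites
    )
  })
}
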