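#' Run the full three-method comparison pipeline
#'
#' Orchestrates, on one cohort of gamma power traces: the structure-pooled
#' permutation cluster tests, the per-contact ML classification, the
#' searchlight MVPA, and the structure-level comparison with pairwise Jaccard
#' agreement. Stages can be subset; `compare` requires the three result
#' tables. When `out_dir` is given, each stage writes its results TSV (and the
#' agreement JSON) plus a run manifest with the seed and configuration, so a
#' rerun with the same inputs and seed is bit-identical.
#'
#' @param gpts_list Named list of [gpt()] objects with contact metadata.
#' @param stages Subset of `c("permtest", "ml", "searchlight", "compare")`.
#' @param perm A [perm_config()].
#' @param space A [search_space()].
#' @param fconfig A [feature_config()].
#' @param slconfig A [searchlight_config()].
#' @param seed Master seed, propagated to every stochastic stage.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A list with elements among `permtest`, `ml`, `searchlight`
#'   (tibbles), `sets` (method sets), `agreement` (tibble).
#' @export
run_pipeline <- function(gpts_list,
                         stages = c("permtest", "ml", "searchlight",
                                    "compare"),
                         perm = perm_config(),
                         space = search_space(),
                         fconfig = feature_config(),
                         slconfig = searchlight_config(),
                         seed = 1, out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  out <- list()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  if ("permtest" %in% stages) {
    perm$seed <- seed
    out$permtest <- permtest_by_structure(gpts_list, perm)
    if (!is.null(out_dir)) {
      readr::write_tsv(select(out$permtest, -"test"),
                       file.path(out_dir, "permtest.tsv"))
      readr::write_tsv(permtest_clusters(out$permtest),
                       file.path(out_dir, "permtest_clusters.tsv"))
    }
  }
  if ("ml" %in% stages) {
    out$ml <- evaluate_contacts(gpts_list, space, fconfig, seed = seed)
    if (!is.null(out_dir)) {
      readr::write_tsv(select(out$ml, -"result"),
                       file.path(out_dir, "ml.tsv"))
    }
  }
  if ("searchlight" %in% stages) {
    slconfig$seed <- seed
    out$searchlight <- run_searchlight(gpts_list, config = slconfig)
    if (!is.null(out_dir)) {
      readr::write_tsv(out$searchlight,
                       file.path(out_dir, "searchlight.tsv"))
    }
  }
  if ("compare" %in% stages) {
    needed <- c("permtest", "ml", "searchlight")
    miss <- setdiff(needed, names(out))
    if (length(miss)) {
      abort(paste0("stage 'compare' needs missing stage output(s): ",
                   paste(miss, collapse = ", "),
                   "; run those stages first"))
    }
    out$sets <- list(
      permutation = significant_structures(out$permtest, "permutation"),
      ml = significant_structures(out$ml, "ml"),
      mvpa = significant_structures(out$searchlight, "mvpa")
    )
    out$agreement <- compare_methods(out$sets$permutation, out$sets$ml,
                                     out$sets$mvpa)
    if (!is.null(out_dir)) {
      write_json(out$agreement, file.path(out_dir, "agreement.json"),
                 auto_unbox = TRUE, digits = NA)
    }
  }
  if (!is.null(out_dir)) {
    manifest <- list(
      seed = seed, stages = stages,
      n_contacts = length(gpts_list),
      n_permutations = perm$n_permutations,
      searchlight_radius_mm = slconfig$radius_mm,
      package_version = as.character(utils::packageVersion("ieegcontrasts"))
    )
    write_json(manifest, file.path(out_dir, "manifest.json"),
               auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Agreement analysis straight from a per-structure count table
#'
#' Convenience path used with the packaged reference summary table (or any
#' table with `structure`, `hemisphere`, `permutation`, `ml`, `mvpa` count
#' columns): builds the three method sets and their pairwise Jaccard
#' agreement.
#'
#' @param counts A tibble shaped like [structure_counts_reference()].
#' @return A list: `sets` (method sets), `agreement` (tibble), `summary`
#'   (per-method [glance.method_set()] rows).
#' @export
compare_from_counts <- function(counts = structure_counts_reference()) {
  sets <- method_sets_from_counts(counts)
  agreement <- compare_methods(sets$permutation, sets$ml, sets$mvpa)
  summary <- bind_rows(
    mutate(glance(sets$permutation), method = "permutation"),
    mutate(glance(sets$ml), method = "ml"),
    mutate(glance(sets$mvpa), method = "mvpa")
  ) %>% select("method", "hemisphere", "n_structures", "n_contacts")
  list(sets = sets, agreement = agreement, summary = summary)
}
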