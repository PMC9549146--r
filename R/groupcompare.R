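#' Structures with a significant contrast, per method
#'
#' Reduces per-contact (ML, searchlight) or per-structure (permutation)
#' significance flags to the set of (structure, hemisphere) pairs containing
#' at least one significant result, together with contact counts: for ML and
#' searchlight the number of significant contacts (searchlight contacts are
#' counted at their *center*), for the permutation test the number of contacts
#' pooled into a significant structure-level test.
#'
#' @param results A tibble with columns `structure`, `hemisphere`,
#'   `significant`, and — for `method = "permutation"` — `n_contacts`.
#' @param method One of `"permutation"`, `"ml"`, `"mvpa"`.
#' @return A tibble of class `method_set`: `structure`, `hemisphere`,
#'   `n_contacts` (one row per member structure), with attribute `method`.
#' @export
significant_structures <- function(results, method) {
  if (!method %in% c("permutation", "ml", "mvpa")) {
    abort(sprintf("unknown method '%s'", method))
  }
  stopifnot(all(c("structure", "hemisphere", "significant") %in%
                  names(results)))
  if (method == "permutation") {
    stopifnot("n_contacts" %in% names(results))
    out <- results %>%
      filter(.data$significant) %>%
      select("structure", "hemisphere", "n_contacts")
  } else {
    out <- results %>%
      filter(.data$significant) %>%
      count(.data$structure, .data$hemisphere, name = "n_contacts")
  }
  out <- out %>% arrange(.data$structure, .data$hemisphere)
  attr(out, "method") <- method
  class(out) <- c("method_set", class(out))
  out
}

#' Jaccard index of two sets
#'
#' |A intersect B| / |A union B|; two empty sets agree vacuously (index 1).
#'
#' @param a,b Vectors treated as sets (duplicates ignored).
#' @return A number in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

# round-half-up to two decimals (base round() is round-half-even)
round2_half_up <- function(x) floor(x * 100 + 0.5) / 100

structure_key <- function(ms, hemi) {
  ms$structure[ms$hemisphere == hemi]
}

#' Pairwise method agreement by hemisphere
#'
#' Computes the Jaccard index between each pair of methods' significant
#' structure sets, separately for the left and right hemispheres (LH and RH
#' structure sets are never merged).
#'
#' @param perm,ml,mvpa [significant_structures()] outputs (`method_set`
#'   tibbles) of the three methods.
#' @return A tibble of class `method_agreement`: `pair`, `hemisphere`,
#'   `jaccard` (raw), `jaccard_2dp` (rounded half-up to 2 decimals).
#' @export
compare_methods <- function(perm, ml, mvpa) {
  sets <- list(permutation = perm, ml = ml, mvpa = mvpa)
  pairs <- list(c("permutation", "ml"), c("permutation", "mvpa"),
                c("ml", "mvpa"))
  rows <- map(pairs, function(p) {
    map(c("LH", "RH"), function(h) {
      j <- jaccard(structure_key(sets[[p[1]]], h),
                   structure_key(sets[[p[2]]], h))
      tibble(pair = paste(p, collapse = "-"), hemisphere = h,
             jaccard = j, jaccard_2dp = round2_half_up(j))
    }) %>% bind_rows()
  }) %>% bind_rows()
  class(rows) <- c("method_agreement", class(rows))
  rows
}

#' Reaction-time statistics per subject and pooled
#'
#' Mann-Whitney U tests (two-sample Wilcoxon) of angry vs happy reaction
#' times, per subject and on the pooled trials, with per-condition trial
#' counts and the group-level mean/SD of per-subject mean reaction times.
#' Subjects missing a condition are skipped with a warning.
#'
#' @param trials A tibble with columns `subject`, `condition`
#'   (`"angry"`/`"happy"`), `rt_s`.
#' @param alpha Significance level for the per-subject flag.
#' @return A list: `by_subject` (tibble `subject`, per-condition n and mean
#'   RT, `u`, `p`, `significant`), `pooled` (`u`, `p`), `group` (tibble
#'   `condition`, `mean_rt_s`, `sd_rt_s`, `mean_n_trials` over subjects).
#' @export
behavior_stats <- function(trials, alpha = 0.05) {
  stopifnot(all(c("subject", "condition", "rt_s") %in% names(trials)))
  subjects <- unique(trials$subject)
  rows <- map(subjects, function(s) {
    d <- trials[trials$subject == s, ]
    a <- d$rt_s[d$condition == "angry"]
    h <- d$rt_s[d$condition == "happy"]
    if (!length(a) || !length(h)) {
      warn(sprintf("subject %s lacks trials in one condition; skipped", s))
      return(NULL)
    }
    wt <- suppressWarnings(wilcox.test(a, h))
    tibble(subject = s, n_angry = length(a), n_happy = length(h),
           mean_rt_angry = mean(a), mean_rt_happy = mean(h),
           u = unname(wt$statistic), p = wt$p.value,
           significant = wt$p.value < alpha)
  })
  by_subject <- bind_rows(rows)
  pooled_wt <- suppressWarnings(wilcox.test(
    trials$rt_s[trials$condition == "angry"],
    trials$rt_s[trials$condition == "happy"]))
  group <- tibble(
    condition = c("angry", "happy"),
    mean_rt_s = c(mean(by_subject$mean_rt_angry),
                  mean(by_subject$mean_rt_happy)),
    sd_rt_s = c(sd(by_subject$mean_rt_angry), sd(by_subject$mean_rt_happy)),
    mean_n_trials = c(mean(by_subject$n_angry), mean(by_subject$n_happy))
  )
  list(by_subject = by_subject,
       pooled = tibble(u = unname(pooled_wt$statistic),
                       p = pooled_wt$p.value),
       group = group)
}

#' Packaged reference summary tables
#'
#' `structure_counts_reference()` returns the packaged per-structure summary
#' of a 13-subject stereo-EEG facial-emotion cohort: implanted contact counts
#' and the number of significant contacts found by each of the three methods,
#' per (structure, hemisphere). Blank entries of the published table are
#' encoded as 0. `task_performance_reference()` returns the matching
#' per-subject behavioral summary (trial counts, mean reaction times, RT-test
#' p-values).
#'
#' @return A tibble.
#' @export
structure_counts_reference <- function() {
  readr::read_tsv(
    system.file("extdata", "structure_counts.tsv",
                package = "ieegcontrasts", mustWork = TRUE),
    show_col_types = FALSE)
}

#' @rdname structure_counts_reference
#' @export
task_performance_reference <- function() {
  readr::read_tsv(
    system.file("extdata", "task_performance.tsv",
                package = "ieegcontrasts", mustWork = TRUE),
    show_col_types = FALSE)
}

#' Method sets from a per-structure count table
#'
#' Converts a summary table with columns `structure`, `hemisphere`,
#' `implanted`, `permutation`, `ml`, `mvpa` (counts, 0 = not significant /
#' none) into the three [significant_structures()] sets, ready for
#' [compare_methods()].
#'
#' @param counts A tibble shaped like [structure_counts_reference()].
#' @return A named list of `method_set` tibbles: `permutation`, `ml`, `mvpa`.
#' @export
method_sets_from_counts <- function(counts) {
  stopifnot(all(c("structure", "hemisphere", "permutation", "ml", "mvpa")
                %in% names(counts)))
  one <- function(col, method) {
    res <- counts %>%
      mutate(n_contacts = .data[[col]],
             significant = .data[[col]] > 0) %>%
      select("structure", "hemisphere", "n_contacts", "significant")
    significant_structures(res, method = method)
  }
  list(
    permutation = one("permutation", "permutation"),
    ml = {
      ml <- one("ml", "ml")
      # counts come from the table, not from per-contact rows
      ml$n_contacts <- counts$ml[match(
        paste(ml$structure, ml$hemisphere),
        paste(counts$structure, counts$hemisphere))]
      ml
    },
    mvpa = {
      mv <- one("mvpa", "mvpa")
      mv$n_contacts <- counts$mvpa[match(
        paste(mv$structure, mv$hemisphere),
        paste(counts$structure, counts$hemisphere))]
      mv
    }
  )
}

#' Summaries of a method set
#'
#' @param x A `method_set`.
#' @param ... Unused.
#' @return One row per hemisphere: number of member structures and total
#'   significant (or pooled) contacts.
#' @export
glance.method_set <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$hemisphere) %>%
    summarise(n_structures = n(), n_contacts = sum(.data$n_contacts),
              .groups = "drop")
}
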