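#' Permutation-test configuration
#'
#' @param n_permutations Number of random label permutations for the
#'   Monte-Carlo null (default 1000).
#' @param cluster_alpha Significance level applied to cluster p-values
#'   (default 0.05).
#' @param cluster_forming_p Two-sided pointwise p threshold that turns the
#'   per-timepoint t statistic into supra-threshold runs (default 0.05).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `perm_config`.
#' @export
perm_config <- function(n_permutations = 1000, cluster_alpha = 0.05,
                        cluster_forming_p = 0.05, seed = NULL) {
  stopifnot(n_permutations >= 1,
            cluster_alpha > 0, cluster_alpha < 1,
            cluster_forming_p > 0, cluster_forming_p < 1)
  structure(
    list(n_permutations = as.integer(n_permutations),
         cluster_alpha = cluster_alpha,
         cluster_forming_p = cluster_forming_p, seed = seed),
    class = "perm_config"
  )
}

# Pointwise two-sample t statistics (pooled variance) for all permutations at
# once. `member` is a n_perm x n 0/1 matrix of group-A membership; X is n x T.
perm_tstats <- function(X, member, nA, nB) {
  SA <- member %*% X
  SA2 <- member %*% (X^2)
  S <- matrix(colSums(X), nrow(member), ncol(X), byrow = TRUE)
  S2 <- matrix(colSums(X^2), nrow(member), ncol(X), byrow = TRUE)
  SB <- S - SA
  SB2 <- S2 - SA2
  mA <- SA / nA
  mB <- SB / nB
  ssA <- SA2 - SA^2 / nA
  ssB <- SB2 - SB^2 / nB
  sp2 <- (ssA + ssB) / (nA + nB - 2)
  denom <- sqrt(sp2 * (1 / nA + 1 / nB))
  tmat <- (mA - mB) / denom
  tmat[denom == 0] <- 0
  tmat
}

# Contiguous runs of `flag`; returns start/end indices and per-run mass
# (sum of tvec inside the run).
threshold_runs <- function(tvec, flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) {
    return(list(start = integer(0), end = integer(0), mass = numeric(0)))
  }
  starts <- starts[keep]
  ends <- ends[keep]
  cs <- c(0, cumsum(tvec))
  list(start = starts, end = ends, mass = cs[ends + 1L] - cs[starts])
}

# All supra-threshold clusters (positive and negative handled separately).
observed_clusters <- function(tvec, thr) {
  pos <- threshold_runs(tvec, tvec > thr)
  neg <- threshold_runs(tvec, tvec < -thr)
  tibble(
    start = c(pos$start, neg$start),
    end = c(pos$end, neg$end),
    mass = c(pos$mass, neg$mass)
  ) %>% arrange(.data$start)
}

# Max |cluster mass| of one permutation's t vector (0 when no cluster forms).
max_cluster_mass <- function(tvec, thr) {
  m <- 0
  pos <- threshold_runs(tvec, tvec > thr)
  if (length(pos$mass)) m <- max(m, max(pos$mass))
  neg <- threshold_runs(tvec, tvec < -thr)
  if (length(neg$mass)) m <- max(m, max(abs(neg$mass)))
  m
}

#' Cluster-level permutation test for a two-condition contrast
#'
#' Non-parametric test for differences between two groups of single-trial
#' traces. A pointwise two-sample t statistic is thresholded at the t quantile
#' implied by `cluster_forming_p` (df = nA + nB - 2, two-sided); contiguous
#' supra-threshold runs form clusters (positive and negative separately) whose
#' statistic is the cluster mass (sum of t). The null distribution is the
#' maximum absolute cluster mass over random relabelings of the trials, and
#' each observed cluster gets the Monte-Carlo p-value
#' (1 + #\{null >= |mass|\}) / (1 + n_permutations).
#'
#' @param traces_a,traces_b Numeric matrices (trials x timepoints), same
#'   number of columns, at least two rows each.
#' @param config A [perm_config()].
#' @param time_s Optional time axis (s) used to report cluster bounds in
#'   seconds.
#' @return An object of class `cluster_test`: a list with `clusters` (tibble
#'   `start`, `end`, `start_s`, `end_s`, `mass`, `p`, `significant`), `tstat`,
#'   `threshold`, `n_permutations`, `significant` (any cluster below
#'   `cluster_alpha`).
#' @export
cluster_permutation_test <- function(traces_a, traces_b,
                                     config = perm_config(),
                                     time_s = NULL) {
  traces_a <- rbind(traces_a)
  traces_b <- rbind(traces_b)
  nA <- nrow(traces_a)
  nB <- nrow(traces_b)
  if (nA < 2 || nB < 2) abort("need at least two trials per condition")
  if (ncol(traces_a) != ncol(traces_b)) {
    abort("both conditions must share the same time axis length")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- nA + nB
  X <- rbind(traces_a, traces_b)
  thr <- qt(1 - config$cluster_forming_p / 2, df = n - 2)

  obs_t <- as.vector(perm_tstats(
    X, matrix(c(rep(1, nA), rep(0, nB)), nrow = 1), nA, nB))
  clusters <- observed_clusters(obs_t, thr)

  nperm <- config$n_permutations
  member <- matrix(0, nperm, n)
  for (p in seq_len(nperm)) member[p, sample.int(n, nA)] <- 1
  tmat <- perm_tstats(X, member, nA, nB)
  null_max <- vapply(seq_len(nperm),
                     function(i) max_cluster_mass(tmat[i, ], thr),
                     numeric(1))

  clusters$p <- vapply(clusters$mass, function(m) {
    (1 + sum(null_max >= abs(m))) / (1 + nperm)
  }, numeric(1))
  clusters$significant <- clusters$p < config$cluster_alpha
  if (is.null(time_s)) time_s <- seq_len(ncol(X))
  clusters$start_s <- time_s[clusters$start]
  clusters$end_s <- time_s[clusters$end]
  clusters <- clusters[c("start", "end", "start_s", "end_s",
                         "mass", "p", "significant")]
  structure(
    list(clusters = clusters, tstat = obs_t, threshold = thr,
         n_permutations = nperm, time_s = time_s,
         n_a = nA, n_b = nB,
         significant = any(clusters$significant)),
    class = "cluster_test"
  )
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d vs %d trials, %d permutations, |t| > %.3f\n",
              x$n_a, x$n_b, x$n_permutations, x$threshold))
  print(x$clusters)
  invisible(x)
}

#' @rdname cluster_permutation_test
#' @param x A `cluster_test` object.
#' @param ... Unused.
#' @export
tidy.cluster_test <- function(x, ...) x$clusters

#' @rdname cluster_permutation_test
#' @export
glance.cluster_test <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    min_p = if (nrow(x$clusters)) min(x$clusters$p) else NA_real_,
    n_permutations = x$n_permutations,
    significant = x$significant
  )
}

#' Structure-pooled permutation cluster test
#'
#' Aggregates, at the group level, the trials of every contact assigned to the
#' same (structure, hemisphere) — simple concatenation across contacts and
#' subjects — and runs [cluster_permutation_test()] on the pooled angry and
#' happy trial sets.
#'
#' @param gpts A list of [gpt()] objects sharing one (structure, hemisphere)
#'   and one time axis.
#' @param config A [perm_config()].
#' @return A `cluster_test` with attributes `structure`, `hemisphere` and
#'   `n_contacts`.
#' @export
structure_pooled_test <- function(gpts, config = perm_config()) {
  if (!length(gpts)) abort("no gamma power traces supplied")
  info <- map(gpts, "contact")
  if (!any(map_lgl(info, is.null))) {
    key <- unique(map_chr(info, ~ paste(.x$label, .x$hemisphere)))
    if (length(key) > 1) {
      abort("contacts from different (structure, hemisphere) cannot be pooled")
    }
  }
  time_s <- gpts[[1]]$time_s
  same_axis <- map_lgl(gpts, ~ isTRUE(all.equal(.x$time_s, time_s)))
  if (!all(same_axis)) abort("all contacts must share one time axis")
  a <- do.call(rbind, map(gpts, ~ .x$values[.x$conditions == "angry", ,
                                            drop = FALSE]))
  b <- do.call(rbind, map(gpts, ~ .x$values[.x$conditions == "happy", ,
                                            drop = FALSE]))
  res <- cluster_permutation_test(a, b, config, time_s)
  if (!is.null(info[[1]])) {
    attr(res, "structure") <- info[[1]]$label
    attr(res, "hemisphere") <- info[[1]]$hemisphere
  }
  attr(res, "n_contacts") <- length(gpts)
  res
}

#' Run pooled permutation tests for every (structure, hemisphere)
#'
#' @param gpts A list of [gpt()] objects with contact metadata.
#' @param config A [perm_config()]; each pooled test is seeded with
#'   `config$seed` plus a per-structure offset so results do not depend on
#'   iteration order.
#' @return A tibble: `structure`, `hemisphere`, `n_contacts`, `n_clusters`,
#'   `min_p`, `significant`, plus a list-column `test` of `cluster_test`
#'   objects.
#' @export
permtest_by_structure <- function(gpts, config = perm_config()) {
  keys <- map_chr(gpts, ~ paste(.x$contact$label, .x$contact$hemisphere,
                                sep = "\t"))
  groups <- split(gpts, keys)
  res <- imap(groups, function(g, key) {
    parts <- strsplit(key, "\t")[[1]]
    cfg <- config
    if (!is.null(cfg$seed)) {
      cfg$seed <- (cfg$seed + utils::head(
        strtoi(substr(digest_key(key), 1, 6), 16L), 1)) %% .Machine$integer.max
    }
    test <- structure_pooled_test(g, cfg)
    tibble(
      structure = parts[1], hemisphere = parts[2],
      n_contacts = length(g),
      n_clusters = nrow(test$clusters),
      min_p = if (nrow(test$clusters)) min(test$clusters$p) else NA_real_,
      significant = test$significant,
      test = list(test)
    )
  })
  bind_rows(res) %>% arrange(.data$structure, .data$hemisphere)
}

#' Cluster-level detail of structure-pooled permutation tests
#'
#' Expands a [permtest_by_structure()] result into one row per detected
#' cluster, the shape written to results TSVs.
#'
#' @param permtest The tibble returned by [permtest_by_structure()].
#' @return A tibble: `group`, `structure`, `hemisphere`, `contact`
#'   (`"pooled"`), `cluster_start_s`, `cluster_end_s`, `mass`, `p`,
#'   `significant`.
#' @export
permtest_clusters <- function(permtest) {
  rows <- map(seq_len(nrow(permtest)), function(i) {
    cl <- permtest$test[[i]]$clusters
    if (!nrow(cl)) return(NULL)
    tibble(
      group = "group", structure = permtest$structure[i],
      hemisphere = permtest$hemisphere[i], contact = "pooled",
      cluster_start_s = cl$start_s, cluster_end_s = cl$end_s,
      mass = cl$mass, p = cl$p, significant = cl$significant
    )
  })
  bind_rows(rows)
}

# Small deterministic string hash (djb2) rendered as hex; avoids a digest
# dependency for per-group seed offsets.
digest_key <- function(s) {
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
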