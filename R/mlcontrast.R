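#' Matthews correlation coefficient
#'
#' MCC of a binary confusion table,
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). Whenever one of the
#' denominator factors is zero (e.g. the classifier predicts a single class),
#' the coefficient is defined as 0, the usual convention.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) abort("confusion counts are all zero")
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Normalized Matthews correlation coefficient
#'
#' NMCC = (MCC + 1) / 2: 0.5 is chance level, 1 perfect classification, 0
#' perfect anti-classification.
#'
#' @inheritParams mcc
#' @return NMCC in \[0, 1\].
#' @export
nmcc <- function(tp, tn, fp, fn) (mcc(tp, tn, fp, fn) + 1) / 2

#' Condition-mean-subtraction data augmentation
#'
#' For each training trial, creates two derived time series by subtracting the
#' training-set average trace of the angry condition and of the happy
#' condition; each derived series keeps its source trial's label. The output
#' holds the originals plus both derived sets (3n series). Condition means are
#' computed only from the trials passed in, so calling this inside a CV fold
#' on the training rows is leakage-safe by construction.
#'
#' @param x Numeric matrix, trials x timepoints.
#' @param labels Per-trial condition labels; both classes must be present.
#' @return A list: `x` (3n x timepoints), `labels` (length 3n), `source`
#'   (index of the originating trial, used to keep augmented copies in their
#'   source trial's fold).
#' @export
augment_trials <- function(x, labels) {
  x <- rbind(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- unique(labels)
  if (length(classes) < 2) {
    abort("augmentation needs both conditions in the training set")
  }
  m1 <- colMeans(x[labels == classes[1], , drop = FALSE])
  m2 <- colMeans(x[labels == classes[2], , drop = FALSE])
  list(
    x = rbind(x, sweep(x, 2, m1, "-"), sweep(x, 2, m2, "-")),
    labels = rep(labels, 3),
    source = rep(seq_len(nrow(x)), 3)
  )
}

#' Interval-statistics feature configuration
#'
#' The default splits the post-stimulus trace into \[0.2, 0.4), \[0.4, 0.6)
#' and \[0.6, 1\] s and summarizes each interval with five statistics (mean,
#' standard deviation, median, skewness, excess kurtosis): a 15-dimensional
#' feature vector per trial.
#'
#' @param intervals_s List of length-2 numeric interval bounds (s). All but
#'   the last interval are half-open on the right.
#' @param statistics Statistic names, a subset of
#'   `c("mean", "sd", "median", "skewness", "kurtosis")`.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(intervals_s = list(c(0.2, 0.4), c(0.4, 0.6),
                                              c(0.6, 1)),
                           statistics = c("mean", "sd", "median",
                                          "skewness", "kurtosis")) {
  stopifnot(all(statistics %in% c("mean", "sd", "median", "skewness",
                                  "kurtosis")))
  structure(list(intervals_s = intervals_s, statistics = statistics),
            class = "feature_config")
}

# Standardized-moment skewness/kurtosis (biased moment estimators); both are
# defined as 0 for zero-variance input.
moment_stats <- function(v) {
  m <- mean(v)
  d <- v - m
  m2 <- mean(d^2)
  if (m2 == 0) return(c(skewness = 0, kurtosis = 0))
  c(skewness = mean(d^3) / m2^1.5, kurtosis = mean(d^4) / m2^2 - 3)
}

#' Extract interval statistics from traces
#'
#' Computes the configured statistics over each configured time interval,
#' interval-major / statistic-minor, for each row of `x`.
#'
#' @param x Numeric matrix, trials x timepoints (a single trace vector is
#'   accepted).
#' @param time_s Time axis (s) matching the columns of `x`.
#' @param config A [feature_config()].
#' @return Numeric matrix, trials x (intervals * statistics), with
#'   descriptive column names.
#' @export
extract_features <- function(x, time_s, config = feature_config()) {
  x <- rbind(x)
  stopifnot(ncol(x) == length(time_s))
  n_int <- length(config$intervals_s)
  blocks <- vector("list", n_int)
  for (i in seq_len(n_int)) {
    iv <- config$intervals_s[[i]]
    closed_right <- i == n_int
    sel <- time_s >= iv[1] - 1e-9 &
      (if (closed_right) time_s <= iv[2] + 1e-9 else time_s < iv[2] - 1e-9)
    if (sum(sel) < 2) {
      abort(sprintf("interval [%g, %g] s holds fewer than 2 samples of the time axis",
                    iv[1], iv[2]))
    }
    seg <- x[, sel, drop = FALSE]
    m <- rowMeans(seg)
    d <- seg - m
    m2 <- rowMeans(d^2)
    safe_m2 <- ifelse(m2 == 0, 1, m2)
    cols <- sapply(config$statistics, function(s) {
      switch(s,
        mean = m,
        sd = sqrt(rowSums(d^2) / (ncol(seg) - 1)),
        median = apply(seg, 1, median),
        skewness = ifelse(m2 == 0, 0, rowMeans(d^3) / safe_m2^1.5),
        kurtosis = ifelse(m2 == 0, 0, rowMeans(d^4) / safe_m2^2 - 3)
      )
    })
    cols <- rbind(cols)
    colnames(cols) <- sprintf("iv%d_%s", i, config$statistics)
    blocks[[i]] <- cols
  }
  do.call(cbind, blocks)
}

#' Random-forest hyperparameter search space
#'
#' The discrete space searched per contact: number of trees, maximum tree
#' depth, and the fraction of features drawn per tree. The full default space
#' has 3 x 9 x 3 = 81 points and is searched exhaustively.
#'
#' @param n_estimators Candidate forest sizes.
#' @param max_depth Candidate maximum tree depths.
#' @param p_features Candidate per-tree feature fractions.
#' @return A tibble grid of class `search_space`.
#' @export
search_space <- function(n_estimators = c(250, 500, 1000),
                         max_depth = 2:10,
                         p_features = c(0.15, 0.5, 0.75)) {
  grid <- tidyr::expand_grid(n_estimators = n_estimators,
                             max_depth = max_depth,
                             p_features = p_features)
  class(grid) <- c("search_space", class(grid))
  grid
}

# Deterministic stratified fold assignment: within each class, trials are
# shuffled then dealt round-robin into k folds.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      abort(sprintf("class '%s' has %d trials; %d-fold stratified CV needs >= %d",
                    cl, length(idx), k, k))
    }
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fold_confusion <- function(truth, pred, positive) {
  c(tp = sum(pred == positive & truth == positive),
    tn = sum(pred != positive & truth != positive),
    fp = sum(pred == positive & truth != positive),
    fn = sum(pred != positive & truth == positive))
}

# One CV round: augmentation + features fit on training rows only, random
# forest fit on augmented features, test folds scored on original trials.
# Returns the k fold NMCCs.
cv_nmcc <- function(x, time_s, labels, folds, params, fconfig, seed,
                    positive = "angry") {
  k <- max(folds)
  vapply(seq_len(k), function(f) {
    tr <- folds != f
    aug <- augment_trials(x[tr, , drop = FALSE], labels[tr])
    ftr <- extract_features(aug$x, time_s, fconfig)
    fte <- extract_features(x[!tr, , drop = FALSE], time_s, fconfig)
    mtry <- max(1L, round(params$p_features * ncol(ftr)))
    fit <- ranger::ranger(
      x = as.data.frame(ftr), y = factor(aug$labels),
      num.trees = params$n_estimators, max.depth = params$max_depth,
      mtry = mtry, seed = seed + f, num.threads = 1
    )
    pred <- as.character(predict(fit, as.data.frame(fte),
                                 num.threads = 1)$predictions)
    cc <- fold_confusion(labels[!tr], pred, positive)
    nmcc(cc["tp"], cc["tn"], cc["fp"], cc["fn"])
  }, numeric(1))
}

# t-test of fold scores against chance; constant folds get the limiting
# convention p = 1 at chance, p = 0 otherwise.
chance_t_test <- function(scores, mu = 0.5) {
  if (sd(scores) == 0) {
    return(list(p = if (isTRUE(all.equal(mean(scores), mu))) 1 else 0,
                stat = NA_real_))
  }
  ht <- t.test(scores, mu = mu)
  list(p = ht$p.value, stat = unname(ht$statistic))
}

#' Per-contact decoding of task condition from single-trial GPTs
#'
#' Runs the per-contact machine-learning pipeline: (1) exhaustive search over
#' the hyperparameter space, scoring each point by stratified `cv_folds`-fold
#' cross-validation in which condition-mean augmentation and interval-statistic
#' feature extraction are refit inside every training fold (no leakage;
#' augmented copies never reach a test fold); (2) a fresh seeded stratified
#' `cv_folds`-fold CV at the selected point, giving `cv_folds` fold NMCCs; (3)
#' a two-sided one-sample t-test of the fold NMCCs against the chance level
#' 0.5. The contact shows a significant contrast iff p < `alpha` *and* the
#' mean NMCC exceeds 0.5.
#'
#' @param gpts A [gpt()] object for one contact.
#' @param space A [search_space()]; a single-row space skips the search.
#' @param fconfig A [feature_config()].
#' @param cv_folds Number of CV folds (default 10).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed controlling fold assignment and forest growth.
#' @return An object of class `contact_decoding`: `fold_nmcc`, `mean_nmcc`,
#'   `p_value`, `significant`, `best_params`, `contact`.
#' @export
evaluate_contact <- function(gpts, space = search_space(),
                             fconfig = feature_config(),
                             cv_folds = 10, alpha = 0.05, seed = 1) {
  x <- gpts$values
  labels <- gpts$conditions
  counts <- table(labels)
  if (length(counts) < 2 || any(counts < cv_folds)) {
    abort(sprintf("need >= %d trials per condition for %d-fold stratified CV",
                  cv_folds, cv_folds))
  }
  if (nrow(space) > 1) {
    inner <- stratified_folds(labels, cv_folds, seed)
    scores <- vapply(seq_len(nrow(space)), function(i) {
      mean(cv_nmcc(x, gpts$time_s, labels, inner, space[i, ], fconfig,
                   seed = seed * 1000L + i))
    }, numeric(1))
    best <- space[which.max(scores), ]
  } else {
    best <- space[1, ]
  }
  outer <- stratified_folds(labels, cv_folds, seed + 1L)
  fold_nmcc <- cv_nmcc(x, gpts$time_s, labels, outer, best, fconfig,
                       seed = seed * 2000L)
  ht <- chance_t_test(fold_nmcc)
  structure(
    list(fold_nmcc = unname(fold_nmcc), mean_nmcc = mean(fold_nmcc),
         p_value = ht$p, statistic = ht$stat,
         significant = ht$p < alpha && mean(fold_nmcc) > 0.5,
         best_params = as.list(best), contact = gpts$contact),
    class = "contact_decoding"
  )
}

#' @export
print.contact_decoding <- function(x, ...) {
  cat(sprintf("<contact_decoding> mean NMCC %.3f, p = %.4g%s\n",
              x$mean_nmcc, x$p_value,
              if (x$significant) " (significant)" else ""))
  invisible(x)
}

#' @rdname evaluate_contact
#' @param x A `contact_decoding` object.
#' @param ... Unused.
#' @export
tidy.contact_decoding <- function(x, ...) {
  tibble(fold = seq_along(x$fold_nmcc), nmcc = x$fold_nmcc)
}

#' @rdname evaluate_contact
#' @export
glance.contact_decoding <- function(x, ...) {
  tibble(
    mean_nmcc = x$mean_nmcc, p_value = x$p_value,
    significant = x$significant,
    n_estimators = x$best_params$n_estimators,
    max_depth = x$best_params$max_depth,
    p_features = x$best_params$p_features
  )
}

#' Decode every contact of a cohort
#'
#' Maps [evaluate_contact()] over a list of per-contact GPTs, deriving a
#' per-contact seed from `seed` and the contact identity so results do not
#' depend on list order.
#'
#' @param gpts_list Named list of [gpt()] objects with contact metadata.
#' @inheritParams evaluate_contact
#' @return A tibble: `subject`, `contact`, `structure`, `hemisphere`,
#'   `mean_nmcc`, `p`, `significant`, selected hyperparameters, and a
#'   list-column `result`.
#' @export
evaluate_contacts <- function(gpts_list, space = search_space(),
                              fconfig = feature_config(), cv_folds = 10,
                              alpha = 0.05, seed = 1) {
  rows <- map(gpts_list, function(g) {
    key <- paste(g$contact$subject, g$contact$contact)
    cseed <- (seed + strtoi(substr(digest_key(key), 1, 6), 16L)) %% 100000L
    res <- evaluate_contact(g, space, fconfig, cv_folds, alpha, cseed)
    tibble(
      subject = g$contact$subject, contact = g$contact$contact,
      structure = g$contact$label, hemisphere = g$contact$hemisphere,
      mean_nmcc = res$mean_nmcc, p = res$p_value,
      significant = res$significant,
      n_estimators = res$best_params$n_estimators,
      max_depth = res$best_params$max_depth,
      p_features = res$best_params$p_features,
      result = list(res)
    )
  })
  bind_rows(rows)
}
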