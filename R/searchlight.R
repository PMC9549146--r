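#' Searchlight configuration
#'
#' @param radius_mm Searchlight radius (default 25 mm): the closed ball
#'   around each center contact whose member contacts contribute channels to
#'   the decoder.
#' @param cv_folds Number of stratified CV folds (default 10).
#' @param lambda_scale Ridge penalty scale for the logistic decoder; the
#'   effective glmnet lambda is `lambda_scale / n_train`, which corresponds to
#'   unit-strength L2 regularization in the common C = 1 parameterization.
#' @param alpha Significance level of the t-test against chance (default
#'   0.05).
#' @param seed Integer seed.
#' @return A list of class `searchlight_config`.
#' @export
searchlight_config <- function(radius_mm = 25, cv_folds = 10,
                               lambda_scale = 1, alpha = 0.05, seed = 1) {
  stopifnot(radius_mm > 0, cv_folds >= 2, lambda_scale > 0)
  structure(
    list(radius_mm = radius_mm, cv_folds = cv_folds,
         lambda_scale = lambda_scale, alpha = alpha, seed = seed),
    class = "searchlight_config"
  )
}

#' Decode task condition from one searchlight neighborhood
#'
#' Builds, per trial, the concatenation over member contacts of their gamma
#' power traces (member_count x timepoints features), standardizes every
#' feature with training-fold mean and SD, and classifies with L2-regularized
#' logistic regression under stratified `cv_folds`-fold cross-validation. Fold
#' NMCCs are tested against the 0.5 chance level exactly as in the per-contact
#' ML pipeline; the neighborhood is significant iff p < alpha and mean NMCC >
#' 0.5.
#'
#' @param gpts_members List of [gpt()] objects, one per member contact, with
#'   identical trial order and time axes (same subject).
#' @param config A [searchlight_config()].
#' @param seed Overrides `config$seed` when given.
#' @return An object of class `searchlight_fit`: `fold_nmcc`, `mean_nmcc`,
#'   `p_value`, `significant`, `member_count`, `center` (contact info of the
#'   first member unless set by the caller).
#' @export
decode_neighborhood <- function(gpts_members, config = searchlight_config(),
                                seed = NULL) {
  if (!length(gpts_members)) abort("empty neighborhood")
  labels <- gpts_members[[1]]$conditions
  n_tr <- nrow(gpts_members[[1]]$values)
  aligned <- map_lgl(gpts_members, function(g) {
    nrow(g$values) == n_tr && identical(g$conditions, labels) &&
      isTRUE(all.equal(g$time_s, gpts_members[[1]]$time_s))
  })
  if (!all(aligned)) {
    abort("member contacts must share trials, labels and time axis")
  }
  if (length(unique(labels)) < 2) abort("both conditions must be present")
  feat <- do.call(cbind, map(gpts_members, "values"))
  if (is.null(seed)) seed <- config$seed
  folds <- stratified_folds(labels, config$cv_folds, seed)
  positive <- "angry"
  fold_nmcc <- vapply(seq_len(config$cv_folds), function(f) {
    tr <- folds != f
    mu <- colMeans(feat[tr, , drop = FALSE])
    sigma <- apply(feat[tr, , drop = FALSE], 2, sd)
    sigma[sigma == 0] <- 1
    xtr <- sweep(sweep(feat[tr, , drop = FALSE], 2, mu, "-"), 2, sigma, "/")
    xte <- sweep(sweep(feat[!tr, , drop = FALSE], 2, mu, "-"), 2, sigma, "/")
    lam <- config$lambda_scale / sum(tr)
    fit <- glmnet::glmnet(xtr, factor(labels[tr]), family = "binomial",
                          alpha = 0, lambda = lam, standardize = FALSE)
    pred <- as.character(predict(fit, xte, type = "class", s = lam))
    cc <- fold_confusion(labels[!tr], pred, positive)
    nmcc(cc["tp"], cc["tn"], cc["fp"], cc["fn"])
  }, numeric(1))
  ht <- chance_t_test(fold_nmcc)
  structure(
    list(fold_nmcc = unname(fold_nmcc), mean_nmcc = mean(fold_nmcc),
         p_value = ht$p,
         significant = ht$p < config$alpha && mean(fold_nmcc) > 0.5,
         member_count = length(gpts_members),
         center = gpts_members[[1]]$contact),
    class = "searchlight_fit"
  )
}

#' @export
print.searchlight_fit <- function(x, ...) {
  cat(sprintf(
    "<searchlight_fit> %d member(s), mean NMCC %.3f, p = %.4g%s\n",
    x$member_count, x$mean_nmcc, x$p_value,
    if (x$significant) " (significant)" else ""))
  invisible(x)
}

#' @rdname decode_neighborhood
#' @param x A `searchlight_fit` object.
#' @param ... Unused.
#' @export
tidy.searchlight_fit <- function(x, ...) {
  tibble(fold = seq_along(x$fold_nmcc), nmcc = x$fold_nmcc)
}

#' @rdname decode_neighborhood
#' @export
glance.searchlight_fit <- function(x, ...) {
  tibble(mean_nmcc = x$mean_nmcc, p_value = x$p_value,
         significant = x$significant, member_count = x$member_count)
}

#' Run the searchlight over a whole cohort
#'
#' Every contact becomes the center of exactly one searchlight; its
#' neighborhood (same-subject contacts within the radius) is decoded with
#' [decode_neighborhood()], and a significant searchlight is attributed to the
#' anatomical structure of its *center* contact.
#'
#' @param gpts_list Named list of [gpt()] objects (names are contact ids,
#'   metadata in each `$contact`).
#' @param neighborhoods Output of [build_neighborhoods()] at
#'   `config$radius_mm`, or `NULL` to build it from the contact metadata.
#' @param config A [searchlight_config()].
#' @return A tibble: `subject`, `contact` (center), `structure`, `hemisphere`,
#'   `member_count`, `mean_nmcc`, `p`, `significant`.
#' @export
run_searchlight <- function(gpts_list, neighborhoods = NULL,
                            config = searchlight_config()) {
  info <- bind_rows(map(gpts_list, ~ as_tibble(.x$contact)))
  if (is.null(neighborhoods)) {
    neighborhoods <- build_neighborhoods(info, config$radius_mm)
  }
  by_key <- setNames(gpts_list,
                     paste(info$subject, info$contact, sep = "\t"))
  rows <- map(seq_len(nrow(neighborhoods)), function(i) {
    nb <- neighborhoods[i, ]
    member_keys <- paste(nb$subject, nb$members[[1]], sep = "\t")
    center_key <- paste(nb$subject, nb$contact, sep = "\t")
    # center first, so the fit reports the center contact
    member_keys <- c(center_key, setdiff(member_keys, center_key))
    seed <- (config$seed +
               strtoi(substr(digest_key(center_key), 1, 6), 16L)) %% 100000L
    fit <- decode_neighborhood(by_key[member_keys], config, seed = seed)
    tibble(
      subject = nb$subject, contact = nb$contact,
      structure = nb$label, hemisphere = nb$hemisphere,
      member_count = fit$member_count, mean_nmcc = fit$mean_nmcc,
      p = fit$p_value, significant = fit$significant
    )
  })
  bind_rows(rows)
}
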