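# shared fixture builders (all programmatic, seeded)

gpt_axis <- time_axis(-0.3, 1, 256)

# one synthetic contact's GPTs: smooth-noise background, optional additive
# class offset (units of SD) inside `window`
make_contact_gpt <- function(n_per = 30, effect = 0, window = c(0.2, 0.6),
                             seed = 1, contact = NULL, time_s = gpt_axis) {
  set.seed(seed)
  labs <- rep(c("angry", "happy"), each = n_per)
  v <- matrix(rnorm(2 * n_per * length(time_s)), 2 * n_per)
  # mild temporal smoothing so traces are not white
  k <- 13
  v <- t(apply(v, 1, function(row) {
    as.vector(stats::filter(c(rnorm(k), row), rep(1 / k, k),
                            sides = 1))[-seq_len(k)]
  })) * sqrt(k)
  if (effect != 0) {
    sel <- time_s >= window[1] & time_s <= window[2]
    v[labs == "angry", sel] <- v[labs == "angry", sel] + effect
  }
  gpt(v, time_s, labs, contact)
}

contact_row <- function(subject = "S1", contact = "A1", x = 0, y = 0, z = 0,
                        label = "INSULA", hemisphere = "LH") {
  tibble::tibble(subject = subject, contact = contact, x = x, y = y, z = z,
                 label = label, hemisphere = hemisphere)
}

# small cohort: one subject, two electrodes of n_ct contacts in different
# structures, optional effect on the first electrode's structure
small_cohort_gpts <- function(n_ct = 4, n_per = 25, effect = 0, seed = 1) {
  contacts <- dplyr::bind_rows(
    contact_row(contact = paste0("A", seq_len(n_ct)),
                x = -36 + (seq_len(n_ct) - 1) * 3.5, y = 0, z = 2,
                label = "INSULA"),
    contact_row(contact = paste0("B", seq_len(n_ct)),
                x = -36 - (seq_len(n_ct) - 1) * 3.5, y = -52, z = -18,
                label = "FUSIFORM")
  )
  spec <- cohort_spec(n_subjects = 1, trials_per_condition = c(n_per, n_per),
                      seed = seed)
  eff <- effect_spec(
    target_structures = tibble::tibble(structure = "INSULA",
                                       hemisphere = "LH"),
    effect_size = effect, effect_window_s = c(0.3, 0.6))
  generate_gpts(contacts, spec, eff)
}

# small single-point hyperparameter space used when search is not under test
fast_space <- function(trees = 100) search_space(trees, 6, 0.5)
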