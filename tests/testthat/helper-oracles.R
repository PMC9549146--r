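# exhaustive relabeling oracle for tiny permutation-test instances: exact
# permutation p of the max-|cluster-mass| statistic over all C(n, nA)
# relabelings
exact_cluster_p <- function(a, b, forming_p = 0.05) {
  n_a <- nrow(a)
  X <- rbind(a, b)
  n <- nrow(X)
  thr <- qt(1 - forming_p / 2, df = n - 2)
  tvec <- function(ia) {
    xa <- X[ia, , drop = FALSE]
    xb <- X[-ia, , drop = FALSE]
    va <- apply(xa, 2, var)
    vb <- apply(xb, 2, var)
    sp <- ((n_a - 1) * va + (n - n_a - 1) * vb) / (n - 2)
    (colMeans(xa) - colMeans(xb)) / sqrt(sp * (1 / n_a + 1 / (n - n_a)))
  }
  maxmass <- function(tv) {
    best <- 0
    for (sgn in c(1, -1)) {
      run <- 0
      for (v in sgn * tv) {
        run <- if (v > thr) run + v else 0
        best <- max(best, run)
      }
    }
    best
  }
  obs_t <- tvec(seq_len(n_a))
  obs <- maxmass(obs_t)
  combos <- utils::combn(n, n_a)
  null <- apply(combos, 2, function(ia) maxmass(tvec(ia)))
  list(obs = obs, p = mean(null >= obs - 1e-12))
}
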