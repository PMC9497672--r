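# Independent brute-force information oracles, computed directly from the
# explicit joint probability tables with base R's table(). These never touch
# the package's estimator path.

brute_entropy <- function(x) {
  p <- as.vector(table(x)) / length(x)
  -sum(p * log2(p))
}

brute_joint_entropy <- function(...) {
  p <- as.vector(table(interaction(..., drop = TRUE))) / length(..1)
  -sum(p * log2(p))
}

brute_mi <- function(x, y) {
  n <- length(x)
  tab <- table(x, y)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  tot <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) tot <- tot + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  unname(tot)
}

# direct triple-sum definition of conditional MI
brute_cmi <- function(x, y, z) {
  n <- length(x)
  tab <- table(x, y, z)
  pz <- apply(tab, 3, sum) / n
  tot <- 0
  for (kk in seq_len(dim(tab)[3])) {
    if (pz[kk] == 0) next
    pxyz <- tab[, , kk] / n
    px_z <- rowSums(pxyz) / pz[kk]
    py_z <- colSums(pxyz) / pz[kk]
    for (i in seq_len(nrow(pxyz))) for (j in seq_len(ncol(pxyz))) {
      if (pxyz[i, j] > 0) {
        tot <- tot + pxyz[i, j] *
          log2((pxyz[i, j] / pz[kk]) / (px_z[i] * py_z[j]))
      }
    }
  }
  unname(tot)
}

brute_interaction <- function(x, y, z) brute_mi(x, y) - brute_cmi(x, y, z)

# random categorical columns / datasets used across tests
random_codes <- function(n, levels) sample.int(levels, n, replace = TRUE)

random_dataset <- function(n_feat, n_obs, levels = 3, seed = 1) {
  set.seed(seed)
  feats <- lapply(seq_len(n_feat), function(i) cat_series(random_codes(n_obs, levels)))
  names(feats) <- paste0("f", seq_len(n_feat))
  dataset_table(feats, cat_series(random_codes(n_obs, 2)))
}

# random MI transfer network (valid: symmetric non-negative U, zero diagonal)
random_network <- function(n, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n), n)
  U <- (A + t(A)) / 4
  diag(U) <- 0
  mi_network(U, b = runif(n))
}

# Table 1 criteria re-derived from scratch on top of the brute oracles;
# the per-step objective of the greedy engine, evaluated independently.
brute_greedy_score <- function(name, f, SEL, cols, C, beta = NULL) {
  rel <- brute_mi(cols[[f]], C)
  if (length(SEL) == 0) return(rel)
  g <- vapply(SEL, function(i) {
    switch(name,
      "MIFS-U" = {
        H <- brute_entropy(cols[[i]])
        if (H <= 0) 0 else brute_mi(cols[[i]], C) / H * brute_mi(cols[[f]], cols[[i]])
      },
      "IGFS" = brute_mi(cols[[f]], interaction(C, cols[[i]], drop = TRUE)),
      "CIFE" = brute_mi(cols[[i]], interaction(C, cols[[f]], drop = TRUE)),
      "MRMD" = brute_mi(cols[[f]], cols[[i]]) - brute_cmi(cols[[f]], C, cols[[i]]),
      "MRI" = 2 * brute_interaction(cols[[f]], cols[[i]], C) -
        brute_mi(cols[[f]], C) - brute_mi(cols[[i]], C),
      "mRMR" = brute_mi(cols[[f]], cols[[i]]),
      "SPEC-CMI" = brute_cmi(cols[[f]], C, cols[[i]]))
  }, numeric(1))
  beta_val <- switch(name,
    "MIFS-U" = beta, "IGFS" = -1 / length(SEL), "CIFE" = 1,
    "MRMD" = 1 / length(SEL), "MRI" = 1, "mRMR" = 1 / length(SEL),
    "SPEC-CMI" = -1)
  rel - beta_val * sum(g)
}
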