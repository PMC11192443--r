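# Independent brute-force oracles. These deliberately share no code with
# the package implementations: explicit loops, no row-sum shortcuts.

# leave-one-out ISC by explicit column loops
oracle_loo_isc <- function(m) {
  n <- ncol(m)
  r <- numeric(n)
  for (i in seq_len(n)) {
    others <- matrix(m[, -i], nrow = nrow(m))
    avg <- apply(others, 1, mean)
    r[i] <- stats::cor(m[, i], avg)
  }
  stats::setNames(r, colnames(m))
}

# Benjamini-Hochberg step-up, written out from the definition
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  ranked <- p[ord] * n / seq_len(n)
  # step-up: running minimum from the largest rank down
  for (i in seq_len(n)) {
    adj[i] <- min(ranked[i:n])
  }
  pmin(stats::setNames(adj[order(ord)], names(p)), 1)
}

# pairwise shared CU types by direct pair enumeration over token lists
oracle_shared_pairwise <- function(type_sets) {
  n <- length(type_sets)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      vals <- c(vals, length(intersect(type_sets[[i]], type_sets[[j]])))
    }
  }
  mean(vals)
}

# build a tiny preprocessed timecourse_set directly from matrices
make_tcs <- function(mats_by_froi, condition = "c1", type = "+M/-L",
                     tr_s = 2, preprocessed = TRUE) {
  timecourse_set(stats::setNames(list(mats_by_froi), condition), tr_s,
                 stats::setNames(type, condition),
                 preprocessed = preprocessed)
}

rand_mat <- function(n_t, n_p, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_t * n_p), n_t, n_p)
  m <- apply(m, 2, function(x) (x - mean(x)) / sd(x))
  dimnames(m) <- list(NULL, sprintf("p%02d", seq_len(n_p)))
  m
}
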