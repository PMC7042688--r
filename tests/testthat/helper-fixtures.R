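# Fixture builders shared across the suite.  Everything is generated in
# code; no binary fixtures.

# tiny two/three-species library with well-separated means and no dispersion
make_flat_library <- function(n_species = 2L, n_spec = 3L, lipid = NULL) {
  fa <- sprintf("FA%02d", 1:6)
  means <- rbind(c(0.40, 0.25, 0.15, 0.10, 0.06, 0.04),
                 c(0.05, 0.10, 0.15, 0.20, 0.25, 0.25),
                 c(0.10, 0.40, 0.10, 0.25, 0.05, 0.10))[seq_len(n_species), ,
                                                        drop = FALSE]
  colnames(means) <- fa
  labels <- c("alpha_sp", "bravo_sp", "charlie_sp")[seq_len(n_species)]
  sigs <- lapply(seq_len(n_species), function(k) {
    m <- matrix(rep(means[k, ], n_spec), n_spec, byrow = TRUE)
    colnames(m) <- fa
    m
  })
  names(sigs) <- labels
  prey_library(sigs, lipid = lipid)
}

# small noisy library via the generator, sized for fast tests
make_small_scenario <- function(seed = 1L, n_predators = 15L, ...) {
  synthetic_scenario(seed = seed,
                     n_specimens = c(12L, 8L, 8L, 10L, 8L),
                     n_predators = n_predators, ...)
}

random_simplex <- function(n, k) {
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}

# independent one-way permanova oracle: group-sum formula + enumeration of
# distinct relabelings (Anderson's direct SS decomposition from distances)
oneway_perm_oracle <- function(D, groups) {
  D <- as.matrix(D)
  n <- nrow(D)
  f_stat <- function(g) {
    ss_tot <- sum(D[upper.tri(D)]^2) / n
    ss_w <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      sub <- D[idx, idx, drop = FALSE]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]^2) / length(idx)
    }
    a <- length(unique(g))
    ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  obs <- f_stat(groups)
  perms <- gtools_perms(n)
  fs <- apply(perms, 1L, function(p) f_stat(groups[p]))
  list(F = obs, p = mean(fs >= obs - 1e-12))
}

# all permutations of 1..n (independent of the engine's enumerator)
gtools_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  do.call(rbind, lapply(seq_len(n), function(i) {
    sub <- gtools_perms(n - 1L)
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}
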