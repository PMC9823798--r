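# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Per-window max-minus-min by explicit scan.
reeg_brute <- function(x, sfreq, window = 2) {
  spw <- round(window * sfreq)
  nwin <- floor(length(x) / spw)
  out <- numeric(nwin)
  for (i in seq_len(nwin)) {
    w <- x[((i - 1) * spw + 1):(i * spw)]
    mx <- w[1]; mn <- w[1]
    for (v in w) { if (v > mx) mx <- v; if (v < mn) mn <- v }
    out[i] <- mx - mn
  }
  out
}

# All permutations of 1..n as a matrix (n! rows).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Spearman rho on average ranks (direct Pearson-on-ranks formula).
rho_ranks <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exact two-sided permutation p-value for Spearman rho by full enumeration.
spearman_enum <- function(x, y) {
  n <- length(x)
  obs <- rho_ranks(x, y)
  pm <- all_perms(n)
  rhos <- apply(pm, 1, function(p) rho_ranks(x, y[p]))
  list(rho = obs, p = mean(abs(rhos) >= abs(obs) - 1e-12))
}

# Exact two-sided rank-sum p by enumerating all group assignments, following
# the doubled-smaller-tail convention.
ranksum_enum <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cmb <- utils::combn(N, n1)
  us <- apply(cmb, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  p <- 2 * min(mean(us <= u_obs + 1e-12), mean(us >= u_obs - 1e-12))
  list(statistic = u_obs, p = min(1, p))
}

# Tie-corrected Kruskal-Wallis H by the rank formula.
kruskal_H <- function(groups) {
  v <- unlist(groups); N <- length(v)
  r <- rank(v)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, function(g) sum(g)^2 / length(g))) - 3 * (N + 1)
  ties <- table(v)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Small synthetic recording shared by several tests.
quick_recording <- function(seed = 1, sync = 0.8, slope = 0, dur = 300,
                            sfreq = 250, amp = 75, artifacts = list()) {
  cfg <- sim_cohort_config(n_subjects = 2, duration_pre = dur,
                           duration_post = dur, sfreq = sfreq)
  synthesize_recording(
    sim_subject_params(baseline_amplitude = amp, sync_level = sync,
                       drug_effect_slope = slope, artifact_spec = artifacts,
                       rng_seed = seed),
    cfg)
}
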