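# shared fixtures and independent oracles -----------------------------------

# reduced-size atlas configuration used across the suite: the default
# region roster and noise, fewer background genes for speed
test_config <- function(noise_sd = 0.2, seed = 1L, n_genes = 600, ...) {
  atlas_config(n_genes = n_genes, noise_sd = noise_sd, seed = seed, ...)
}

# peak region of every gene at once (test-side shortcut; ties -> first)
peak_regions_all <- function(profile) {
  profile$regions[max.col(profile$values, ties.method = "first")]
}

# literal transcription of the two-stage step-up FDR, coded independently
# of bky_adjust: stage 1 BH at q/(1+q); m0 = m - r1; stage 2 BH at
# (q/(1+q)) * m / m0
oracle_bky <- function(p, q) {
  m <- length(p)
  bh <- function(pv, level) {
    ord <- order(pv)
    sorted <- pv[ord]
    thresh <- (seq_len(m) / m) * level
    below <- which(sorted <= thresh)
    out <- rep(FALSE, m)
    if (length(below) > 0) out[ord[1:max(below)]] <- TRUE
    out
  }
  q1 <- q / (1 + q)
  stage1 <- bh(p, q1)
  r1 <- sum(stage1)
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh(p, q1 * m / (m - r1))
}

oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  below <- which(p[ord] <= (seq_len(m) / m) * q)
  out <- rep(FALSE, m)
  if (length(below) > 0) out[ord[1:max(below)]] <- TRUE
  out
}

# brute-force running-sum enrichment score: explicit walk, evaluating the
# deviation at every position; magnitude ties resolve to the positive side
oracle_es <- function(stats_vec, hit, p) {
  N <- length(stats_vec)
  nh <- sum(hit)
  nr <- sum(abs(stats_vec[hit])^p)
  run <- 0
  devs <- numeric(N)
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) abs(stats_vec[i])^p / nr else -1 / (N - nh)
    devs[i] <- run
  }
  if (max(devs) >= -min(devs) - 1e-12) max(devs) else min(devs)
}

# p = 0 enrichment score as a two-sample KS statistic between hit and
# miss position empirical CDFs (signed by which CDF leads at the
# extremum; ties resolve positive, as in oracle_es)
oracle_ks_es <- function(hit) {
  N <- length(hit)
  pos_h <- which(hit)
  pos_m <- which(!hit)
  dev <- vapply(seq_len(N), function(i) {
    mean(pos_h <= i) - mean(pos_m <= i)
  }, numeric(1))
  if (max(dev) >= -min(dev) - 1e-12) max(dev) else min(dev)
}

# literal double-loop topological overlap
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - 1
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) s <- s + a[i, u] * a[u, j]
      }
      out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(out) <- dimnames(a)
  out
}

# random valid adjacency: symmetric, [0, 1], unit diagonal
random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
  a
}

# tiny handmade expression matrix fixture
toy_matrix <- function() {
  vals <- matrix(c(10, 0, 5,
                   30, 0, 5,
                   60, 8, 5,
                   20, 2, 5), nrow = 4, byrow = TRUE,
                 dimnames = list(c("Pomc", "Agrp", "Gapdh", "Lepr"),
                                 c("ARH_r1", "ARH_r2", "PVH_r1")))
  samples <- data.frame(sample_id = c("ARH_r1", "ARH_r2", "PVH_r1"),
                        region = c("ARH", "ARH", "PVH"),
                        group = c("homeostatic", "homeostatic",
                                  "homeostatic"),
                        replicate = c(1L, 2L, 1L),
                        stringsAsFactors = FALSE)
  expr_matrix(vals, samples)
}
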