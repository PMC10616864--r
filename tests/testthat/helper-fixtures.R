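# Shared fixtures, all generated in code.

toy_atlas <- function(n = 4) {
  region_atlas(
    node_id = 0:(n - 1),
    name = sprintf("r%02d", seq_len(n)),
    hemisphere = rep(c("left", "right"), length.out = n),
    x = seq_len(n), y = -seq_len(n), z = rep(0, n)
  )
}

# random symmetric connectivity with entries in (-1, 1)
random_cm <- function(n, seed = 1, subject = "s1", timepoint = "pre") {
  set.seed(seed)
  m <- matrix(runif(n * n, -1, 1), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- NA_real_
  connectivity_matrix(m, subject, timepoint)
}

# connectivity with every off-diagonal entry equal to v
constant_cm <- function(n, v, subject = "s1", timepoint = "pre") {
  m <- matrix(v, n, n)
  diag(m) <- NA_real_
  connectivity_matrix(m, subject, timepoint)
}

# centrality panel built directly from a degree array [node, subject, timepoint]
panel_from_array <- function(deg, timepoints, threshold = 0.10) {
  n <- dim(deg)[1]; ns <- dim(deg)[2]; nt <- dim(deg)[3]
  df <- do.call(rbind, lapply(seq_len(nt), function(ti) {
    do.call(rbind, lapply(seq_len(ns), function(si) {
      data.frame(node_id = 0:(n - 1), subject = sprintf("sub-%02d", si),
                 timepoint = timepoints[ti], degree = deg[, si, ti])
    }))
  }))
  df$timepoint <- factor(df$timepoint, levels = timepoints, ordered = TRUE)
  hubshift:::new_centrality_panel(tibble::as_tibble(df), n_nodes = n,
                                  threshold = threshold)
}

# brute-force double-loop Pearson oracle
oracle_cor_matrix <- function(x) {
  n <- nrow(x)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- x[i, ]; b <- x[j, ]
    da <- a - mean(a); db <- b - mean(b)
    out[i, j] <- sum(da * db) / sqrt(sum(da^2) * sum(db^2))
  }
  out
}

# brute-force per-node degree oracle over an adjacency matrix
oracle_degree <- function(adj) {
  n <- nrow(adj)
  deg <- integer(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (j in seq_len(n)) if (j != i && adj[i, j]) cnt <- cnt + 1L
    deg[i] <- cnt
  }
  deg
}

# brute-force unique-pair edge count oracle
oracle_edges <- function(adj) {
  n <- nrow(adj); cnt <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) if (adj[i, j]) cnt <- cnt + 1L
  cnt
}

# FFT amplitude of a sinusoidal component at frequency f (cycles/sample unit dt)
fft_amplitude <- function(v, f, dt = 1) {
  n <- length(v)
  k <- round(f * n * dt)
  as.numeric(Mod(stats::fft(v))[k + 1] * 2 / n)
}
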