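# Shared fixture builders, all seeded and cheap.

small_connectome <- function(n = 8, seed = 7) {
  generate_connectome(n, density = 0.6, candidate_frontal = 2,
                      candidate_parietal = 2, seed = seed)
}

# Independent modal-controllability oracle: singular-value decomposition of
# the normalized matrix (for a symmetric matrix the singular vectors are the
# eigenvectors up to sign and d = |lambda|), summed node by node in loops.
phi_oracle <- function(weights) {
  lam_max <- max(eigen(weights, symmetric = TRUE, only.values = TRUE)$values)
  a <- weights / (1 + lam_max)
  sv <- svd(a)
  n <- nrow(a)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      acc <- acc + (1 - sv$d[j]^2) * sv$u[i, j]^2
    }
    phi[i] <- acc
  }
  phi
}

# Balanced two-visit accuracy cells for stats tests: one row per
# subject x task x target x stimulation, built from a base mean plus
# optional per-factor shifts and Gaussian noise.
make_cells <- function(n_subj = 10, seed = 1, base = 0.75,
                       task_shift = 0, stim_shift = 0, noise = 0.05) {
  withr::with_seed(seed, {
    grid <- expand.grid(
      subject = sprintf("s%02d", seq_len(n_subj)),
      task = c("DRAT", "DRMT"),
      target = c("DLPFC", "LPC"),
      stimulation = c("active", "sham"),
      stringsAsFactors = FALSE
    )
    grid$accuracy <- base +
      ifelse(grid$task == "DRMT", task_shift, 0) +
      ifelse(grid$stimulation == "active", stim_shift, 0) +
      rnorm(nrow(grid), sd = noise)
    grid
  })
}

default_levels <- function(easy = 5L) {
  structure(list(easy = easy, medium = easy + 1L, hard = easy + 2L,
                 threshold = 0.82),
            class = "difficulty_levels")
}
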