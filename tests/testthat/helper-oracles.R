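# Independent oracles used to verify the package's recursive/vectorized
# computations.  These deliberately use naive exhaustive enumeration and
# plain loops, sharing no code path with the implementations they check.

# Marginal likelihood of a cue sequence and posterior of the final hidden
# state, by summing the joint probability over all 2^t hidden state paths.
oracle_forward <- function(cues, process, reliability, start = "stationary") {
  cues <- as.integer(cues)
  t <- length(cues)
  m <- transition_matrix(process)
  start_p <- switch(start,
                    stationary = unname(stationary_distribution(process)),
                    E0 = c(1, 0), E1 = c(0, 1))
  paths <- as.matrix(expand.grid(rep(list(0:1), t)))
  lik_total <- 0
  p_last_e1 <- 0
  for (i in seq_len(nrow(paths))) {
    s <- paths[i, ]
    p <- start_p[s[1] + 1]
    if (t > 1)
      for (j in 2:t) p <- p * m[s[j - 1] + 1, s[j] + 1]
    for (j in seq_len(t))
      p <- p * if (cues[j] == s[j]) reliability else 1 - reliability
    lik_total <- lik_total + p
    if (s[t] == 1) p_last_e1 <- p_last_e1 + p
  }
  list(belief = p_last_e1 / lik_total, likelihood = lik_total)
}

# All cue sequences of length t as a matrix of 0/1 rows, period 1 in column 1,
# ordered to match the lattice node numbering (row k = bits of k - 1, MSB
# first).
oracle_sequences <- function(t) {
  as.matrix(expand.grid(rep(list(0:1), t))[, t:1, drop = FALSE])
}

# Walk one explicit cue sequence through a solved policy using plain loops,
# returning the mature phenotype.  Node indices are recomputed from the raw
# cue bits rather than taken from the package's walker.
oracle_walk <- function(policy, cues) {
  y0 <- 0L; y1 <- 0L
  for (t in seq_along(cues)) {
    # node of the length-t prefix: bits MSB-first
    bits <- cues[seq_len(t)]
    node <- sum(bits * 2L^((t - 1L):0L)) + 1L
    phen_j <- phen_index_oracle(y0, y1, t - 1L)
    a <- policy$action[[t]][node, phen_j]
    if (a == 2L) y0 <- y0 + 1L else if (a == 3L) y1 <- y1 + 1L
  }
  c(y0 = y0, y1 = y1)
}

# index of (y0, y1) in the package's y0-major phenotype grid with
# y0 + y1 <= max_total (re-derived by counting, not reusing phen_index)
phen_index_oracle <- function(y0, y1, max_total) {
  count <- 0L
  for (a in 0:max_total)
    for (b in 0:(max_total - a)) {
      count <- count + 1L
      if (a == y0 && b == y1) return(count)
    }
  stop("phenotype not in grid")
}

# Adoption study by explicit pair-by-pair loops: enumerate focal sequences,
# flip the tail for the copy, walk both, and average distances.
oracle_adoption <- function(policy, start_env, sep) {
  T_ont <- policy$T_ont
  seqs <- oracle_sequences(T_ont)
  total <- 0
  r <- policy$cue_model$reliability
  for (i in seq_len(nrow(seqs))) {
    focal <- as.integer(seqs[i, ])
    copy <- focal
    copy[sep:T_ont] <- 1L - copy[sep:T_ont]
    pf <- oracle_walk(policy, focal)
    pc <- oracle_walk(policy, copy)
    w <- oracle_forward(focal, policy$process, r, start_env)$likelihood
    total <- total + w * sqrt(sum((pf - pc)^2))
  }
  total / (sqrt(2) * (T_ont - sep + 1))
}

# phenotype grid (y0 + y1 <= max_total) in the package's y0-major order,
# re-derived with plain loops
phen_grid_df <- function(max_total) {
  rows <- list()
  for (a in 0:max_total)
    for (b in 0:(max_total - a))
      rows[[length(rows) + 1L]] <- data.frame(y0 = a, y1 = b)
  do.call(rbind, rows)
}

# default small configurations reused across tests
sym_proc <- function() env_process(0.1, 0.1)
asym_proc <- function() env_process(0.3, 0.2)
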