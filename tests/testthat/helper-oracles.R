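# Independent brute-force oracle for sample entropy: direct enumeration of
# ordered template pairs (vectorized only over the second index), kept
# deliberately separate from the package's compiled counting kernel.
sampen_oracle <- function(x, m = 2, r_factor = 0.2) {
  N <- length(x)
  r <- r_factor * stats::sd(x)
  if (!is.finite(r) || r == 0) return(NA_real_)
  n <- N - m
  B <- 0; A <- 0
  for (i in 1:(n - 1)) {
    js <- (i + 1):n
    dm <- abs(x[js] - x[i])
    if (m > 1) for (k in 1:(m - 1)) dm <- pmax(dm, abs(x[js + k] - x[i + k]))
    hit <- dm <= r
    B <- B + 2 * sum(hit)
    A <- A + 2 * sum(hit & abs(x[js + m] - x[i + m]) <= r)
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# one clean four-channel test session with a single planted forward edge
make_coupled_session <- function(seed, strength = 0.4, source = "AF07",
                                 target = "TP10", duration_s = 66,
                                 line_noise_uv = 5) {
  edges <- data.frame(source = source, target = target, strength = strength)
  vm <- make_var_model(edges, base_diag = 0.3, order = 1)
  generate_session(vm, duration_s = duration_s,
                   plan = artifact_plan(line_noise_uv = line_noise_uv),
                   seed = seed)
}

# epochs cut straight from a VAR simulation (no filtering), for tests whose
# subject is the downstream analysis rather than the cleaning chain
make_var_epochs <- function(model, n_epochs, seed, epoch_len = 1320) {
  x <- simulate_var(model, n_epochs * epoch_len, seed = seed)
  rownames(x) <- model$channels
  lapply(seq_len(n_epochs), function(i)
    x[, ((i - 1) * epoch_len + 1):(i * epoch_len), drop = FALSE])
}
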