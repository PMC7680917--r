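# Shared fixtures: everything is generated in code at test time.

# Single uncoupled oscillator with the optimised decay rate.
single_net <- function(alpha = 0.849) network_spec(1L, alpha = alpha, beta = 0)

# Coarse-but-count-safe integrator: h = 1e-3, sampling interval 0.01.
coarse_cfg <- function(t_max) integrator_config(t_max, h = 1e-3, store_stride = 10L)

fine_cfg <- function(t_max) integrator_config(t_max, h = 1e-4, store_stride = 100L)

# Single-oscillator French-flag genome of the worked example.
french_genome <- function() {
  network_genome("normal", t_ilum3 = 0, t_start = 0, t_end = 32.4,
                 t_max = 47, alpha = 0.849, beta = 0)
}

# Maxima count of a lone oscillator released at t_ilum, observed on [0, t_max].
single_osc_count <- function(t_ilum, alpha = 0.849, t_max = 47, h = 1e-3) {
  cfg <- integrator_config(t_max, h = h,
                           store_stride = as.integer(round(0.01 / h)))
  traj <- integrate_network(oregonator_params(), single_net(alpha),
                            illumination_schedule(t_ilum), cfg)
  count_maxima(traj)
}

# Random joint contingency table (2 x k) with at least one non-zero cell.
random_joint <- function(k = 4L, n_max = 50L) {
  m <- matrix(sample(0:n_max, 2L * k, replace = TRUE), nrow = 2L)
  if (sum(m) == 0) m[1, 1] <- 1L
  m
}

# Brute-force double-sum mutual information oracle (bits), independent of
# the entropy-decomposition implementation.
mi_double_sum <- function(joint) {
  N <- sum(joint)
  pg <- rowSums(joint) / N
  po <- colSums(joint) / N
  s <- 0
  for (i in seq_len(nrow(joint))) {
    for (j in seq_len(ncol(joint))) {
      pij <- joint[i, j] / N
      if (pij > 0) s <- s + pij * log2(pij / (pg[i] * po[j]))
    }
  }
  s
}
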