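# Shared fixtures, built in code at test time.

# pure one-step network: only channel A is live, substrate pool n_total
one_step_params <- function(k_a = 1e-5, x0 = 1e4, n_total = 3) {
  network_params(x0 = x0, x1_total = 0, x2_total = 0, x3_total = n_total,
                 k_a = k_a, k_b1 = 0, k_b2 = 0, k_b3 = 0)
}

# deep stochastic (all-or-none) regime: slow intermediate step well below
# the aggregate fast rates, stimulus below the type B threshold
weak_params <- function() network_preset("weak")

# empirical total-variation distance between a sample of counts and a
# probability vector over 0..n
tv_distance <- function(counts, probs) {
  n <- length(probs) - 1
  emp <- tabulate(counts + 1, nbins = n + 1) / length(counts)
  sum(abs(emp - probs)) / 2
}

# replace the activated-X3 record of every cell in an ensemble (keeps the
# object structure; used to build exactly-known populations)
set_x3a <- function(ensemble, per_cell_x3a) {
  for (i in seq_along(ensemble$trajectories)) {
    st <- ensemble$trajectories[[i]]$states
    st$x3a <- per_cell_x3a[[i]]
    st$x3 <- ensemble$params$x3_total - st$x3a
    ensemble$trajectories[[i]]$states <- st
  }
  ensemble
}

# per-cell 10% -> 90% rise times and half-activation spread diagnostics
all_or_none_stats <- function(ensemble) {
  t10 <- activation_times(ensemble, theta = 0.1)$time
  t90 <- activation_times(ensemble, theta = 0.9)$time
  half <- activation_times(ensemble, theta = 0.5)$time
  list(rise = t90 - t10,
       half = half,
       spread = unname(diff(stats::quantile(half, c(0.1, 0.9),
                                            na.rm = TRUE))))
}
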