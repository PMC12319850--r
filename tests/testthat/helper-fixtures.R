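# Shared helpers for the suite. All fixtures are generated in code.

rand_spd <- riemnet:::rand_spd

# Tiny labelled SPD sets: two classes of diagonally-dominant matrices whose
# dominant axes differ, separable in the tangent space.
two_class_spd <- function(n_per_class = 8, dim = 3, seed = 1) {
  set.seed(seed)
  make <- function(base) {
    lapply(seq_len(n_per_class), function(i) {
      base + 0.05 * rand_spd(dim, spread = 0.3)
    })
  }
  b1 <- diag(c(4, 1, 1))
  b2 <- diag(c(1, 1, 4))
  list(S = c(make(b1), make(b2)),
       y = factor(rep(c("a", "b"), each = n_per_class)))
}

# Tiny network + data for optimisation and probing tests.
tiny_net_data <- function(seed = 1, kind = "conv", n_bire = 1, nf = 1,
                          specificity = "chind", n_per_class = 15) {
  cfg <- synth_config(ne = 4, nt = 256, fs = 128, n_classes = 2,
                      n_trials_per_class = n_per_class,
                      planted_bands = list(
                        list(list(electrodes = 1:2, band = c(10, 20), power = 1)),
                        list(list(electrodes = 3:4, band = c(30, 45), power = 1))),
                      snr = 4, seed = seed)
  ts <- generate_trials(cfg)
  net <- network_config(ne = 4, n_classes = 2, fs = 128, nf = nf,
                        n_bire = n_bire, kind = kind,
                        specificity = specificity, seed = seed)
  list(trials = ts, config = net)
}
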