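# Shared fixture builders. Everything is generated in code at test time.

# Two (or more) well-separated integer "blobs" as a cbce_matrix: class c
# lives near 10*c on its own coordinate, so classes are trivially separable.
blob_matrix <- function(n_per_class = 20L, n_classes = 2L, L = 4L,
                        seed = 42L, encoding = "numeric") {
  withr_seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_classes), function(c) {
    base <- matrix(sample(0:1, n_per_class * L, replace = TRUE),
                   n_per_class, L)
    base[, ((c - 1L) %% L) + 1L] <- 10L * c + sample(0:2, n_per_class,
                                                     replace = TRUE)
    base
  }))
  colnames(rows) <- paste0("s", seq_len(L))
  labels <- rep(paste0("class", seq_len(n_classes)), each = n_per_class)
  cbce_matrix(rows, labels, encoding)
}

# Binary-encoded smart-home-like synthetic data.
smarthome_binary <- function(n = 245L, seed = 2L, noise = 0) {
  cfg <- default_smarthome_config(n = n, noise = noise)
  encode_instances(generate_instances(cfg, seed = seed),
                   kasteren_inventory(), "binary")
}

# set.seed without leaking state decisions into other tests
withr_seed <- function(seed) set.seed(seed)

# Random event sequence over an inventory
random_sequence <- function(inv, max_len = 12L) {
  n <- sample(0:max_len, 1L)
  sample(unclass(inv), n, replace = TRUE)
}
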