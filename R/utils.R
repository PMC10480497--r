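# Internal helpers shared across modules.

# Deterministic sub-stream seed derived from a master seed. Keeps results
# reproducible when one user-facing seed drives several independent draws.
# Always below 2^31 - 1 so it is a valid R integer seed.
.sub_seed <- function(seed, offset) {
  (abs(as.numeric(seed)) * 7919 + 104729 * offset) %% 2147483647
}

# Spearman rank correlation with average ranks for ties.
.spearman <- function(x, y = NULL) {
  stats::cor(x, y, method = "spearman")
}

# Ascending rank with deterministic tie-break chain: primary key first,
# then secondary, then lexicographic ID. Returns integer positions 1..n.
.tie_break_order <- function(primary, secondary, ids) {
  order(primary, secondary, ids, method = "radix")
}
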