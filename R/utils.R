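# Internal helpers shared across modules.

# Edge weights as a plain numeric vector; an edgeless graph yields numeric(0).
edge_weights <- function(net) {
  w <- igraph::E(net)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(net))
  as.numeric(w)
}

# Edge endpoints as an ecount x 2 integer matrix of vertex indices.
edge_ends <- function(net) {
  igraph::ends(net, igraph::E(net), names = FALSE)
}

# Sum of the k largest values of x (all of x when k >= length(x); 0 when k <= 0).
sum_top <- function(x, k) {
  if (k <= 0 || length(x) == 0) return(0)
  k <- min(k, length(x))
  sum(sort(x, decreasing = TRUE)[seq_len(k)])
}

# Seed the RNG for the duration of the caller's frame, restoring state after.
local_seed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(seed, .local_envir = env)
  invisible(seed)
}

# Deterministic per-control child seeds: drawn once under the parent seed so
# control i is reproducible and the streams are independent across i.
child_seeds <- function(n) {
  sample.int(2147483646L, n, replace = TRUE)
}

# 17-significant-digit formatting: round-trips doubles exactly through text.
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}
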