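# Shared fixtures, built in code.

# Hand-built 4-node chain with distinctive weights: a-b (2), b-c (3), c-d (9).
toy_chain <- function() {
  weighted_network(c("a", "b", "c"), c("b", "c", "d"), c(2, 3, 9))
}

# Complete graph on k named nodes with the given constant weight.
complete_net <- function(k, weight = 1) {
  pairs <- utils::combn(k, 2)
  weighted_network(letters[pairs[1, ]], letters[pairs[2, ]], weight)
}

# Star: hub "h" linked to n_leaves leaves.
star_net <- function(n_leaves, weights = 1) {
  weighted_network(rep("h", n_leaves), paste0("l", seq_len(n_leaves)), weights)
}

# Random weighted network shorthand used across property tests.
rand_net <- function(n, p, seed, law = weight_law("uniform", min = 0.1, max = 2)) {
  er_weighted(n, p, law, seed = seed)
}
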