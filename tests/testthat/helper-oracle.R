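# Brute-force oracles, coded independently of the package internals: they
# work from the raw edge table and explicit pair enumeration only.

# Edge table as a plain data frame (from, to, weight).
oracle_edges <- function(net) {
  ends <- igraph::ends(net, igraph::E(net), names = TRUE)
  data.frame(from = ends[, 1], to = ends[, 2],
             weight = igraph::E(net)$weight, stringsAsFactors = FALSE)
}

# N, E, P, C by exhaustive enumeration of member pairs.
oracle_club_stats <- function(net, members) {
  ed <- oracle_edges(net)
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  N <- length(members)
  E <- 0L
  C <- 0
  if (N >= 2) {
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        k <- paste(min(members[i], members[j]), max(members[i], members[j]))
        hit <- which(key == k)
        if (length(hit)) {
          E <- E + 1L
          C <- C + ed$weight[hit]
        }
      }
    }
  }
  list(N = N, E = E, P = N * (N - 1) / 2, C = C)
}

# Maximal connectedness by explicit candidate-set construction.
oracle_F <- function(net, members, budget, source, w_max = NULL) {
  ed <- oracle_edges(net)
  st <- oracle_club_stats(net, members)
  L <- nrow(ed)
  if (source == "capped") {
    k <- switch(budget, P = st$P, E = st$E, all = min(L, st$P))
    return(k * w_max)
  }
  cand <- switch(source,
    global = ed$weight,
    local = ed$weight[ed$from %in% members | ed$to %in% members])
  if (budget == "all") return(sum(cand))
  k <- min(switch(budget, P = st$P, E = st$E), length(cand))
  if (k <= 0) return(0)
  sum(sort(cand, decreasing = TRUE)[seq_len(k)])
}

# Independent Maslov-Sneppen double-edge-swap rewiring, pure R, for
# cross-checking the topological control ensemble.
oracle_rewire <- function(net, n_swaps) {
  ed <- oracle_edges(net)
  m <- nrow(ed)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- key(ed$from, ed$to)
  for (s in seq_len(n_swaps)) {
    ij <- sample.int(m, 2)
    a <- ed$from[ij[1]]; b <- ed$to[ij[1]]
    c_ <- ed$from[ij[2]]; d <- ed$to[ij[2]]
    # the two admissible re-pairings of {(a,b),(c,d)}: choose one at random
    if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    if (a == d || c_ == b) next
    k1 <- key(a, d); k2 <- key(c_, b)
    if (k1 %in% keys || k2 %in% keys || k1 == k2) next
    ed$from[ij[1]] <- a; ed$to[ij[1]] <- d
    ed$from[ij[2]] <- c_; ed$to[ij[2]] <- b
    keys[ij[1]] <- k1
    keys[ij[2]] <- k2
  }
  ed
}

# C of the club at a degree threshold, straight from an edge table.
oracle_c_at <- function(ed, threshold, weights = NULL) {
  nodes <- unique(c(ed$from, ed$to))
  deg <- sapply(nodes, function(v) sum(ed$from == v) + sum(ed$to == v))
  club <- nodes[deg > threshold]
  w <- if (is.null(weights)) rep(1, nrow(ed)) else weights
  sum(w[ed$from %in% club & ed$to %in% club])
}
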