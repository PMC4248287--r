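#' Degree-preserving randomized control (topological)
#'
#' Randomizes link placement while preserving the degree sequence exactly,
#' by repeated double-edge swaps starting from the real network
#' (Maslov-Sneppen rewiring); swaps that would create self-loops or
#' duplicate links are rejected. All weights are set to 1, because this
#' control is used to detect purely topological rich clubs, for which link
#' weights are ignored.
#'
#' @param net a weighted network (igraph) with at least 2 links.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param n_swaps number of attempted swaps; the default, 10 times the link
#'   count, is the usual mixing heuristic for configuration-model rewiring.
#' @return a network with the same nodes and degree sequence, unit weights.
#' @export
topological_control <- function(net, seed = NULL, n_swaps = 10 * igraph::ecount(net)) {
  if (igraph::ecount(net) < 2) {
    stop("degree-preserving rewiring needs at least 2 links")
  }
  local_seed(seed)
  g <- igraph::rewire(net, igraph::keeping_degseq(loops = FALSE, niter = n_swaps))
  igraph::E(g)$weight <- 1
  g
}

# Symmetric iterative proportional rescaling of link weights toward a target
# strength sequence on a fixed topology. Each sweep multiplies w_ij by
# sqrt(f_i f_j) with f_i = s_target_i / s_current_i; convergence is declared
# when every node's strength is within relative tolerance tol of its target.
ipf_strengths <- function(ends, n, w, s_target, tol, max_iter) {
  i1 <- ends[, 1]
  i2 <- ends[, 2]
  B <- Matrix::sparseMatrix(i = c(i1, i2), j = rep(seq_along(w), 2L),
                            x = 1, dims = c(n, length(w)))
  active <- s_target > 0
  dev <- Inf
  for (it in seq_len(max_iter)) {
    s_cur <- as.numeric(B %*% w)
    dev <- max(abs(s_cur[active] - s_target[active]) / s_target[active])
    if (dev < tol) return(w)
    f <- rep(1, n)
    f[active] <- s_target[active] / s_cur[active]
    w <- w * sqrt(f[i1] * f[i2])
  }
  stop(sprintf(paste0("strength rescaling did not converge in %d iterations ",
                      "(worst relative strength deviation %.3g)"),
       max_iter, dev))
}

#' Topology-preserving weight-decorrelating control (weighted)
#'
#' Keeps the link set identical and replaces the weights by decorrelated
#' values that closely preserve the strength sequence: the weight multiset is
#' globally permuted over the fixed links, then iterative proportional
#' rescaling drives every node's strength to within relative tolerance
#' \code{tol} of its original value. Rescaled weights are real-valued even if
#' the inputs were integers (e.g. fiber counts); no re-rounding is applied,
#' since rounding would break strength preservation and only weight sums
#' enter C.
#'
#' @param net a weighted network (igraph).
#' @param seed integer seed, or NULL.
#' @param tol relative strength tolerance (default 1e-3).
#' @param max_iter rescaling iteration cap; non-convergence is an error
#'   reporting the worst strength deviation.
#' @return a network with the same topology and decorrelated weights.
#' @export
weighted_control <- function(net, seed = NULL, tol = 1e-3, max_iter = 10000L) {
  if (tol <= 0) stop("`tol` must be positive")
  L <- igraph::ecount(net)
  if (L == 0) return(net)
  local_seed(seed)
  w0 <- edge_weights(net)
  w <- w0[sample.int(L)]
  w <- ipf_strengths(edge_ends(net), igraph::vcount(net), w,
                     as.numeric(node_strength(net)), tol, max_iter)
  igraph::E(net)$weight <- w
  net
}

#' Combined control: shuffled topology and decorrelated weights (mixed)
#'
#' Composes the two controls: link placement is randomized by
#' degree-preserving rewiring, then the original weight multiset is permuted
#' onto the new links and rescaled toward the original strength sequence.
#' This control conflates topological and weighted rich-club structure by
#' design; it answers "is the club's weighted connectedness high given only
#' the degree sequence?".
#'
#' @inheritParams weighted_control
#' @return a rewired, reweighted network with the original degree sequence.
#' @export
mixed_control <- function(net, seed = NULL, tol = 1e-3, max_iter = 10000L) {
  local_seed(seed)
  w0 <- edge_weights(net)
  s_t <- as.numeric(node_strength(net))
  g <- topological_control(net, seed = NULL)
  w <- w0[sample.int(length(w0))]
  igraph::E(g)$weight <- ipf_strengths(edge_ends(g), igraph::vcount(g), w,
                                       s_t, tol, max_iter)
  g
}

#' Per-node weight shuffle for directed networks
#'
#' For each node independently, permutes the weights among that node's
#' outgoing (or incoming) links, leaving topology untouched. This preserves
#' each node's out-strength (or in-strength) exactly, as well as the global
#' weight multiset and each node's out-/in-weight multiset. The orientation
#' of the links is carried by the directed graph itself.
#'
#' @param net a \emph{directed} igraph with positive link weights.
#' @param mode \code{"out"} to shuffle each node's outgoing weights,
#'   \code{"in"} for incoming.
#' @param seed integer seed, or NULL.
#' @return the network with shuffled weights.
#' @export
directed_weight_shuffle <- function(net, mode = c("out", "in"), seed = NULL) {
  mode <- match.arg(mode)
  if (!igraph::is_igraph(net)) stop("`net` must be an igraph object")
  if (!igraph::is_directed(net)) {
    stop("every link must be oriented: supply a directed graph")
  }
  w <- edge_weights(net)
  if (length(w) == 0) return(net)
  if (any(!is.finite(w) | w <= 0)) {
    stop("link weights must be strictly positive and finite")
  }
  local_seed(seed)
  ends <- edge_ends(net)
  anchor <- if (mode == "out") ends[, 1] else ends[, 2]
  for (grp in split(seq_along(w), anchor)) {
    if (length(grp) > 1) w[grp] <- w[grp][sample.int(length(grp))]
  }
  igraph::E(net)$weight <- w
  net
}

#' Build a null ensemble of C_rand values
#'
#' Generates \code{n_rand} independent randomized controls of the requested
#' kind and records, for every control and every richness threshold, the
#' weighted connectedness C_rand of the control's club. Club membership is
#' recomputed from each control's own richness values: for sequence-preserved
#' richness (degree under any control here, custom values under all) this
#' reproduces clubs of identical size at every threshold, and for
#' structure-dependent richness (strength) it is the only faithful reading.
#'
#' Child seeds for the controls are drawn once under \code{seed}, so the
#' ensemble is reproducible and controls are independent.
#'
#' @param net a weighted network (igraph).
#' @param kind \code{"topological"} (degree-preserving, unit weights),
#'   \code{"weighted"} (topology-preserving, decorrelated weights), or
#'   \code{"mixed"} (both randomizations).
#' @param thresholds numeric vector of richness cutoffs.
#' @param richness richness parameter; see [node_richness()].
#' @param n_rand number of controls (the reference analyses use 1000).
#' @param seed integer seed, or NULL.
#' @param tol strength tolerance passed to the weight-decorrelating controls.
#' @return an object of class \code{null_ensemble}: list with \code{kind},
#'   \code{n_rand}, \code{thresholds}, \code{c_samples} (an
#'   \code{n_rand} x \code{length(thresholds)} matrix), \code{seed}.
#' @export
build_ensemble <- function(net, kind = c("topological", "weighted", "mixed"),
                           thresholds, richness = "degree",
                           n_rand = 1000L, seed = NULL, tol = 1e-3) {
  kind <- match.arg(kind)
  n_rand <- as.integer(n_rand)
  if (is.na(n_rand) || n_rand < 1) stop("`n_rand` must be at least 1")
  thresholds <- as.numeric(thresholds)
  local_seed(seed)
  seeds <- child_seeds(n_rand)
  base <- if (kind == "topological") strip_weights(net) else net
  K <- length(thresholds)
  cs <- matrix(0, nrow = n_rand, ncol = K)
  for (i in seq_len(n_rand)) {
    ctrl <- switch(kind,
      topological = topological_control(base, seed = seeds[i]),
      weighted    = weighted_control(base, seed = seeds[i], tol = tol),
      mixed       = mixed_control(base, seed = seeds[i], tol = tol))
    r <- as.numeric(node_richness(ctrl, richness))
    if (igraph::ecount(ctrl) > 0) {
      ends <- edge_ends(ctrl)
      w <- edge_weights(ctrl)
      rmin <- pmin(r[ends[, 1]], r[ends[, 2]])
      cs[i, ] <- vapply(thresholds, function(t) sum(w[rmin > t]), numeric(1))
    }
  }
  structure(list(kind = kind, n_rand = n_rand, thresholds = thresholds,
                 c_samples = cs, seed = seed),
            class = "null_ensemble")
}
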