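#' Link-weight distributions for the synthetic generators
#'
#' @param family \code{"uniform"} on (min, max), \code{"lognormal"} with the
#'   given log-scale parameters, or \code{"constant"}.
#' @param min,max uniform support; \code{min} must be nonnegative (weights
#'   are strictly positive; a draw of exactly 0 is redrawn).
#' @param meanlog,sdlog lognormal parameters.
#' @param value constant weight.
#' @return an object of class \code{weight_law}.
#' @export
weight_law <- function(family = c("uniform", "lognormal", "constant"),
                       min = 0, max = 1, meanlog = 0, sdlog = 1, value = 1) {
  family <- match.arg(family)
  params <- switch(family,
    uniform = {
      if (min < 0 || max <= min) stop("uniform law needs 0 <= min < max")
      list(min = min, max = max)
    },
    lognormal = {
      if (sdlog < 0) stop("lognormal law needs sdlog >= 0")
      list(meanlog = meanlog, sdlog = sdlog)
    },
    constant = {
      if (!is.finite(value) || value <= 0) stop("constant weight must be positive")
      list(value = value)
    })
  structure(list(family = family, params = params), class = "weight_law")
}

# Draw m strictly positive weights from a weight_law.
draw_weights <- function(law, m) {
  if (!inherits(law, "weight_law")) stop("`law` must be a weight_law object")
  p <- law$params
  w <- switch(law$family,
    uniform   = stats::runif(m, p$min, p$max),
    lognormal = stats::rlnorm(m, p$meanlog, p$sdlog),
    constant  = rep(p$value, m))
  while (any(w <= 0)) {  # guard against a uniform draw of exactly min = 0
    idx <- which(w <= 0)
    w[idx] <- switch(law$family,
      uniform   = stats::runif(length(idx), p$min, p$max),
      lognormal = stats::rlnorm(length(idx), p$meanlog, p$sdlog),
      constant  = rep(p$value, length(idx)))
  }
  w
}

#' Erdos-Renyi network with random link weights
#'
#' Each unordered node pair is linked independently with probability p;
#' linked pairs draw i.i.d. weights from \code{law}. This is the fully
#' unstructured baseline: it contains no planted club, so normalized
#' rich-club curves on it should hover around 1.
#'
#' @param n number of nodes (named "1".."n").
#' @param p link probability in (0, 1].
#' @param law a [weight_law()]; default uniform(0, 1).
#' @param seed integer seed, or NULL.
#' @return a weighted network (igraph).
#' @export
er_weighted <- function(n, p, law = weight_law("uniform"), seed = NULL) {
  if (!(p > 0 && p <= 1)) stop("`p` must lie in (0, 1]")
  local_seed(seed)
  g <- igraph::sample_gnp(n, p, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  m <- igraph::ecount(g)
  g <- igraph::set_edge_attr(g, "weight", value = draw_weights(law, m))
  g
}

#' Plant a topological rich club
#'
#' Generates an Erdos-Renyi backbone in which a designated set of nodes is
#' wired more densely among itself: pairs inside the planted set are linked
#' with probability \code{club_p}, all other pairs with \code{baseline_p}.
#' Weights are i.i.d. regardless of membership, so the planted structure is
#' purely in link placement — the signature a degree-preserving
#' (topological) control detects. With \code{club_p = baseline_p} the output
#' is statistically indistinguishable from [er_weighted()].
#'
#' @param n_nodes total nodes.
#' @param club_size size of the planted set (the first \code{club_size}
#'   nodes).
#' @param baseline_p,club_p link probabilities in (0, 1].
#' @param law a [weight_law()].
#' @param seed integer seed, or NULL.
#' @return list with \code{network} and \code{club} (the planted node
#'   names), for ground-truth checks.
#' @export
plant_topological_club <- function(n_nodes, club_size, baseline_p, club_p,
                                   law = weight_law("uniform"), seed = NULL) {
  if (club_size > n_nodes) stop("`club_size` cannot exceed `n_nodes`")
  if (!(baseline_p > 0 && baseline_p <= 1) || !(club_p > 0 && club_p <= 1)) {
    stop("link probabilities must lie in (0, 1]")
  }
  local_seed(seed)
  pairs <- utils::combn(n_nodes, 2)
  intra <- pairs[1, ] <= club_size & pairs[2, ] <= club_size
  prob <- ifelse(intra, club_p, baseline_p)
  keep <- stats::runif(ncol(pairs)) < prob
  from <- as.character(pairs[1, keep])
  to <- as.character(pairs[2, keep])
  net <- weighted_network(from, to, draw_weights(law, sum(keep)),
                          nodes = as.character(seq_len(n_nodes)))
  list(network = net, club = as.character(seq_len(club_size)))
}

#' Plant a weighted rich club
#'
#' Generates a single Erdos-Renyi topology, anchors the planted club to the
#' \code{club_size} highest-degree nodes of that fixed topology (so that
#' degree-based richness finds it), and multiplies the weights of the links
#' \emph{between} club members by \code{boost}. The link set is untouched:
#' the planted structure is purely in weight allocation — the signature a
#' topology-preserving (weighted) control detects, and one a topological
#' control is blind to. As \code{boost} approaches 1 the output reduces to
#' [er_weighted()].
#'
#' @param n_nodes total nodes.
#' @param club_size planted club size; ties in the degree ranking are broken
#'   by node order. All selected nodes must have at least one link.
#' @param baseline_p link probability of the backbone.
#' @param boost multiplicative intra-club weight factor, >= 1.
#' @param law a [weight_law()].
#' @param seed integer seed, or NULL.
#' @return list with \code{network} and \code{club}.
#' @export
plant_weighted_club <- function(n_nodes, club_size, baseline_p, boost,
                                law = weight_law("uniform"), seed = NULL) {
  if (club_size > n_nodes) stop("`club_size` cannot exceed `n_nodes`")
  if (boost < 1) stop("`boost` must be >= 1")
  local_seed(seed)
  net <- er_weighted(n_nodes, baseline_p, law, seed = NULL)
  deg <- node_degree(net)
  ord <- order(deg, decreasing = TRUE)
  club <- igraph::V(net)$name[ord[seq_len(club_size)]]
  if (any(deg[club] == 0)) {
    stop("not enough connected high-degree nodes to host a club of size ",
         club_size)
  }
  if (igraph::ecount(net) > 0 && boost > 1) {
    ends <- igraph::ends(net, igraph::E(net), names = TRUE)
    intra <- ends[, 1] %in% club & ends[, 2] %in% club
    w <- edge_weights(net)
    w[intra] <- w[intra] * boost
    igraph::E(net)$weight <- w
  }
  list(network = net, club = club)
}
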