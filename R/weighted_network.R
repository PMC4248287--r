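#' Construct a weighted undirected network
#'
#' Builds the canonical network object used throughout the package: a simple
#' undirected igraph with a \code{name} vertex attribute and a strictly
#' positive, finite \code{weight} on every link. Self-loops, duplicate links
#' (multigraph input) and non-positive weights are errors, not silently
#' repaired: the framework distinguishes topology (link existence) from
#' weights, and a zero weight or a collapsed multi-link would conflate the
#' two and change both the intra-club link count E and the weighted
#' connectedness C.
#'
#' @param from,to character vectors (or coercible) of link endpoints.
#' @param weight numeric vector of positive link weights; defaults to 1 for
#'   every link, which recovers an unweighted network.
#' @param nodes optional character vector of node identifiers to include even
#'   if they carry no links (isolated nodes cannot be declared by an edge
#'   list alone).
#' @return an undirected igraph object with \code{name} and \code{weight}
#'   attributes.
#' @examples
#' net <- weighted_network(c("a", "b"), c("b", "c"), c(2, 3))
#' node_strength(net)
#' @export
weighted_network <- function(from, to, weight = NULL, nodes = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) {
    stop("`from` and `to` must have the same length")
  }
  m <- length(from)
  if (is.null(weight)) weight <- rep(1, m)
  weight <- as.numeric(weight)
  if (length(weight) == 1L && m > 1L) weight <- rep(weight, m)
  if (length(weight) != m) {
    stop("`weight` must have one value per link")
  }
  if (m > 0) {
    bad <- which(!is.finite(weight) | weight <= 0)
    if (length(bad)) {
      stop("link weights must be strictly positive and finite; offending link ",
           bad[1], " (", from[bad[1]], " -- ", to[bad[1]], ") has weight ",
           weight[bad[1]])
    }
    loops <- which(from == to)
    if (length(loops)) {
      stop("self-loops are not allowed: link ", loops[1], " (",
           from[loops[1]], " -- ", to[loops[1]], ")")
    }
    key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup)) {
      stop("duplicate link ", from[dup[1]], " -- ", to[dup[1]],
           "; multigraph input is not supported")
    }
  }
  verts <- unique(c(from, to, as.character(nodes)))
  if (length(verts) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::set_edge_attr(g, "weight", value = numeric(0))
    return(g)
  }
  d <- data.frame(from = from, to = to, weight = weight,
                  stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(d, directed = FALSE, vertices = verts)
}

#' Validate an igraph object as a weighted network
#'
#' Checks the invariants every analysis function relies on (undirected,
#' simple, positive finite weights) and fills in defaults: unnamed vertices
#' get their index as name, and a missing \code{weight} attribute is set
#' to 1 on every link.
#'
#' @param g an igraph object.
#' @return the validated (possibly attribute-augmented) graph.
#' @export
as_weighted_network <- function(g) {
  if (!igraph::is_igraph(g)) stop("`g` must be an igraph object")
  if (igraph::is_directed(g)) stop("network must be undirected")
  if (igraph::any_loop(g)) stop("self-loops are not allowed")
  if (igraph::any_multiple(g)) stop("duplicate links are not allowed")
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  if (igraph::ecount(g) > 0) {
    w <- igraph::E(g)$weight
    if (is.null(w)) {
      igraph::E(g)$weight <- 1
    } else if (any(!is.finite(w) | w <= 0)) {
      stop("link weights must be strictly positive and finite")
    }
  }
  g
}

#' Node degree
#'
#' Number of links incident upon each node.
#'
#' @param net a weighted network (igraph).
#' @return named numeric vector, one entry per node.
#' @export
node_degree <- function(net) {
  igraph::degree(net, loops = FALSE)
}

#' Node strength
#'
#' Sum of the weights of each node's incident links; with unit weights this
#' equals the degree.
#'
#' @param net a weighted network (igraph).
#' @return named numeric vector, one entry per node.
#' @export
node_strength <- function(net) {
  igraph::strength(net, weights = edge_weights(net))
}

#' Node richness
#'
#' Richness is any node property by which all nodes can be ranked; the rich
#' club at threshold r is the set of nodes whose richness strictly exceeds r.
#' Built-in parameters are degree and strength; any other ranking can be
#' supplied as a named numeric vector covering every node.
#'
#' @param net a weighted network (igraph).
#' @param richness \code{"degree"}, \code{"strength"}, or a named numeric
#'   vector of custom richness values (one per node).
#' @return named numeric vector of richness values in vertex order.
#' @export
node_richness <- function(net, richness = "degree") {
  if (is.numeric(richness)) {
    nm <- igraph::V(net)$name
    if (is.null(names(richness))) {
      stop("custom richness values must be named by node")
    }
    missing <- setdiff(nm, names(richness))
    if (length(missing)) {
      stop("custom richness is missing node(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    r <- richness[nm]
    if (any(!is.finite(r))) stop("richness values must be finite")
    return(r)
  }
  richness <- match.arg(richness, c("degree", "strength"))
  switch(richness,
         degree = node_degree(net),
         strength = node_strength(net))
}

# Replace all weights by 1 (topological view of a network).
strip_weights <- function(net) {
  if (igraph::ecount(net) > 0) igraph::E(net)$weight <- 1
  net
}
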