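#' Identify the rich club at a threshold
#'
#' The club is the set of nodes whose richness is strictly greater than the
#' threshold. Ties at the boundary are excluded together: no tie-breaking is
#' applied, so nodes with identical richness always share club membership.
#'
#' @param net a weighted network (igraph).
#' @param richness richness parameter; see [node_richness()].
#' @param threshold richness cutoff (strict inequality).
#' @return character vector of member node names (possibly empty).
#' @examples
#' net <- weighted_network(c("a", "b", "c", "c"), c("b", "c", "a", "d"))
#' identify_club(net, "degree", 2)  # only c has degree > 2
#' @export
identify_club <- function(net, richness = "degree", threshold) {
  r <- node_richness(net, richness)
  names(r)[r > threshold]
}

#' Club statistics at one threshold
#'
#' Computes, on the subgraph induced by the club members: the club size N,
#' the intra-club link count E, the maximal intra-club link count
#' P = N(N-1)/2, and the weighted connectedness C (sum of the weights of the
#' links between club members). With unit weights C equals E.
#'
#' @param net a weighted network (igraph).
#' @param members character vector of club node names (subset of the
#'   network's nodes).
#' @param threshold the richness cutoff that produced the club (recorded for
#'   bookkeeping; not used in the computation).
#' @return an object of class \code{club_snapshot}: a list with elements
#'   \code{threshold}, \code{members}, \code{N}, \code{E}, \code{P}, \code{C}.
#' @export
club_snapshot <- function(net, members, threshold = NA_real_) {
  members <- as.character(members)
  nm <- igraph::V(net)$name
  missing <- setdiff(members, nm)
  if (length(missing)) {
    stop("club members not in network: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  N <- length(members)
  if (N == 0) {
    snap <- list(threshold = threshold, members = character(0),
                 N = 0L, E = 0L, P = 0, C = 0)
  } else {
    sub <- igraph::induced_subgraph(net, members)
    E <- igraph::ecount(sub)
    C <- if (E > 0) sum(edge_weights(sub)) else 0
    snap <- list(threshold = threshold, members = members,
                 N = N, E = E, P = N * (N - 1) / 2, C = C)
  }
  structure(snap, class = "club_snapshot")
}

#' @export
print.club_snapshot <- function(x, ...) {
  cat(sprintf("Rich club at threshold %s: N = %d, E = %d, P = %g, C = %g\n",
              format(x$threshold), x$N, x$E, x$P, x$C))
  invisible(x)
}

#' Topological rich-club coefficient
#'
#' phi = 2E / (N(N-1)): the fraction of possible intra-club links that
#' exist. Undefined (NA) for clubs of fewer than two nodes, which are routine
#' at high thresholds; callers must propagate the NA rather than zero-fill.
#'
#' @param snap a [club_snapshot()].
#' @return a number in [0, 1], or NA when N < 2.
#' @export
topological_phi <- function(snap) {
  if (snap$N < 2) return(NA_real_)
  2 * snap$E / (snap$N * (snap$N - 1))
}

#' Maximal weighted connectedness of a club (nine variants)
#'
#' The maximal connectedness F is the largest weighted connectedness the club
#' could attain under domain-specific assumptions about how links and weights
#' may be rearranged. The nine variants are organised along two dimensions:
#'
#' \strong{Link budget} (how many links could contribute to F):
#' \describe{
#'   \item{\code{"P"}}{additional links can be created inside the club, up to
#'     the topological limit P = N(N-1)/2;}
#'   \item{\code{"E"}}{the intra-club link count is fixed at the existing E;}
#'   \item{\code{"all"}}{weights can be redistributed among the links of the
#'     whole network.}
#' }
#'
#' \strong{Weight source} (where the weights on those links come from):
#' \describe{
#'   \item{\code{"capped"}}{any link may carry weight up to a cap
#'     \code{w_max} (e.g. correlation networks where weights cannot
#'     exceed 1);}
#'   \item{\code{"global"}}{weights are tied to links, and the strongest
#'     links from anywhere in the network are placed inside the club;}
#'   \item{\code{"local"}}{only links already attached to at least one club
#'     member can be rewired into the club. Links wholly inside the club
#'     count among the candidates, so F can never fall below C.}
#' }
#'
#' Concretely, with L the total link count and w the network's weights:
#' (P, capped) = P * w_max; (P, global) = sum of the min(P, L) largest w;
#' (P, local) as (P, global) restricted to club-incident links;
#' (E, capped) = E * w_max; (E, global) = sum of the E largest w;
#' (E, local) restricted to club-incident links;
#' (all, capped) = min(L, P) * w_max (every network link could carry the cap,
#' but the club can hold at most P of them);
#' (all, global) = total network weight;
#' (all, local) = total weight of club-incident links.
#'
#' @param net a weighted network (igraph).
#' @param snap a [club_snapshot()] derived from \code{net}.
#' @param link_budget one of \code{"P"}, \code{"E"}, \code{"all"}.
#' @param weight_source one of \code{"capped"}, \code{"global"},
#'   \code{"local"}.
#' @param w_max positive weight cap; required iff
#'   \code{weight_source = "capped"}.
#' @return F, a nonnegative number. F = 0 is possible for empty clubs and is
#'   treated as undefined by [phi_ratio()].
#' @export
maximal_connectedness <- function(net, snap,
                                  link_budget = c("P", "E", "all"),
                                  weight_source = c("capped", "global", "local"),
                                  w_max = NULL) {
  link_budget <- match.arg(link_budget)
  weight_source <- match.arg(weight_source)
  if (weight_source == "capped") {
    if (is.null(w_max)) {
      stop("variant (", link_budget, ", capped) requires `w_max`")
    }
    if (!is.finite(w_max) || w_max <= 0) stop("`w_max` must be positive and finite")
  }
  w <- edge_weights(net)
  L <- length(w)
  if (weight_source == "local") {
    if (L > 0) {
      ends <- igraph::ends(net, igraph::E(net), names = TRUE)
      local <- ends[, 1] %in% snap$members | ends[, 2] %in% snap$members
    } else {
      local <- logical(0)
    }
  }
  switch(paste(link_budget, weight_source, sep = "."),
    P.capped   = snap$P * w_max,
    P.global   = sum_top(w, snap$P),
    P.local    = sum_top(w[local], snap$P),
    E.capped   = snap$E * w_max,
    E.global   = sum_top(w, snap$E),
    E.local    = sum_top(w[local], snap$E),
    all.capped = min(L, snap$P) * w_max,
    all.global = sum(w),
    all.local  = sum(w[local])
  )
}

#' Weighted rich-club coefficient phi = C / F
#'
#' Ratio of the club's weighted connectedness to its maximal possible
#' weighted connectedness under a chosen variant. Undefined (NA) when F = 0
#' (e.g. empty clubs); a negative F indicates an internal inconsistency and
#' is an error.
#'
#' @param snap a [club_snapshot()].
#' @param F maximal connectedness from [maximal_connectedness()] for the
#'   same snapshot.
#' @return C / F, or NA when F = 0.
#' @export
phi_ratio <- function(snap, F) {
  if (!is.finite(F) || F < 0) {
    stop("F must be a nonnegative finite number (got ", format(F), ")")
  }
  if (F == 0) return(NA_real_)
  snap$C / F
}
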