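#' Richness threshold grid
#'
#' The cutoffs at which rich-club coefficients are evaluated: every unique
#' richness value present in the network, sorted increasing. Because clubs
#' use strict inequality, the largest cutoff yields an empty club (and an
#' undefined coefficient); it is retained so the curve covers the full range.
#'
#' @param net a weighted network (igraph).
#' @param richness richness parameter; see [node_richness()].
#' @return increasing numeric vector of cutoffs.
#' @export
threshold_grid <- function(net, richness = "degree") {
  if (igraph::vcount(net) == 0) stop("network has no nodes")
  sort(unique(as.numeric(node_richness(net, richness))))
}

#' Two-sided empirical p-value with add-one correction
#'
#' p = 2 * min(r+, r-) / (n + 1), capped at 1, where
#' r+ = 1 + number of null samples >= the observation and
#' r- = 1 + number of null samples <= the observation. The add-one
#' correction counts the observation among the null draws, so p can never be
#' 0 and the test is valid (super-uniform under the null). Two-sided because
#' departures below 1 (clubs carrying \emph{less} weight than chance) are a
#' finding in their own right.
#'
#' @param c_obs observed statistic.
#' @param c_samples numeric vector of null-ensemble samples.
#' @return p-value in (0, 1].
#' @export
empirical_pvalue <- function(c_obs, c_samples) {
  n <- length(c_samples)
  if (n == 0) stop("`c_samples` must be nonempty")
  r_up <- 1 + sum(c_samples >= c_obs)
  r_dn <- 1 + sum(c_samples <= c_obs)
  min(1, 2 * min(r_up, r_dn) / (n + 1))
}

#' Normalized rich-club curve phi_norm = C / C_rand
#'
#' Evaluates, at every unique richness value, the club's weighted
#' connectedness C against the mean connectedness C_rand of \code{n_rand}
#' randomized controls, together with an empirical p-value per threshold.
#' The choice of control determines what is being detected:
#' \describe{
#'   \item{topological}{degree-preserving controls with weights ignored
#'     (set to 1 in the real network as well), i.e. the classical unweighted
#'     normalization — detects preferential link placement among rich
#'     nodes;}
#'   \item{weighted}{topology-preserving, weight-decorrelating controls —
#'     detects preferential weight allocation on the existing intra-club
#'     links, over and above topology;}
#'   \item{mixed}{controls randomizing both — a compound signal that
#'     conflates the two effects.}
#' }
#'
#' Thresholds whose club has fewer than two nodes, or where the ensemble
#' mean is zero, carry NA in \code{phi_norm}, \code{p_value} and
#' \code{significant}; they are never zero-filled.
#'
#' No correction for multiple thresholds is applied by default;
#' \code{p_adjust = "BH"} opts in to Benjamini-Hochberg adjustment across
#' the defined thresholds.
#'
#' @param net a weighted network (igraph).
#' @param richness richness parameter; see [node_richness()].
#' @param kind control family: \code{"topological"}, \code{"weighted"} or
#'   \code{"mixed"}.
#' @param n_rand number of randomized controls (reference analyses: 1000).
#' @param seed integer seed, or NULL.
#' @param alpha significance level for the per-threshold flag
#'   (default 0.05).
#' @param tol strength tolerance for the weight-decorrelating controls.
#' @param p_adjust \code{"none"} (default) or \code{"BH"}.
#' @return an object of classes \code{rich_club_curve} and
#'   \code{data.frame}, one row per threshold, with columns
#'   \code{threshold}, \code{N}, \code{E}, \code{C}, \code{c_rand_mean},
#'   \code{phi_norm}, \code{p_value}, \code{significant}; attributes record
#'   \code{kind}, \code{n_rand}, \code{seed}, \code{alpha}.
#' @examples
#' net <- er_weighted(30, 0.2, seed = 1)
#' phi_norm_curve(net, "degree", "weighted", n_rand = 20, seed = 1)
#' @export
phi_norm_curve <- function(net, richness = "degree",
                           kind = c("topological", "weighted", "mixed"),
                           n_rand = 1000L, seed = NULL, alpha = 0.05,
                           tol = 1e-3, p_adjust = c("none", "BH")) {
  kind <- match.arg(kind)
  p_adjust <- match.arg(p_adjust)
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must lie in (0, 1)")
  net_eval <- if (kind == "topological") strip_weights(net) else net
  r <- as.numeric(node_richness(net_eval, richness))
  grid <- sort(unique(r))
  K <- length(grid)
  if (igraph::ecount(net_eval) > 0) {
    ends <- edge_ends(net_eval)
    w <- edge_weights(net_eval)
    rmin <- pmin(r[ends[, 1]], r[ends[, 2]])
  } else {
    w <- numeric(0)
    rmin <- numeric(0)
  }
  N <- vapply(grid, function(t) sum(r > t), numeric(1))
  E <- vapply(grid, function(t) sum(rmin > t), numeric(1))
  C <- vapply(grid, function(t) sum(w[rmin > t]), numeric(1))
  ens <- build_ensemble(net_eval, kind, grid, richness,
                        n_rand = n_rand, seed = seed, tol = tol)
  crm <- colMeans(ens$c_samples)
  defined <- N >= 2 & crm > 0
  degenerate <- N >= 2 & crm == 0 & C > 0
  if (any(degenerate)) {
    warning("mean C_rand is zero at ", sum(degenerate),
            " threshold(s) with positive observed C; phi_norm is undefined there")
  }
  phi <- ifelse(defined, C / crm, NA_real_)
  p <- rep(NA_real_, K)
  for (k in which(defined)) {
    p[k] <- empirical_pvalue(C[k], ens$c_samples[, k])
  }
  if (p_adjust == "BH" && any(defined)) {
    p[defined] <- stats::p.adjust(p[defined], method = "BH")
  }
  sig <- ifelse(defined, p < alpha, NA)
  out <- data.frame(threshold = grid, N = as.integer(N), E = as.integer(E),
                    C = C, c_rand_mean = crm, phi_norm = phi,
                    p_value = p, significant = sig)
  structure(out,
            kind = kind, richness = if (is.numeric(richness)) "custom" else richness,
            n_rand = as.integer(n_rand), seed = seed, alpha = alpha,
            class = c("rich_club_curve", "data.frame"))
}

#' @export
print.rich_club_curve <- function(x, ...) {
  cat(sprintf("Normalized rich-club curve (%s control, %d controls, alpha = %g)\n",
              attr(x, "kind"), attr(x, "n_rand"), attr(x, "alpha")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a normalized rich-club curve
#'
#' phi_norm against the richness threshold, with the chance reference line
#' at 1 and significant thresholds (p < alpha) marked by filled points.
#'
#' @param x a [phi_norm_curve()] result.
#' @param ... passed to [plot()].
#' @export
plot.rich_club_curve <- function(x, ...) {
  ok <- !is.na(x$phi_norm)
  plot(x$threshold[ok], x$phi_norm[ok], type = "b",
       pch = ifelse(x$significant[ok] %in% TRUE, 19, 1),
       xlab = "richness threshold", ylab = expression(phi[norm]), ...)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  invisible(x)
}
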