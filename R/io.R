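#' Read a weighted (or unweighted) edge list
#'
#' One link per line: \code{source target weight} (weighted) or
#' \code{source target} (unweighted; all weights set to 1). Fields are
#' separated by whitespace unless \code{delim} is given; \code{#} starts a
#' comment; blank lines are skipped. Every validation failure (wrong column
#' count, non-numeric or non-positive weight, self-loop, duplicate pair)
#' is reported with its file line number — there is no silent coercion.
#'
#' An edge list alone cannot declare isolated nodes; pass them through
#' \code{nodes} if they matter for bookkeeping (clubs never contain
#' zero-degree nodes, so omitting them does not change any coefficient).
#'
#' @param path file path.
#' @param weighted logical; declare whether a third (weight) column is
#'   expected.
#' @param delim field separator; NULL (default) splits on runs of spaces or
#'   tabs.
#' @param comment comment character.
#' @param nodes optional character vector of node names to include even if
#'   they carry no links.
#' @return a weighted network (igraph). An empty file yields an empty
#'   network with a warning.
#' @export
read_edgelist <- function(path, weighted = TRUE, delim = NULL, comment = "#",
                          nodes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  stripped <- sub(paste0("\\", comment, ".*$"), "", raw)
  keep <- which(nzchar(trimws(stripped)))
  if (length(keep) == 0) {
    warning("no links in ", path, "; returning an empty network")
    return(weighted_network(character(0), character(0), nodes = nodes))
  }
  toks <- if (is.null(delim)) {
    strsplit(trimws(stripped[keep]), "[ \t]+")
  } else {
    strsplit(trimws(stripped[keep]), delim, fixed = TRUE)
  }
  need <- if (weighted) 3L else 2L
  nc <- lengths(toks)
  bad <- which(nc != need)
  if (length(bad)) {
    stop(sprintf("%s line %d: expected %d columns, found %d",
                 path, keep[bad[1]], need, nc[bad[1]]))
  }
  from <- vapply(toks, `[[`, character(1), 1L)
  to <- vapply(toks, `[[`, character(1), 2L)
  if (weighted) {
    wtxt <- vapply(toks, `[[`, character(1), 3L)
    w <- suppressWarnings(as.numeric(wtxt))
    bad <- which(is.na(w))
    if (length(bad)) {
      stop(sprintf("%s line %d: non-numeric weight '%s'",
                   path, keep[bad[1]], wtxt[bad[1]]))
    }
    bad <- which(!is.finite(w) | w <= 0)
    if (length(bad)) {
      stop(sprintf("%s line %d: weight must be strictly positive and finite (got %s)",
                   path, keep[bad[1]], wtxt[bad[1]]))
    }
  } else {
    w <- rep(1, length(from))
  }
  bad <- which(from == to)
  if (length(bad)) {
    stop(sprintf("%s line %d: self-loop on node '%s'",
                 path, keep[bad[1]], from[bad[1]]))
  }
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad)) {
    stop(sprintf("%s line %d: duplicate link %s -- %s",
                 path, keep[bad[1]], from[bad[1]], to[bad[1]]))
  }
  weighted_network(from, to, w, nodes = nodes)
}

#' Write a network as a tab-separated edge list
#'
#' @param net a weighted network (igraph).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_edgelist <- function(net, path) {
  if (igraph::ecount(net) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ends <- igraph::ends(net, igraph::E(net), names = TRUE)
  lines <- paste(ends[, 1], ends[, 2], fmt_num(edge_weights(net)), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a custom node-richness table
#'
#' Two columns (node, value), same comment and delimiter dialect as
#' [read_edgelist()].
#'
#' @inheritParams read_edgelist
#' @return named numeric vector suitable as the \code{richness} argument of
#'   the analysis functions.
#' @export
read_richness <- function(path, delim = NULL, comment = "#") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  stripped <- sub(paste0("\\", comment, ".*$"), "", raw)
  keep <- which(nzchar(trimws(stripped)))
  if (length(keep) == 0) stop("no richness values in ", path)
  toks <- if (is.null(delim)) {
    strsplit(trimws(stripped[keep]), "[ \t]+")
  } else {
    strsplit(trimws(stripped[keep]), delim, fixed = TRUE)
  }
  nc <- lengths(toks)
  bad <- which(nc != 2L)
  if (length(bad)) {
    stop(sprintf("%s line %d: expected 2 columns, found %d",
                 path, keep[bad[1]], nc[bad[1]]))
  }
  node <- vapply(toks, `[[`, character(1), 1L)
  vtxt <- vapply(toks, `[[`, character(1), 2L)
  v <- suppressWarnings(as.numeric(vtxt))
  bad <- which(is.na(v) | !is.finite(v))
  if (length(bad)) {
    stop(sprintf("%s line %d: non-numeric richness '%s'",
                 path, keep[bad[1]], vtxt[bad[1]]))
  }
  bad <- which(duplicated(node))
  if (length(bad)) {
    stop(sprintf("%s line %d: duplicate node '%s'",
                 path, keep[bad[1]], node[bad[1]]))
  }
  stats::setNames(v, node)
}

#' Write a normalized rich-club curve as TSV
#'
#' Tab-separated, one row per threshold, with a commented header recording
#' the control kind, ensemble size, seed, alpha and package version.
#' Numeric fields are formatted with 17 significant digits so that
#' [read_curve()] reproduces every value exactly; undefined entries are the
#' literal string \code{NA}.
#'
#' @param curve a [phi_norm_curve()] result.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_curve <- function(curve, path) {
  if (!inherits(curve, "rich_club_curve")) {
    stop("`curve` must be a rich_club_curve")
  }
  seed <- attr(curve, "seed")
  header <- c(
    "# normalized rich-club curve",
    paste0("# kind: ", attr(curve, "kind")),
    paste0("# richness: ", attr(curve, "richness")),
    paste0("# n_rand: ", attr(curve, "n_rand")),
    paste0("# seed: ", if (is.null(seed)) "NA" else seed),
    paste0("# alpha: ", fmt_num(attr(curve, "alpha"))),
    paste0("# richclub version: ", as.character(utils::packageVersion("richclub"))),
    paste("threshold", "N", "E", "C", "c_rand_mean", "phi_norm",
          "p_value", "significant", sep = "\t"))
  rows <- paste(fmt_num(curve$threshold), curve$N, curve$E,
                fmt_num(curve$C), fmt_num(curve$c_rand_mean),
                fmt_num(curve$phi_norm), fmt_num(curve$p_value),
                ifelse(is.na(curve$significant), "NA", curve$significant),
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read back a curve written by [write_curve()]
#'
#' @param path file path.
#' @return a \code{rich_club_curve} data frame; header metadata are restored
#'   as attributes.
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", raw, value = TRUE)
  meta <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), meta_lines, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, ": "), "", hit[1]) else NA_character_
  }
  body <- raw[!grepl("^#", raw)]
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t",
                          na.strings = "NA", stringsAsFactors = FALSE)
  for (col in c("threshold", "C", "c_rand_mean", "phi_norm", "p_value")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$N <- as.integer(df$N)
  df$E <- as.integer(df$E)
  df$significant <- as.logical(df$significant)
  seed <- meta("seed")
  structure(df,
            kind = meta("kind"), richness = meta("richness"),
            n_rand = as.integer(meta("n_rand")),
            seed = if (identical(seed, "NA")) NULL else as.integer(seed),
            alpha = as.numeric(meta("alpha")),
            class = c("rich_club_curve", "data.frame"))
}
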