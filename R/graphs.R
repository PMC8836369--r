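#' Generate a synthetic network ensemble member
#'
#' Undirected, unweighted simple graphs of the three families the
#' reconstruction experiments run on: scale-free (Barabasi-Albert
#' preferential attachment with `m = round(mean_degree/2)`), small-world
#' (Watts-Strogatz ring with `mean_degree` nearest neighbours and rewiring
#' probability `rewire_p`), and random (Erdos-Renyi with a fixed edge count
#' `round(n * mean_degree / 2)`, which pins the realized mean degree).
#'
#' @param model One of `"scale_free"`, `"small_world"`, `"random"`.
#' @param n Number of nodes (`>= 10`).
#' @param mean_degree Requested average degree; must be below `n - 1`.
#' @param seed Optional integer seed.
#' @param rewire_p Watts-Strogatz rewiring probability.
#' @return An [igraph::igraph] object.
#' @examples
#' g <- generate_network("scale_free", 100, 6, seed = 1)
#' mean(igraph::degree(g))
#' @export
generate_network <- function(model = c("scale_free", "small_world", "random"),
                             n, mean_degree = 6, seed = NULL, rewire_p = 0.1) {
  model <- match.arg(model)
  if (n < 10) stop("n must be at least 10")
  if (mean_degree <= 0 || mean_degree > n - 1)
    stop("infeasible degree request: need 0 < mean_degree <= n - 1")
  if (!is.null(seed)) set.seed(seed)
  g <- switch(model,
    scale_free = igraph::sample_pa(n, m = max(1L, round(mean_degree / 2)),
                                   directed = FALSE),
    small_world = igraph::sample_smallworld(1, n,
                                            max(1L, round(mean_degree / 2)),
                                            rewire_p),
    random = igraph::sample_gnm(n, min(round(n * mean_degree / 2),
                                       choose(n, 2)))
  )
  igraph::simplify(g)
}

#' Read a network from a plain edge list
#'
#' Accepts whitespace- or comma-delimited integer pairs, one edge per line.
#' Node ids are normalized to contiguous 1-based integers internally; the
#' original labels are kept in the vertex attribute `label`. Self-loops and
#' duplicate edges are dropped with a warning.
#'
#' @param path File to read.
#' @param zero_based `TRUE` if ids start at 0, `FALSE` if at 1, or `NULL`
#'   (default) to detect from the smallest id.
#' @return An undirected [igraph::igraph] with vertex attribute `label`.
#' @export
load_edgelist <- function(path, zero_based = NULL) {
  lines <- readLines(path)
  lines <- trimws(gsub(",", " ", lines, fixed = TRUE))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\\s+")
  if (any(lengths(toks) != 2))
    stop("parse error: each line must hold exactly two node ids")
  flat <- unlist(toks)
  if (any(grepl("[^0-9-]", flat)))
    stop("parse error: non-integer token in edge list")
  ids <- matrix(as.integer(flat), ncol = 2, byrow = TRUE)
  if (is.null(zero_based)) zero_based <- min(ids) == 0L
  labels <- sort(unique(as.vector(ids)))
  idx <- matrix(match(ids, labels), ncol = 2)
  loops <- idx[, 1] == idx[, 2]
  if (any(loops)) warning(sum(loops), " self-loop(s) dropped")
  idx <- idx[!loops, , drop = FALSE]
  key <- paste(pmin(idx[, 1], idx[, 2]), pmax(idx[, 1], idx[, 2]))
  dup <- duplicated(key)
  if (any(dup)) warning(sum(dup), " duplicate edge(s) dropped")
  idx <- idx[!dup, , drop = FALSE]
  g <- igraph::graph_from_edgelist(idx, directed = FALSE)
  igraph::V(g)$label <- labels[seq_len(igraph::vcount(g))]
  g
}

#' Write a network as a plain edge list
#'
#' @param net An [igraph::igraph].
#' @param path Output file (two whitespace-separated columns).
#' @param zero_based Write 0-based ids (default `FALSE`).
#' @return The path, invisibly.
#' @export
save_edgelist <- function(net, path, zero_based = FALSE) {
  el <- igraph::as_edgelist(net, names = FALSE)
  if (zero_based) el <- el - 1L
  write.table(el, path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Dense adjacency matrix of a network
#'
#' @param net An [igraph::igraph].
#' @return A 0/1 numeric matrix with zero diagonal.
#' @export
adjacency_matrix <- function(net) {
  a <- as.matrix(igraph::as_adjacency_matrix(net, sparse = TRUE))
  a[a > 1] <- 1
  diag(a) <- 0
  storage.mode(a) <- "double"
  unname(a)
}
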