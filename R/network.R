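# Gene-interaction network robustness under node removal: the mean fraction
# of the original nodes remaining in the largest connected component after
# deleting a fixed number (or percentage) of nodes, chosen at random or by
# descending degree.

#' Network robustness under node removal
#'
#' Per trial, `n_remove` nodes are deleted (random without replacement, or
#' the top-degree nodes deterministically) and the size of the largest
#' connected component is divided by the ORIGINAL node count; the reported
#' value is the mean over trials. Percent removals convert to a node count
#' with half-up rounding.
#'
#' @param net `igraph` graph (simple, undirected); vertex names are gene
#'   ids.
#' @param n_remove number of nodes to delete (must be `< vcount(net)`);
#'   ignored when `percent` is given.
#' @param percent percentage of nodes to delete in `(0, 100)`.
#' @param mode `"random"` (sampled per trial) or `"degree"` (top-degree,
#'   ties broken by vertex-name order; fully deterministic, 1 trial).
#' @param trials number of random trials (default 1000).
#' @param seed integer seed for random removal.
#' @return list of class `"robustness_result"`: `value` (mean largest-
#'   component fraction), `per_trial`, `n_remove`, `mode`, `trials`,
#'   `n_nodes`.
#' @export
robustness <- function(net, n_remove = NULL, percent = NULL,
                       mode = c("random", "degree"), trials = 1000,
                       seed = 1) {
  mode <- match.arg(mode)
  n <- igraph::vcount(net)
  if (n < 2) stop("need at least 2 nodes")
  if (!is.null(percent)) {
    if (percent <= 0 || percent >= 100) stop("percent must be in (0, 100)")
    n_remove <- round_half_up(n * percent / 100)
  }
  if (is.null(n_remove)) stop("give n_remove or percent")
  n_remove <- as.integer(n_remove)
  if (n_remove < 0) stop("n_remove must be >= 0")
  if (n_remove >= n) stop("cannot remove all nodes (n_remove >= node count)")
  vnames <- igraph::V(net)$name %||% as.character(seq_len(n))

  lcc_fraction <- function(drop) {
    g2 <- igraph::delete_vertices(net, drop)
    if (igraph::vcount(g2) == 0) return(0)
    max(igraph::components(g2)$csize) / n
  }

  if (mode == "degree") {
    deg <- igraph::degree(net)
    ord <- order(-deg, vnames)
    per_trial <- lcc_fraction(ord[seq_len(n_remove)])
    trials <- 1L
  } else {
    per_trial <- with_seed(seed, vapply(seq_len(trials), function(t)
      lcc_fraction(sample.int(n, n_remove)), numeric(1)))
  }
  structure(list(value = mean(per_trial), per_trial = per_trial,
                 n_remove = n_remove, mode = mode, trials = trials,
                 n_nodes = n),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf(
    "robustness: %.3f (remove %d of %d nodes, %s%s)\n",
    x$value, x$n_remove, x$n_nodes, x$mode,
    if (x$mode == "random") sprintf(", %d trials", x$trials) else ""))
  invisible(x)
}

#' Read a gene-interaction edge list
#'
#' @param path 2-column TSV of undirected edges (gene ids). Self-loops and
#'   duplicate edges are dropped.
#' @return simple undirected `igraph` graph.
#' @export
read_edge_list <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("edge list requires 2 columns")
  g <- igraph::graph_from_data_frame(raw[, 1:2], directed = FALSE)
  igraph::simplify(g)
}
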