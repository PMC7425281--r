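#' Weighted simple social network
#'
#' Lightweight container for the networks handled throughout the package:
#' a simple graph (no self-loops, no duplicate edges) over a fixed node
#' roster, directed or undirected, with edge weights in `[0, 1]`. Isolated
#' nodes are first-class citizens: the node set is the roster, not the set
#' of edge endpoints, because thresholding proximity networks routinely
#' disconnects nodes and their prevalence is itself a quantity of interest.
#'
#' @param edges data frame with columns `from`, `to` and optionally
#'   `weight` (defaults to 1). For undirected networks each unordered pair
#'   appears once; for directed networks each arc appears once.
#' @param nodes character vector of node identifiers (the roster). Defaults
#'   to the nodes appearing in `edges`.
#' @param directed logical; is the network directed?
#' @return An object of class `social_network`: a list with elements
#'   `nodes`, `edges` (data.frame `from`, `to`, `weight`) and `directed`.
#' @examples
#' net <- social_network(data.frame(from = "a", to = "b", weight = 0.5),
#'                       nodes = c("a", "b", "c"))
#' net
#' @export
social_network <- function(edges = NULL, nodes = NULL, directed = FALSE) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  edges <- as.data.frame(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    stop("`edges` must have columns `from` and `to`", call. = FALSE)
  }
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids in roster", call. = FALSE)
  missing_n <- setdiff(unique(c(edges$from, edges$to)), nodes)
  if (length(missing_n) > 0) {
    stop("edge endpoints not in roster: ", paste(missing_n, collapse = ", "),
         call. = FALSE)
  }
  if (any(edges$from == edges$to)) stop("self-loops are not allowed", call. = FALSE)
  if (any(edges$weight < 0 | edges$weight > 1)) {
    stop("edge weights must lie in [0, 1]", call. = FALSE)
  }
  key <- pair_key(edges$from, edges$to, directed)
  if (anyDuplicated(key)) stop("duplicate edges", call. = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges[c("from", "to", "weight")],
                 directed = directed),
            class = "social_network")
}

# Canonical key for a node pair: ordered "i->j" when directed,
# sorted "i--j" when undirected.
pair_key <- function(from, to, directed) {
  if (directed) {
    paste(from, to, sep = "->")
  } else {
    paste(pmin(from, to), pmax(from, to), sep = "--")
  }
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf("<social_network: %s, %d nodes, %d edges>\n",
              if (x$directed) "directed" else "undirected",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Edge set of a network
#'
#' Canonical representation of the network's positive-weight edges, used for
#' validation against a reference network: ordered pairs (`"i->j"`) when
#' directed, unordered pairs (`"i--j"`, endpoints sorted) when undirected.
#'
#' @param net a [social_network].
#' @return character vector of canonical pair keys.
#' @export
edge_set <- function(net) {
  stopifnot(inherits(net, "social_network"))
  e <- net$edges[net$edges$weight > 0, , drop = FALSE]
  sort(pair_key(e$from, e$to, net$directed))
}

#' @rdname edge_set
#' @export
gt_edge_set <- edge_set

#' Convert to an igraph graph
#'
#' @param net a [social_network].
#' @return an [igraph::graph] with the roster as vertices (isolates kept)
#'   and a `weight` edge attribute.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "social_network"))
  g <- igraph::make_empty_graph(n = 0, directed = net$directed)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(g, rbind(net$edges$from, net$edges$to),
                           weight = net$edges$weight)
  }
  g
}

#' Weight (adjacency) matrix of a network
#'
#' @param net a [social_network].
#' @return numeric matrix indexed by roster node, zero where no edge. For
#'   undirected networks the matrix is symmetric.
#' @export
weight_matrix_of <- function(net) {
  stopifnot(inherits(net, "social_network"))
  n <- length(net$nodes)
  m <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0) {
    m[cbind(net$edges$from, net$edges$to)] <- net$edges$weight
    if (!net$directed) m[cbind(net$edges$to, net$edges$from)] <- net$edges$weight
  }
  m
}

#' Fraction of isolated nodes
#'
#' The share of roster nodes with no incident edge. Thresholding a proximity
#' network at increasing weights disconnects more and more nodes; this
#' fraction (as a share of class size) is the usual diagnostic for choosing
#' a sensible threshold range.
#'
#' @param net a [social_network].
#' @param roster node ids over which the fraction is taken; defaults to the
#'   network's roster, and must contain it.
#' @return fraction in `[0, 1]`.
#' @export
isolated_fraction <- function(net, roster = NULL) {
  stopifnot(inherits(net, "social_network"))
  if (is.null(roster)) roster <- net$nodes
  if (length(roster) == 0) stop("empty roster", call. = FALSE)
  if (!all(net$nodes %in% roster)) {
    stop("roster must contain all network nodes", call. = FALSE)
  }
  connected <- unique(c(net$edges$from, net$edges$to))
  sum(!(roster %in% connected)) / length(roster)
}

#' Write a network to disk
#'
#' `edgelist` writes a `source,target,weight` CSV (edges only — supply the
#' roster separately to [read_network()] to recover isolated nodes);
#' `graphml` writes standard GraphML with a `weight` attribute and preserves
#' isolates.
#'
#' @param net a [social_network].
#' @param path output file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml")) {
  stopifnot(inherits(net, "social_network"))
  format <- match.arg(format)
  if (format == "edgelist") {
    out <- net$edges
    names(out) <- c("source", "target", "weight")
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a network from disk
#'
#' @param path file written by [write_network()].
#' @param format `"edgelist"` or `"graphml"`.
#' @param directed logical; only used for `edgelist` (GraphML records it).
#' @param nodes optional roster for `edgelist` input, so that isolated nodes
#'   survive the round trip.
#' @return a [social_network].
#' @export
read_network <- function(path, format = c("edgelist", "graphml"),
                         directed = FALSE, nodes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edgelist") {
    df <- utils::read.csv(path, colClasses = c("character", "character",
                                               "numeric"))
    names(df) <- c("from", "to", "weight")
    social_network(df, nodes = nodes, directed = directed)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    if (is.null(ed$weight)) ed$weight <- rep(1, nrow(ed))
    social_network(ed[c("from", "to", "weight")],
                   nodes = igraph::V(g)$name,
                   directed = igraph::is_directed(g))
  }
}

#' Read a binary friendship matrix
#'
#' Reads a square 0/1 adjacency matrix (CSV, with or without row/column
#' names) describing reported friendships, e.g. mutual online friendships
#' used as a ground-truth reference. A symmetric matrix yields an
#' undirected network; an asymmetric one a directed network. The diagonal
#' is ignored.
#'
#' @param path CSV file containing the matrix.
#' @return a [social_network] with unit edge weights.
#' @export
read_friendship_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (is.character(raw[[1]])) {
    # first column holds row names
    rn <- raw[[1]]
    raw <- raw[-1]
    m <- as.matrix(raw)
    rownames(m) <- rn
  } else {
    m <- as.matrix(raw)
    rownames(m) <- colnames(m)
  }
  if (nrow(m) != ncol(m)) {
    stop("friendship matrix must be square, got ",
         nrow(m), "x", ncol(m), call. = FALSE)
  }
  if (!all(m %in% c(0, 1))) stop("matrix cells must be 0 or 1", call. = FALSE)
  ids <- colnames(m)
  if (is.null(ids)) ids <- sprintf("N%02d", seq_len(ncol(m)))
  dimnames(m) <- list(ids, ids)
  diag(m) <- 0
  directed <- !isTRUE(all.equal(m, t(m), check.attributes = FALSE))
  if (directed) {
    idx <- which(m == 1, arr.ind = TRUE)
  } else {
    idx <- which(m == 1 & upper.tri(m), arr.ind = TRUE)
  }
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      weight = rep(1, nrow(idx)))
  social_network(edges, nodes = ids, directed = directed)
}
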