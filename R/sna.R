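#' Network density
#'
#' Ratio of the number of edges to the number of possible edges:
#' `E / (N(N-1))` for directed, `2E / (N(N-1))` for undirected networks.
#' Isolated roster nodes count towards `N`; a fully connected network has
#' density 1. Computed on the binarized (unweighted) graph.
#'
#' @param net a [social_network].
#' @return density in `[0, 1]`.
#' @export
net_density <- function(net) {
  stopifnot(inherits(net, "social_network"))
  n <- length(net$nodes)
  if (n < 2) stop("density needs at least 2 nodes", call. = FALSE)
  e <- sum(net$edges$weight > 0)
  if (net$directed) e / (n * (n - 1)) else 2 * e / (n * (n - 1))
}

#' Gender assortativity (discrete attribute mixing)
#'
#' Newman's assortativity coefficient for a categorical attribute,
#' \deqn{r = \frac{\sum_i e_{ii} - \sum_i a_i b_i}{1 - \sum_i a_i b_i}}
#' computed from the mixing matrix `e` of edge-end attribute pairs
#' (`a`, `b` are its marginals; for undirected networks each edge
#' contributes both orientations). The coefficient is 1 when every edge
#' joins same-gender nodes (perfect homophily), -1 when every edge crosses gender
#' (perfect disassortativity). When all edge endpoints carry a single
#' category the coefficient is undefined and `NA` is returned. Computed on
#' the binarized graph.
#'
#' @param net a [social_network] with at least one edge.
#' @param gender named vector (names = node ids) of categories; every
#'   connected node must be labelled.
#' @return assortativity in `[-1, 1]`, or `NA` if undefined.
#' @export
assortativity_gender <- function(net, gender) {
  stopifnot(inherits(net, "social_network"))
  e <- net$edges[net$edges$weight > 0, , drop = FALSE]
  if (nrow(e) == 0) stop("assortativity needs at least one edge",
                         call. = FALSE)
  ends <- unique(c(e$from, e$to))
  if (!all(ends %in% names(gender)) || anyNA(gender[ends])) {
    stop("every connected node needs a gender label", call. = FALSE)
  }
  gf <- gender[e$from]
  gt_ <- gender[e$to]
  if (!net$directed) {
    # each undirected edge contributes both edge-end orderings
    tmp <- gf
    gf <- c(gf, gt_)
    gt_ <- c(gt_, tmp)
  }
  cats <- sort(unique(c(gf, gt_)))
  if (length(cats) < 2) return(NA_real_)
  m <- table(factor(gf, cats), factor(gt_, cats))
  e_mat <- m / sum(m)
  a <- rowSums(e_mat)
  b <- colSums(e_mat)
  sab <- sum(a * b)
  if (1 - sab == 0) return(NA_real_)
  (sum(diag(e_mat)) - sab) / (1 - sab)
}

#' Freeman centralization
#'
#' Graph-level dispersion of node centralities,
#' \deqn{C = \frac{\sum_v (c_{max} - c_v)}{H}}
#' with `H` the maximum attainable sum for a graph of the same size, reached
#' by the star topology — so a star scores exactly 1 and a clique exactly 0.
#' Normalizers: `(n-1)(n-2)` for undirected degree, `(n-1)^2` for in-degree
#' on directed graphs, and `(n-1)(n-2)/(2n-3)` for closeness on normalized
#' closeness scores. Closeness on disconnected graphs follows the
#' Wasserman–Faust convention: each node's closeness is computed within its
#' reachable set and scaled by `(reachable-1)/(n-1)`; unreachable parts
#' contribute 0. Computed on the binarized graph.
#'
#' @param net a [social_network] with at least 3 nodes.
#' @param kind `"degree"` (undirected), `"in_degree"` (directed) or
#'   `"closeness"`.
#' @return centralization, 0 to 1 for the calibrated kinds.
#' @export
centralization <- function(net, kind = c("degree", "in_degree", "closeness")) {
  stopifnot(inherits(net, "social_network"))
  kind <- match.arg(kind)
  n <- length(net$nodes)
  if (n < 3) stop("centralization needs at least 3 nodes", call. = FALSE)
  if (kind == "degree") {
    if (net$directed) stop("use kind = 'in_degree' for directed networks",
                           call. = FALSE)
    cv <- node_centrality(net, "degree")
    h <- (n - 1) * (n - 2)
  } else if (kind == "in_degree") {
    if (!net$directed) stop("in-degree centralization needs a directed network",
                            call. = FALSE)
    cv <- node_centrality(net, "in_degree")
    h <- (n - 1)^2
  } else {
    cv <- closeness_scores(net)
    h <- (n - 1) * (n - 2) / (2 * n - 3)
  }
  sum(max(cv) - cv) / h
}

# Wasserman–Faust closeness: within-reachable-set closeness scaled by the
# reachable fraction; directed graphs use outgoing paths.
closeness_scores <- function(net) {
  g <- as_igraph(net)
  n <- length(net$nodes)
  d <- igraph::distances(g, mode = if (net$directed) "out" else "all",
                         weights = NA)
  vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    reach <- is.finite(dv)
    r <- sum(reach)
    if (r == 0) return(0)
    (r / sum(dv[reach])) * (r / (n - 1))
  }, numeric(1))
}

#' Node centrality
#'
#' `degree` and `in_degree` return integer tie counts; `eigenvector`
#' returns principal-eigenvector scores of the binarized adjacency matrix
#' (incoming ties for directed networks), normalized to maximum 1 and
#' computed by power iteration (tolerance 1e-9, at most 10000 iterations —
#' an error reports the iteration count on non-convergence).
#'
#' @param net a [social_network].
#' @param kind `"degree"`, `"in_degree"` or `"eigenvector"`.
#' @param tol,max_iter power-iteration controls (eigenvector only).
#' @return named vector over the roster.
#' @export
node_centrality <- function(net, kind = c("degree", "in_degree",
                                          "eigenvector"),
                            tol = 1e-9, max_iter = 10000) {
  stopifnot(inherits(net, "social_network"))
  kind <- match.arg(kind)
  nodes <- net$nodes
  e <- net$edges[net$edges$weight > 0, , drop = FALSE]
  if (kind == "degree") {
    cnt <- table(factor(c(e$from, e$to), levels = nodes))
    return(stats::setNames(as.integer(cnt), nodes))
  }
  if (kind == "in_degree") {
    if (!net$directed) stop("in-degree needs a directed network",
                            call. = FALSE)
    cnt <- table(factor(e$to, levels = nodes))
    return(stats::setNames(as.integer(cnt), nodes))
  }
  if (nrow(e) == 0) stop("eigenvector centrality needs at least one edge",
                         call. = FALSE)
  a <- adjacency_over(net, nodes)
  m <- if (net$directed) t(a) else a  # incoming ties confer centrality
  mode(m) <- "numeric"
  # iterate on A + I: same principal eigenvector, but immune to the
  # sign-flip oscillation of bipartite graphs (where -lambda_1 is also an
  # eigenvalue and plain power iteration never settles)
  diag(m) <- diag(m) + 1
  x <- rep(1, length(nodes))
  for (it in seq_len(max_iter)) {
    x_new <- drop(m %*% x)
    x_new <- x_new / max(x_new)
    if (max(abs(x_new - x)) < tol) {
      return(stats::setNames(x_new, nodes))
    }
    x <- x_new
  }
  stop(sprintf("eigenvector power iteration did not converge in %d iterations",
               max_iter), call. = FALSE)
}

#' Structural report for one network
#'
#' The metric battery used to compare inferred and reference networks:
#' density, gender assortativity, (in-)degree and closeness centralization,
#' and per-node degree and eigenvector centrality. Directed networks use
#' in-degree for the degree-type measures. All metrics are computed on the
#' binarized graph.
#'
#' @param net a [social_network].
#' @param gender optional named gender vector; without it assortativity and
#'   the female share are reported as `NA`.
#' @return object of class `sna_report`.
#' @export
sna_report <- function(net, gender = NULL) {
  stopifnot(inherits(net, "social_network"))
  n <- length(net$nodes)
  has_edges <- any(net$edges$weight > 0)
  deg_kind <- if (net$directed) "in_degree" else "degree"
  eig <- if (has_edges) node_centrality(net, "eigenvector") else
    stats::setNames(rep(NA_real_, n), net$nodes)
  structure(list(
    n_nodes = n,
    directed = net$directed,
    pct_female = if (is.null(gender)) NA_real_ else
      mean(tolower(as.character(gender[net$nodes])) %in% c("f", "female")),
    density = net_density(net),
    assortativity_gender = if (is.null(gender) || !has_edges) NA_real_ else
      assortativity_gender(net, gender),
    centralization_degree = centralization(net, deg_kind),
    centralization_closeness = centralization(net, "closeness"),
    degree_centrality = node_centrality(net, deg_kind),
    eigenvector_centrality = eig),
    class = "sna_report")
}

#' @export
print.sna_report <- function(x, ...) {
  cat(sprintf("<sna_report: %s, %d nodes>\n",
              if (x$directed) "directed" else "undirected", x$n_nodes))
  cat(sprintf("  density                  %.3f\n", x$density))
  cat(sprintf("  assortativity (gender)   %s\n",
              if (is.na(x$assortativity_gender)) "n/a" else
                sprintf("%.3f", x$assortativity_gender)))
  cat(sprintf("  centralization (%s) %.3f\n",
              if (x$directed) "in-deg." else "degree ",
              x$centralization_degree))
  cat(sprintf("  centralization (closen.) %.3f\n",
              x$centralization_closeness))
  top <- sort(x$degree_centrality, decreasing = TRUE)
  top <- top[seq_len(min(3, length(top)))]
  cat("  top degree: ", paste(sprintf("%s (%d)", names(top), top),
                              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Compare the structural reports of a reference and an inferred network
#'
#' Side-by-side global metrics with deltas (inferred minus reference), plus
#' the Spearman rank correlation between the two degree sequences — low
#' rank correlation flags that different nodes look central in the two
#' networks even when global metrics agree.
#'
#' @param gt_report,bt_report [sna_report]s over the same roster.
#' @return object of class `sna_comparison`: list with `table` (metric, GT,
#'   BT, delta) and `degree_rank_correlation`.
#' @export
compare_sna <- function(gt_report, bt_report) {
  stopifnot(inherits(gt_report, "sna_report"),
            inherits(bt_report, "sna_report"))
  ng <- names(gt_report$degree_centrality)
  nb <- names(bt_report$degree_centrality)
  if (!identical(sort(ng), sort(nb))) {
    stop("reports cover different rosters", call. = FALSE)
  }
  metrics <- c("density", "assortativity_gender", "centralization_degree",
               "centralization_closeness")
  gtv <- vapply(metrics, function(m) gt_report[[m]], numeric(1))
  btv <- vapply(metrics, function(m) bt_report[[m]], numeric(1))
  tab <- data.frame(metric = metrics, gt = gtv, bt = btv, delta = btv - gtv,
                    row.names = NULL, stringsAsFactors = FALSE)
  dg <- gt_report$degree_centrality[ng]
  db <- bt_report$degree_centrality[ng]
  rho <- if (stats::sd(dg) == 0 || stats::sd(db) == 0) {
    NA_real_  # a constant degree sequence has no ranking to correlate
  } else {
    stats::cor(dg, db, method = "spearman")
  }
  structure(list(table = tab, degree_rank_correlation = rho),
            class = "sna_comparison")
}

#' @export
print.sna_comparison <- function(x, ...) {
  cat("Structural comparison (GT vs inferred):\n")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-24s %6s / %6s  (delta %+.3f)\n", tab$metric[i],
                ifelse(is.na(tab$gt[i]), "n/a", sprintf("%.3f", tab$gt[i])),
                ifelse(is.na(tab$bt[i]), "n/a", sprintf("%.3f", tab$bt[i])),
                tab$delta[i]))
  }
  cat(sprintf("  degree rank correlation  %.3f\n",
              x$degree_rank_correlation))
  invisible(x)
}
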