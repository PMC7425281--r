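#' Restrict a scan log to an observation window
#'
#' A window is a prefix of the ordered day list and a prefix of the ordered
#' schedule of eligible scan periods; it gives the inferred network a time
#' dimension (e.g. "the first two days, first twelve scan periods"). Only
#' records whose day is among the first `n_days` days *and* whose period is
#' among the first `n_scans` eligible periods are kept. Windows nest: a
#' smaller window never contains records absent from a larger one.
#'
#' @param log a [scan_log].
#' @param n_days number of days to keep (prefix of the sorted distinct days).
#' @param n_scans number of scan periods to keep (prefix of the schedule).
#' @return a windowed [scan_log].
#' @export
window_log <- function(log, n_days = NULL, n_scans = NULL) {
  stopifnot(inherits(log, "scan_log"))
  days <- sort(unique(log$records$day))
  periods <- log$schedule
  if (is.null(n_days)) n_days <- length(days)
  if (is.null(n_scans)) n_scans <- length(periods)
  if (n_days < 1 || n_days > length(days)) {
    stop(sprintf("n_days must be in 1..%d", length(days)), call. = FALSE)
  }
  if (n_scans < 1 || n_scans > length(periods)) {
    stop(sprintf("n_scans must be in 1..%d", length(periods)), call. = FALSE)
  }
  keep_days <- days[seq_len(n_days)]
  keep_periods <- periods[seq_len(n_scans)]
  keep <- log$records$day %in% keep_days & log$records$period %in% keep_periods
  log$records <- log$records[keep, , drop = FALSE]
  rownames(log$records) <- NULL
  log$schedule <- keep_periods
  log
}

#' Detection counts underlying the connection weight
#'
#' Tallies, over the log's (wave, day, scan-period) slots,
#' `num_connections(i, j)` — the number of slots in which `i` detected `j` —
#' and `num_scans(i)` — the number of slots in which `i` scanned
#' successfully, i.e. logged at least one detection. Because the log is
#' deduplicated per slot, `num_connections(i, j) <= num_scans(i)` always
#' holds.
#'
#' @param log a [scan_log].
#' @return object of class `detection_counts`: list with `connections`
#'   (matrix, scanner in rows), `scans` (named vector) and `nodes`.
#' @export
count_detections <- function(log) {
  stopifnot(inherits(log, "scan_log"))
  nodes <- log$roster$id
  r <- log$records
  conn <- table(factor(r$scanner, levels = nodes),
                factor(r$detected, levels = nodes))
  conn <- matrix(as.integer(conn), nrow = length(nodes),
                 dimnames = list(nodes, nodes))
  slot <- paste(r$wave, r$day, r$period, sep = "\r")
  first <- !duplicated(paste(r$scanner, slot, sep = "\r"))
  scans <- table(factor(r$scanner[first], levels = nodes))
  scans <- stats::setNames(as.integer(scans), nodes)
  structure(list(connections = conn, scans = scans, nodes = nodes),
            class = "detection_counts")
}

#' Laplace-smoothed connection weight
#'
#' The weight of the tie between nodes `i` and `j` is the smoothed ratio of
#' their mutual detections to their combined scan activity:
#' \deqn{w_{ij} = \frac{c_{ij} + c_{ji} + \alpha}{s_i + s_j + \beta}}
#' where \eqn{c_{ij}} is the number of scan periods in which `i` detected
#' `j` and \eqn{s_i} the number of successful scan periods of `i`. The
#' smoothing pair compensates for unequal scan participation: with the
#' defaults \eqn{\alpha = 0, \beta = 1} the weight is biased towards 0, the
#' more so the fewer scans the pair logged, so a pair detected in 44 of 44
#' combined scans outranks one detected in 5 of 5. The weight is symmetric
#' by construction.
#'
#' `connection_weight()` is the scalar kernel on raw counts;
#' [edge_weight()] looks the counts up in a [count_detections()] result.
#'
#' @param c_ij,c_ji detections of `j` by `i` and of `i` by `j`.
#' @param s_i,s_j successful scan counts of the two nodes.
#' @param alpha,beta smoothing parameters (defaults 0 and 1).
#' @return weight in `[0, 1]` (strictly below 1 whenever `beta >= 1`).
#' @examples
#' connection_weight(22, 22, 22, 22, alpha = 0, beta = 0)  # 1
#' connection_weight(22, 22, 22, 22)                       # 44/45
#' @export
connection_weight <- function(c_ij, c_ji, s_i, s_j, alpha = 0, beta = 1) {
  if (any(c(c_ij, c_ji, s_i, s_j) < 0) || alpha < 0 || beta < 0) {
    stop("counts and smoothing parameters must be non-negative",
         call. = FALSE)
  }
  den <- s_i + s_j + beta
  if (den == 0) {
    stop("zero denominator: no scans and beta = 0; use beta > 0",
         call. = FALSE)
  }
  (c_ij + c_ji + alpha) / den
}

#' @rdname connection_weight
#' @param counts a [count_detections()] result.
#' @param i,j node ids (`i != j`).
#' @export
edge_weight <- function(counts, i, j, alpha = 0, beta = 1) {
  stopifnot(inherits(counts, "detection_counts"))
  if (i == j) stop("i and j must differ", call. = FALSE)
  if (!all(c(i, j) %in% counts$nodes)) {
    stop("unknown node id", call. = FALSE)
  }
  connection_weight(counts$connections[i, j], counts$connections[j, i],
                    counts$scans[[i]], counts$scans[[j]],
                    alpha = alpha, beta = beta)
}

# Full symmetric weight matrix; diagonal set to 0.
weight_matrix <- function(counts, alpha = 0, beta = 1) {
  c2 <- counts$connections + t(counts$connections)
  den <- outer(counts$scans, counts$scans, "+") + beta
  if (any(den == 0)) {
    stop("zero denominator in weight matrix; use beta > 0", call. = FALSE)
  }
  w <- (c2 + alpha) / den
  diag(w) <- 0
  w
}

#' Infer a proximity network from a scan log
#'
#' Builds the weighted network over the log's roster: pairwise connection
#' weights from the (optionally windowed) log, then a strict threshold —
#' only edges with weight `> threshold` survive. The undirected network has
#' one edge per qualifying pair; the directed variant carries two opposite
#' arcs with equal weight (the weight itself is symmetric). Roster nodes
#' with no surviving edge are retained as isolates.
#'
#' @param log a [scan_log].
#' @param n_days,n_scans optional window, see [window_log()].
#' @param directed logical connection type.
#' @param threshold edge-weight threshold in `[0, 1)`, strict.
#' @param alpha,beta smoothing parameters of [connection_weight()].
#' @return a [social_network].
#' @export
build_bt_network <- function(log, n_days = NULL, n_scans = NULL,
                             directed = FALSE, threshold = 0,
                             alpha = 0, beta = 1) {
  stopifnot(inherits(log, "scan_log"))
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(n_days) || !is.null(n_scans)) {
    log <- window_log(log, n_days = n_days, n_scans = n_scans)
  }
  counts <- count_detections(log)
  w <- weight_matrix(counts, alpha = alpha, beta = beta)
  nodes <- counts$nodes
  if (directed) {
    idx <- which(w > threshold, arr.ind = TRUE)
  } else {
    idx <- which(w > threshold & upper.tri(w), arr.ind = TRUE)
  }
  edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                      weight = w[idx])
  social_network(edges, nodes = nodes, directed = directed)
}
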