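#' Parameter grid for the brute-force network validation
#'
#' The search space of the validation algorithm: edge-weight thresholds,
#' cumulative day windows and cumulative scan-period windows. Thresholds
#' start above 0 (the threshold-0, full-window candidate is the *baseline*
#' scenario, not a grid member); windows are prefix lengths, so `n_days = 2`
#' means "the first two days". The default threshold set is 0.01 to 0.60 in
#' steps of 0.01 — 60 values; beyond about 0.6 thresholding mostly
#' manufactures isolated nodes rather than removing noise (see
#' [isolated_fraction()]).
#'
#' @param weights strictly increasing thresholds in `[0, 1)`.
#' @param day_windows increasing day-prefix lengths.
#' @param scan_windows increasing scan-period-prefix lengths.
#' @return object of class `bva_grid`.
#' @export
bva_grid <- function(weights = seq(0.01, 0.60, by = 0.01),
                     day_windows = 1:5, scan_windows = 1:16) {
  weights <- as.numeric(weights)
  day_windows <- as.integer(day_windows)
  scan_windows <- as.integer(scan_windows)
  if (length(weights) == 0 || length(day_windows) == 0 ||
      length(scan_windows) == 0) {
    stop("grid components must be non-empty", call. = FALSE)
  }
  if (any(diff(weights) <= 0) || any(weights < 0) || any(weights >= 1)) {
    stop("weights must be strictly increasing and in [0, 1)", call. = FALSE)
  }
  if (any(day_windows < 1) || any(scan_windows < 1)) {
    stop("window lengths must be >= 1", call. = FALSE)
  }
  structure(list(weights = weights, day_windows = sort(day_windows),
                 scan_windows = sort(scan_windows)),
            class = "bva_grid")
}

#' Enumerate the parameter tuples of a grid
#'
#' Cartesian product of thresholds, day windows and scan windows, in
#' deterministic lexicographic order on (weight, n_days, n_scans). This is
#' the candidate count *per connection type*.
#'
#' @param grid a [bva_grid].
#' @return data frame with columns `weight`, `n_days`, `n_scans`.
#' @examples
#' nrow(enumerate_grid(bva_grid()))  # 60 x 5 x 16 = 4800
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "bva_grid"))
  tuples <- expand.grid(n_scans = grid$scan_windows,
                        n_days = grid$day_windows,
                        weight = grid$weights,
                        KEEP.OUT.ATTRS = FALSE)
  tuples[c("weight", "n_days", "n_scans")]
}

# Expand detection counts to a pair-universe that may exceed the log roster
# (survey participants who never logged a scan are legitimate isolates).
pad_counts <- function(counts, nodes) {
  extra <- setdiff(nodes, counts$nodes)
  if (length(extra) == 0) {
    return(list(connections = counts$connections[nodes, nodes, drop = FALSE],
                scans = counts$scans[nodes]))
  }
  n <- length(nodes)
  conn <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  conn[counts$nodes, counts$nodes] <- counts$connections
  scans <- stats::setNames(integer(n), nodes)
  scans[counts$nodes] <- counts$scans
  list(connections = conn, scans = scans)
}

# Confusion over adjacency matrices restricted to the pair mask.
confusion_from_mask <- function(B, G, mask) {
  tp <- sum(B & G & mask); fp <- sum(B & !G & mask)
  fn <- sum(!B & G & mask); tn <- sum(!B & !G & mask)
  structure(c(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

metric_function <- function(metric) if (metric == "mcc") mcc else accuracy

# Logical adjacency of a network over an enclosing roster (extra rows and
# columns stay FALSE); undirected networks are symmetrised.
adjacency_over <- function(net, nodes) {
  n <- length(nodes)
  m <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  e <- net$edges[net$edges$weight > 0, , drop = FALSE]
  if (nrow(e) > 0) {
    m[cbind(e$from, e$to)] <- TRUE
    if (!net$directed) m[cbind(e$to, e$from)] <- TRUE
  }
  m
}

#' Brute-force validation of proximity-network inference
#'
#' Fits the inference parameters by exhaustive search: for every grid tuple
#' (edge-weight threshold, day window, scan window) a candidate network is
#' inferred from the scan log and scored against the ground-truth network by
#' classification [accuracy()] or [mcc()] over the full pair universe. The
#' best-scoring candidate is selected, with ties broken in favour of fewer
#' scan records used, then fewer days, then fewer scan periods, then the
#' lexicographically smallest parameter tuple — so the selection is fully
#' deterministic. The connection type (directed/undirected) is taken from
#' the ground-truth network.
#'
#' @param log a [scan_log], already filtered for data quality (see
#'   [filter_scan_periods()]).
#' @param gt reference [social_network] (edges = positive weights).
#' @param grid a [bva_grid]; defaults to 60 thresholds times all available
#'   day and scan-period prefixes of `log`.
#' @param metric `"accuracy"` (balanced classes) or `"mcc"` (imbalanced).
#' @param alpha,beta smoothing parameters of [connection_weight()].
#' @return An object of class `bva`: list with `results` (one row per
#'   tuple: parameters, confusion counts, metric, records used, canonical
#'   edge-set fingerprint), `optimal`, `trace` (tie-break ordering of the
#'   top candidates), `baseline`, `optimal_network`, `distinct`, `metric`,
#'   `grid`, `nodes`, with `print`, `summary`, `coef`, `predict` and `plot`
#'   methods.
#' @export
bva <- function(log, gt, grid = NULL, metric = c("accuracy", "mcc"),
                alpha = 0, beta = 1) {
  stopifnot(inherits(log, "scan_log"), inherits(gt, "social_network"))
  metric <- match.arg(metric)
  mfun <- metric_function(metric)
  days <- sort(unique(log$records$day))
  periods <- log$schedule
  if (length(days) == 0 || length(periods) == 0) {
    stop("scan log has no records", call. = FALSE)
  }
  if (is.null(grid)) {
    grid <- bva_grid(day_windows = seq_along(days),
                     scan_windows = seq_along(periods))
  }
  stopifnot(inherits(grid, "bva_grid"))
  if (max(grid$day_windows) > length(days)) {
    stop("grid day windows exceed the log's ", length(days), " day(s)",
         call. = FALSE)
  }
  if (max(grid$scan_windows) > length(periods)) {
    stop("grid scan windows exceed the log's ", length(periods),
         " scan period(s)", call. = FALSE)
  }

  nodes <- union(gt$nodes, log$roster$id)
  n <- length(nodes)
  directed <- gt$directed
  G <- adjacency_over(gt, nodes)
  mask <- if (directed) {
    matrix(TRUE, n, n) & !diag(n)
  } else {
    upper.tri(matrix(0, n, n))
  }

  day_idx <- match(log$records$day, days)
  per_idx <- match(log$records$period, periods)

  res <- vector("list", length(grid$day_windows) * length(grid$scan_windows))
  k <- 0
  for (d in grid$day_windows) {
    for (s in grid$scan_windows) {
      keep <- day_idx <= d & per_idx <= s
      sub <- log
      sub$records <- log$records[keep, , drop = FALSE]
      cts <- pad_counts(count_detections(sub), nodes)
      w <- weight_matrix(cts, alpha = alpha, beta = beta)
      n_obs <- sum(keep)
      rows <- lapply(grid$weights, function(t) {
        B <- w > t
        cc <- confusion_from_mask(B, G, mask)
        data.frame(weight = t, n_days = d, n_scans = s,
                   type = if (directed) "directed" else "undirected",
                   tp = cc[["tp"]], tn = cc[["tn"]],
                   fp = cc[["fp"]], fn = cc[["fn"]],
                   metric_value = mfun(cc), n_obs = n_obs,
                   fingerprint = paste(which(B & mask), collapse = ","),
                   stringsAsFactors = FALSE)
      })
      k <- k + 1
      res[[k]] <- do.call(rbind, rows)
    }
  }
  results <- do.call(rbind, res)
  results <- results[order(results$weight, results$n_days, results$n_scans), ]
  rownames(results) <- NULL

  sel <- select_optimal(results)
  bl <- baseline(log, gt, metric = metric, alpha = alpha, beta = beta)

  opt <- sel$optimal
  opt_net <- {
    keep <- day_idx <= opt$n_days & per_idx <= opt$n_scans
    sub <- log
    sub$records <- log$records[keep, , drop = FALSE]
    cts <- pad_counts(count_detections(sub), nodes)
    w <- weight_matrix(cts, alpha = alpha, beta = beta)
    B <- w > opt$weight
    idx <- which(B & (if (directed) !diag(n) else upper.tri(B)),
                 arr.ind = TRUE)
    social_network(data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                              weight = w[idx]),
                   nodes = nodes, directed = directed)
  }

  structure(list(results = results, optimal = opt, trace = sel$trace,
                 baseline = bl, optimal_network = opt_net,
                 distinct = count_distinct(results), metric = metric,
                 grid = grid, nodes = nodes,
                 alpha = alpha, beta = beta, call = match.call()),
            class = "bva")
}

#' Select the optimal candidate from a results table
#'
#' Argmax of the metric; ties go to the candidate generated from fewer scan
#' records, then fewer days, then fewer scan periods, then the
#' lexicographically smallest parameter tuple.
#'
#' @param results results data frame as produced by [bva()] (columns
#'   `metric_value`, `n_obs`, `n_days`, `n_scans`, `weight`).
#' @return list with `optimal` (one-row data frame) and `trace` (all
#'   metric-tied candidates in tie-break order).
#' @export
select_optimal <- function(results) {
  if (nrow(results) == 0) stop("empty results", call. = FALSE)
  ord <- order(-results$metric_value, results$n_obs, results$n_days,
               results$n_scans, results$weight)
  ranked <- results[ord, , drop = FALSE]
  top <- ranked[ranked$metric_value == ranked$metric_value[1], , drop = FALSE]
  rownames(top) <- NULL
  list(optimal = top[1, , drop = FALSE], trace = top)
}

#' Count distinct metric values and distinct candidate networks
#'
#' The grid routinely produces far fewer distinct networks than tuples:
#' many parameter combinations are observationally equivalent. Metric
#' values are compared after rounding; networks by their canonical edge-set
#' fingerprint. Note that distinct networks can share a metric value, so
#' neither count bounds the other.
#'
#' @param results results data frame as produced by [bva()].
#' @param digits rounding applied to the metric before counting (default 4).
#' @return list with `values` and `networks` counts.
#' @export
count_distinct <- function(results, digits = 4) {
  if (nrow(results) == 0) stop("empty results", call. = FALSE)
  list(values = length(unique(round(results$metric_value, digits))),
       networks = length(unique(results$fingerprint)))
}

#' Baseline scenario: no parameter optimization
#'
#' The candidate inferred with threshold 0 and the maximal window (all days,
#' all scan periods) — every observed detection becomes an edge. This is
#' what naive use of the raw proximity data amounts to; the brute-force
#' search is judged against it.
#'
#' @inheritParams bva
#' @return one-row data frame in the layout of [bva()]'s `results`.
#' @export
baseline <- function(log, gt, metric = c("accuracy", "mcc"),
                     alpha = 0, beta = 1) {
  stopifnot(inherits(log, "scan_log"), inherits(gt, "social_network"))
  metric <- match.arg(metric)
  nodes <- union(gt$nodes, log$roster$id)
  directed <- gt$directed
  bt <- build_bt_network(log, directed = directed, threshold = 0,
                         alpha = alpha, beta = beta)
  # pair universe = full roster, so compare over `nodes`
  cc <- confusion(bt, gt, roster = nodes)
  n <- length(nodes)
  mask <- if (directed) matrix(TRUE, n, n) & !diag(n) else
    upper.tri(matrix(0, n, n))
  B <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(bt$edges) > 0) {
    B[cbind(bt$edges$from, bt$edges$to)] <- TRUE
    if (!directed) B[cbind(bt$edges$to, bt$edges$from)] <- TRUE
  }
  data.frame(weight = 0, n_days = length(unique(log$records$day)),
             n_scans = length(log$schedule),
             type = if (directed) "directed" else "undirected",
             tp = cc[["tp"]], tn = cc[["tn"]], fp = cc[["fp"]],
             fn = cc[["fn"]],
             metric_value = metric_function(metric)(cc),
             n_obs = nrow(log$records),
             fingerprint = paste(which(B & mask), collapse = ","),
             stringsAsFactors = FALSE)
}

#' @export
print.bva <- function(x, ...) {
  cat(sprintf("Brute-force network validation (%s)\n", x$metric))
  cat(sprintf("  candidates: %d (%d thresholds x %d day x %d scan windows)\n",
              nrow(x$results), length(x$grid$weights),
              length(x$grid$day_windows), length(x$grid$scan_windows)))
  cat(sprintf("  optimal:    %s = %.4f at weight > %.2f, days = %d, scans = %d (%d records)\n",
              x$metric, x$optimal$metric_value, x$optimal$weight,
              x$optimal$n_days, x$optimal$n_scans, x$optimal$n_obs))
  cat(sprintf("  baseline:   %s = %.4f (threshold 0, full window)\n",
              x$metric, x$baseline$metric_value))
  invisible(x)
}

#' @export
summary.bva <- function(object, ...) {
  r <- object$results
  out <- list(
    metric = object$metric,
    n_candidates = nrow(r),
    range = range(r$metric_value),
    distinct = object$distinct,
    optimal = object$optimal,
    n_tied = nrow(object$trace),
    baseline = object$baseline$metric_value,
    improvement = object$optimal$metric_value - object$baseline$metric_value)
  class(out) <- "summary.bva"
  out
}

#' @export
print.summary.bva <- function(x, ...) {
  cat(sprintf("Brute-force network validation, metric = %s\n", x$metric))
  cat(sprintf("  %d candidates; metric range [%.4f, %.4f]\n",
              x$n_candidates, x$range[1], x$range[2]))
  cat(sprintf("  distinct metric values: %d; distinct networks: %d\n",
              x$distinct$values, x$distinct$networks))
  cat(sprintf("  %d candidate(s) tied at the optimum\n", x$n_tied))
  cat(sprintf("  optimal %.4f vs baseline %.4f (improvement %+.4f)\n",
              x$optimal$metric_value, x$baseline, x$improvement))
  cat(sprintf("  selected: weight > %.2f, days = %d, scans = %d\n",
              x$optimal$weight, x$optimal$n_days, x$optimal$n_scans))
  invisible(x)
}

#' @describeIn bva optimal parameters as a named vector
#'   (`weight`, `n_days`, `n_scans`).
#' @param object,x a fitted `bva` object.
#' @param ... unused.
#' @export
coef.bva <- function(object, ...) {
  c(weight = object$optimal$weight, n_days = object$optimal$n_days,
    n_scans = object$optimal$n_scans)
}

#' @describeIn bva the selected optimal [social_network].
#' @export
predict.bva <- function(object, ...) {
  object$optimal_network
}

#' @describeIn bva metric-versus-threshold profile, one line per day
#'   window at the widest scan window, with the baseline as a dashed line.
#' @export
plot.bva <- function(x, ...) {
  r <- x$results
  smax <- max(r$n_scans)
  r <- r[r$n_scans == smax, ]
  dws <- sort(unique(r$n_days))
  cols <- grDevices::hcl.colors(max(2L, length(dws)), "Dark 2")
  plot(NA, xlim = range(r$weight), ylim = range(x$results$metric_value),
       xlab = "connection weight threshold", ylab = x$metric,
       main = "Validation profile", ...)
  for (i in seq_along(dws)) {
    ri <- r[r$n_days == dws[i], ]
    graphics::lines(ri$weight, ri$metric_value, col = cols[i])
  }
  graphics::abline(h = x$baseline$metric_value, lty = 2)
  graphics::points(x$optimal$weight, x$optimal$metric_value, pch = 19)
  graphics::legend("bottomright", legend = sprintf("%d day(s)", dws),
                   col = cols[seq_along(dws)], lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}
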