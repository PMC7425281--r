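# Independent brute-force oracles, deliberately written as plain loops over
# raw rows/pairs so they share no code path with the package internals.

# Confusion counts by explicit enumeration of every node pair.
oracle_confusion <- function(bt, gt, roster) {
  has_edge <- function(net, i, j) {
    e <- net$edges[net$edges$weight > 0, , drop = FALSE]
    if (net$directed) {
      any(e$from == i & e$to == j)
    } else {
      any((e$from == i & e$to == j) | (e$from == j & e$to == i))
    }
  }
  tp <- tn <- fp <- fn <- 0
  for (i in roster) {
    for (j in roster) {
      if (i == j) next
      if (!bt$directed && i > j) next
      b <- has_edge(bt, i, j)
      g <- has_edge(gt, i, j)
      if (b && g) tp <- tp + 1
      else if (b && !g) fp <- fp + 1
      else if (!b && g) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

oracle_accuracy <- function(cc) (cc[["tp"]] + cc[["tn"]]) / sum(cc)

oracle_mcc <- function(cc) {
  tp <- cc[["tp"]]; tn <- cc[["tn"]]; fp <- cc[["fp"]]; fn <- cc[["fn"]]
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# Detection tallies by looping over raw record rows.
oracle_counts <- function(records, nodes) {
  conn <- matrix(0, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  scan_slots <- lapply(stats::setNames(nm = nodes), function(x) character(0))
  for (r in seq_len(nrow(records))) {
    i <- records$scanner[r]; j <- records$detected[r]
    conn[i, j] <- conn[i, j] + 1
    slot <- paste(records$wave[r], records$day[r], records$period[r])
    scan_slots[[i]] <- union(scan_slots[[i]], slot)
  }
  list(connections = conn,
       scans = vapply(scan_slots, length, numeric(1)))
}

# Newman assortativity from an explicitly assembled 2x2 mixing matrix.
oracle_assortativity <- function(net, gender) {
  e <- net$edges[net$edges$weight > 0, , drop = FALSE]
  cats <- sort(unique(gender))
  m <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  for (r in seq_len(nrow(e))) {
    gi <- gender[[e$from[r]]]; gj <- gender[[e$to[r]]]
    m[gi, gj] <- m[gi, gj] + 1
    if (!net$directed) m[gj, gi] <- m[gj, gi] + 1
  }
  em <- m / sum(m)
  sab <- sum(rowSums(em) * colSums(em))
  (sum(diag(em)) - sab) / (1 - sab)
}

# Random simple network over sprintf-named nodes.
rand_net <- function(n, p, directed = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  if (!directed) pairs <- pairs[pairs$from < pairs$to, ]
  keep <- runif(nrow(pairs)) < p
  social_network(data.frame(pairs[keep, , drop = FALSE],
                            weight = rep(1, sum(keep))),
                 nodes = nodes, directed = directed)
}

# Random scan log: k records drawn uniformly over (i, j, day, period).
rand_log <- function(n_nodes, n_days, n_periods, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  i <- sample(nodes, k, replace = TRUE)
  j <- sample(nodes, k, replace = TRUE)
  ok <- i != j
  suppressWarnings(scan_log(
    data.frame(scanner = i[ok], detected = j[ok], wave = "W1",
               day = sample(n_days, sum(ok), replace = TRUE),
               period = sample(0:(n_periods - 1), sum(ok), replace = TRUE)),
    roster = data.frame(id = nodes),
    schedule = 0:(n_periods - 1)))
}

# Small star / clique builders used across metric tests.
star_net <- function(n) {
  nodes <- sprintf("s%02d", seq_len(n))
  social_network(data.frame(from = nodes[1], to = nodes[-1], weight = 1),
                 nodes = nodes)
}

complete_net <- function(n, directed = FALSE) {
  nodes <- sprintf("c%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  if (!directed) pairs <- pairs[pairs$from < pairs$to, ]
  social_network(data.frame(pairs, weight = 1), nodes = nodes,
                 directed = directed)
}
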