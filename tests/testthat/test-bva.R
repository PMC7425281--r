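test_that("grid enumeration is the full cartesian product in fixed order", {
  g <- bva_grid()  # 60 thresholds x 5 day x 16 scan windows
  tuples <- enumerate_grid(g)
  expect_equal(nrow(tuples), 4800)

  expect_equal(nrow(enumerate_grid(bva_grid(0.1, 1, 1))), 1)

  g2 <- enumerate_grid(bva_grid(c(0.1, 0.2), 1:3, 1:4))
  expect_equal(nrow(g2), 24)
  # lexicographic on (weight, n_days, n_scans)
  expect_equal(g2, g2[order(g2$weight, g2$n_days, g2$n_scans), ],
               ignore_attr = TRUE)

  expect_error(bva_grid(weights = numeric(0)), "non-empty")
  expect_error(bva_grid(weights = c(0.2, 0.1)), "increasing")
})

test_that("confusion counts enumerate the full pair universe", {
  nodes <- c("A", "B", "C", "D")
  gt <- social_network(data.frame(from = c("A", "B"), to = c("B", "C")),
                       nodes = nodes)
  bt <- social_network(data.frame(from = c("A", "C"), to = c("B", "D")),
                       nodes = nodes)
  cc <- confusion(bt, gt)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               c(tp = 1L, fp = 1L, fn = 1L, tn = 3L))
  expect_equal(sum(cc), 6)  # 4*3/2 unordered pairs
  expect_equal(accuracy(cc), 4 / 6)
  expect_equal(mcc(cc), (3 - 1) / sqrt(2 * 2 * 4 * 4))

  # identical edge sets: no errors, both metrics maximal
  ccp <- confusion(gt, gt)
  expect_equal(ccp[["fp"]] + ccp[["fn"]], 0)
  expect_equal(accuracy(ccp), 1.0)
  expect_equal(mcc(ccp), 1.0)

  # complement prediction: perfect misclassification
  pairs <- t(combn(nodes, 2))
  keep <- !(paste(pairs[, 1], pairs[, 2], sep = "--") %in% edge_set(gt))
  comp <- social_network(data.frame(from = pairs[keep, 1],
                                    to = pairs[keep, 2]), nodes = nodes)
  ccc <- confusion(comp, gt)
  expect_equal(ccc[["tp"]] + ccc[["tn"]], 0)
  expect_equal(accuracy(ccc), 0.0)
  expect_equal(mcc(ccc), -1.0)

  expect_error(confusion(social_network(nodes = nodes, directed = TRUE), gt),
               "connection type")
})

test_that("MCC uses the zero-denominator convention", {
  expect_equal(mcc(c(tp = 0, tn = 10, fp = 0, fn = 0)), 0)
  expect_equal(mcc(c(tp = 3, tn = 3, fp = 0, fn = 0)), 1)
  expect_equal(mcc(c(tp = 0, tn = 0, fp = 3, fn = 3)), -1)
})

test_that("the grid search agrees with per-tuple reconstruction", {
  st <- simulate_study(sim_config(n_nodes = 8, n_days = 3, periods = 0:5,
                                  seed = 12))
  grid <- bva_grid(weights = c(0.05, 0.15, 0.30), day_windows = 1:3,
                   scan_windows = c(2, 4, 6))
  for (gt in list(st$gt_undirected, st$gt_directed)) {
    fit <- bva(st$log, gt, grid = grid)
    expect_equal(nrow(fit$results), 27)
    for (r in sample(nrow(fit$results), 8)) {
      row <- fit$results[r, ]
      net <- build_bt_network(st$log, n_days = row$n_days,
                              n_scans = row$n_scans,
                              directed = gt$directed,
                              threshold = row$weight)
      cc <- oracle_confusion(net, gt, fit$nodes)
      expect_equal(c(row$tp, row$tn, row$fp, row$fn),
                   unname(cc[c("tp", "tn", "fp", "fn")]))
      expect_equal(row$metric_value, oracle_accuracy(cc))
      expect_equal(row$n_obs,
                   nrow(window_log(st$log, row$n_days, row$n_scans)$records))
    }
    # confusion totals conserve the pair-universe size
    n <- length(fit$nodes)
    tot <- if (gt$directed) n * (n - 1) else n * (n - 1) / 2
    expect_true(all(fit$results$tp + fit$results$tn + fit$results$fp +
                      fit$results$fn == tot))
  }
})

test_that("optimal selection applies the documented tie-breaks", {
  res <- data.frame(
    weight = c(0.2, 0.1, 0.3, 0.4),
    n_days = c(2, 2, 1, 2),
    n_scans = c(3, 3, 5, 2),
    metric_value = c(0.9, 0.9, 0.9, 0.5),
    n_obs = c(100, 50, 50, 10),
    fingerprint = letters[1:4])
  sel <- select_optimal(res)
  # ties at 0.9: fewer observations wins, then fewer days
  expect_equal(sel$optimal$weight, 0.3)
  expect_equal(sel$optimal$n_days, 1)
  expect_equal(nrow(sel$trace), 3)

  single <- res[4, ]
  expect_equal(select_optimal(single)$optimal$weight, 0.4)

  # full tie resolved lexicographically, stable under shuffling
  tied <- data.frame(weight = c(0.3, 0.1), n_days = 1, n_scans = 1,
                     metric_value = 0.7, n_obs = 5, fingerprint = "x")
  expect_equal(select_optimal(tied)$optimal$weight, 0.1)
  expect_equal(select_optimal(tied[2:1, ])$optimal$weight, 0.1)
})

test_that("grid evaluation is order-independent and dominates the baseline", {
  st <- simulate_study(sim_config(n_nodes = 10, n_days = 2, periods = 0:7,
                                  seed = 77))
  grid <- bva_grid(weights = seq(0.05, 0.5, by = 0.05), day_windows = 1:2,
                   scan_windows = c(4, 8))
  fit <- bva(st$log, st$gt_undirected, grid = grid)
  # argmax dominates every member and the baseline is reproduced exactly
  expect_true(all(fit$optimal$metric_value >= fit$results$metric_value))
  bl <- baseline(st$log, st$gt_undirected)
  expect_equal(fit$baseline, bl)
  full0 <- build_bt_network(st$log, threshold = 0)
  cc <- oracle_confusion(full0, st$gt_undirected, fit$nodes)
  expect_equal(bl$metric_value, oracle_accuracy(cc))

  shuffled <- fit$results[sample(nrow(fit$results)), ]
  expect_equal(select_optimal(shuffled)$optimal,
               select_optimal(fit$results)$optimal, ignore_attr = TRUE)
})

test_that("distinct accounting counts rounded values and fingerprints", {
  res <- data.frame(metric_value = c(0.5, 0.50004, 0.6),
                    fingerprint = c("1,2", "1,2", "1,3"))
  d <- count_distinct(res)
  expect_equal(d$values, 2)   # 0.5 and 0.50004 collide at 4 decimals
  expect_equal(d$networks, 2)

  one <- data.frame(metric_value = rep(0.5, 5), fingerprint = "1,2")
  expect_equal(unlist(count_distinct(one)), c(values = 1, networks = 1))

  # two thresholds straddling a single edge weight give 2 networks
  log <- scan_log(data.frame(scanner = c("a", "a", "a"), detected = "b",
                             wave = "W1", day = 1, period = 0:2),
                  roster = data.frame(id = c("a", "b", "c")))
  gt <- social_network(data.frame(from = "a", to = "b"),
                       nodes = c("a", "b", "c"))
  fit <- bva(log, gt, grid = bva_grid(weights = c(0.1, 0.9), day_windows = 1,
                                      scan_windows = 3))
  expect_equal(fit$distinct$networks, 2)
})

test_that("bva methods expose the fit in the modelling idiom", {
  st <- simulate_study(sim_config(n_nodes = 8, n_days = 2, periods = 0:4,
                                  seed = 100))
  fit <- bva(st$log, st$gt_undirected,
             grid = bva_grid(weights = c(0.1, 0.3), day_windows = 1:2,
                             scan_windows = c(2, 4)))
  expect_s3_class(fit, "bva")
  expect_named(coef(fit), c("weight", "n_days", "n_scans"))
  expect_s3_class(predict(fit), "social_network")
  expect_output(print(fit), "optimal")
  expect_output(print(summary(fit)), "distinct")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
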