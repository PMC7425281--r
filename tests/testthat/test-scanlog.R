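make_log_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("Wave,Day,Scan_Period,Child_ID,Detected_Child_ID", rows), path)
  path
}

test_that("scan logs read, deduplicate and drop self-detections", {
  p <- make_log_csv(c("W1,D1,S3,a,b", "W1,D1,S3,b,a", "W1,D2,S4,a,c"))
  log <- read_scan_log(p)
  expect_s3_class(log, "scan_log")
  expect_equal(nrow(log$records), 3)
  expect_equal(sort(log$roster$id), c("a", "b", "c"))
  expect_equal(log$schedule, c(3L, 4L))

  # duplicate (scanner, detected, wave, day, period) collapses to one
  p2 <- make_log_csv(c("W1,D1,S3,a,b", "W1,D1,S3,a,b"))
  expect_equal(nrow(read_scan_log(p2)$records), 1)

  # self-detections dropped and counted
  p3 <- make_log_csv(c("W1,D1,S3,a,a", "W1,D1,S3,a,b"))
  expect_warning(log3 <- read_scan_log(p3), "self-detection")
  expect_equal(nrow(log3$records), 1)

  # header-only file
  p4 <- make_log_csv(character(0))
  log4 <- read_scan_log(p4)
  expect_equal(nrow(log4$records), 0)
  expect_equal(nrow(log4$roster), 0)
})

test_that("scan-log format errors name the offending column or row", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("Wave,Day,Child_ID,Detected_Child_ID", "W1,D1,a,b"), p)
  expect_error(read_scan_log(p), "Scan_Period")
  p2 <- make_log_csv(c("W1,D1,S3,a,b", "W1,Dx,S3,a,c"))
  expect_error(read_scan_log(p2), "row 2")
})

test_that("off-roster detections are excluded, not added", {
  expect_warning(
    log <- scan_log(data.frame(scanner = c("a", "a"), detected = c("b", "z"),
                               wave = "W1", day = 1, period = 0),
                    roster = data.frame(id = c("a", "b"))),
    "unknown")
  expect_equal(nrow(log$records), 1)
})

test_that("scan-log write/read round-trips and dedup is idempotent", {
  st <- simulate_study(sim_config(n_nodes = 8, n_days = 2, periods = 0:5,
                                  seed = 7))
  p <- tempfile(fileext = ".csv")
  write_scan_log(st$log, p)
  back <- read_scan_log(p, roster = st$roster)
  expect_equal(back$records[order(back$records$day, back$records$period,
                                  back$records$scanner, back$records$detected), ],
               st$log$records[order(st$log$records$day, st$log$records$period,
                                    st$log$records$scanner,
                                    st$log$records$detected), ],
               ignore_attr = TRUE)
  again <- scan_log(back$records, roster = back$roster,
                    schedule = back$schedule)
  expect_equal(again$records, back$records)
})

test_that("nomination reading validates items and round-trips", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("nominator,nominee,item,wave",
               sprintf("a,b,%d,W1", 1:6)), p)
  noms <- read_nominations(p)
  expect_equal(nrow(noms), 6)

  writeLines(c("nominator,nominee,item,wave", "a,b,7,W1", "a,b,1,W1",
               "c,c,2,W1"), p)
  expect_warning(expect_warning(noms2 <- read_nominations(p),
                                "item outside"), "self-nomination")
  expect_equal(nrow(noms2), 1)

  st <- generate_gt(sim_config(n_nodes = 6, seed = 3))
  p2 <- tempfile(fileext = ".csv")
  write_nominations(st$nominations, p2)
  expect_equal(read_nominations(p2), st$nominations, ignore_attr = TRUE)
})

test_that("participation filter is strict at the threshold", {
  r <- filter_participation(18, 29)
  expect_equal(r$rate, 18 / 29, tolerance = 1e-12)
  expect_true(r$pass)                               # 62% > 60%
  expect_false(filter_participation(12, 20)$pass)   # exactly 60% fails
  expect_true(filter_participation(20, 25)$pass)    # 80%
  expect_error(filter_participation(5, 0), "class_size")
})

test_that("sparse scan periods are filtered out", {
  recs <- rbind(
    data.frame(scanner = rep("a", 30), detected = rep("b", 30), wave = "W1",
               day = rep(1:3, 10), period = 0),
    data.frame(scanner = rep("b", 29), detected = rep("a", 29), wave = "W1",
               day = rep(1:3, length.out = 29), period = 1))
  # duplicates within a slot would collapse; spread over fake distinct days
  recs$day <- seq_len(nrow(recs))
  recs$period <- rep(c(0, 1), c(30, 29))
  log <- scan_log(recs)
  expect_identical(filter_scan_periods(log, min_obs = 0), log)
  f <- filter_scan_periods(log, min_obs = 30)
  expect_equal(f$schedule, 0L)        # 29-record period removed
  expect_equal(nrow(f$records), 30)
  f2 <- filter_scan_periods(log, min_obs = 1000)
  expect_equal(length(f2$schedule), 0)
  expect_equal(nrow(f2$records), 0)
  # never increases record count
  expect_lte(nrow(filter_scan_periods(log, 10)$records), nrow(log$records))
})

test_that("friendship matrices read as binary networks", {
  p <- tempfile(fileext = ".csv")
  m <- matrix(0, 15, 15)
  write.csv(as.data.frame(m), p, row.names = FALSE)
  net <- read_friendship_matrix(p)
  expect_equal(length(net$nodes), 15)
  expect_equal(nrow(net$edges), 0)
  expect_false(net$directed)

  m3 <- matrix(0, 3, 3, dimnames = list(NULL, c("x", "y", "z")))
  m3[1, 2] <- m3[2, 1] <- 1
  write.csv(as.data.frame(m3), p, row.names = FALSE)
  net3 <- read_friendship_matrix(p)
  expect_false(net3$directed)
  expect_equal(edge_set(net3), "x--y")

  m3[1, 3] <- 1  # asymmetric now
  write.csv(as.data.frame(m3), p, row.names = FALSE)
  net4 <- read_friendship_matrix(p)
  expect_true(net4$directed)
  expect_setequal(edge_set(net4), c("x->y", "y->x", "x->z"))

  write.csv(data.frame(a = c(0, 2), b = c(1, 0)), p, row.names = FALSE)
  expect_error(read_friendship_matrix(p), "0 or 1")
})

test_that("network write/read round-trips in both formats", {
  net <- rand_net(8, 0.4, directed = FALSE, seed = 11)
  net$edges$weight <- round(runif(nrow(net$edges)), 6)

  p <- tempfile(fileext = ".csv")
  write_network(net, p, format = "edgelist")
  back <- read_network(p, format = "edgelist", nodes = net$nodes)
  expect_equal(sort(edge_set(back)), sort(edge_set(net)))
  expect_equal(back$edges$weight[order(back$edges$from, back$edges$to)],
               net$edges$weight[order(net$edges$from, net$edges$to)])

  g <- tempfile(fileext = ".graphml")
  write_network(net, g, format = "graphml")
  back2 <- read_network(g, format = "graphml")
  expect_setequal(back2$nodes, net$nodes)
  expect_equal(sort(edge_set(back2)), sort(edge_set(net)))

  # empty network: header-only edge list
  empty <- social_network(nodes = c("a", "b"))
  p2 <- tempfile(fileext = ".csv")
  write_network(empty, p2)
  expect_equal(length(readLines(p2)), 1)
})
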