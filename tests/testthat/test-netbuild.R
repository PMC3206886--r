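test_that("Pearson matrix matches closed-form values", {
  ts <- RoiTimeSeries(rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 5),
                            c = c(4, 3, 2, 1), d = c(1, 2, 3, 4)), trSeconds = 2)
  cm <- correlationMatrix(ts)
  r <- corValues(cm)
  expect_equal(r["a", "b"], 6.5 / sqrt(5 * 8.75), tolerance = 1e-10)
  expect_equal(r["a", "b"], 0.9827, tolerance = 1e-4)
  expect_equal(r["a", "d"], 1)
  expect_equal(r["a", "c"], -1)
  expect_identical(r, t(r))
  expect_true(all(diag(r) == 1))
})

test_that("degenerate correlation inputs raise informative errors", {
  flat <- RoiTimeSeries(rbind(a = rnorm(20), b = rep(3, 20)), trSeconds = 2)
  expect_error(correlationMatrix(flat), "b")
  short <- RoiTimeSeries(matrix(rnorm(4), 2, 2), c("a", "b"), 2)
  expect_error(correlationMatrix(short), "3 timepoints")
})

test_that("sparsity thresholding keeps exactly the target edge count", {
  set.seed(5)
  r <- randomAdjacency(90, 1) * 0  # placeholder for dims
  rm <- matrix(rnorm(90 * 90), 90, 90)
  rm <- (rm + t(rm)) / 2
  cm <- ConnectivityMatrix(tanh(rm / 4))
  g15 <- thresholdBySparsity(cm, 0.15)
  expect_equal(edgeCount(g15), 601)   # round(0.15 * 4005)
  gFull <- thresholdBySparsity(cm, 1)
  expect_equal(edgeCount(gFull), 4005)

  # exact edge counts over random matrices and random sparsities
  set.seed(6)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    m <- matrix(rnorm(n * n), n, n)
    cmi <- ConnectivityMatrix(tanh((m + t(m)) / 4))
    s <- stats::runif(1, 0.05, 0.9)
    k <- restnet:::.roundHalfUp(s * n * (n - 1) / 2)
    if (k < 1) next
    expect_equal(edgeCount(thresholdBySparsity(cmi, s)), k)
  }
})

test_that("rank selection keeps the strongest signed correlations", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.9
  r[1, 3] <- r[3, 1] <- 0.5
  r[2, 3] <- r[3, 2] <- 0.1
  g <- thresholdBySparsity(ConnectivityMatrix(r), 2 / 3)
  a <- adjacency(g)
  expect_equal(unname(a[1, 2]), 1)
  expect_equal(unname(a[1, 3]), 1)
  expect_equal(unname(a[2, 3]), 0)

  # absolute mode ranks a strong negative above a weak positive
  r[2, 3] <- r[3, 2] <- -0.95
  ga <- thresholdBySparsity(ConnectivityMatrix(r), 1 / 3, mode = "absolute")
  expect_equal(unname(adjacency(ga)[2, 3]), 1)
  gs <- thresholdBySparsity(ConnectivityMatrix(r), 1 / 3, mode = "signed")
  expect_equal(unname(adjacency(gs)[1, 2]), 1)
})

test_that("tie-breaking at the cut rank is lexicographic and deterministic", {
  r <- diag(5)  # all off-diagonal ties at 0
  g <- thresholdBySparsity(ConnectivityMatrix(r), 0.4)
  # k = 4 edges: lexicographically first pairs (1,2),(1,3),(1,4),(1,5)
  expect_equal(unname(adjacency(g)[1, 2:5]), rep(1, 4))
  expect_equal(edgeCount(g), 4)
  g2 <- thresholdBySparsity(ConnectivityMatrix(r), 0.4)
  expect_identical(adjacency(g), adjacency(g2))
})

test_that("threshold sweep nests edge sets and hits both endpoints", {
  set.seed(8)
  m <- matrix(rnorm(40 * 40), 40, 40)
  cm <- ConnectivityMatrix(tanh((m + t(m)) / 4))
  graphs <- sweepThresholds(cm)
  expect_length(graphs, 11)
  expect_equal(names(graphs)[c(1, 11)], c("0.15", "0.25"))
  aLow <- adjacency(graphs[[1]])
  aHigh <- adjacency(graphs[[11]])
  expect_true(all(aHigh[aLow == 1] == 1))   # monotone nesting
  for (i in 2:11) {
    prev <- adjacency(graphs[[i - 1]])
    cur <- adjacency(graphs[[i]])
    expect_true(all(cur[prev == 1] == 1))
  }
  expect_length(sweepThresholds(cm, 0.15, 0.15), 1)
  expect_error(sweepThresholds(cm, 0.3, 0.1), "exceed")
})

test_that("minimum connected sparsity finds the isolate-free threshold", {
  # a correlation structure whose top edges form a connected graph
  n <- 12
  r <- matrix(0.8, n, n)
  cmDense <- ConnectivityMatrix(r)
  expect_equal(minConnectedSparsity(cmDense, c(0.2, 0.4, 0.6)), 0.2)

  # engineered: node 20's correlations rank below the 15% cut but above
  # the 20% cut, so the first qualifying candidate is 0.20
  n <- 20
  npairs <- n * (n - 1) / 2                      # 190
  k15 <- restnet:::.roundHalfUp(0.15 * npairs)   # 29
  k20 <- restnet:::.roundHalfUp(0.20 * npairs)   # 38
  r <- matrix(0.1, n, n)
  core <- cbind(seq_len(n - 2), 2:(n - 1))       # path over nodes 1..19
  extra <- cbind(rep(1, k15 - nrow(core)), 3:(k15 - nrow(core) + 2))
  for (e in seq_len(nrow(core))) r[core[e, 1], core[e, 2]] <-
      r[core[e, 2], core[e, 1]] <- 0.9
  for (e in seq_len(nrow(extra))) r[extra[e, 1], extra[e, 2]] <-
      r[extra[e, 2], extra[e, 1]] <- 0.85
  hub <- cbind(rep(20, k20 - k15), seq_len(k20 - k15))
  for (e in seq_len(nrow(hub))) r[hub[e, 1], hub[e, 2]] <-
      r[hub[e, 2], hub[e, 1]] <- 0.5
  cm <- ConnectivityMatrix(r)
  g15 <- thresholdBySparsity(cm, 0.15)
  expect_equal(sum(rowSums(adjacency(g15))[20] > 0), 0)  # node 20 isolated
  expect_equal(minConnectedSparsity(cm, c(0.15, 0.20, 0.25)), 0.20)

  # all-tied matrix: deterministic answer under the lexicographic tie rule
  rZero <- diag(5)
  expect_equal(minConnectedSparsity(ConnectivityMatrix(rZero),
                                    c(0.4, 0.7, 1)), 0.4)

  expect_error(minConnectedSparsity(cmDense, numeric(0)), "empty")
  # k = round(0.04 * 780) = 31 < n - 1: some node must stay isolated
  expect_true(is.na(minConnectedSparsity(ConnectivityMatrix(diag(40)),
                                         c(0.04))))
})

test_that("Fisher z is arctanh with its symmetries", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisherZ(-0.5), -fisherZ(0.5))
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisherZ(r), atanh(r))
  expect_true(all(diff(fisherZ(r)) > 0))        # strictly increasing
  expect_equal(tanh(fisherZ(r)), r, tolerance = 1e-12)
  expect_error(fisherZ(1), "\\|r\\| < 1")
  expect_error(fisherZ(c(0.2, -1.2)), "\\|r\\| < 1")
})
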