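# Brute-force normalization oracle: build A + I, its degree matrix, and
# D^{-1/2} (A + I) D^{-1/2} element by element.
normalizeByHand <- function(A) {
  At <- A + diag(nrow(A))
  deg <- rowSums(At)
  out <- matrix(0, nrow(A), ncol(A))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      out[i, j] <- At[i, j] / sqrt(deg[i] * deg[j])
    }
  }
  out
}

test_that("complete-graph normalized adjacency equals J/P for P up to 16", {
  for (p in 1:16) {
    adj <- buildAdjacency(p, "complete")
    expect_equal(adjacencyMatrix(adj), matrix(1 / p, p, p),
                 tolerance = 1e-12)
    expect_equal(adjacencyMatrix(adj), normalizeByHand(adj@a),
                 tolerance = 1e-12)
    expect_equal(rowSums(adjacencyMatrix(adj)), rep(1, p),
                 tolerance = 1e-12)
  }
  expect_error(buildAdjacency(0), "at least 1")
})

test_that("single node and path topologies match hand normalization", {
  expect_equal(adjacencyMatrix(buildAdjacency(1)), matrix(1, 1, 1))
  path3 <- buildAdjacency(3, "path")
  expect_equal(adjacencyMatrix(path3)[1, 2], 1 / sqrt(2 * 3),
               tolerance = 1e-12)
  expect_equal(adjacencyMatrix(path3), normalizeByHand(path3@a),
               tolerance = 1e-12)
  for (top in c("path", "cycle", "star")) {
    adj <- buildAdjacency(7, top)
    expect_equal(adjacencyMatrix(adj), normalizeByHand(adj@a),
                 tolerance = 1e-12)
    ev <- eigen(adjacencyMatrix(adj), symmetric = TRUE, only.values = TRUE)
    expect_lte(max(abs(ev$values)), 1 + 1e-10)
  }
})

test_that("propagation on identical rows through J/P is the ReLU identity", {
  p <- 5L; C <- 4L
  x <- c(2, -1, 0.5, -3)
  G0 <- matrix(rep(x, each = p), p, C)
  params <- list(list(W = diag(C), b = numeric(C)))
  out <- nodeValues(gcnForward(G0, params, buildAdjacency(p)))
  expect_equal(out, matrix(rep(pmax(x, 0), each = p), p, C),
               tolerance = 1e-12)
})

test_that("hand-computed two-node example and ReLU clamping hold", {
  adj <- buildAdjacency(2L)
  expect_equal(adjacencyMatrix(adj), matrix(0.5, 2, 2))
  G0 <- matrix(c(2, 0, 0, 2), 2, 2)
  params <- list(list(W = diag(2), b = numeric(2)))
  expect_equal(nodeValues(gcnForward(G0, params, adj)),
               matrix(1, 2, 2), tolerance = 1e-12)
  paramsNeg <- list(list(W = -diag(2), b = numeric(2)))
  expect_equal(nodeValues(gcnForward(abs(G0), paramsNeg, adj)),
               matrix(0, 2, 2))
})

test_that("forward matches a triple-nested-loop oracle on random 13x8 input", {
  set.seed(23)
  P <- 13L; C <- 8L
  G0 <- matrix(rnorm(P * C), P, C)
  adj <- buildAdjacency(P)
  params <- gcnInit(C, layers = 2L, seed = 5L)
  out <- nodeValues(gcnForward(G0, params, adj))
  # oracle: explicit loops for Ahat %*% G %*% W per layer
  A <- adjacencyMatrix(adj)
  G <- G0
  for (l in 1:2) {
    AG <- matrix(0, P, C)
    for (i in 1:P) for (j in 1:C) {
      for (k in 1:P) AG[i, j] <- AG[i, j] + A[i, k] * G[k, j]
    }
    Z <- matrix(0, P, C)
    for (i in 1:P) for (j in 1:C) {
      for (k in 1:C) Z[i, j] <- Z[i, j] + AG[i, k] * params[[l]]$W[k, j]
      Z[i, j] <- Z[i, j] + params[[l]]$b[j]
    }
    G <- pmax(Z, 0)
  }
  expect_lt(max(abs(out - G)), 1e-6)
})

test_that("propagation is equivariant to node permutation", {
  set.seed(29)
  P <- 7L; C <- 5L
  G0 <- matrix(rnorm(P * C), P, C)
  params <- gcnInit(C, layers = 2L, seed = 2L)
  adj <- buildAdjacency(P, "path")    # non-uniform degrees
  perm <- sample(P)
  Pi <- diag(P)[perm, ]
  permAdj <- methods::new("NormalizedAdjacency",
                          ahat = Pi %*% adjacencyMatrix(adj) %*% t(Pi),
                          a = Pi %*% adj@a %*% t(Pi), topology = "path")
  lhs <- nodeValues(gcnForward(Pi %*% G0, params, permAdj))
  rhs <- Pi %*% nodeValues(gcnForward(G0, params, adj))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("two layers equal the composition of two single layers", {
  set.seed(37)
  G0 <- matrix(rnorm(13 * 6), 13, 6)
  adj <- buildAdjacency(13L)
  params <- gcnInit(6L, layers = 2L, seed = 9L)
  once <- gcnForward(gcnForward(G0, params[1], adj), params[2], adj)
  both <- gcnForward(G0, params, adj)
  expect_equal(nodeValues(once), nodeValues(both), tolerance = 1e-12)
})

test_that("identical input rows give identical output rows on the complete graph", {
  set.seed(41)
  C <- 4L
  G0 <- matrix(rep(rnorm(C), each = 6), 6, C)
  params <- gcnInit(C, layers = 2L, seed = 3L)
  out <- nodeValues(gcnForward(G0, params, buildAdjacency(6L)))
  expect_equal(out, out[rep(1, 6), ], tolerance = 1e-12)
})

test_that("shape and finiteness preconditions are enforced", {
  adj <- buildAdjacency(4L)
  params <- gcnInit(3L, layers = 1L, seed = 1L)
  expect_error(gcnForward(matrix(1, 5, 3), params, adj), "mismatch")
  expect_error(gcnForward(matrix(c(1, NA), 4, 3), params, adj), "finite")
  expect_error(gcnForward(matrix(1, 4, 2), params, adj), "chain")
})
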