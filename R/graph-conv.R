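# Graph convolutional module.  The node graph is complete (every region
# interacts with every other, however far apart), and propagation follows the
# first-order renormalized rule G^(l+1) = ReLU(Ahat G^(l) W^(l) + b^(l)) with
# Ahat = Dtilde^{-1/2} (A + I) Dtilde^{-1/2}.  For a complete graph with
# self-loops Ahat is the constant matrix J/P.

#' Build a symmetrically normalized adjacency
#'
#' Constructs the binary adjacency of the requested topology, adds self-loops
#' and applies the symmetric renormalization
#' \eqn{\hat{A} = \tilde{D}^{-1/2}(A + I)\tilde{D}^{-1/2}}.  The network uses
#' the complete topology; the others exist for testing propagation on graphs
#' with non-uniform degrees.
#'
#' @param p Number of nodes (>= 1).
#' @param topology `"complete"` (default), `"path"`, `"cycle"` or `"star"`.
#' @return A [NormalizedAdjacency-class].
#' @export
buildAdjacency <- function(p, topology = c("complete", "path", "cycle", "star")) {
  topology <- match.arg(topology)
  p <- as.integer(p)
  if (p < 1L) stop("node count must be at least 1")
  A <- matrix(0, p, p)
  if (p > 1L) {
    switch(topology,
      complete = { A[] <- 1; diag(A) <- 0 },
      path = for (i in seq_len(p - 1L)) { A[i, i + 1L] <- 1; A[i + 1L, i] <- 1 },
      cycle = {
        for (i in seq_len(p - 1L)) { A[i, i + 1L] <- 1; A[i + 1L, i] <- 1 }
        if (p > 2L) { A[1L, p] <- 1; A[p, 1L] <- 1 }
      },
      star = { A[1L, -1L] <- 1; A[-1L, 1L] <- 1 }
    )
  }
  At <- A + diag(p)
  dInvSqrt <- 1 / sqrt(rowSums(At))
  ahat <- At * tcrossprod(dInvSqrt)
  new("NormalizedAdjacency", ahat = ahat, a = A, topology = topology)
}

#' Initialize graph-convolution weights
#'
#' Glorot-uniform weight matrices and zero biases for each layer; channel
#' width is kept uniform through the module by default.
#'
#' @param cIn Input channel width C.
#' @param layers Number of layers (default 2).
#' @param cOut Output width of every layer (default `cIn`).
#' @param seed Integer seed.
#' @return List of per-layer `list(W, b)`.
#' @export
gcnInit <- function(cIn, layers = 2L, cOut = cIn, seed = 1L) {
  widths <- c(cIn, rep(cOut, layers))
  withr::with_seed(seed, {
    lapply(seq_len(layers), function(l) {
      ci <- widths[l]; co <- widths[l + 1L]
      list(W = matrix(glorotUniform(ci, co, ci * co), ci, co), b = numeric(co))
    })
  })
}

# Internal forward keeping pre-activations for backprop.
gcnForwardInternal <- function(G, params, ahat) {
  cache <- list(inputs = list(), pre = list())
  for (l in seq_along(params)) {
    cache$inputs[[l]] <- G
    Z <- ahat %*% G %*% params[[l]]$W
    Z <- sweep(Z, 2, params[[l]]$b, "+")
    cache$pre[[l]] <- Z
    G <- pmax(Z, 0)
  }
  list(out = G, cache = cache)
}

gcnBackwardInternal <- function(dOut, params, ahat, cache) {
  grads <- vector("list", length(params))
  dG <- dOut
  for (l in rev(seq_along(params))) {
    dZ <- dG * (cache$pre[[l]] > 0)
    AG <- ahat %*% cache$inputs[[l]]
    grads[[l]] <- list(W = crossprod(AG, dZ), b = colSums(dZ))
    dG <- ahat %*% (dZ %*% t(params[[l]]$W))   # ahat symmetric
  }
  list(grads = grads, dInput = dG)
}

#' Graph-convolution forward pass
#'
#' Applies `G^(l+1) = ReLU(Ahat G^(l) W^(l) + b^(l))` for every layer.
#'
#' @param nodes A [NodeFeatures-class] or a numeric P x C matrix (G^(0)).
#' @param params Per-layer weights from [gcnInit()].
#' @param adj A [NormalizedAdjacency-class] over the same P nodes.
#' @return A [NodeFeatures-class] with the propagated features.
#' @export
gcnForward <- function(nodes, params, adj) {
  G <- if (is(nodes, "NodeFeatures")) nodeValues(nodes) else nodes
  if (!is.matrix(G)) stop("node features must be a matrix")
  if (!all(is.finite(G))) stop("node features must be finite")
  if (nrow(G) != nrow(adj@ahat)) stop("node/adjacency size mismatch")
  for (l in seq_along(params)) {
    if (ncol(G) != nrow(params[[l]]$W))
      stop("weight shape does not chain at layer ", l)
    G <- gcnForwardInternal(G, params[l], adj@ahat)$out
  }
  new("NodeFeatures", values = G)
}
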