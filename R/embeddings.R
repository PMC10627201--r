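#' Embedding configuration
#'
#' Settings for the three neighborhood-based node embedding methods applied
#' to the sample similarity graph.
#'
#' @param dim embedding dimension per method (default 32).
#' @param methods subset of \code{c("socdim", "node2vec", "grarep")}.
#' @param node2vec list of Node2Vec settings: return parameter \code{p},
#'   in-out parameter \code{q}, \code{walk_len}, \code{walks_per_node},
#'   skip-gram \code{window}, \code{epochs}, \code{negative} samples and
#'   initial learning rate \code{alpha}.
#' @param grarep list of GraRep settings: \code{k_max} transition steps and
#'   \code{beta} log shift (default \code{NULL} means 1/m at fit time).
#' @param seed integer seed driving walk generation and skip-gram updates.
#' @return an object of class \code{m5u_embed_config}.
#' @export
embed_config <- function(dim = 32L,
                         methods = c("socdim", "node2vec", "grarep"),
                         node2vec = list(), grarep = list(), seed = 42L) {
  methods <- match.arg(methods, c("socdim", "node2vec", "grarep"),
                       several.ok = TRUE)
  n2v <- utils::modifyList(list(p = 1, q = 1, walk_len = 80L,
                                walks_per_node = 10L, window = 5L,
                                epochs = 5L, negative = 5L, alpha = 0.025),
                           node2vec)
  gr <- utils::modifyList(list(k_max = 3L, beta = NULL), grarep)
  stopifnot(dim >= 1L, n2v$p > 0, n2v$q > 0, gr$k_max >= 1L)
  structure(list(dim = as.integer(dim), methods = methods, node2vec = n2v,
                 grarep = gr, seed = as.integer(seed)),
            class = "m5u_embed_config")
}

m5u_embedding <- function(ids, method, E) {
  E <- as.matrix(E)
  stopifnot(nrow(E) == length(ids), all(is.finite(E)))
  structure(list(ids = as.character(ids), method = method, E = E),
            class = "m5u_embedding")
}

#' @export
print.m5u_embedding <- function(x, ...) {
  cat("m5u_embedding (", x$method, "): ", nrow(x$E), " nodes x ", ncol(x$E),
      " dims\n", sep = "")
  invisible(x)
}

# Fix eigen/SVD sign indeterminacy: largest-magnitude entry positive.
fix_signs <- function(E) {
  for (j in seq_len(ncol(E))) {
    i <- which.max(abs(E[, j]))
    if (length(i) && E[i, j] < 0) E[, j] <- -E[, j]
  }
  E
}

# y = Bx + shift*x with B = A - d d'/(2m), without forming B.
modularity_op <- function(A, d, twom, shift) {
  function(x) as.vector(A %*% x) - d * sum(d * x) / twom + shift * x
}

# Top-nev eigenpairs (algebraic) of the symmetric operator `op` (already
# shifted positive) by Lanczos with full reorthogonalization; exact when
# the Krylov dimension reaches n.
lanczos_top <- function(op, n, nev, krylov = NULL) {
  q <- if (is.null(krylov)) min(n, max(2L * nev + 40L, nev + 2L)) else min(n, krylov)
  V <- matrix(0, n, q)
  alpha <- numeric(q)
  beta <- numeric(q)
  v <- sin(seq_len(n)) + 1.5        # deterministic, generic start
  v <- v / sqrt(sum(v^2))
  V[, 1L] <- v
  for (j in seq_len(q)) {
    w <- op(V[, j])
    alpha[j] <- sum(V[, j] * w)
    w <- w - V[, seq_len(j), drop = FALSE] %*%
      crossprod(V[, seq_len(j), drop = FALSE], w)  # full reorth
    w <- w - V[, seq_len(j), drop = FALSE] %*%
      crossprod(V[, seq_len(j), drop = FALSE], w)
    b <- sqrt(sum(w^2))
    if (j == q) break
    if (b < 1e-10) {                 # invariant subspace: restart direction
      w <- cos(seq_len(n) * (j + 1))
      w <- w - V[, seq_len(j), drop = FALSE] %*%
        crossprod(V[, seq_len(j), drop = FALSE], w)
      b <- sqrt(sum(w^2))
      if (b < 1e-12) { q <- j; break }
      beta[j] <- 0
    } else beta[j] <- b
    V[, j + 1L] <- w / b
  }
  Tq <- diag(alpha[seq_len(q)], q, q)
  if (q > 1L)
    for (j in seq_len(q - 1L)) Tq[j, j + 1L] <- Tq[j + 1L, j] <- beta[j]
  es <- eigen(Tq, symmetric = TRUE)
  idx <- seq_len(nev)
  vec <- V[, seq_len(q), drop = FALSE] %*% es$vectors[, idx, drop = FALSE]
  vec <- sweep(vec, 2L, sqrt(colSums(vec^2)), "/")
  list(values = es$values[idx], vectors = vec)
}

#' SocDim embedding (modularity eigenvectors)
#'
#' Top eigenvectors by algebraic eigenvalue of the modularity matrix
#' \code{B = A - d d' / (2m)} (d the degree vector, 2m the total degree),
#' computed matrix-free through the product \code{Bx}. Columns are
#' unit-norm with the largest-magnitude entry made positive.
#'
#' @param g an \code{m5u_graph}.
#' @param dim number of social dimensions (must be < number of nodes).
#' @return an \code{m5u_embedding}.
#' @export
embed_socdim <- function(g, dim = 32L) {
  m <- length(g$ids)
  if (dim >= m) stop("socdim requires dim < number of nodes")
  if (g$n_edges < 1) stop("graph has no edges")
  d <- g$degree
  twom <- sum(d)
  shift <- 2 * max(d) + 1e-8       # |lambda(B)| <= 2 max degree
  op <- modularity_op(g$A, d, twom, shift)
  res <- lanczos_top(op, m, dim)
  E <- fix_signs(res$vectors)
  m5u_embedding(g$ids, "socdim", E)
}

#' Node2Vec embedding (biased random walks + skip-gram)
#'
#' Generates \code{walks_per_node} second-order random walks of length
#' \code{walk_len} from every node (unnormalized transition weight 1/p to
#' return to the previous node, 1 to a common neighbor of the previous
#' node, 1/q otherwise, times the edge weight) and fits skip-gram with
#' negative sampling on the walk corpus. Fully determined by
#' \code{cfg$seed}.
#'
#' @param g an \code{m5u_graph}; every node should have degree >= 1.
#' @param cfg an \code{\link{embed_config}}.
#' @return an \code{m5u_embedding}.
#' @export
embed_node2vec <- function(g, cfg = embed_config()) {
  m <- length(g$ids)
  if (all(g$degree == 0)) stop("node2vec requires at least one edge")
  nb <- lapply(seq_len(m), function(i) which(g$A[i, ] > 0))
  off <- c(0L, cumsum(lengths(nb)))
  nbr <- unlist(nb, use.names = FALSE)
  if (is.null(nbr)) nbr <- integer(0)
  wt <- g$A[cbind(rep.int(seq_len(m), lengths(nb)), nbr)]
  n2v <- cfg$node2vec
  E <- withr::with_seed(cfg$seed, {
    walks <- cpp_node2vec_walks(as.integer(nbr - 1L), as.numeric(wt),
                                as.integer(off), m, n2v$p, n2v$q,
                                as.integer(n2v$walk_len),
                                as.integer(n2v$walks_per_node))
    cpp_skipgram(walks, m, cfg$dim, as.integer(n2v$window),
                 as.integer(n2v$epochs), as.integer(n2v$negative),
                 n2v$alpha)
  })
  m5u_embedding(g$ids, "node2vec", E)
}

#' Generate biased second-order random walks
#'
#' The walk corpus underlying \code{\link{embed_node2vec}}, exposed for
#' inspection: from the current node, a candidate next node x with previous
#' node t gets unnormalized weight edge_weight * 1/p if x = t, * 1 if x is
#' a neighbor of t, * 1/q otherwise. Uses the current R RNG state.
#'
#' @param g an \code{m5u_graph}.
#' @param p,q return and in-out parameters.
#' @param walk_len walk length.
#' @param walks_per_node walks started per node.
#' @return integer matrix of 1-based node indices, one walk per row
#'   (\code{NA} past the end of a stuck walk).
#' @export
node2vec_walks <- function(g, p = 1, q = 1, walk_len = 80L,
                           walks_per_node = 10L) {
  m <- length(g$ids)
  nb <- lapply(seq_len(m), function(i) which(g$A[i, ] > 0))
  off <- c(0L, cumsum(lengths(nb)))
  nbr <- unlist(nb, use.names = FALSE)
  wt <- g$A[cbind(rep.int(seq_len(m), lengths(nb)), nbr)]
  w <- cpp_node2vec_walks(as.integer(nbr - 1L), as.numeric(wt),
                          as.integer(off), m, p, q, as.integer(walk_len),
                          as.integer(walks_per_node))
  w[w < 0L] <- NA_integer_
  w + 1L
}

#' GraRep embedding (k-step transition SVD)
#'
#' Forms the row-stochastic transition matrix \code{A1 = D^-1 S}, its
#' powers \code{A1^k} for k = 1..k_max, the truncated log-ratio matrices
#' \code{X^k = max(log(A^k_ij / sum_t A^k_tj) - log(beta), 0)}, and
#' concatenates the rank-(dim/k_max) SVD factors \code{U sqrt(Sigma)} of
#' each step into one representation of total width \code{dim} (any
#' remainder of the split goes to k = 1; rank-deficient steps are padded
#' with zero columns).
#'
#' @param g an \code{m5u_graph} with all degrees > 0.
#' @param cfg an \code{\link{embed_config}} (uses \code{dim} and
#'   \code{grarep$k_max}, \code{grarep$beta}).
#' @return an \code{m5u_embedding}.
#' @export
embed_grarep <- function(g, cfg = embed_config()) {
  m <- length(g$ids)
  if (any(g$degree == 0)) stop("grarep requires all node degrees > 0")
  if (cfg$dim >= m) stop("grarep requires dim < number of nodes")
  k_max <- cfg$grarep$k_max
  beta <- if (is.null(cfg$grarep$beta)) 1 / m else cfg$grarep$beta
  r <- cfg$dim %/% k_max
  widths <- rep(r, k_max)
  widths[1L] <- cfg$dim - r * (k_max - 1L)
  A1 <- g$A / g$degree
  Ak <- diag(m)
  parts <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    Ak <- Ak %*% A1
    colsum <- colSums(Ak)
    X <- matrix(0, m, m)
    pos <- Ak > 0 & colsum[col(Ak)] > 0
    X[pos] <- log(Ak[pos] / colsum[col(Ak)[pos]]) - log(beta)
    X[X < 0] <- 0
    rk <- widths[k]
    sv <- svd(X, nu = rk, nv = 0L)
    W <- sv$u %*% diag(sqrt(pmax(sv$d[seq_len(rk)], 0)), rk, rk)
    W[, sv$d[seq_len(rk)] < 1e-12] <- 0   # rank-deficient: zero pad
    parts[[k]] <- fix_signs(W)
  }
  m5u_embedding(g$ids, "grarep", do.call(cbind, parts))
}

#' Run all configured embedding methods and fuse the results
#'
#' @param g an \code{m5u_graph}.
#' @param cfg an \code{\link{embed_config}}.
#' @return an \code{m5u_features} with one block per method.
#' @export
embed_all <- function(g, cfg = embed_config()) {
  stopifnot(length(cfg$methods) >= 1L)
  embs <- lapply(cfg$methods, function(mth) {
    e <- switch(mth,
                socdim = embed_socdim(g, cfg$dim),
                node2vec = embed_node2vec(g, cfg),
                grarep = embed_grarep(g, cfg))
    m5u_features(e$ids, e$E, data.frame(name = mth, n_cols = ncol(e$E)))
  })
  fuse_features(embs)
}

#' Project new samples onto a trained embedding
#'
#' Inductive extension: for each new sample, non-negative reconstruction
#' weights over its nearest training samples are fitted with the same
#' multiplicative update as the similarity network (restricted to one row),
#' and the sample's embedding is the weight-average of the training
#' embeddings.
#'
#' @param E_train matrix of training-node embeddings (rows align with
#'   \code{X_train}).
#' @param X_new,X_train standardized feature matrices (same columns; apply
#'   training-fold standardization to both).
#' @param flnsa_cfg an \code{\link{flnsa_config}} (uses K, mu, max_iter, tol).
#' @param ids optional ids for the new samples.
#' @return matrix \code{nrow(X_new) x ncol(E_train)}.
#' @export
project_new_nodes <- function(E_train, X_new, X_train,
                              flnsa_cfg = flnsa_config(), ids = NULL) {
  X_new <- as.matrix(X_new)
  X_train <- as.matrix(X_train)
  m <- nrow(X_train)
  k <- max(1L, min(m, floor(flnsa_cfg$K * m)))
  mu <- flnsa_cfg$mu
  out <- matrix(0, nrow(X_new), ncol(E_train))
  for (i in seq_len(nrow(X_new))) {
    x <- X_new[i, ]
    d2 <- colSums((t(X_train) - x)^2)
    nbrs <- order(d2, seq_len(m))[seq_len(k)]
    Xn <- X_train[nbrs, , drop = FALSE]
    gvec <- as.vector(Xn %*% x)
    H <- tcrossprod(Xn)
    c0 <- max(0, -min(gvec), -min(H))   # constant-feature shift (see fit_weights)
    w <- rep(1 / k, k)
    for (it in seq_len(flnsa_cfg$max_iter)) {
      den <- pmax(as.vector(H %*% w) + c0 * sum(w) + mu * sum(w), 1e-12)
      w_new <- w * (gvec + c0 + mu) / den
      delta <- max(abs(w_new - w) / pmax(abs(w), 1e-12))
      w <- w_new
      if (delta < flnsa_cfg$tol) break
    }
    w <- solve_simplex_row(w, H, gvec)  # exact constrained finish
    s <- sum(w)
    if (!is.finite(s) || s <= 0)
      stop("projection failed (all-zero weights) for sample ",
           if (is.null(ids)) i else ids[i])
    out[i, ] <- as.vector(crossprod(E_train[nbrs, , drop = FALSE], w / s))
  }
  rownames(out) <- ids
  out
}
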