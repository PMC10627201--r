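#' FLNSA configuration
#'
#' Settings for the fast linear neighborhood similarity approach, which
#' learns non-negative neighbor reconstruction weights W minimizing
#' \deqn{\frac12\|X - (C \odot W)X\|_F^2 + \frac{\mu}{2}\|(C \odot W)e - e\|^2}
#' subject to W >= 0, with each sample reconstructed from its K-nearest
#' neighbors and row weights summing to one.
#'
#' @param K neighborhood ratio in (0, 1]: each sample uses its
#'   \code{floor(K * (m - 1))} nearest neighbors (Euclidean distance).
#' @param mu tradeoff parameter on the row-sum constraint (default 3).
#' @param max_iter maximum multiplicative-update iterations.
#' @param tol convergence tolerance on the maximum relative weight change.
#' @param adjacency_mode \code{"binarized"} (default; any weight above
#'   \code{binarize_threshold} becomes an unweighted edge) or
#'   \code{"weighted"} (symmetrized weights).
#' @param binarize_threshold weight threshold for binarized mode.
#' @return an object of class \code{m5u_flnsa_config}.
#' @export
flnsa_config <- function(K = 0.3, mu = 3, max_iter = 500L, tol = 1e-6,
                         adjacency_mode = c("binarized", "weighted"),
                         binarize_threshold = 0) {
  stopifnot(K > 0, K <= 1, mu > 0, max_iter >= 1L, tol > 0,
            binarize_threshold >= 0)
  structure(list(K = K, mu = mu, max_iter = as.integer(max_iter), tol = tol,
                 adjacency_mode = match.arg(adjacency_mode),
                 binarize_threshold = binarize_threshold),
            class = "m5u_flnsa_config")
}

#' Select K-nearest neighbors
#'
#' Returns the 0/1 indicator matrix C with \code{C[i, j] = 1} for the
#' \code{floor(K * (m - 1))} nearest neighbors of sample i by Euclidean
#' distance (ties broken toward the lower index), zero diagonal.
#'
#' @param X m x n feature matrix (standardize columns first so distances
#'   are commensurate).
#' @param K neighborhood ratio in (0, 1].
#' @return m x m 0/1 matrix.
#' @export
select_neighbors <- function(X, K = 0.3) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (m < 2L) stop("need at least 2 samples")
  k <- floor(K * (m - 1L))
  if (k < 1L) stop("K = ", K, " gives zero neighbors for m = ", m)
  D <- as.matrix(stats::dist(X))
  C <- matrix(0L, m, m)
  for (i in seq_len(m)) {
    ord <- order(D[i, ], seq_len(m))        # ties -> lower index
    ord <- ord[ord != i]
    C[i, ord[seq_len(k)]] <- 1L
  }
  C
}

#' Fit FLNSA reconstruction weights
#'
#' Runs the multiplicative update
#' \code{W <- W * (XX' + mu) / ((C*W) XX' + mu (C*W) ee')} on neighbor
#' entries only, from a uniform initialization over each row's neighbors,
#' until the maximum relative change falls below \code{tol} or
#' \code{max_iter} is reached. Two numerical refinements keep the update
#' well-defined and the constraint exact: (i) the Gram matrix is shifted by
#' a constant \code{c0 = max(0, -min(XX'))} — equivalent to appending a
#' constant feature column, which changes the objective only through the
#' row-sum penalty and so leaves the constrained solution unchanged, while
#' keeping the update's numerator/denominator nonnegative for standardized
#' features; (ii) after the multiplicative phase each row is finished on
#' its converged support with an exact equality-constrained active-set
#' solve, so \code{(C*W)e = e} holds exactly and the weights are the
#' constrained optimum.
#'
#' @param X m x n feature matrix.
#' @param C neighbor indicator from \code{\link{select_neighbors}}.
#' @param cfg an \code{\link{flnsa_config}}.
#' @param trace if \code{TRUE}, attach the per-iteration objective values
#'   (reconstruction + row-sum penalty) as attribute \code{"objective"}.
#' @return m x m non-negative weight matrix with rows summing to one over
#'   each sample's neighbors.
#' @export
fit_weights <- function(X, C, cfg = flnsa_config(), trace = FALSE) {
  X <- as.matrix(X)
  m <- nrow(X)
  stopifnot(all(dim(C) == m), all(diag(C) == 0))
  nn <- rowSums(C)
  if (any(nn == 0)) stop("every sample needs at least one neighbor")
  G0 <- tcrossprod(X)                       # XX'
  c0 <- max(0, -min(G0))                    # constant-feature shift
  G <- G0 + c0
  mu <- cfg$mu
  num <- G + mu                             # XX' + c0 + mu ee'
  W <- C / nn                               # uniform over neighbors
  obj <- if (trace) numeric(0) else NULL
  for (it in seq_len(cfg$max_iter)) {
    M <- C * W
    if (trace) obj <- c(obj, flnsa_objective(X, M, mu + c0))
    den <- M %*% G + mu * rowSums(M)        # (C*W)XX' + mu (C*W)ee'
    den <- pmax(den, 1e-12)
    W_new <- C * (W * num / den)
    if (!all(is.finite(W_new)))
      stop("non-finite weights at iteration ", it)
    delta <- max(abs(W_new - W) / pmax(abs(W), 1e-12))
    W <- W_new
    if (delta < cfg$tol) break
  }
  W <- W / rowSums(W)
  for (i in seq_len(m)) {                   # exact constrained finish
    nb <- which(C[i, ] == 1L)
    Xn <- X[nb, , drop = FALSE]
    W[i, nb] <- solve_simplex_row(W[i, nb], tcrossprod(Xn),
                                  as.vector(Xn %*% X[i, ]))
    W[i, -nb] <- 0
  }
  if (trace) attr(W, "objective") <- obj
  W
}

flnsa_objective <- function(X, M, penalty) {
  0.5 * sum((X - M %*% X)^2) + 0.5 * penalty * sum((rowSums(M) - 1)^2)
}

# Exact minimizer of 0.5 w'Hw - w'g subject to sum(w) = 1, w >= 0, by
# active-set iteration warm-started from the multiplicative solution.
solve_simplex_row <- function(w, H, g, max_pass = 200L) {
  k <- length(w)
  S <- which(w > 1e-10)
  if (!length(S)) S <- seq_len(k)
  for (pass in seq_len(max_pass)) {
    ks <- length(S)
    Hs <- H[S, S, drop = FALSE]
    ridge <- 1e-10 * (mean(diag(Hs)) + 1)
    A <- rbind(cbind(Hs + diag(ridge, ks), 1), c(rep(1, ks), 0))
    sol <- tryCatch(solve(A, c(g[S], 1)), error = function(e) NULL)
    if (is.null(sol)) break
    ws <- sol[seq_len(ks)]
    lam <- sol[ks + 1L]
    if (any(ws < -1e-12)) {                 # drop the most negative weight
      S <- S[-which.min(ws)]
      if (!length(S)) break
      next
    }
    wfull <- numeric(k)
    wfull[S] <- pmax(ws, 0)
    grad <- as.vector(H %*% wfull) - g
    out <- setdiff(seq_len(k), S)
    viol <- out[grad[out] < -lam - 1e-10]   # KKT: inactive gradient >= -lam
    if (!length(viol)) return(wfull / sum(wfull))
    S <- sort(c(S, viol[which.min(grad[viol])]))
  }
  w <- pmax(w, 0)                           # fallback: renormalize as-is
  w / sum(w)
}

#' Build the similarity graph from FLNSA weights
#'
#' Symmetrizes the learned weight matrix into the adjacency used by the
#' embedding methods: in binarized mode (default) an undirected unweighted
#' edge joins i and j when \code{max(W[i,j], W[j,i])} exceeds the
#' threshold; in weighted mode \code{A = (W + W') / 2}.
#'
#' @param W weight matrix from \code{\link{fit_weights}}.
#' @param cfg an \code{\link{flnsa_config}}.
#' @param ids optional node ids (default \code{1..m} as character).
#' @return an object of class \code{m5u_graph} with fields \code{ids},
#'   \code{W}, \code{A}, \code{degree}, \code{n_edges}, \code{mode}.
#' @export
build_graph <- function(W, cfg = flnsa_config(), ids = NULL) {
  W <- as.matrix(W)
  m <- nrow(W)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  if (cfg$adjacency_mode == "binarized") {
    A <- (pmax(W, t(W)) > cfg$binarize_threshold) * 1
  } else {
    A <- (W + t(W)) / 2
  }
  diag(A) <- 0
  deg <- rowSums(A)
  n_edges <- sum(A > 0) / 2
  if (n_edges == 0) stop("similarity graph has no edges")
  if (any(deg == 0))
    warning(sum(deg == 0), " isolated node(s) in the similarity graph")
  structure(list(ids = as.character(ids), W = W, A = A, degree = deg,
                 n_edges = n_edges, mode = cfg$adjacency_mode),
            class = "m5u_graph")
}

#' @export
print.m5u_graph <- function(x, ...) {
  cat("m5u_graph: ", length(x$ids), " nodes, ", x$n_edges, " edges (",
      x$mode, " adjacency)\n", sep = "")
  invisible(x)
}

#' Write a graph's edge list as TSV
#'
#' @param g an \code{m5u_graph}.
#' @param path output path; columns \code{u}, \code{v}, \code{weight}
#'   (upper triangle only).
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(g, path) {
  idx <- which(upper.tri(g$A) & g$A > 0, arr.ind = TRUE)
  df <- data.frame(u = g$ids[idx[, 1L]], v = g$ids[idx[, 2L]],
                   weight = sprintf("%.12g", g$A[idx]))
  write.table(df[order(idx[, 1L], idx[, 2L]), ], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
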