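test_that("the modularity operator annihilates the all-ones vector", {
  withr::with_seed(2, {
    A <- random_graph_adj(12)
    B <- dense_modularity(A)
    expect_lt(max(abs(B %*% rep(1, 12))), 1e-10)
  })
})

test_that("SocDim matches a dense eigendecomposition oracle", {
  withr::with_seed(5, {
    for (m in c(12, 20)) {
      A <- random_graph_adj(m)
      g <- graph_from_adj(A)
      E <- embed_socdim(g, dim = 4L)$E
      B <- dense_modularity(A)
      es <- eigen(B, symmetric = TRUE)
      for (j in 1:4) {
        lam <- sum(E[, j] * (B %*% E[, j]))
        expect_equal(lam, es$values[j], tolerance = 1e-8)
        # eigenpair residual is robust to (near-)degenerate eigenvalues
        expect_lt(max(abs(B %*% E[, j] - lam * E[, j])), 1e-8)
      }
      # orthonormal columns
      expect_equal(crossprod(E), diag(4), tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
  })
})

test_that("two disjoint triangles split along the leading social dimension", {
  A <- matrix(0, 6, 6)
  for (e in list(c(1,2), c(2,3), c(1,3), c(4,5), c(5,6), c(4,6)))
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  E <- embed_socdim(graph_from_adj(A), dim = 2L)$E
  v <- E[, 1]
  expect_true(all(sign(v[1:3]) == sign(v[1])))
  expect_true(all(sign(v[4:6]) == sign(v[4])))
  expect_true(sign(v[1]) != sign(v[4]))
})

test_that("the top social dimensions carry at least random-subspace modularity", {
  withr::with_seed(6, {
    A <- random_graph_adj(15)
    B <- dense_modularity(A)
    E <- embed_socdim(graph_from_adj(A), dim = 3L)$E
    q_top <- sum(diag(crossprod(E, B %*% E)))
    for (i in 1:100) {
      S <- qr.Q(qr(matrix(rnorm(15 * 3), 15, 3)))
      expect_lte(sum(diag(crossprod(S, B %*% S))), q_top + 1e-8)
    }
  })
})

test_that("node relabeling permutes embedding rows", {
  withr::with_seed(8, {
    A <- random_graph_adj(10)
    p <- sample(10)
    E1 <- embed_socdim(graph_from_adj(A), dim = 3L)$E
    E2 <- embed_socdim(graph_from_adj(A[p, p]), dim = 3L)$E
    # eigenvalues of the permuted graph are identical; columns may flip sign
    for (j in 1:3)
      expect_equal(abs(E2[, j]), abs(E1[p, j]), tolerance = 1e-6)
  })
})

test_that("node2vec walk transitions follow the p/q bias rule", {
  # 4-cycle, p = q = 1: first-order walk, uniform over the two neighbors
  A <- matrix(0, 4, 4)
  for (e in list(c(1,2), c(2,3), c(3,4), c(4,1)))
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  g <- graph_from_adj(A)
  withr::with_seed(10, {
    walks <- node2vec_walks(g, p = 1, q = 1, walk_len = 100L,
                            walks_per_node = 250L)
    # at node 1 (having come from anywhere) next is 2 or 4 with prob 1/2
    from1 <- which(walks[, -ncol(walks)] == 1, arr.ind = TRUE)
    nxt <- walks[cbind(from1[, 1], from1[, 2] + 1)]
    n <- length(nxt)
    phat <- mean(nxt == 2)
    expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / n))

    # path 1-2-3 with p = 0.25, q = 4: from 2 having come from 1,
    # P(return to 1) = (1/p) / (1/p + 1/q) = 16/17
    P <- matrix(0, 3, 3)
    P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- 1
    gp <- graph_from_adj(P)
    w <- node2vec_walks(gp, p = 0.25, q = 4, walk_len = 60L,
                        walks_per_node = 300L)
    ret <- 0L; tot <- 0L
    for (r in seq_len(nrow(w))) for (c in seq_len(ncol(w) - 2L)) {
      if (w[r, c] == 1 && w[r, c + 1] == 2) {
        tot <- tot + 1L
        if (w[r, c + 2] == 1) ret <- ret + 1L
      }
    }
    p0 <- 16 / 17
    expect_lt(abs(ret / tot - p0), 3 * sqrt(p0 * (1 - p0) / tot))
  })
})

test_that("node2vec is deterministic under its seed", {
  withr::with_seed(4, {
    A <- random_graph_adj(15)
    g <- graph_from_adj(A)
    cfg <- embed_config(dim = 8L, seed = 99L,
                        node2vec = list(walk_len = 20L, walks_per_node = 4L,
                                        epochs = 2L))
    E1 <- embed_node2vec(g, cfg)$E
    E2 <- embed_node2vec(g, cfg)$E
    expect_identical(E1, E2)
    cfg2 <- cfg; cfg2$seed <- 100L
    expect_false(identical(embed_node2vec(g, cfg2)$E, E1))
  })
})

test_that("GraRep reproduces the printed log-ratio formula", {
  # 2-node single-edge graph
  A <- rbind(c(0, 1), c(1, 0))
  A1 <- A / rowSums(A)
  expect_equal(rowSums(A1), c(1, 1), tolerance = 1e-12)
  expect_equal(A1 %*% A1, diag(2), ignore_attr = TRUE)

  # beta = 1/2, k = 1: off-diagonal Y = log(1/1) - log(1/2) = log 2,
  # diagonal truncated to 0; X = [[0, log2], [log2, 0]] has singular
  # values log2, log2, so U sqrt(S) reconstructs X exactly at rank 2.
  g <- graph_from_adj(A)
  cfg <- embed_config(dim = 1L, grarep = list(k_max = 1L, beta = 1/2))
  # dim must be < nodes; use the internal matrix directly via a 3-node path
  # for the rank check, and verify the 2-node entries through k_max = 1
  E <- embed_grarep(g, embed_config(dim = 1L,
                                    grarep = list(k_max = 1L, beta = 1/2)))$E
  X <- rbind(c(0, log(2)), c(log(2), 0))
  sv <- svd(X)
  Wk <- sv$u[, 1, drop = FALSE] * sqrt(sv$d[1])
  expect_equal(abs(E[, 1]), abs(Wk[, 1]), tolerance = 1e-10)
})

test_that("GraRep truncated SVD is rank-optimal and row-stochastic inside", {
  withr::with_seed(12, {
    A <- random_graph_adj(14)
    g <- graph_from_adj(A)
    cfg <- embed_config(dim = 6L, grarep = list(k_max = 2L))
    E <- embed_grarep(g, cfg)$E
    expect_equal(ncol(E), 6L)
    expect_true(all(is.finite(E)))
    # reconstruct step k = 1 and check SVD optimality against dense oracle
    A1 <- A / rowSums(A)
    beta <- 1 / 14
    X <- log(pmax(A1, 1e-300)) - log(rep(colSums(A1), each = 14)) - log(beta)
    X[A1 == 0] <- 0
    X[X < 0] <- 0
    sv <- svd(X)
    r <- 3L                      # k = 1 block width at dim 6, k_max 2
    W1 <- E[, 1:r]
    # our factor is U sqrt(Sigma) of the dense SVD: column energies are the
    # singular values and columns align with the dense singular vectors
    expect_equal(unname(colSums(W1^2)), sv$d[seq_len(r)], tolerance = 1e-8)
    for (j in seq_len(r))
      expect_gt(abs(sum(W1[, j] * sv$u[, j])) / sqrt(sum(W1[, j]^2)),
                1 - 1e-6)
  })
})

test_that("embedding fusion has additive width and fixed-seed determinism", {
  withr::with_seed(14, {
    A <- random_graph_adj(18)
    g <- graph_from_adj(A)
    cfg <- embed_config(dim = 4L, seed = 3L,
                        node2vec = list(walk_len = 15L, walks_per_node = 3L,
                                        epochs = 2L),
                        grarep = list(k_max = 2L))
    f <- embed_all(g, cfg)
    expect_equal(ncol(f$X), 12L)
    expect_equal(f$blocks$name, c("socdim", "node2vec", "grarep"))
    f_soc <- embed_all(g, embed_config(dim = 4L, methods = "socdim"))
    expect_equal(f_soc$X[, 1:4], embed_socdim(g, 4L)$E, ignore_attr = TRUE)
    # byte-identical artifact on re-run
    p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
    write_feature_matrix(f, p1)
    write_feature_matrix(embed_all(g, cfg), p2)
    expect_identical(readLines(p1), readLines(p2))
  })
})

test_that("new nodes project consistently onto the trained embedding", {
  withr::with_seed(21, {
    Xtr <- scale(matrix(rnorm(20 * 6), 20, 6))
    Etr <- matrix(rnorm(20 * 4), 20, 4)
    cfg <- flnsa_config(K = 0.1)   # 2 neighbors
    # identical to training sample 5 -> its embedding exactly
    E <- project_new_nodes(Etr, Xtr[5, , drop = FALSE], Xtr, cfg)
    expect_equal(as.vector(E), Etr[5, ], tolerance = 1e-8)
    # midway between two identical-feature training points -> their average
    Xd <- rbind(Xtr, Xtr[5, ])
    Ed <- rbind(Etr, Etr[5, ] + 1)
    E2 <- project_new_nodes(Ed, Xd[5, , drop = FALSE], Xd, cfg)
    expect_equal(as.vector(E2), (Ed[5, ] + Ed[21, ]) / 2, tolerance = 1e-5)
  })
})

test_that("training points project close to their transductive embeddings", {
  ds <- generate_windows(synth_config(n_pos = 40L, n_neg = 40L, seed = 17L))
  prof <- fit_profiles(ds)
  fm <- encode_dataset(ds, profile = prof)
  Xs <- scale(fm$X)
  Xs[, apply(fm$X, 2, sd) < 1e-12] <- 0
  cfg <- flnsa_config()
  C <- select_neighbors(Xs, cfg$K)
  W <- fit_weights(Xs, C, cfg)
  g <- build_graph(W, cfg, ids = ds$id)
  E <- embed_socdim(g, dim = 8L)$E
  Ep <- project_new_nodes(E, Xs, Xs, cfg)
  cosines <- vapply(seq_len(nrow(E)), function(i)
    sum(E[i, ] * Ep[i, ]) / sqrt(sum(E[i, ]^2) * sum(Ep[i, ]^2)), numeric(1))
  expect_gt(mean(cosines), 0.9)
})
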