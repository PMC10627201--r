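# Shared fixtures and independent oracles used across the test files.

# Unvalidated dataset constructor for tiny toy windows (L may be even,
# centre need not be U) used to exercise the maths of profile-based
# encoders in isolation of window validation.
toy_dataset <- function(seqs, labels, L = nchar(seqs[1L])) {
  structure(list(id = paste0("t", seq_along(seqs)), seq = seqs,
                 label = labels, groups = NULL, L = as.integer(L)),
            class = "m5u_dataset")
}

random_window <- function(L = 41L) {
  nts <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
  nts[(L + 1L) %/% 2L] <- "U"
  paste(nts, collapse = "")
}

random_dataset <- function(n_pos, n_neg, L = 41L) {
  n <- n_pos + n_neg
  m5u_dataset(sprintf("r%03d", seq_len(n)),
              vapply(seq_len(n), function(i) random_window(L), character(1L)),
              rep(c("positive", "negative"), c(n_pos, n_neg)), L = L)
}

# Euclidean projection onto the probability simplex.
proj_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  pmax(v - (css[rho] - 1) / rho, 0)
}

# Independent oracle for one FLNSA row: projected-gradient descent on
# min 0.5 || x - w' Xn ||^2 over the simplex.
pg_simplex_row <- function(x, Xn, iters = 15000L) {
  H <- tcrossprod(Xn)
  g <- as.vector(Xn %*% x)
  lr <- 1 / (max(eigen(H, symmetric = TRUE, only.values = TRUE)$values) + 1e-9)
  w <- rep(1 / nrow(Xn), nrow(Xn))
  for (i in seq_len(iters)) w <- proj_simplex(w - lr * (as.vector(H %*% w) - g))
  w
}

# Dense modularity matrix for the eigen oracle.
dense_modularity <- function(A) {
  d <- rowSums(A)
  A - outer(d, d) / sum(d)
}

# A deterministic random binary symmetric graph adjacency.
random_graph_adj <- function(m, p = 0.3) {
  A <- matrix(0, m, m)
  A[upper.tri(A)] <- rbinom(m * (m - 1) / 2, 1L, p)
  A <- A + t(A)
  # ensure no isolated nodes
  for (i in which(rowSums(A) == 0)) {
    j <- if (i == 1L) 2L else 1L
    A[i, j] <- A[j, i] <- 1
  }
  A
}

graph_from_adj <- function(A, mode = "binarized") {
  structure(list(ids = as.character(seq_len(nrow(A))), W = A, A = A,
                 degree = rowSums(A), n_edges = sum(A > 0) / 2, mode = mode),
            class = "m5u_graph")
}

# Brute-force confusion/metric computation used as the evaluate() oracle.
brute_metrics <- function(y, scores, cutoff) {
  pred <- ifelse(scores > cutoff, 1L, 0L)
  TP <- 0L; TN <- 0L; FP <- 0L; FN <- 0L
  for (i in seq_along(y)) {
    if (y[i] == 1L && pred[i] == 1L) TP <- TP + 1L
    if (y[i] == 0L && pred[i] == 0L) TN <- TN + 1L
    if (y[i] == 0L && pred[i] == 1L) FP <- FP + 1L
    if (y[i] == 1L && pred[i] == 0L) FN <- FN + 1L
  }
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  # AUROC by exhaustive pair counting (ties count half)
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  auc <- if (!length(pos) || !length(neg)) NA_real_ else {
    s <- 0
    for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       Sn = 100 * TP / (TP + FN), Sp = 100 * TN / (TN + FP),
       ACC = 100 * (TP + TN) / length(y),
       MCC = if (den == 0) 0 else (TP * TN - FP * FN) / den,
       AUROC = auc)
}
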