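#' Encoder configuration
#'
#' Hyperparameters for the seven sequence-derived feature encoders.
#'
#' @param d_max maximum spacing for the nucleotide pair spectrum (NPS);
#'   features count ordered pairs separated by 0..\code{d_max} arbitrary
#'   bases. Default 2 (48 features).
#' @param k tuple size for pseudo k-tuple nucleotide composition (PseKNC).
#' @param lam number of sequence-order correlation factors (lambda) in
#'   PseKNC; must satisfy \code{lam < L - 1}.
#' @param w PseKNC weight on the correlation factors, in (0, 1].
#' @param xi_set integer spacings for the position-specific nucleotide pair
#'   propensity (NPPS) features; default \code{1} (adjacent pairs).
#' @param pseudocount additive smoothing for the Bi-profile Bayes and NPPS
#'   frequency tables.
#' @param prop_table 16 x 6 numeric matrix of dinucleotide structural
#'   properties (Shift, Slide, Rise, Tilt, Roll, Twist), rows named by
#'   dinucleotide. Z-standardized over the 16 dinucleotides before use.
#'   Defaults to published RNA duplex step parameters.
#' @return an object of class \code{m5u_encoder_config}.
#' @export
encoder_config <- function(d_max = 2L, k = 2L, lam = 2L, w = 0.1,
                           xi_set = 1L, pseudocount = 1.0,
                           prop_table = rna_dinucleotide_properties()) {
  stopifnot(d_max >= 0L, k >= 1L, lam >= 0L, w > 0, w <= 1,
            all(xi_set >= 1L), pseudocount >= 0)
  prop_table <- as.matrix(prop_table)
  dinucs <- as.vector(outer(M5U_ALPHABET, M5U_ALPHABET, paste0))
  if (!all(dinucs %in% rownames(prop_table)))
    stop("prop_table must have all 16 dinucleotide rows")
  prop_table <- prop_table[dinucs, , drop = FALSE]
  prop_table <- scale(prop_table)            # z over the 16 dinucleotides
  attr(prop_table, "scaled:center") <- attr(prop_table, "scaled:scale") <- NULL
  structure(list(d_max = as.integer(d_max), k = as.integer(k),
                 lam = as.integer(lam), w = w,
                 xi_set = sort(unique(as.integer(xi_set))),
                 pseudocount = pseudocount, prop_table = prop_table),
            class = "m5u_encoder_config")
}

#' Default RNA dinucleotide structural property table
#'
#' Published RNA duplex step parameters (Shift, Slide, Rise in Angstrom;
#' Tilt, Roll, Twist in degrees) for the 16 dinucleotides, used by the
#' PseKNC sequence-order correlation term.
#'
#' @return a 16 x 6 numeric matrix with dinucleotide row names.
#' @export
rna_dinucleotide_properties <- function() {
  v <- rbind(
    AA = c(-0.08, -1.27, 3.18, -0.8,  7.0, 31),
    AC = c( 0.23, -1.43, 3.24,  0.8,  4.8, 32),
    AG = c(-0.04, -1.50, 3.30,  0.5,  8.5, 30),
    AU = c(-0.06, -1.36, 3.24,  1.1,  7.1, 33),
    CA = c( 0.11, -1.46, 3.09,  1.0,  9.9, 31),
    CC = c(-0.01, -1.78, 3.32,  0.3,  8.7, 32),
    CG = c( 0.30, -1.89, 3.30, -0.1, 12.1, 27),
    CU = c(-0.04, -1.50, 3.30,  0.5,  8.5, 30),
    GA = c( 0.07, -1.70, 3.38,  1.3,  9.4, 32),
    GC = c( 0.07, -1.39, 3.22,  0.0,  6.1, 35),
    GG = c(-0.01, -1.78, 3.32,  0.3, 12.1, 32),
    GU = c( 0.23, -1.43, 3.24,  0.8,  4.8, 32),
    UA = c(-0.02, -1.45, 3.26, -0.2, 10.7, 32),
    UC = c( 0.07, -1.70, 3.38,  1.3,  9.4, 32),
    UG = c( 0.11, -1.46, 3.09,  1.0,  9.9, 31),
    UU = c(-0.08, -1.27, 3.18, -0.8,  7.0, 31))
  colnames(v) <- c("Shift", "Slide", "Rise", "Tilt", "Roll", "Twist")
  v
}

seq_to_int <- function(seq) {
  x <- match(strsplit(seq, "", fixed = TRUE)[[1L]], M5U_ALPHABET)
  if (anyNA(x)) stop("sequence contains characters outside A,C,G,U")
  x
}

#' Electron-ion interaction pseudopotential encoding
#'
#' Maps each nucleotide to its EIIP value: A 0.1260, C 0.1340, G 0.0806,
#' U 0.1335.
#'
#' @param seq an RNA string over A,C,G,U.
#' @return numeric vector of length \code{nchar(seq)}.
#' @export
encode_eiip <- function(seq) {
  eiip <- c(0.1260, 0.1340, 0.0806, 0.1335)  # A C G U
  eiip[seq_to_int(seq)]
}

#' Nucleotide pair spectrum (k-spaced pair composition)
#'
#' For each spacing d in 0..\code{d_max} and each ordered pair (a, b),
#' counts positions i with \code{seq[i] == a} and \code{seq[i+d+1] == b},
#' normalized by the number of such positions, L - d - 1. Blocks are
#' ordered by spacing, pairs lexicographically (AA, AC, ..., UU).
#'
#' @param seq RNA string.
#' @param d_max maximum spacing (default 2; 16 * (d_max + 1) features).
#' @return numeric vector of length \code{16 * (d_max + 1)}.
#' @export
encode_nps <- function(seq, d_max = 2L) {
  x <- seq_to_int(seq)
  L <- length(x)
  if (d_max >= L - 1L) stop("d_max must be < L - 1")
  out <- numeric(0)
  for (d in 0:d_max) {
    i <- seq_len(L - d - 1L)
    pair <- (x[i] - 1L) * 4L + x[i + d + 1L]
    out <- c(out, tabulate(pair, 16L) / (L - d - 1L))
  }
  out
}

#' Composition / transition / distribution (CTD) descriptors
#'
#' Composition: the 4 mononucleotide fractions. Transition: the 16 ordered
#' adjacent-dinucleotide fractions over the L - 1 neighbouring pairs.
#' Distribution: for each nucleotide, the relative sequence position
#' (1-based index / L) of its first occurrence and of the occurrences at
#' 25\%, 50\%, 75\% and 100\% of its total count; all five are 0 when the
#' nucleotide is absent.
#'
#' @param seq RNA string.
#' @return numeric vector of length 40 (4 + 16 + 20).
#' @export
encode_ctd <- function(seq) {
  x <- seq_to_int(seq)
  L <- length(x)
  comp <- tabulate(x, 4L) / L
  pair <- (x[-L] - 1L) * 4L + x[-1L]
  trans <- tabulate(pair, 16L) / (L - 1L)
  distr <- unlist(lapply(1:4, function(nt) {
    pos <- which(x == nt)
    if (!length(pos)) return(numeric(5L))
    cnt <- length(pos)
    idx <- c(1L, ceiling(c(0.25, 0.5, 0.75, 1) * cnt))
    pos[idx] / L
  }))
  c(comp, trans, distr)
}

#' Fit position profiles from a labeled training set
#'
#' Estimates, separately on positive and negative windows, per-position
#' nucleotide probabilities (for the Bi-profile Bayes encoder) and, for each
#' spacing xi, per-position ordered-pair and single-nucleotide counts (for
#' the NPPS encoder). Additive pseudocount smoothing is applied to the
#' probability tables; the pair/single tables keep raw counts and are
#' smoothed at encoding time.
#'
#' @param train an \code{m5u_dataset} with at least one positive and one
#'   negative window.
#' @param cfg an \code{\link{encoder_config}}.
#' @return an object of class \code{m5u_profile}.
#' @export
fit_profiles <- function(train, cfg = encoder_config()) {
  lab <- train$label
  if (!any(lab == "positive") || !any(lab == "negative"))
    stop("profile fitting requires both positive and negative windows")
  L <- train$L
  pc <- cfg$pseudocount
  mat <- t(vapply(train$seq, seq_to_int, integer(L)))
  count_tab <- function(m) {            # L x 4 counts
    t(apply(m, 2L, tabulate, nbins = 4L))
  }
  pos <- mat[lab == "positive", , drop = FALSE]
  neg <- mat[lab == "negative", , drop = FALSE]
  smooth <- function(cnt, n) (cnt + pc) / (n + 4 * pc)
  pair_counts <- function(m, xi) {      # (L - xi) x 16 counts
    t(vapply(seq_len(L - xi), function(k) {
      tabulate((m[, k] - 1L) * 4L + m[, k + xi], 16L)
    }, numeric(16L)))
  }
  pair <- lapply(cfg$xi_set, function(xi) {
    list(xi = xi,
         pos_pair = pair_counts(pos, xi), neg_pair = pair_counts(neg, xi),
         pos_single = count_tab(pos), neg_single = count_tab(neg))
  })
  names(pair) <- as.character(cfg$xi_set)
  structure(list(pos_table = smooth(count_tab(pos), nrow(pos)),
                 neg_table = smooth(count_tab(neg), nrow(neg)),
                 pair = pair, L = L, pseudocount = pc, xi_set = cfg$xi_set),
            class = "m5u_profile")
}

#' Bi-profile Bayes encoding
#'
#' Encodes a window as the per-position posterior nucleotide probabilities
#' under the positive profile followed by those under the negative profile.
#'
#' @param seq RNA string of the profile's length.
#' @param profile an \code{m5u_profile} from \code{\link{fit_profiles}}.
#' @return numeric vector of length 2L.
#' @export
encode_biprofile <- function(seq, profile) {
  x <- seq_to_int(seq)
  if (length(x) != profile$L)
    stop("sequence length ", length(x), " does not match profile L = ", profile$L)
  idx <- cbind(seq_along(x), x)
  c(profile$pos_table[idx], profile$neg_table[idx])
}

#' Pseudo k-tuple nucleotide composition (PseKNC)
#'
#' Combines normalized k-mer frequencies with \code{lam} sequence-order
#' correlation factors theta_j computed from six z-standardized dinucleotide
#' structural properties:
#' theta_j = mean over i of (1/6) sum_v (P_v(i) - P_v(i+j))^2.
#' Component u is f_u / (sum f + w sum theta) for u <= 4^k and
#' w theta_{u-4^k} / (sum f + w sum theta) above; components sum to 1.
#'
#' @param seq RNA string.
#' @param cfg an \code{\link{encoder_config}} (uses k, lam, w, prop_table).
#' @return numeric vector of length \code{4^k + lam}.
#' @export
encode_pseknc <- function(seq, cfg = encoder_config()) {
  x <- seq_to_int(seq)
  L <- length(x)
  k <- cfg$k
  if (cfg$lam >= L - 1L) stop("lam must be < L - 1")
  nk <- L - k + 1L
  kmer <- x[seq_len(nk)] - 1L
  if (k > 1L) for (j in 2:k) kmer <- kmer * 4L + (x[j:(j + nk - 1L)] - 1L)
  f <- tabulate(kmer + 1L, 4L^k) / nk
  theta <- numeric(cfg$lam)
  if (cfg$lam > 0L) {
    din <- (x[-L] - 1L) * 4L + x[-1L]            # dinucleotide index 1..16
    P <- cfg$prop_table[din, , drop = FALSE]      # (L-1) x 6
    for (j in seq_len(cfg$lam)) {
      i <- seq_len(L - j - 1L)
      d <- P[i, , drop = FALSE] - P[i + j, , drop = FALSE]
      theta[j] <- mean(rowMeans(d^2))
    }
  }
  denom <- sum(f) + cfg$w * sum(theta)
  c(f, cfg$w * theta) / denom
}

#' Nucleotide chemical properties with cumulative density (NCP-ND)
#'
#' Per position: three chemical-property coordinates
#' (A = (1,1,1), C = (0,1,0), G = (1,0,0), U = (0,0,1), encoding ring
#' number, hydrogen bonding and functional group) plus the cumulative
#' density of the position's nucleotide in the prefix ending there,
#' flattened position-major.
#'
#' @param seq RNA string.
#' @return numeric vector of length \code{4 * nchar(seq)}.
#' @export
encode_ncp_nd <- function(seq) {
  ncp <- rbind(A = c(1, 1, 1), C = c(0, 1, 0), G = c(1, 0, 0), U = c(0, 0, 1))
  x <- seq_to_int(seq)
  L <- length(x)
  cum <- matrix(0L, L, 4L)
  cum[cbind(seq_len(L), x)] <- 1L
  cum <- matrix(apply(cum, 2L, cumsum), nrow = L)
  dens <- cum[cbind(seq_len(L), x)] / seq_len(L)
  as.vector(t(cbind(ncp[x, , drop = FALSE], dens)))
}

#' Position-specific nucleotide pair propensity (NPPS)
#'
#' For each spacing xi and position k, computes the conditional probability
#' of the observed pair (seq[k], seq[k+xi]) given the nucleotide at k+xi,
#' separately under the positive and negative training frequency tables,
#' and emits their difference p+ - p-. Conditionals are smoothed
#' additively: (pair count + pc) / (single count + 4 pc).
#'
#' @param seq RNA string of the profile's length.
#' @param profile an \code{m5u_profile} fitted with matching \code{xi_set}.
#' @param cfg an \code{\link{encoder_config}}.
#' @return numeric vector of length \code{sum(L - xi_set)}.
#' @export
encode_npps <- function(seq, profile, cfg = encoder_config()) {
  x <- seq_to_int(seq)
  L <- profile$L
  if (length(x) != L) stop("sequence length does not match profile")
  if (any(cfg$xi_set >= L)) stop("xi must be < L")
  if (!all(cfg$xi_set %in% profile$xi_set))
    stop("profile was not fitted for all requested xi values")
  pc <- profile$pseudocount
  unlist(lapply(cfg$xi_set, function(xi) {
    tb <- profile$pair[[as.character(xi)]]
    k <- seq_len(L - xi)
    pi <- (x[k] - 1L) * 4L + x[k + xi]
    pp <- (tb$pos_pair[cbind(k, pi)] + pc) /
          (tb$pos_single[cbind(k + xi, x[k + xi])] + 4 * pc)
    pn <- (tb$neg_pair[cbind(k, pi)] + pc) /
          (tb$neg_single[cbind(k + xi, x[k + xi])] + 4 * pc)
    pp - pn
  }))
}

#' Fuse feature blocks into one matrix
#'
#' Column-binds feature matrices that share the same ordered id list,
#' concatenating their block schemas in the given order.
#'
#' @param blocks a named list of \code{m5u_features} objects (names are
#'   ignored; block names come from each object's schema).
#' @return an \code{m5u_features} with all blocks.
#' @export
fuse_features <- function(blocks) {
  stopifnot(length(blocks) >= 1L)
  ids <- blocks[[1L]]$ids
  for (b in blocks) {
    if (!identical(b$ids, ids)) {
      off <- union(setdiff(b$ids, ids), setdiff(ids, b$ids))
      stop("cannot fuse blocks with mismatched ids",
           if (length(off)) paste0(": ", paste(utils::head(off, 5L), collapse = ", "))
           else " (same set, different order)")
    }
  }
  m5u_features(ids,
               do.call(cbind, lapply(blocks, function(b) b$X)),
               do.call(rbind, lapply(blocks, function(b) b$blocks)))
}

#' Encode a dataset with the sequence-derived feature schemes
#'
#' Applies the requested encoders to every window and fuses the results
#' into one block-structured feature matrix. The profile-based encoders
#' (\code{bpb}, \code{npps}) require a profile fitted on labeled training
#' data; fit it on training folds only to avoid test-label leakage.
#'
#' @param ds an \code{m5u_dataset}.
#' @param cfg an \code{\link{encoder_config}}.
#' @param profile an \code{m5u_profile}, required when \code{encoders}
#'   includes \code{"bpb"} or \code{"npps"}.
#' @param encoders character vector naming the schemes to apply, a subset of
#'   \code{c("nps", "ctd", "bpb", "eiip", "pseknc", "ncpnd", "npps")}.
#' @return an \code{m5u_features} with one block per encoder.
#' @export
encode_dataset <- function(ds, cfg = encoder_config(), profile = NULL,
                           encoders = c("nps", "ctd", "bpb", "eiip",
                                        "pseknc", "ncpnd", "npps")) {
  encoders <- match.arg(encoders, c("nps", "ctd", "bpb", "eiip", "pseknc",
                                    "ncpnd", "npps"), several.ok = TRUE)
  if (any(encoders %in% c("bpb", "npps")) && is.null(profile))
    stop("encoders 'bpb' and 'npps' require a fitted profile")
  enc_fun <- list(
    nps = function(s) encode_nps(s, cfg$d_max),
    ctd = encode_ctd,
    bpb = function(s) encode_biprofile(s, profile),
    eiip = encode_eiip,
    pseknc = function(s) encode_pseknc(s, cfg),
    ncpnd = encode_ncp_nd,
    npps = function(s) encode_npps(s, profile, cfg))
  mats <- lapply(encoders, function(e) {
    f <- enc_fun[[e]]
    width <- length(f(ds$seq[1L]))
    X <- t(vapply(ds$seq, f, numeric(width)))
    m5u_features(ds$id, X, data.frame(name = e, n_cols = width))
  })
  fuse_features(mats)
}
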