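test_that("EIIP maps nucleotides to their published potentials", {
  expect_equal(encode_eiip("ACGU"), c(0.1260, 0.1340, 0.0806, 0.1335))
  expect_equal(encode_eiip("AAAA"), rep(0.1260, 4))
  v <- encode_eiip(random_window())
  expect_length(v, 41L)
  expect_true(all(v %in% c(0.1260, 0.1340, 0.0806, 0.1335)))
  expect_error(encode_eiip("ACGT"), "outside")
})

test_that("NPS matches brute-force pair enumeration", {
  expect_length(encode_nps(random_window(), d_max = 2L), 48L)

  v <- encode_nps(strrep("A", 41), d_max = 2L)
  expect_equal(v[1], 1)            # AA at spacing 0: 40/40
  expect_equal(sum(v[2:16]), 0)

  # independent enumeration oracle for arbitrary seq and d_max
  brute_nps <- function(seq, d_max) {
    x <- strsplit(seq, "")[[1]]
    nts <- c("A", "C", "G", "U")
    out <- c()
    for (d in 0:d_max) {
      cnt <- matrix(0, 4, 4, dimnames = list(nts, nts))
      for (i in seq_len(length(x) - d - 1))
        cnt[x[i], x[i + d + 1]] <- cnt[x[i], x[i + d + 1]] + 1
      out <- c(out, as.vector(t(cnt)) / (length(x) - d - 1))
    }
    out
  }
  expect_equal(encode_nps("AUAU", 0L), brute_nps("AUAU", 0L))
  expect_equal(encode_nps("AUAU", 0L)[4], 2 / 3)   # AU
  expect_equal(encode_nps("AUAU", 0L)[13], 1 / 3)  # UA
  withr::with_seed(2, for (i in 1:5) {
    w <- random_window()
    expect_equal(encode_nps(w, 2L), brute_nps(w, 2L))
  })
  expect_error(encode_nps("ACG", 2L), "d_max")
})

test_that("CTD composition/transition/distribution follow the quantile rule", {
  v <- encode_ctd("AAAA")
  expect_equal(v[1:4], c(1, 0, 0, 0))
  expect_equal(v[5], 1)                       # AA transition
  expect_equal(v[21:25], c(0.25, 0.25, 0.5, 0.75, 1.0))
  expect_equal(v[26:40], rep(0, 15))          # C, G, U absent

  v <- encode_ctd("ACGU")
  expect_equal(v[1:4], rep(0.25, 4))
  expect_equal(unname(v[c(6, 11, 16)]), rep(1 / 3, 3))  # AC, CG, GU
  expect_equal(v[21:25], rep(0.25, 5))        # single A at position 1/4

  withr::with_seed(3, for (i in 1:5) {
    v <- encode_ctd(random_window())
    expect_length(v, 40L)
    expect_equal(sum(v[1:4]), 1)
    expect_equal(sum(v[5:20]), 1)
  })
})

test_that("position profiles use additive smoothing per class", {
  ds <- toy_dataset(c("AC", "AC", "GU"), c("positive", "positive", "negative"))
  prof <- fit_profiles(ds, encoder_config(pseudocount = 0, xi_set = 1L))
  expect_equal(prof$pos_table, rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)))
  expect_equal(prof$neg_table, rbind(c(0, 0, 1, 0), c(0, 0, 0, 1)))

  # single positive "AA" with pseudocount 1: (1+1)/(1+4) then 1/5
  ds2 <- toy_dataset(c("AA", "CC"), c("positive", "negative"))
  prof2 <- fit_profiles(ds2, encoder_config(pseudocount = 1))
  expect_equal(prof2$pos_table[1, ], c(2, 1, 1, 1) / 5)

  # rows are probability distributions
  expect_equal(rowSums(prof2$pos_table), rep(1, 2), tolerance = 1e-9)
  expect_true(all(prof2$neg_table > 0))

  # law of large numbers: uniform classes converge to 0.25
  withr::with_seed(9, {
    seqs <- vapply(1:1000, function(i)
      paste(sample(c("A", "C", "G", "U"), 5, replace = TRUE), collapse = ""),
      character(1))
    ds3 <- toy_dataset(seqs, rep(c("positive", "negative"), 500))
    prof3 <- fit_profiles(ds3, encoder_config(pseudocount = 0))
    expect_lt(max(abs(prof3$pos_table - 0.25)), 0.05)
    expect_lt(max(abs(prof3$neg_table - 0.25)), 0.05)
  })

  expect_error(fit_profiles(toy_dataset("AA", "positive")), "both")
})

test_that("Bi-profile encoding concatenates class posteriors", {
  ds <- toy_dataset(c("AC", "GU"), c("positive", "negative"))
  prof <- fit_profiles(ds, encoder_config(pseudocount = 0))
  expect_equal(encode_biprofile("AC", prof), c(1, 1, 0, 0))
  prof$pos_table[] <- 0.25
  prof$neg_table[] <- 0.25
  expect_equal(encode_biprofile("GU", prof), rep(0.25, 4))
  ds41 <- random_dataset(3, 3)
  p41 <- fit_profiles(ds41)
  expect_length(encode_biprofile(ds41$seq[1], p41), 82L)
  expect_error(encode_biprofile("ACG", prof), "match")
})

test_that("PseKNC components are a normalized composition", {
  w <- random_window()
  cfg0 <- encoder_config(lam = 0L)
  x <- strsplit(w, "")[[1]]
  kmers <- paste0(x[-41], x[-1])
  f <- table(factor(kmers, levels = as.vector(t(outer(c("A","C","G","U"),
                                                      c("A","C","G","U"),
                                                      paste0)))))
  expect_equal(encode_pseknc(w, cfg0), as.vector(f) / 40)
  expect_length(encode_pseknc(w, encoder_config(lam = 4L)), 20L)
  withr::with_seed(4, for (i in 1:5) {
    v <- encode_pseknc(random_window(), encoder_config())
    expect_equal(sum(v), 1, tolerance = 1e-9)
    expect_true(all(v >= 0))
  })
  expect_error(encode_pseknc("ACGU", encoder_config(lam = 3L)), "lam")
})

test_that("the property table is z-standardized over dinucleotides", {
  pt <- encoder_config()$prop_table
  expect_equal(unname(colMeans(pt)), rep(0, 6), tolerance = 1e-6)
  expect_equal(unname(apply(pt, 2, sd)), rep(1, 6), tolerance = 1e-6)
})

test_that("NCP-ND encodes chemistry coordinates and prefix densities", {
  v <- encode_ncp_nd("A")
  expect_equal(v, c(1, 1, 1, 1))
  expect_equal(encode_ncp_nd("AAAA")[c(4, 8, 12, 16)], c(1, 1, 1, 1))
  expect_equal(encode_ncp_nd("ACGU")[c(4, 8, 12, 16)], c(1, 1/2, 1/3, 1/4))
  expect_equal(encode_ncp_nd("C")[1:3], c(0, 1, 0))
  expect_equal(encode_ncp_nd("G")[1:3], c(1, 0, 0))
  expect_equal(encode_ncp_nd("U")[1:3], c(0, 0, 1))
  expect_length(encode_ncp_nd(random_window()), 164L)
})

test_that("NPPS equals hand-computed conditional probability differences", {
  # identical positive and negative sets: all features zero
  seqs <- c("AUG", "GUA")
  ds <- toy_dataset(rep(seqs, 2), rep(c("positive", "negative"), each = 2))
  cfg <- encoder_config(pseudocount = 1, xi_set = 1L)
  prof <- fit_profiles(ds, cfg)
  expect_equal(encode_npps("AUG", prof, cfg), c(0, 0))

  # brute-force: pos {AUG}, neg {GUA}, pc = 1, xi = 1
  ds2 <- toy_dataset(c("AUG", "GUA"), c("positive", "negative"))
  prof2 <- fit_profiles(ds2, cfg)
  # position k=1 of "AUG": pair (A,U) at k=1, single U at k=2
  # pos: pair count 1, single count 1 -> (1+1)/(1+4) = 2/5
  # neg ("GUA"): pair (A,U)@1 count 0, single U@2 count 1 -> 1/5
  # k=2: pair (U,G)@2: pos 1, single G@3 pos 1 -> 2/5; neg 0 & G@3 count 0 -> 1/4
  expect_equal(encode_npps("AUG", prof2, cfg),
               c(2/5 - 1/5, 2/5 - 1/4))

  ds41 <- random_dataset(4, 4)
  p41 <- fit_profiles(ds41)
  expect_length(encode_npps(ds41$seq[1], p41), 40L)
})

test_that("feature fusion concatenates blocks in order", {
  ds <- random_dataset(3, 2)
  prof <- fit_profiles(ds)
  a <- encode_dataset(ds, profile = prof, encoders = c("nps"))
  b <- encode_dataset(ds, profile = prof, encoders = c("bpb"))
  f <- fuse_features(list(a, b))
  expect_equal(ncol(f$X), 48L + 82L)
  expect_equal(f$blocks$name, c("nps", "bpb"))
  expect_identical(fuse_features(list(a))$X, a$X)
  g <- fuse_features(list(b, a))
  expect_equal(g$blocks$name, c("bpb", "nps"))
  expect_identical(g$X[, 83:130], f$X[, 1:48])
  a2 <- a; a2$ids <- rev(a2$ids)
  expect_error(fuse_features(list(a, a2)), "mismatched ids")
})

test_that("encoders are pure and match their stated dimensions", {
  ds <- random_dataset(3, 3)
  prof <- fit_profiles(ds)
  fm1 <- encode_dataset(ds, profile = prof)
  fm2 <- encode_dataset(ds, profile = prof)
  expect_identical(fm1$X, fm2$X)
  widths <- setNames(fm1$blocks$n_cols, fm1$blocks$name)
  expect_equal(widths[["nps"]], 48L)
  expect_equal(widths[["ctd"]], 40L)
  expect_equal(widths[["bpb"]], 82L)
  expect_equal(widths[["eiip"]], 41L)
  expect_equal(widths[["pseknc"]], 18L)
  expect_equal(widths[["ncpnd"]], 164L)
  expect_equal(widths[["npps"]], 40L)
  # NPS per-spacing blocks and PseKNC sum to 1
  nps <- fm1$X[, 1:48]
  for (d in 0:2)
    expect_equal(unname(rowSums(nps[, (16 * d + 1):(16 * d + 16)])),
                 rep(1, 6), tolerance = 1e-9)
})

test_that("profile encoders never see test labels", {
  train <- random_dataset(5, 5)
  test <- random_dataset(4, 4)
  test$id <- paste0("te", seq_along(test$id))
  prof <- fit_profiles(train)
  f1 <- encode_dataset(test, profile = prof)
  shuffled <- test
  shuffled$label <- sample(test$label)
  f2 <- encode_dataset(shuffled, profile = prof)
  expect_identical(f1$X, f2$X)
})
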