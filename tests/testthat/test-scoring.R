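test_that("ssGSEA reproduces the worked 4-gene example", {
  tpm <- c(g1 = 8, g2 = 4, g3 = 2, g4 = 1)
  # P_in steps 0.5180, 1, 1, 1; P_out steps 0, 0, 0.5, 1
  es <- ssgsea_score(tpm, c("g1", "g2"), alpha = 0.25)
  expect_equal(es, 2.0180, tolerance = 1e-4)
  expect_equal(es, ssgsea_brute(tpm, c("g1", "g2")), tolerance = 1e-12)
})

test_that("a singleton top-gene set scores N/2 for any alpha", {
  for (N in c(2, 5, 17)) {
    for (alpha in c(0, 0.25, 1, 2)) {
      tpm <- setNames(seq_len(N) + runif(N, 0, 0.4), paste0("g", 1:N))
      top <- names(tpm)[which.max(tpm)]
      expect_equal(ssgsea_score(tpm, top, alpha), N / 2, tolerance = 1e-12)
    }
  }
})

test_that("ssGSEA equals the brute-force ECDF oracle on random cases", {
  set.seed(31)
  for (trial in 1:30) {
    N <- sample(3:10, 1)
    tpm <- setNames(round(rexp(N), 2), paste0("g", 1:N))  # ties likely
    size <- sample(seq_len(N - 1), 1)
    set <- sample(names(tpm), size)
    alpha <- sample(c(0, 0.25, 1), 1)
    expect_equal(ssgsea_score(tpm, set, alpha),
                 ssgsea_brute(tpm, set, alpha), tolerance = 1e-9)
  }
})

test_that("singscore matches the closed form and attains its bounds", {
  tpm <- c(g1 = 10, g2 = 5, g3 = 3, g4 = 2, g5 = 1)
  # mean rank (5+3)/2 = 4, n = 2: (4 - 1.5) / 3
  expect_equal(singscore_score(tpm, c("g1", "g3")), 0.8333333333,
               tolerance = 1e-10)
  expect_equal(singscore_score(tpm, c("g1", "g3"), center = TRUE),
               singscore_score(tpm, c("g1", "g3")) - 0.5)

  set.seed(5)
  for (trial in 1:10) {
    N <- sample(4:12, 1)
    tpm <- setNames(rexp(N), paste0("g", 1:N))
    n <- sample(seq_len(N - 1), 1)
    ord <- names(sort(tpm, decreasing = TRUE))
    expect_equal(singscore_score(tpm, ord[seq_len(n)]), 1, tolerance = 1e-12)
    expect_equal(singscore_score(tpm, rev(ord)[seq_len(n)]), 0,
                 tolerance = 1e-12)
    # all scores of random subsets stay inside [0, 1]
    s <- singscore_score(tpm, sample(names(tpm), n))
    expect_true(s >= 0 && s <= 1)
  }
})

test_that("singscore range normalization is exact over all 2-subsets", {
  tpm <- c(a = 9, b = 7, c = 5, d = 3, e = 1)
  subsets <- combn(names(tpm), 2, simplify = FALSE)
  scores <- vapply(subsets, function(s) singscore_score(tpm, s), numeric(1))
  expect_equal(min(scores), 0)
  expect_equal(max(scores), 1)
})

test_that("both scores see expression only through midranks", {
  set.seed(19)
  for (trial in 1:10) {
    tpm <- setNames(rexp(20), paste0("g", 1:20))
    set <- sample(names(tpm), 6)
    warped <- exp(tpm) * 3 + 1
    expect_identical(ssgsea_score(tpm, set), ssgsea_score(warped, set))
    expect_identical(singscore_score(tpm, set),
                     singscore_score(warped, set))
  }
})

test_that("degenerate sets yield missing scores; absent genes are ignored", {
  tpm <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  expect_true(is.na(ssgsea_score(tpm, c("zz", "yy"))))
  expect_true(is.na(ssgsea_score(tpm, names(tpm))))
  expect_true(is.na(singscore_score(tpm, "zz")))
  expect_true(is.na(singscore_score(tpm, names(tpm))))
  expect_equal(ssgsea_score(tpm, c("g1", "g2", "not_present")),
               ssgsea_score(tpm, c("g1", "g2")))
  expect_equal(singscore_score(tpm, c("g1", "g2", "not_present")),
               singscore_score(tpm, c("g1", "g2")))
})

test_that("score_pathways composes per-set scalar calls into a table", {
  set.seed(9)
  vals <- matrix(rexp(30) + 0.2, ncol = 3,
                 dimnames = list(NULL, c("s1", "s2", "s3")))
  m <- toy_matrix(vals, gene_ids = paste0("g", 1:10))
  col <- toy_collection(list(A = paste0("g", 1:4), B = paste0("g", c(2, 8, 9)),
                             C = paste0("g", 5:10)))
  for (method in c("singscore", "ssgsea")) {
    tab <- score_pathways(m, col, method = method, normalize = FALSE,
                          expr_threshold = 0)
    expect_equal(tab$pathway, col$name)
    for (j in 1:3) {
      v <- setNames(vals[, j], m$gene_id)
      expected <- vapply(col$genes, function(g) {
        if (method == "ssgsea") ssgsea_score(v, g) else singscore_score(v, g)
      }, numeric(1))
      expect_equal(tab[[paste0("s", j)]], unname(expected), tolerance = 1e-12)
    }
  }
})

test_that("identical sample columns give identical score columns", {
  vals <- matrix(rexp(20) + 0.2, ncol = 2)
  vals[, 2] <- vals[, 1]
  m <- toy_matrix(vals, gene_ids = paste0("g", 1:10))
  col <- toy_collection(list(A = paste0("g", 1:3), B = paste0("g", 4:9)))
  tab <- score_pathways(m, col, method = "ssgsea")
  expect_identical(tab[[2]], tab[[3]])
})

test_that("ssGSEA global normalization does not change sample rankings", {
  set.seed(27)
  vals <- matrix(rexp(60) + 0.2, ncol = 2)
  m <- toy_matrix(vals, gene_ids = paste0("g", 1:30))
  col <- toy_collection(as.list(setNames(
    replicate(8, sample(paste0("g", 1:30), 6), simplify = FALSE),
    paste0("P", 1:8))))
  on_ <- score_pathways(m, col, method = "ssgsea", normalize = TRUE)
  off <- score_pathways(m, col, method = "ssgsea", normalize = FALSE)
  expect_equal(spearman_cor(on_[[2]], on_[[3]]),
               spearman_cor(off[[2]], off[[3]]), tolerance = 1e-12)
})
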