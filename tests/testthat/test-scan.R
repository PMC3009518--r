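# Position-weighted similarity, density clustering and the Q-score scan.

test_that("similarity combines run length and match count as specified", {
  expect_equal(similarity("11011", "11011", focal = 3, W = 5), 10)  # 5 + 5
  # "11011" vs "11001": matches at 1,2,3,5 -> N = 4; focal run spans 1-3
  expect_equal(similarity("11011", "11001", focal = 3, W = 5), 7)
  # focal mismatch forces L = 0 regardless of flanks
  expect_equal(similarity("11011", "11111", focal = 3, W = 5), 4)
  # weights scale the two components separately
  expect_equal(similarity("11011", "11001", focal = 3, W = 5, w_L = 2, w_N = 0), 6)
  expect_equal(similarity("11011", "11001", focal = 3, W = 5, w_L = 0, w_N = 1), 4)
  # window clipping at chromosome ends
  expect_equal(similarity("11", "12", focal = 1, W = 5), 2)  # N = 1, L = 1
  expect_error(similarity("11", "111", 1), "length mismatch")
})

test_that("similarity is symmetric and matches the matrix fast path", {
  set.seed(8)
  for (i in 1:30) {
    L <- sample(3:8, 1)
    hmat <- matrix(sample(1:2, 4 * L, replace = TRUE), 4, L)
    focal <- sample(seq_len(L), 1)
    W <- sample(c(1, 3, 5), 1)
    S <- fhapminer:::similarity_matrix(hmat, focal, W)
    for (a in 1:4) for (b in 1:4) {
      expect_equal(S[a, b],
                   similarity(hmat[a, ], hmat[b, ], focal, W))
      expect_equal(S[a, b], S[b, a])
    }
  }
})

test_that("density clustering isolates a clone set among scattered strings", {
  set.seed(12)
  clones <- rep("1111111111", 10)
  # ten mutually distinct strings, none identical to the clone
  others <- c("2222222222", "2111111111", "1211111111", "1121111111",
              "1112111111", "1111211111", "1111121111", "1111112111",
              "1111111211", "1111111121")
  haps <- c(clones, others)
  cl <- hap_cluster(haps, focal = 5, W = 10, minpts = 3, eps_frac = 1)
  expect_length(cl, 1)
  expect_setequal(cl[[1]], 1:10)
})

test_that("degenerate clustering cases behave", {
  haps <- rep("1212", 7)
  cl <- hap_cluster(haps, focal = 2, W = 3)
  expect_length(cl, 1)
  expect_length(cl[[1]], 7)
  expect_length(hap_cluster(haps, focal = 2, W = 3, minpts = 10), 0)
  expect_length(hap_cluster(haps[1], focal = 2), 0)  # n < 2
})

test_that("q_score matches the Welch t-test and its closed-form edge cases", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1))
    y <- rnorm(sample(3:8, 1))
    all <- c(x, y)
    got <- q_score(x, all)
    ref <- t.test(x, y)
    expect_equal(got$Q, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    # sign flip negates Q, keeps p
    neg <- q_score(-x, -all)
    expect_equal(neg$Q, -got$Q, tolerance = 1e-10)
    expect_equal(neg$p, got$p, tolerance = 1e-10)
  }
  # equal means, zero variance -> Q = 0, p = 1
  expect_equal(q_score(c(1, 1), c(1, 1, 1, 1)), list(Q = 0, p = 1))
  # separated constants with tiny jitter -> overwhelming evidence
  set.seed(4)
  cl <- 2 + rnorm(4, sd = 1e-6)
  rest <- rnorm(4, sd = 1e-6)
  expect_lt(q_score(cl, c(cl, rest))$p, 1e-6)
  expect_error(q_score(1, c(1, 2, 3)), "strict subset")
})

test_that("scan with W = 1 reduces to grouping by the focal allele", {
  set.seed(19)
  n <- 80
  haps <- replicate(n, paste(sample(1:2, 5, replace = TRUE), collapse = ""))
  scores <- rnorm(n)
  pooled <- data.frame(haplotype = haps, score = scores,
                       stringsAsFactors = FALSE)
  res <- hap_scan(pooled, W = 1)
  minpts <- max(2, ceiling(0.05 * n))
  hmat <- do.call(rbind, lapply(haps, function(s)
    as.integer(strsplit(s, "")[[1]])))
  for (m in 1:5) {
    # direct oracle: allele groups of size >= minpts, Welch Q, max |Q|
    qs <- c()
    for (al in unique(hmat[, m])) {
      idx <- which(hmat[, m] == al)
      if (length(idx) < minpts || length(idx) < 2 ||
          length(idx) > n - 2) next
      qs <- c(qs, q_score(scores[idx], scores)$Q)
    }
    if (length(qs)) expect_equal(abs(res$Q[m]), max(abs(qs)), tolerance = 1e-10)
  }
  # single-marker panel: Bonferroni with L = 1 leaves p unchanged
  one <- hap_scan(data.frame(haplotype = substr(haps, 1, 1), score = scores),
                  W = 1)
  expect_equal(one$p_adjusted, one$p_raw)
})

test_that("a planted high-scoring haplotype wins every focal marker", {
  set.seed(23)
  n <- 200
  carrier <- 1:60
  haps <- character(n)
  haps[carrier] <- "1111111111"
  haps[-carrier] <- replicate(n - 60,
    paste(sample(1:2, 10, replace = TRUE, prob = c(.3, .7)), collapse = ""))
  scores <- rnorm(n)
  scores[carrier] <- scores[carrier] + 3
  res <- hap_scan(data.frame(haplotype = haps, score = scores), W = 9)
  cl <- attr(res, "clusters")
  for (m in 1:10) expect_true(all(carrier %in% cl[[m]]))
  expect_true(all(res$significant))
})

test_that("family-wise error is controlled on null scans", {
  set.seed(31)
  n <- 60; L <- 6
  hits <- logical(400)
  for (r in seq_len(400)) {
    haps <- replicate(n, paste(sample(1:2, L, replace = TRUE), collapse = ""))
    res <- hap_scan(data.frame(haplotype = haps, score = rnorm(n)), W = 1)
    hits[r] <- any(res$significant, na.rm = TRUE)
  }
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("permutation correction is valid and dominates the raw p", {
  set.seed(37)
  n <- 50
  haps <- replicate(n, paste(sample(1:2, 4, replace = TRUE), collapse = ""))
  scores <- rnorm(n)
  res <- hap_scan(data.frame(haplotype = haps, score = scores), W = 1,
                  correction = "permutation", B = 99, seed = 5)
  ok <- !is.na(res$p_adjusted)
  expect_true(all(res$p_adjusted[ok] >= res$p_raw[ok]))
  expect_true(all(res$p_adjusted[ok] >= 1 / 100))
  # bonferroni adjustment is monotone in the raw p
  res2 <- hap_scan(data.frame(haplotype = haps, score = scores), W = 1)
  ord <- order(res2$p_raw)
  expect_true(!is.unsorted(res2$p_adjusted[ord], na.rm = TRUE))
})
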