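test_that("allele frequency is the column mean, with lookup errors", {
  H <- cbind(c(0, 0, 0, 0), c(1, 1, 1, 1), c(0, 1, 0, 1))
  panel <- mini_panel(H)
  expect_equal(allele_freq(panel, "s1"), 0)
  expect_equal(allele_freq(panel, "s2"), 1)
  expect_equal(allele_freq(panel, "s3"), 0.5)
  expect_error(allele_freq(panel, "nope"), "not found")
})

test_that("pairwise r2 matches haplotype-count cases", {
  a <- c(0, 0, 1, 1, 0, 1, 0, 1)
  panel <- mini_panel(cbind(a, a, 1 - a, c(0, 0, 1, 1, 0, 0, 1, 1)))
  expect_equal(pairwise_r2(panel, "s1", "s2"), 1)       # identical columns
  expect_equal(pairwise_r2(panel, "s1", "s3"), 1)       # r = -1
  # independence: one haplotype of each configuration
  H4 <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(pairwise_r2(mini_panel(H4), "s1", "s2"), 0)
  # counts AB=3, Ab=1, aB=1, ab=3 -> r2 = 0.25
  Hc <- cbind(c(1, 1, 1, 1, 0, 0, 0, 0), c(1, 1, 1, 0, 1, 0, 0, 0))
  expect_equal(pairwise_r2(mini_panel(Hc), "s1", "s2"), 0.25)
})

test_that("r2 equals the haplotype-count oracle and is symmetric in [0,1]", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(c(20, 50, 101), 1)
    H <- matrix(rbinom(n * 4, 1, runif(1, 0.2, 0.8)), nrow = n)
    poly <- apply(H, 2, function(x) var(x) > 0)
    if (sum(poly) < 2) next
    panel <- mini_panel(H)
    ids <- paste0("s", which(poly))
    for (pair in list(ids[1:2], rev(ids[1:2]))) {
      r2 <- pairwise_r2(panel, pair[1], pair[2])
      expect_equal(r2, oracle_r2(H, as.integer(sub("s", "", pair[1])),
                                 as.integer(sub("s", "", pair[2]))))
      expect_true(r2 >= 0 && r2 <= 1 + 1e-12)
    }
    expect_equal(pairwise_r2(panel, ids[1], ids[2]),
                 pairwise_r2(panel, ids[2], ids[1]))
  }
})

test_that("monomorphic SNPs give an undefined-LD error, not zero", {
  panel <- mini_panel(cbind(c(0, 0, 0, 0), c(0, 1, 0, 1)))
  expect_error(pairwise_r2(panel, "s1", "s2"), "monomorphic")
  expect_error(pairwise_r2(panel, "s2", "s1"), "monomorphic")
})

test_that("greedy clumping handles the degenerate and pairwise cases", {
  g <- generate_panel(200, n_blocks = 2, snps_per_block = 2,
                      within_block_r2 = 0.9, seed = 7)
  panel <- g$panel

  one <- greedy_clump(data.frame(snp = "b1_s1", p = 1e-8), panel)
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_members, 1L)

  # strong within-block pair joins, indexed by the smaller P
  two <- greedy_clump(data.frame(snp = c("b1_s1", "b1_s2"),
                                 p = c(1e-8, 1e-10)), panel)
  expect_equal(nrow(two), 1L)
  expect_equal(two$index_snp, "b1_s2")
  expect_equal(two$index_p, 1e-10)

  # between-block pair (r2 ~ 0) stays independent at threshold 0.05
  sep <- greedy_clump(data.frame(snp = c("b1_s1", "b2_s1"),
                                 p = c(1e-8, 1e-10)), panel,
                      r2_threshold = 0.05)
  expect_equal(nrow(sep), 2L)

  # near-1 threshold: every variant its own clump
  all4 <- greedy_clump(data.frame(snp = colnames(panel$H),
                                  p = rep(1e-6, 4)), panel,
                       r2_threshold = 0.999)
  expect_equal(nrow(all4), 4L)
})

test_that("a variant below threshold r2 stays independent", {
  # plant a pair with known weak LD: r2 = 0.04 is below 0.05
  set.seed(11)
  n <- 5000
  a <- rbinom(n, 1, 0.5)
  flip <- rbinom(n, 1, (1 - sqrt(0.04)) / 2)
  b <- as.integer(xor(a, flip))
  panel <- mini_panel(cbind(a, b))
  r2 <- pairwise_r2(panel, "s1", "s2")
  expect_lt(abs(r2 - 0.04), 0.02)
  cl <- greedy_clump(data.frame(snp = c("s1", "s2"), p = c(1e-10, 1e-8)),
                     panel, r2_threshold = max(r2 + 0.001, 0.05))
  expect_equal(nrow(cl), 2L)
})

test_that("clumping recovers planted blocks and matches the brute-force oracle", {
  g <- generate_panel(1000, n_blocks = 5, snps_per_block = 4,
                      within_block_r2 = 0.9, seed = 1)
  panel <- g$panel
  set.seed(2)
  vars <- data.frame(snp = panel$snps$snp,
                     p = 10^(-runif(20, 6, 20)))
  cl <- greedy_clump(vars, panel, r2_threshold = 0.05)
  expect_equal(nrow(cl), 5L)
  # each clump is exactly one planted block
  mem <- clump_members(cl)
  for (ms in mem) {
    expect_equal(length(unique(g$truth$block[ms])), 1L)
    expect_equal(length(ms), 4L)
  }
  # agreement with the independent reference implementation
  r2mat <- matrix(NA_real_, 20, 20,
                  dimnames = list(panel$snps$snp, panel$snps$snp))
  for (i in 1:20) for (j in 1:20) {
    if (i != j) r2mat[i, j] <- oracle_r2(panel$H, i, j)
  }
  df <- data.frame(snp = panel$snps$snp, p = vars$p,
                   chrom = panel$snps$chrom, pos = panel$snps$pos,
                   stringsAsFactors = FALSE)
  ref <- oracle_clump(df, r2mat, 0.05)
  expect_equal(sort(cl$index_snp), sort(vapply(ref, `[[`, "", "index")))
  ref_members <- lapply(ref, `[[`, "members")
  names(ref_members) <- vapply(ref, `[[`, "", "index")
  for (ix in cl$index_snp) {
    expect_equal(sort(mem[[ix]]), ref_members[[ix]])
  }
})

test_that("clumping agrees with the oracle on random small instances", {
  set.seed(99)
  for (rep in 1:40) {
    m <- sample(2:8, 1)
    n <- 200
    H <- matrix(rbinom(n * m, 1, 0.5), nrow = n)
    # induce some LD by copying columns with noise
    for (j in seq_len(m)[-1]) {
      if (runif(1) < 0.5) {
        e <- runif(1, 0, 0.5)
        H[, j] <- as.integer(xor(H[, j - 1], rbinom(n, 1, e)))
      }
    }
    H <- apply(H, 2, function(x) { if (var(x) == 0) x[1] <- 1 - x[1]; x })
    panel <- mini_panel(H)
    p <- signif(10^(-runif(m, 3, 12)), 3)
    if (rep %% 3 == 0) p[1:2] <- p[2:1] * 0 + min(p)  # force equal-P ties
    thr <- runif(1, 0.02, 0.5)
    cl <- greedy_clump(data.frame(snp = panel$snps$snp, p = p), panel,
                       r2_threshold = thr)
    r2mat <- matrix(NA_real_, m, m,
                    dimnames = list(panel$snps$snp, panel$snps$snp))
    for (i in 1:m) for (j in 1:m) {
      if (i != j) r2mat[i, j] <- oracle_r2(H, i, j)
    }
    ref <- oracle_clump(data.frame(snp = panel$snps$snp, p = p,
                                   chrom = panel$snps$chrom,
                                   pos = panel$snps$pos,
                                   stringsAsFactors = FALSE),
                        r2mat, thr)
    expect_equal(sort(cl$index_snp), sort(vapply(ref, `[[`, "", "index")))
    # output partitions the input
    all_members <- unlist(clump_members(cl))
    expect_setequal(all_members, panel$snps$snp)
    expect_equal(anyDuplicated(all_members), 0L)
  }
})

test_that("clump count is non-increasing as the r2 threshold decreases", {
  g <- generate_panel(500, n_blocks = 4, snps_per_block = 3,
                      within_block_r2 = 0.6, seed = 5)
  vars <- data.frame(snp = g$panel$snps$snp,
                     p = 10^(-seq_len(12)))
  counts <- vapply(c(0.9, 0.5, 0.3, 0.1, 0.02),
                   function(t) nrow(greedy_clump(vars, g$panel,
                                                 r2_threshold = t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("variants absent from the panel follow the configured policy", {
  g <- generate_panel(100, 1, 2, 0.9, seed = 3)
  vars <- data.frame(snp = c("b1_s1", "ghost"), p = c(1e-8, 1e-9))
  expect_warning(cl <- greedy_clump(vars, g$panel), "absent")
  expect_equal(nrow(cl), 1L)
  expect_error(greedy_clump(vars, g$panel, missing = "error"), "absent")
})

test_that("best_proxy picks the strongest qualifying candidate", {
  g <- generate_panel(1000, n_blocks = 2, snps_per_block = 3,
                      within_block_r2 = 0.9, seed = 13)
  panel <- g$panel
  # the target itself always qualifies at r2 = 1
  self <- best_proxy("b1_s1", panel$snps$snp, panel, r2_min = 0.8)
  expect_equal(self$snp, "b1_s1")
  expect_equal(self$r2, 1)
  expect_equal(self$r_sign, 1)
  # candidates all in the other block: nothing qualifies
  expect_null(best_proxy("b1_s1", c("b2_s1", "b2_s2", "b2_s3"), panel,
                         r2_min = 0.5))
  expect_null(best_proxy("b1_s1", character(0), panel, r2_min = 0.1))
})

test_that("a planted ~0.75 proxy is accepted at 0.7 and rejected at 0.8", {
  set.seed(21)
  n <- 4000
  a <- rbinom(n, 1, 0.5)
  flip <- rbinom(n, 1, (1 - sqrt(0.75)) / 2)  # copy-with-noise
  b <- as.integer(xor(a, flip))
  panel <- mini_panel(cbind(a, b, rbinom(n, 1, 0.5)))
  r2 <- oracle_r2(panel$H, 1, 2)
  expect_lt(abs(r2 - 0.75), 0.05)
  hit <- best_proxy("s1", c("s2", "s3"), panel, r2_min = 0.7)
  expect_equal(hit$snp, "s2")
  expect_equal(hit$r2, r2)
  expect_null(best_proxy("s1", c("s2", "s3"), panel, r2_min = 0.8))
})

test_that("anti-correlated proxies carry a negative sign", {
  a <- rep(c(0, 1), 50)
  panel <- mini_panel(cbind(a, 1 - a))
  hit <- best_proxy("s1", "s2", panel, r2_min = 0.9)
  expect_equal(hit$r2, 1)
  expect_equal(hit$r_sign, -1)
})

test_that("panel invariants are enforced at construction", {
  expect_error(hap_panel("a", "1", 1, matrix(0:1, ncol = 1)), NA)
  expect_error(hap_panel(c("a", "a"), c("1", "1"), c(1, 2),
                         matrix(0L, 2, 2)), "duplicate")
  expect_error(hap_panel("a", "1", 1, matrix(c(0, 2), ncol = 1)),
               "0 or 1")
  expect_error(hap_panel("a", "1", 1, matrix(0L, 1, 1)), "at least 2")
  expect_error(hap_panel(c("a", "b"), c("1", "1"), c(5, 2),
                         matrix(0:1, 2, 2)), "non-decreasing")
})
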