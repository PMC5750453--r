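test_that("generators are pure functions of their seed", {
  a <- generate_panel(100, 2, 3, 0.8, seed = 42)
  b <- generate_panel(100, 2, 3, 0.8, seed = 42)
  c <- generate_panel(100, 2, 3, 0.8, seed = 43)
  expect_identical(a$panel$H, b$panel$H)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$panel$H, c$panel$H))

  fr <- setNames(rep(0.3, 5), paste0("s", 1:5))
  s1 <- simulate_case_control(freqs = fr, prevalence_K = 0.2,
                              n_cases = 200, n_controls = 200, seed = 9)
  s2 <- simulate_case_control(freqs = fr, prevalence_K = 0.2,
                              n_cases = 200, n_controls = 200, seed = 9)
  expect_identical(s1, s2)

  gm <- data.frame(snp = "b1_s1", gene = "G1", beta = 0.5)
  e1 <- simulate_eqtl(a$panel, gm, n_samples = 60, seed = 5)
  e2 <- simulate_eqtl(a$panel, gm, n_samples = 60, seed = 5)
  expect_identical(e1, e2)
})

test_that("generator calls leave the global RNG stream untouched", {
  set.seed(1234)
  x1 <- runif(1)
  set.seed(1234)
  invisible(generate_panel(60, 1, 2, 0.9, seed = 99))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("panel realizes the requested block LD structure", {
  # flip probability 0: all within-block r2 exactly 1
  g1 <- generate_panel(200, 2, 3, within_block_r2 = 1, seed = 2)
  for (b in c("b1", "b2")) {
    expect_equal(pairwise_r2(g1$panel, paste0(b, "_s1"), paste0(b, "_s2")), 1)
    expect_equal(pairwise_r2(g1$panel, paste0(b, "_s2"), paste0(b, "_s3")), 1)
  }

  # blocks of size 1: all pairwise r2 near zero
  g2 <- generate_panel(2000, 6, 1, within_block_r2 = 0.9, seed = 3)
  ids <- g2$panel$snps$snp
  r2s <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    r2s <- c(r2s, pairwise_r2(g2$panel, ids[i], ids[j]))
  }
  expect_lt(mean(r2s), 0.02)

  # founder-copy r2 near target, between-block r2 small (n >= 500)
  g3 <- generate_panel(1000, 4, 4, within_block_r2 = 0.8, seed = 4)
  fc <- c()
  for (b in 1:4) {
    for (s in 2:4) {
      fc <- c(fc, pairwise_r2(g3$panel, sprintf("b%d_s1", b),
                              sprintf("b%d_s%d", b, s)))
    }
  }
  expect_lt(abs(mean(fc) - 0.8), 0.1)
  between <- c()
  for (i in 1:4) for (j in 5:8) {
    between <- c(between, pairwise_r2(g3$panel, g3$panel$snps$snp[i],
                                      g3$panel$snps$snp[j]))
  }
  expect_lt(mean(between), 0.02)

  expect_error(generate_panel(10, 1, 2, 0.9), "50 haplotypes")
  expect_error(generate_panel(100, 1, 2, 1.2), "within_block_r2")
})

test_that("clumping the planted panel recovers exactly the blocks", {
  g <- generate_panel(1000, 5, 4, within_block_r2 = 0.9, seed = 1)
  cl <- greedy_clump(data.frame(snp = g$panel$snps$snp,
                                p = 10^(-(1:20))), g$panel,
                     r2_threshold = 0.05)
  expect_equal(nrow(cl), 5L)
  for (ms in clump_members(cl)) {
    expect_equal(length(unique(g$truth$block[ms])), 1L)
  }
})

test_that("unascertained population prevalence matches K", {
  fr <- setNames(runif(10, 0.2, 0.8), paste0("s", 1:10))
  betas <- setNames(rep(0.1, 10), names(fr))
  for (seed in 1:3) {
    pop <- simulate_population(freqs = fr, causal_betas = betas,
                               prevalence_K = 0.15, n = 50000, seed = seed)
    se <- sqrt(0.15 * 0.85 / 50000)
    expect_lt(abs(mean(pop$case) - 0.15), 4 * se)
  }
})

test_that("estimated OR is unbiased at K = 0.5 with equal quotas", {
  p <- 0.4
  beta <- 0.15
  or_true <- oracle_marginal_or(p, beta, K = 0.5)
  lors <- vapply(1:10, function(seed) {
    s <- simulate_case_control(freqs = c(snp1 = p),
                               causal_betas = c(snp1 = beta),
                               prevalence_K = 0.5, n_cases = 2000,
                               n_controls = 2000, seed = seed)
    log(s$OR)
  }, numeric(1))
  # Wald SE ~ sqrt(4/(2*2000*2p(1-p))) per seed; 3 SEs over the 10-seed mean
  se_mean <- sqrt(4 / (4000 * 2 * p * (1 - p))) / sqrt(10)
  expect_lt(abs(mean(lors) - log(or_true)), 3 * se_mean)
})

test_that("null P-values are uniform (KS) and quotas are enforced", {
  fr <- setNames(runif(2000, 0.1, 0.9), paste0("s", 1:2000))
  s <- simulate_case_control(freqs = fr, prevalence_K = 0.15,
                             n_cases = 1000, n_controls = 1000, seed = 1)
  ks <- suppressWarnings(ks.test(s$P, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_error(
    simulate_case_control(freqs = c(a = 0.5), prevalence_K = 0.001,
                          n_cases = 5000, n_controls = 100, seed = 1,
                          max_batches = 2),
    "simulation error")
  expect_error(
    simulate_case_control(freqs = c(a = 0.5),
                          causal_betas = c(a = 2), prevalence_K = 0.5),
    "below 1")
})

test_that("eQTL simulator gives uniform P under beta = 0 and power at beta = 1", {
  g <- generate_panel(600, 3, 2, within_block_r2 = 0.9, seed = 20)
  gm0 <- data.frame(snp = "b2_s1", gene = "G0", beta = 0)
  # aggregate null P across seeds for a stable uniformity check
  ps <- unlist(lapply(1:10, function(s) {
    simulate_eqtl(g$panel, gm0, n_samples = 100, seed = s)$p
  }))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)

  gm1 <- data.frame(snp = "b2_s1", gene = "G1", beta = 1)
  hits <- vapply(1:20, function(s) {
    e <- simulate_eqtl(g$panel, gm1, n_samples = 200, seed = s)
    e$p[e$snp == "b2_s1"] < 2.3e-9
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("a planted eQTL is recovered through its strong-LD partner", {
  g <- generate_panel(1000, 2, 3, within_block_r2 = 0.9, seed = 30)
  gm <- data.frame(snp = "b1_s2", gene = "TARGET", beta = 1)
  e <- simulate_eqtl(g$panel, gm, n_samples = 300, seed = 30)
  e <- cis_filter(e, 1e6)
  e <- significance_filter(e)
  sent <- select_sentinels(e, g$panel)
  hits <- link_targets("b1_s1", sent, g$panel, r2_min = 0.8)
  expect_true("TARGET" %in% hits$gene)
})

test_that("the full synthetic pipeline reproduces its planted truth", {
  g <- generate_panel(1000, 4, 3, within_block_r2 = 0.9, seed = 50)
  panel <- g$panel
  # plant liability effects of h2 ~ 0.4% on two block founders (NCP ~ 33
  # at this design: detection is near-certain at the screening threshold)
  p1 <- allele_freq(panel, "b1_s1")
  p2 <- allele_freq(panel, "b3_s1")
  betas <- c(b1_s1 = sqrt(0.004 / (2 * p1 * (1 - p1))),
             b3_s1 = sqrt(0.004 / (2 * p2 * (1 - p2))))
  orig <- simulate_case_control(panel = panel, causal_betas = betas,
                                prevalence_K = 0.15, n_cases = 5000,
                                n_controls = 5000, seed = 51)
  repl <- simulate_case_control(panel = panel, causal_betas = betas,
                                prevalence_K = 0.15, n_cases = 5000,
                                n_controls = 5000, seed = 52)
  # clumping the genome-wide-significant original hits recovers the 2 loci
  sig <- orig[orig$P < 1e-3, ]
  cl <- greedy_clump(data.frame(snp = sig$SNP, p = sig$P), panel,
                     r2_threshold = 0.05)
  expect_equal(sort(unique(g$truth$block[cl$index_snp])),
               sort(unique(g$truth$block[names(betas)])))
  # the planted causal SNPs replicate: same direction, small P
  o <- data.frame(SNP = orig$SNP, EA = "G", OA = "A", EAF = orig$EAF,
                  OR = orig$OR, P = orig$P)
  r <- data.frame(SNP = repl$SNP, EA = "G", OA = "A", EAF = repl$EAF,
                  OR = repl$OR, P = repl$P)
  res <- assess_replication(o[o$SNP %in% names(betas), ], r, alpha = 0.05)
  expect_equal(res$summary$n_significant, 2)
  # liability accounting on the causal SNPs recovers the planted total
  est <- summarize_h2(data.frame(SNP = names(betas),
                                 EAF = orig$EAF[match(names(betas),
                                                      orig$SNP)],
                                 OR = orig$OR[match(names(betas),
                                                    orig$SNP)]))
  expect_lt(abs(est$total_pct - 0.8), 0.3)
})
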