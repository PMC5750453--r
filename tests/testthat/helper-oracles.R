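# Independent reference implementations used as oracles. These work directly
# on raw haplotype matrices / r2 lookup tables and share no code with the
# package internals they check.

# r2 from the four haplotype counts, written out longhand
oracle_r2 <- function(H, i, j) {
  n <- nrow(H)
  n11 <- sum(H[, i] == 1 & H[, j] == 1)
  n10 <- sum(H[, i] == 1 & H[, j] == 0)
  n01 <- sum(H[, i] == 0 & H[, j] == 1)
  p_ab <- n11 / n
  p_a <- (n11 + n10) / n
  p_b <- (n11 + n01) / n
  (p_ab - p_a * p_b)^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
}

# Reference clumping over an explicit r2 matrix: repeatedly pick the best
# remaining variant (ties by chrom, pos, id) and absorb every remaining
# variant within the window whose r2 exceeds the threshold.
oracle_clump <- function(df, r2mat, threshold, window_bp = 1e6) {
  remaining <- df
  clumps <- list()
  while (nrow(remaining) > 0) {
    o <- order(remaining$p, remaining$chrom, remaining$pos, remaining$snp)
    idx <- remaining[o[1], ]
    rest <- remaining[-o[1], , drop = FALSE]
    in_clump <- logical(nrow(rest))
    if (nrow(rest) > 0) {
      for (k in seq_len(nrow(rest))) {
        same_chr <- rest$chrom[k] == idx$chrom
        near <- abs(rest$pos[k] - idx$pos) <= window_bp
        if (same_chr && near && r2mat[idx$snp, rest$snp[k]] > threshold) {
          in_clump[k] <- TRUE
        }
      }
    }
    clumps[[length(clumps) + 1]] <- list(
      index = idx$snp,
      members = sort(c(idx$snp, rest$snp[in_clump]))
    )
    remaining <- rest[!in_clump, , drop = FALSE]
  }
  clumps
}

# small panel builder from an explicit 0/1 matrix
mini_panel <- function(H, chrom = NULL, pos = NULL, ids = NULL) {
  m <- ncol(H)
  if (is.null(ids)) ids <- paste0("s", seq_len(m))
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  hap_panel(snp_id = ids, chrom = chrom, pos = pos, H = H)
}

# one-row sumstats record
rec <- function(SNP = "rs1", EA = "A", OA = "G", EAF = 0.3, OR = 1.2,
                P = 1e-9) {
  data.frame(SNP = SNP, EA = EA, OA = OA, EAF = EAF, OR = OR, P = P,
             stringsAsFactors = FALSE)
}

# expected population-level case/control allele frequencies and allelic OR
# under the liability-threshold model, by direct integration over the three
# genotypes (HWE weights)
oracle_marginal_or <- function(p, beta, K) {
  g <- 0:2
  w <- stats::dbinom(g, 2, p)
  resid_sd <- sqrt(1 - 2 * p * (1 - p) * beta^2)
  thr <- stats::qnorm(1 - K)
  pc <- 1 - stats::pnorm((thr - beta * (g - 2 * p)) / resid_sd)
  f_case <- sum(g * w * pc) / sum(2 * w * pc)
  f_ctrl <- sum(g * w * (1 - pc)) / sum(2 * w * (1 - pc))
  (f_case / (1 - f_case)) / (f_ctrl / (1 - f_ctrl))
}
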