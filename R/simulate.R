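# Seeded generators for every input the analysis pipeline consumes:
# block-LD haplotype panels, liability-threshold case-control summary
# statistics, and planted cis-eQTL association records. Each generator is a
# pure function of its arguments including the seed (RNG state is saved and
# restored around every call).

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# shared genotype sampler: haplotype pairing from a panel, or independent
# HWE draws from allele frequencies
.draw_genotypes <- function(panel, p, n) {
  if (!is.null(panel)) {
    i1 <- sample.int(nrow(panel$H), n, replace = TRUE)
    i2 <- sample.int(nrow(panel$H), n, replace = TRUE)
    panel$H[i1, , drop = FALSE] + panel$H[i2, , drop = FALSE]
  } else {
    matrix(stats::rbinom(n * length(p), 2L, rep(p, each = n)), nrow = n)
  }
}

.resolve_betas <- function(snp_ids, causal_betas) {
  beta <- rep(0, length(snp_ids))
  names(beta) <- snp_ids
  if (!is.null(causal_betas)) {
    if (is.null(names(causal_betas))) {
      stop("causal_betas must be named by SNP id", call. = FALSE)
    }
    unknown <- setdiff(names(causal_betas), snp_ids)
    if (length(unknown)) {
      stop("causal_betas name unknown SNP(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    beta[names(causal_betas)] <- causal_betas
  }
  beta
}

#' Simulate an unascertained population under the liability-threshold model
#'
#' Draws `n` individuals with liability `sum_j beta_j (g_j - 2 p_j) + eps`,
#' `eps ~ N(0, 1 - sum_j 2 p_j (1-p_j) beta_j^2)`, and labels cases where
#' liability exceeds `qnorm(1 - K)`. With correct variance bookkeeping the
#' empirical case fraction matches K up to binomial error — the calibration
#' check for the case-control simulator.
#'
#' @inheritParams simulate_case_control
#' @param n number of individuals.
#' @return data.frame with columns `liability` and `case` (logical);
#'   genotypes are attached as attribute `G`.
#' @export
simulate_population <- function(panel = NULL, freqs = NULL,
                                causal_betas = NULL, prevalence_K = 0.15,
                                n = 10000, seed = 1) {
  if (is.null(panel) == is.null(freqs)) {
    stop("supply exactly one of 'panel' or 'freqs'", call. = FALSE)
  }
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "hap_panel"))
    snp_ids <- panel$snps$snp
    p <- colMeans(panel$H)
  } else {
    snp_ids <- names(freqs)
    if (is.null(snp_ids)) snp_ids <- sprintf("snp%d", seq_along(freqs))
    p <- as.numeric(freqs)
  }
  beta <- .resolve_betas(snp_ids, causal_betas)
  var_g <- 2 * p * (1 - p) * beta^2
  if (sum(var_g) >= 1) {
    stop("planted liability variance must sum below 1", call. = FALSE)
  }
  thr <- stats::qnorm(1 - prevalence_K)
  with_seed(seed, {
    G <- .draw_genotypes(panel, p, n)
    liab <- as.vector(sweep(G, 2, 2 * p) %*% beta) +
      stats::rnorm(n, 0, sqrt(1 - sum(var_g)))
    out <- data.frame(liability = liab, case = liab > thr)
    attr(out, "G") <- G
    out
  })
}

#' Generate a block-structured haplotype panel
#'
#' Each LD block is built from a founder column (allele frequency 0.5);
#' the remaining columns of the block are copies of the founder with a
#' per-site flip probability `e = (1 - sqrt(r2))/2`, which makes the
#' founder-copy r2 equal `within_block_r2` in expectation (copy-copy pairs
#' realize its square). Columns of different blocks are independent, so
#' between-block r2 is ~1/n_haplotypes. Monomorphic draws are repaired by
#' flipping one haplotype.
#'
#' @param n_haplotypes number of haplotypes (>= 50 for stable r2).
#' @param n_blocks,snps_per_block block structure.
#' @param within_block_r2 target founder-copy r2 in \[0, 1\].
#' @param seed integer seed; identical seeds give identical panels.
#' @param chrom chromosome label for all SNPs.
#' @param spacing_bp distance between adjacent SNPs (default 1 kb; blocks
#'   are separated by ten spacings, all within a 1 Mb clump window).
#' @return List with `panel` (a [hap_panel]) and `truth` (list: `seed`,
#'   `block` — named SNP-to-block map, `flip_prob`, `target_r2`).
#' @export
generate_panel <- function(n_haplotypes, n_blocks, snps_per_block,
                           within_block_r2 = 0.9, seed = 1,
                           chrom = "1", spacing_bp = 1000) {
  if (n_haplotypes < 50) {
    stop("need at least 50 haplotypes for stable r2", call. = FALSE)
  }
  if (!(within_block_r2 >= 0 && within_block_r2 <= 1)) {
    stop("within_block_r2 must be in [0, 1]", call. = FALSE)
  }
  e <- (1 - sqrt(within_block_r2)) / 2
  with_seed(seed, {
    cols <- list()
    ids <- character(0)
    block_of <- integer(0)
    for (b in seq_len(n_blocks)) {
      founder <- stats::rbinom(n_haplotypes, 1L, 0.5)
      for (s in seq_len(snps_per_block)) {
        x <- if (s == 1L) founder else {
          flip <- stats::rbinom(n_haplotypes, 1L, e)
          as.integer(xor(founder, flip))
        }
        if (all(x == x[1])) x[1] <- 1L - x[1]  # repair monomorphic draw
        cols[[length(cols) + 1L]] <- x
        ids <- c(ids, sprintf("b%d_s%d", b, s))
        block_of <- c(block_of, b)
      }
    }
    H <- do.call(cbind, cols)
    n_snps <- length(ids)
    pos <- integer(n_snps)
    cur <- 0L
    for (i in seq_len(n_snps)) {
      gap <- if (i > 1L && block_of[i] != block_of[i - 1L]) {
        10L * as.integer(spacing_bp)
      } else {
        as.integer(spacing_bp)
      }
      cur <- cur + gap
      pos[i] <- cur
    }
    list(
      panel = hap_panel(snp_id = ids, chrom = rep(chrom, n_snps),
                        pos = pos, H = H, ancestry = "synthetic"),
      truth = list(seed = seed, block = stats::setNames(block_of, ids),
                   flip_prob = e, target_r2 = within_block_r2)
    )
  })
}

#' Simulate case-control summary statistics under a liability-threshold model
#'
#' Individuals carry a liability `l = sum_j beta_j (g_j - 2 p_j) + eps` with
#' `eps ~ N(0, 1 - sum_j var_g_j)` and `var_g_j = 2 p_j (1-p_j) beta_j^2`,
#' and are cases iff `l > qnorm(1 - K)`. Sampling continues in batches until
#' the case and control quotas are met (ascertainment), up to an iteration
#' cap. Per-SNP odds ratios and P-values come from the 2x2 allele-count
#' table (Wald test on ln OR, with a Haldane 0.5 correction for zero
#' cells) — a deliberate simplification relative to logistic regression
#' that matches the scale the liability variance formula consumes.
#'
#' @param panel optional [hap_panel]; diploid genotypes are formed by
#'   pairing two haplotype rows sampled with replacement (no recombination).
#' @param freqs optional named vector of alternate-allele frequencies used
#'   instead of a panel (independent `Binomial(2, p)` genotypes); exactly
#'   one of `panel` / `freqs` must be given.
#' @param causal_betas per-SNP liability effects in liability-SD units per
#'   allele; a named vector (defaults to all zero) matched to SNP ids.
#' @param prevalence_K disease prevalence in (0, 1).
#' @param n_cases,n_controls sampling quotas (>= 100 recommended).
#' @param seed integer seed.
#' @param max_batches iteration cap; exceeded quotas raise a simulation
#'   error (e.g. K too small to fill the case quota).
#' @return data.frame (`SNP`, `EAF_cases`, `EAF_controls`, `EAF`, `OR`,
#'   `P`) with attribute `truth` (betas, prevalence, seed).
#' @export
simulate_case_control <- function(panel = NULL, freqs = NULL,
                                  causal_betas = NULL, prevalence_K = 0.15,
                                  n_cases = 1000, n_controls = 1000,
                                  seed = 1, max_batches = 200) {
  if (is.null(panel) == is.null(freqs)) {
    stop("supply exactly one of 'panel' or 'freqs'", call. = FALSE)
  }
  if (!(prevalence_K > 0 && prevalence_K < 1)) {
    stop("prevalence must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "hap_panel"))
    snp_ids <- panel$snps$snp
    p <- colMeans(panel$H)
  } else {
    snp_ids <- names(freqs)
    if (is.null(snp_ids)) snp_ids <- sprintf("snp%d", seq_along(freqs))
    p <- as.numeric(freqs)
    if (any(p <= 0 | p >= 1)) {
      stop("allele frequencies must be in (0, 1)", call. = FALSE)
    }
  }
  m <- length(snp_ids)
  beta <- .resolve_betas(snp_ids, causal_betas)
  var_g <- 2 * p * (1 - p) * beta^2
  if (sum(var_g) >= 1) {
    stop("planted liability variance must sum below 1", call. = FALSE)
  }
  resid_sd <- sqrt(1 - sum(var_g))
  thr <- stats::qnorm(1 - prevalence_K)

  with_seed(seed, {
    # batch size scales with the quotas (memory-bounded); the iteration cap
    # then limits the total sampling effort, so an extreme prevalence that
    # cannot fill its quota fails fast instead of looping forever
    batch_n <- min(20000L,
                   max(2000L, as.integer(ceiling(1.2 * (n_cases +
                                                          n_controls)))))
    case_counts <- matrix(0, nrow = 2, ncol = m)  # alt / total alleles
    ctrl_counts <- matrix(0, nrow = 2, ncol = m)
    got_cases <- 0L
    got_ctrls <- 0L
    for (b in seq_len(max_batches)) {
      if (got_cases >= n_cases && got_ctrls >= n_controls) break
      G <- .draw_genotypes(panel, p, batch_n)
      gen <- as.vector(sweep(G, 2, 2 * p) %*% beta)
      liab <- gen + stats::rnorm(batch_n, 0, resid_sd)
      is_case <- liab > thr
      take_case <- which(is_case)[seq_len(min(sum(is_case),
                                              n_cases - got_cases))]
      take_ctrl <- which(!is_case)[seq_len(min(sum(!is_case),
                                               n_controls - got_ctrls))]
      if (length(take_case)) {
        case_counts[1, ] <- case_counts[1, ] +
          colSums(G[take_case, , drop = FALSE])
        case_counts[2, ] <- case_counts[2, ] + 2 * length(take_case)
        got_cases <- got_cases + length(take_case)
      }
      if (length(take_ctrl)) {
        ctrl_counts[1, ] <- ctrl_counts[1, ] +
          colSums(G[take_ctrl, , drop = FALSE])
        ctrl_counts[2, ] <- ctrl_counts[2, ] + 2 * length(take_ctrl)
        got_ctrls <- got_ctrls + length(take_ctrl)
      }
    }
    if (got_cases < n_cases || got_ctrls < n_controls) {
      stop("simulation error: quotas not met within the iteration cap ",
           "(prevalence too extreme?)", call. = FALSE)
    }
    a1c <- case_counts[1, ]; a0c <- case_counts[2, ] - a1c
    a1t <- ctrl_counts[1, ]; a0t <- ctrl_counts[2, ] - a1t
    zero <- a1c == 0 | a0c == 0 | a1t == 0 | a0t == 0
    a1c[zero] <- a1c[zero] + 0.5; a0c[zero] <- a0c[zero] + 0.5
    a1t[zero] <- a1t[zero] + 0.5; a0t[zero] <- a0t[zero] + 0.5
    or_hat <- (a1c * a0t) / (a0c * a1t)
    se <- sqrt(1 / a1c + 1 / a0c + 1 / a1t + 1 / a0t)
    pval <- 2 * stats::pnorm(-abs(log(or_hat) / se))
    out <- data.frame(
      SNP = snp_ids,
      EAF_cases = case_counts[1, ] / case_counts[2, ],
      EAF_controls = ctrl_counts[1, ] / ctrl_counts[2, ],
      EAF = (case_counts[1, ] + ctrl_counts[1, ]) /
        (case_counts[2, ] + ctrl_counts[2, ]),
      OR = or_hat,
      P = pval,
      stringsAsFactors = FALSE
    )
    attr(out, "truth") <- list(betas = beta, var_g = var_g,
                               prevalence_K = prevalence_K, seed = seed)
    out
  })
}

#' Simulate cis-eQTL association records on a haplotype panel
#'
#' For each mapped gene, expression is `beta * dosage(causal SNP) + noise`
#' over `n_samples` diploid individuals (sequentially paired haplotypes
#' sampled with replacement); every panel SNP is then tested against each
#' gene by simple linear regression, yielding the (SNP, gene, P) records
#' that the sentinel-selection and target-linking steps consume. Gene TSSs
#' default to the causal SNP's position.
#'
#' @param panel a [hap_panel].
#' @param gene_map data.frame with columns `snp` (causal SNP id), `gene`,
#'   `beta` (expression SD per allele when `noise_sd = 1`), optional
#'   `gene_tss`.
#' @param n_samples number of diploid individuals (>= 50).
#' @param noise_sd residual expression SD (default 1).
#' @param seed integer seed.
#' @param study,tissue labels stamped on every record.
#' @return data.frame of eQTL records: `snp`, `gene`, `p`, `beta_hat`,
#'   `study`, `tissue`, `snp_pos`, `gene_tss`.
#' @export
simulate_eqtl <- function(panel, gene_map, n_samples = 200, noise_sd = 1,
                          seed = 1, study = "sim", tissue = "sim") {
  stopifnot(inherits(panel, "hap_panel"))
  if (n_samples < 50) stop("need n_samples >= 50", call. = FALSE)
  if (!all(c("snp", "gene", "beta") %in% names(gene_map))) {
    stop("gene_map needs columns snp, gene, beta", call. = FALSE)
  }
  if (!all(gene_map$snp %in% panel$snps$snp)) {
    stop("gene_map names SNP(s) absent from panel", call. = FALSE)
  }
  with_seed(seed, {
    G <- .draw_genotypes(panel, colMeans(panel$H), n_samples)
    out <- list()
    for (k in seq_len(nrow(gene_map))) {
      causal <- as.character(gene_map$snp[k])
      y <- gene_map$beta[k] * G[, causal] +
        stats::rnorm(n_samples, 0, noise_sd)
      tss <- if ("gene_tss" %in% names(gene_map) &&
                 !is.na(gene_map$gene_tss[k])) {
        gene_map$gene_tss[k]
      } else {
        panel$snps$pos[match(causal, panel$snps$snp)]
      }
      sdg <- apply(G, 2, stats::sd)
      r <- rep(NA_real_, ncol(G))
      ok <- sdg > 0
      r[ok] <- as.vector(stats::cor(y, G[, ok, drop = FALSE]))
      tstat <- r * sqrt((n_samples - 2) / pmax(1 - r^2, 1e-300))
      pv <- 2 * stats::pt(-abs(tstat), df = n_samples - 2)
      bhat <- r * stats::sd(y) / ifelse(ok, sdg, NA_real_)
      out[[k]] <- data.frame(
        snp = panel$snps$snp, gene = as.character(gene_map$gene[k]),
        p = pv, beta_hat = bhat, study = study, tissue = tissue,
        snp_pos = panel$snps$pos, gene_tss = tss,
        stringsAsFactors = FALSE
      )
    }
    res <- do.call(rbind, out)
    res[!is.na(res$p), , drop = FALSE]
  })
}
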