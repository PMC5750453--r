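#' Keep cis eQTL records only
#'
#' Retains records whose SNP lies within `window_bp` of the gene anchor
#' (inclusive boundary: a distance of exactly the window survives).
#'
#' @param records data.frame of eQTL associations with columns `snp`,
#'   `gene`, `p` and positions `snp_pos` and `gene_tss` (1-based bp).
#' @param window_bp cis window (default 1 Mb).
#' @return The filtered data.frame.
#' @export
cis_filter <- function(records, window_bp = 1e6) {
  need <- c("snp_pos", "gene_tss")
  if (!all(need %in% names(records))) {
    stop("records need columns 'snp_pos' and 'gene_tss'", call. = FALSE)
  }
  if (anyNA(records$snp_pos) || anyNA(records$gene_tss)) {
    stop("missing positions in eQTL records", call. = FALSE)
  }
  records[abs(records$snp_pos - records$gene_tss) <= window_bp, ,
          drop = FALSE]
}

#' Bonferroni significance filter for eQTL records
#'
#' Keeps records with `p < alpha / (n_genes * n_indep_snps)` (strict
#' inequality: a record exactly at the threshold is dropped). With the
#' defaults of 21472 genes and 1000 independent SNPs per gene the threshold
#' is 2.3e-9 to two significant figures.
#'
#' @param records data.frame with a `p` column.
#' @param n_genes number of genes tested (default 21472).
#' @param n_indep_snps assumed independent SNPs per gene (default 1000).
#' @param alpha family-wise error rate (default 0.05).
#' @return The filtered data.frame; the threshold is attached as attribute
#'   `threshold`.
#' @export
significance_filter <- function(records, n_genes = 21472,
                                n_indep_snps = 1000, alpha = 0.05) {
  if (n_genes < 1 || n_indep_snps < 1) {
    stop("n_genes and n_indep_snps must be >= 1", call. = FALSE)
  }
  thr <- bonferroni_alpha(alpha, n_genes * n_indep_snps)
  out <- records[records$p < thr, , drop = FALSE]
  attr(out, "threshold") <- thr
  out
}

#' Select sentinel eQTLs per study and gene
#'
#' Within each (study, gene) stratum, clumps the record SNPs at low r2 via
#' [greedy_clump()]; the clump index SNPs are the sentinels — the strongest
#' eQTLs that are approximately independent of each other. Records whose
#' SNP is absent from the panel are dropped with a warning.
#'
#' @param records cis- and significance-filtered eQTL data.frame (`snp`,
#'   `gene`, `p`, `study`, plus carried columns).
#' @param panel a [hap_panel].
#' @param r2_threshold independence threshold (default 0.05).
#' @param window_bp clump window passed to [greedy_clump()].
#' @return data.frame of sentinel records (subset of input rows).
#' @export
select_sentinels <- function(records, panel, r2_threshold = 0.05,
                             window_bp = 1e6) {
  if (nrow(records) == 0L) return(records)
  if (!all(c("snp", "gene", "p", "study") %in% names(records))) {
    stop("records need columns snp, gene, p, study", call. = FALSE)
  }
  key <- paste(records$study, records$gene, sep = "\r")
  keep <- logical(nrow(records))
  for (k in unique(key)) {
    idx <- which(key == k)
    grp <- records[idx, , drop = FALSE]
    # one row per SNP (best P) within the stratum before clumping
    grp_best <- grp[order(grp$p), , drop = FALSE]
    grp_best <- grp_best[!duplicated(grp_best$snp), , drop = FALSE]
    cl <- greedy_clump(data.frame(snp = grp_best$snp, p = grp_best$p),
                       panel, r2_threshold = r2_threshold,
                       window_bp = window_bp, missing = "drop")
    sent <- cl$index_snp
    for (s in sent) {
      cand <- idx[records$snp[idx] == s]
      keep[cand[which.min(records$p[cand])]] <- TRUE
    }
  }
  records[keep, , drop = FALSE]
}

#' Link GWAS risk variants to target genes through sentinel eQTLs
#'
#' For each (GWAS SNP, gene, study) combination, reports an assignment when
#' the maximal r2 between the GWAS SNP and any sentinel eQTL for that gene
#' and study exceeds `r2_min`; the sentinel of maximal r2 is reported, with
#' r2 ties broken by smaller eQTL P. Assignments are sorted by GWAS SNP and
#' then descending r2.
#'
#' @param gwas_snps character vector of risk-variant identifiers (clumped
#'   index SNPs and any declared correlated variants).
#' @param sentinels sentinel eQTL data.frame from [select_sentinels()].
#' @param panel a [hap_panel]; SNPs absent from it are skipped.
#' @param r2_min strong-LD threshold (default 0.8).
#' @return data.frame with `gwas_snp`, `sentinel_eqtl`, `r2`, `gene`,
#'   `study`, `tissue`, `eqtl_p`.
#' @export
link_targets <- function(gwas_snps, sentinels, panel, r2_min = 0.8) {
  out <- list()
  gwas_snps <- unique(as.character(gwas_snps))
  tissue <- if ("tissue" %in% names(sentinels)) sentinels$tissue else
    rep(NA_character_, nrow(sentinels))
  for (g in gwas_snps) {
    if (!(g %in% panel$snps$snp)) next
    key <- paste(sentinels$gene, sentinels$study, sep = "\r")
    for (k in unique(key)) {
      idx <- which(key == k)
      r2s <- vapply(idx, function(i) {
        s <- sentinels$snp[i]
        if (!(s %in% panel$snps$snp)) return(NA_real_)
        tryCatch(pairwise_r2(panel, g, s), error = function(e) NA_real_)
      }, numeric(1))
      ok <- which(!is.na(r2s) & r2s > r2_min)
      if (length(ok) == 0L) next
      best <- ok[order(-r2s[ok], sentinels$p[idx[ok]])][1]
      i <- idx[best]
      out[[length(out) + 1L]] <- data.frame(
        gwas_snp = g, sentinel_eqtl = sentinels$snp[i], r2 = r2s[best],
        gene = sentinels$gene[i], study = sentinels$study[i],
        tissue = tissue[i], eqtl_p = sentinels$p[i],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gwas_snp = character(), sentinel_eqtl = character(),
                      r2 = numeric(), gene = character(), study = character(),
                      tissue = character(), eqtl_p = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$gwas_snp, -res$r2), , drop = FALSE]
}

#' Distinct target genes across assignments
#'
#' @param assignments data.frame with a `gene` column (e.g. from
#'   [link_targets()] or the bundled published-assignment table).
#' @return List with `n` (count of unique genes) and `genes` (sorted
#'   character vector).
#' @export
distinct_genes <- function(assignments) {
  col <- intersect(c("gene", "GENE"), names(assignments))
  if (length(col) == 0L) {
    stop("assignments need a 'gene' column", call. = FALSE)
  }
  genes <- sort(unique(as.character(assignments[[col[1]]])))
  list(n = length(genes), genes = genes)
}
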