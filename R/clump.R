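#' Greedy P-value-ordered LD clumping
#'
#' PLINK-style clumping: variants are processed in ascending P order; each
#' still-unassigned variant becomes a clump index and absorbs every remaining
#' unassigned variant on the same chromosome within `window_bp` whose r2 with
#' the index exceeds `r2_threshold`. Every variant ends up in exactly one
#' clump. Equal-P ties are broken by (chrom, pos, id) so the result is
#' deterministic.
#'
#' @param variants data.frame with columns `snp` and `p` (P-values in (0, 1]).
#' @param panel a [hap_panel] supplying LD and coordinates.
#' @param r2_threshold r2 above which a variant joins the index's clump;
#'   in (0, 1). The published analysis used 0.05.
#' @param window_bp half-window in base pairs around the index (default 1 Mb
#'   each side).
#' @param missing policy for variants absent from the panel: `"drop"`
#'   (default, with a warning) or `"error"`.
#' @return data.frame of class `clump_set`, one row per clump: `index_snp`,
#'   `chrom`, `pos`, `index_p`, `n_members`, `members` (comma-joined,
#'   including the index).
#' @export
greedy_clump <- function(variants, panel, r2_threshold = 0.05,
                         window_bp = 1e6, missing = c("drop", "error")) {
  missing <- match.arg(missing)
  stopifnot(inherits(panel, "hap_panel"))
  if (!all(c("snp", "p") %in% names(variants))) {
    stop("variants needs columns 'snp' and 'p'", call. = FALSE)
  }
  if (!(r2_threshold > 0 && r2_threshold < 1)) {
    stop("r2_threshold must be in (0, 1)", call. = FALSE)
  }
  if (any(variants$p <= 0 | variants$p > 1)) {
    stop("P-values must be in (0, 1]", call. = FALSE)
  }
  v <- data.frame(snp = as.character(variants$snp), p = variants$p,
                  stringsAsFactors = FALSE)
  absent <- !(v$snp %in% panel$snps$snp)
  if (any(absent)) {
    if (missing == "error") {
      stop("variant(s) absent from panel: ",
           paste(v$snp[absent], collapse = ", "), call. = FALSE)
    }
    warning(sum(absent), " variant(s) absent from panel, dropped: ",
            paste(v$snp[absent], collapse = ", "), call. = FALSE)
    v <- v[!absent, , drop = FALSE]
  }
  if (nrow(v) == 0L) {
    return(.empty_clump_set())
  }
  m <- match(v$snp, panel$snps$snp)
  v$chrom <- panel$snps$chrom[m]
  v$pos <- panel$snps$pos[m]
  v <- v[order(v$p, v$chrom, v$pos, v$snp), , drop = FALSE]

  assigned <- rep(FALSE, nrow(v))
  out <- vector("list", nrow(v))
  k <- 0L
  for (i in seq_len(nrow(v))) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    members <- v$snp[i]
    cand <- which(!assigned &
                    v$chrom == v$chrom[i] &
                    abs(v$pos - v$pos[i]) <= window_bp)
    for (j in cand) {
      if (pairwise_r2(panel, v$snp[i], v$snp[j]) > r2_threshold) {
        assigned[j] <- TRUE
        members <- c(members, v$snp[j])
      }
    }
    k <- k + 1L
    out[[k]] <- data.frame(
      index_snp = v$snp[i], chrom = v$chrom[i], pos = v$pos[i],
      index_p = v$p[i], n_members = length(members),
      members = paste(members, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[seq_len(k)])
  class(res) <- c("clump_set", "data.frame")
  res
}

.empty_clump_set <- function() {
  res <- data.frame(index_snp = character(), chrom = character(),
                    pos = integer(), index_p = numeric(),
                    n_members = integer(), members = character(),
                    stringsAsFactors = FALSE)
  class(res) <- c("clump_set", "data.frame")
  res
}

#' Clump members as a list
#'
#' @param clumps a `clump_set` from [greedy_clump()].
#' @return Named list (by index SNP) of member identifier vectors.
#' @export
clump_members <- function(clumps) {
  stats::setNames(strsplit(clumps$members, ",", fixed = TRUE),
                  clumps$index_snp)
}

#' Best LD proxy for a target SNP
#'
#' Among `candidates`, returns the one with maximal r2 to `target` provided
#' that r2 >= `r2_min`; ties are broken by smaller base-pair distance, then
#' lexicographic identifier. Used when a reported variant is absent from a
#' replication dataset and a correlated stand-in must be found.
#'
#' @param target SNP identifier present in the panel.
#' @param candidates character vector of candidate identifiers (absent or
#'   monomorphic candidates are skipped); may include the target itself.
#' @param panel a [hap_panel].
#' @param r2_min minimum acceptable r2 (the published analysis accepted a
#'   proxy at 0.75 while calling r2 > 0.8 "strong LD"; default 0.8).
#' @return `NULL` if no candidate qualifies, else a list with `snp`, `r2`,
#'   and `r_sign` (sign of the haplotype correlation between the alternate
#'   alleles of target and proxy, needed to orient effect directions).
#' @export
best_proxy <- function(target, candidates, panel, r2_min = 0.8) {
  stopifnot(inherits(panel, "hap_panel"))
  candidates <- unique(as.character(candidates))
  candidates <- candidates[candidates %in% panel$snps$snp]
  if (length(candidates) == 0L) return(NULL)
  t_pos <- panel$snps$pos[match(target, panel$snps$snp)]
  rs <- vapply(candidates, function(s) {
    tryCatch(ld_r(panel, target, s), error = function(e) NA_real_)
  }, numeric(1))
  ok <- !is.na(rs) & rs^2 >= r2_min
  if (!any(ok)) return(NULL)
  cand <- data.frame(snp = candidates[ok], r = rs[ok],
                     stringsAsFactors = FALSE)
  cand$r2 <- cand$r^2
  cand$dist <- abs(panel$snps$pos[match(cand$snp, panel$snps$snp)] - t_pos)
  cand <- cand[order(-cand$r2, cand$dist, cand$snp), , drop = FALSE]
  list(snp = cand$snp[1], r2 = cand$r2[1], r_sign = sign(cand$r[1]))
}

#' Write a clump report TSV
#'
#' @param clumps a `clump_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clump_report <- function(clumps, path) {
  utils::write.table(as.data.frame(clumps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
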