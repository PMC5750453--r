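#' Haplotype reference panel
#'
#' A `hap_panel` holds a haplotype-by-SNP matrix of 0/1 alternate-allele
#' indicators together with per-SNP metadata. It is the sole source of
#' linkage disequilibrium in the package: all r2 values are computed from
#' phased haplotypes, never from unphased genotype correlation.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chrom chromosome label per SNP.
#' @param pos 1-based base-pair coordinate per SNP; must be non-decreasing
#'   within each chromosome.
#' @param H integer/numeric matrix (haplotypes x SNPs) of 0/1 allele
#'   indicators; no missing values. Column order matches `snp_id`.
#' @param ref,alt reference / alternate allele per SNP (defaults "A"/"G"
#'   for synthetic panels).
#' @param ancestry free-text ancestry label.
#'
#' @return An object of class `hap_panel`: a list with elements `snps`
#'   (data.frame: snp, chrom, pos, ref, alt) and `H` (matrix with SNP ids as
#'   column names), plus an `ancestry` attribute.
#' @export
hap_panel <- function(snp_id, chrom, pos, H,
                      ref = rep("A", length(snp_id)),
                      alt = rep("G", length(snp_id)),
                      ancestry = "synthetic") {
  snp_id <- as.character(snp_id)
  if (anyDuplicated(snp_id)) {
    stop("duplicate SNP identifiers in panel", call. = FALSE)
  }
  H <- as.matrix(H)
  if (ncol(H) != length(snp_id)) {
    stop("H must have one column per SNP", call. = FALSE)
  }
  if (nrow(H) < 2) {
    stop("a haplotype panel needs at least 2 haplotypes", call. = FALSE)
  }
  if (anyNA(H) || !all(H %in% c(0L, 1L))) {
    stop("haplotype matrix entries must be 0 or 1 with no missing values",
         call. = FALSE)
  }
  storage.mode(H) <- "integer"
  colnames(H) <- snp_id
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p)) {
      stop("positions must be non-decreasing within chromosome ", ch,
           call. = FALSE)
    }
  }
  structure(
    list(
      snps = data.frame(snp = snp_id, chrom = chrom, pos = pos,
                        ref = as.character(ref), alt = as.character(alt),
                        stringsAsFactors = FALSE),
      H = H,
      ancestry = ancestry
    ),
    class = "hap_panel"
  )
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("hap_panel: %d haplotypes x %d SNPs (%s)\n",
              nrow(x$H), ncol(x$H), x$ancestry))
  cat(sprintf("chromosomes: %s\n",
              paste(unique(x$snps$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.hap_panel <- function(x) dim(x$H)

.panel_col <- function(panel, snp) {
  j <- match(snp, colnames(panel$H))
  if (is.na(j)) {
    stop("SNP '", snp, "' not found in panel", call. = FALSE)
  }
  panel$H[, j]
}

#' Alternate-allele frequency of a panel SNP
#'
#' @param panel a [hap_panel].
#' @param snp SNP identifier.
#' @return Frequency in \[0, 1\] of the alternate (counted) allele.
#' @export
allele_freq <- function(panel, snp) {
  stopifnot(inherits(panel, "hap_panel"))
  mean(.panel_col(panel, snp))
}

# Signed haplotype correlation between the alt alleles of two SNPs.
# Errors on monomorphic input: LD is undefined there, not zero.
ld_r <- function(panel, a, b) {
  xa <- .panel_col(panel, a)
  xb <- .panel_col(panel, b)
  pa <- mean(xa)
  pb <- mean(xb)
  if (pa <= 0 || pa >= 1) {
    stop("LD undefined: SNP '", a, "' is monomorphic in panel", call. = FALSE)
  }
  if (pb <= 0 || pb >= 1) {
    stop("LD undefined: SNP '", b, "' is monomorphic in panel", call. = FALSE)
  }
  pab <- mean(xa * xb)
  (pab - pa * pb) / sqrt(pa * (1 - pa) * pb * (1 - pb))
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared haplotype correlation between two panel SNPs:
#' r2 = (p_ab - p_a p_b)^2 / (p_a(1-p_a) p_b(1-p_b)), where p_ab is the
#' frequency of haplotypes carrying the alternate allele at both sites.
#' Symmetric in its arguments.
#'
#' @inheritParams allele_freq
#' @param a,b SNP identifiers; both must be polymorphic in the panel.
#' @return r2 in \[0, 1\].
#' @export
pairwise_r2 <- function(panel, a, b) {
  stopifnot(inherits(panel, "hap_panel"))
  ld_r(panel, a, b)^2
}

#' Read a haplotype panel from a phased VCF
#'
#' Parses phased GT fields into one column pair of haplotypes per sample.
#' Sites with missing or unphased genotypes, or with more than one ALT
#' allele, are dropped with a warning by default.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param on_bad `"drop"` (default) drops offending sites with a warning;
#'   `"error"` aborts.
#' @param ancestry ancestry label stored on the panel.
#' @return A [hap_panel].
#' @export
read_panel_vcf <- function(path, on_bad = c("drop", "error"),
                           ancestry = basename(path)) {
  on_bad <- match.arg(on_bad)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  ok_site <- !grepl(",", fix$ALT) & fix$ALT != "." &
    apply(gt, 1, function(g) all(grepl("^[01]\\|[01]$", g)))
  if (!all(ok_site)) {
    msg <- sprintf("%d site(s) with missing/unphased/multiallelic genotypes",
                   sum(!ok_site))
    if (on_bad == "error") stop(msg, call. = FALSE)
    warning(msg, ": dropped", call. = FALSE)
    gt <- gt[ok_site, , drop = FALSE]
    fix <- fix[ok_site, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no usable sites in VCF", call. = FALSE)
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix$CHROM[no_id], ":", fix$POS[no_id])
  # one row per haplotype: sample1.hap1, sample1.hap2, sample2.hap1, ...
  hap1 <- substr(gt, 1, 1)
  hap2 <- substr(gt, 3, 3)
  H <- matrix(0L, nrow = 2L * ncol(gt), ncol = nrow(gt))
  H[seq(1L, nrow(H), by = 2L), ] <- t(matrix(as.integer(hap1), nrow = nrow(gt)))
  H[seq(2L, nrow(H), by = 2L), ] <- t(matrix(as.integer(hap2), nrow = nrow(gt)))
  hap_panel(snp_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
            H = H, ref = fix$REF, alt = fix$ALT, ancestry = ancestry)
}

#' Write a haplotype panel as a phased VCF
#'
#' Haplotypes are paired sequentially into diploid samples (hap 1+2 form
#' sample 1, and so on); an odd trailing haplotype is dropped with a warning.
#' Round-trips through [read_panel_vcf()].
#'
#' @param panel a [hap_panel].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "hap_panel"))
  n_hap <- nrow(panel$H)
  if (n_hap %% 2L == 1L) {
    warning("odd number of haplotypes: last one dropped in VCF output",
            call. = FALSE)
    n_hap <- n_hap - 1L
  }
  i1 <- seq(1L, n_hap, by = 2L)
  gt <- matrix(paste0(t(panel$H[i1, , drop = FALSE]),
                      "|",
                      t(panel$H[i1 + 1L, , drop = FALSE])),
               nrow = ncol(panel$H))
  samples <- sprintf("S%04d", seq_len(n_hap / 2L))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=postgwas",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(panel$snps$chrom, panel$snps$pos, panel$snps$snp,
                panel$snps$ref, panel$snps$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a haplotype panel from hap/legend text files
#'
#' The legend file has a header row `id chrom pos ref alt`; the hap file has
#' one space-separated row of 0/1 per haplotype (columns = legend rows).
#'
#' @param hap_path,legend_path paths to the two files.
#' @param ancestry ancestry label.
#' @return A [hap_panel].
#' @export
read_hap_legend <- function(hap_path, legend_path,
                            ancestry = basename(hap_path)) {
  leg <- utils::read.table(legend_path, header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(need, names(leg))
  if (length(missing_cols)) {
    stop("legend file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  H <- as.matrix(utils::read.table(hap_path, header = FALSE))
  if (ncol(H) != nrow(leg)) {
    stop("hap file has ", ncol(H), " columns but legend describes ",
         nrow(leg), " SNPs", call. = FALSE)
  }
  hap_panel(snp_id = leg$id, chrom = leg$chrom, pos = leg$pos, H = H,
            ref = leg$ref, alt = leg$alt, ancestry = ancestry)
}

#' Write a haplotype panel as hap/legend text files
#'
#' @inheritParams write_panel_vcf
#' @param hap_path,legend_path output paths.
#' @return `hap_path`, invisibly.
#' @export
write_hap_legend <- function(panel, hap_path, legend_path) {
  stopifnot(inherits(panel, "hap_panel"))
  leg <- panel$snps
  names(leg)[names(leg) == "snp"] <- "id"
  utils::write.table(leg, legend_path, sep = " ", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(panel$H, hap_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(hap_path)
}
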