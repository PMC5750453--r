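#' Liability-scale variance explained by one variant
#'
#' For a biallelic variant with effect-allele frequency `p` and per-allele
#' odds ratio `OR`, the contribution to the variance of the (logistic)
#' disease liability is `var(g) = 2 p (1 - p) (ln OR)^2`. The value is
#' invariant under the allele flip (p -> 1 - p, OR -> 1/OR), so the minor
#' allele frequency may be supplied in place of the effect-allele frequency.
#'
#' @param eaf effect-allele frequency, strictly inside (0, 1); vectorised.
#' @param or odds ratio per effect allele, > 0; vectorised.
#' @return `var_g`, the liability-variance contribution (unitless).
#' @export
variance_explained <- function(eaf, or) {
  if (any(!is.finite(eaf)) || any(eaf <= 0 | eaf >= 1)) {
    stop("effect-allele frequency must be in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(or)) || any(or <= 0)) {
    stop("odds ratio must be > 0", call. = FALSE)
  }
  2 * eaf * (1 - eaf) * log(or)^2
}

#' Per-variant SNP heritability on the liability scale
#'
#' Converts a liability-variance contribution into a proportion of total
#' liability variance under the logistic liability model, whose residual
#' variance is pi^2/3: `h2 = var_g / (var_g + pi^2/3)`. Monotone increasing
#' in `var_g` and strictly below 1.
#'
#' @param var_g non-negative liability-variance contribution; vectorised.
#' @return `h2` in \[0, 1).
#' @export
snp_h2 <- function(var_g) {
  if (any(!is.finite(var_g)) || any(var_g < 0)) {
    stop("var_g must be non-negative", call. = FALSE)
  }
  var_g / (var_g + pi^2 / 3)
}

#' Liability heritability accounting over a set of reported variants
#'
#' Computes per-variant `var_g` and `h2` from the `EAF` and `OR` columns and
#' summarises the set: the total (sum) and the median of the per-variant h2,
#' both in percent. The per-variant table preserves input order.
#'
#' @param variants data.frame of risk variants with columns `EAF` and `OR`
#'   (the dialect of [read_sumstats()]); an `SNP` column is carried through
#'   when present.
#' @return List with `per_variant` (data.frame adding `VAR_G`, `H2`,
#'   `H2_PCT`), `total_pct` and `median_pct` (raw, unrounded percents).
#' @export
summarize_h2 <- function(variants) {
  if (!is.data.frame(variants) || nrow(variants) == 0L) {
    stop("variants must be a non-empty data.frame", call. = FALSE)
  }
  if (!all(c("EAF", "OR") %in% names(variants))) {
    stop("variants needs columns 'EAF' and 'OR'", call. = FALSE)
  }
  var_g <- variance_explained(variants$EAF, variants$OR)
  h2 <- snp_h2(var_g)
  per <- variants
  per$VAR_G <- var_g
  per$H2 <- h2
  per$H2_PCT <- 100 * h2
  list(per_variant = per,
       total_pct = sum(per$H2_PCT),
       median_pct = stats::median(per$H2_PCT))
}

#' Heritability remaining to be discovered
#'
#' Difference between a cohort-level SNP-based heritability estimate and the
#' part already explained by reported variants, floored at zero (a negative
#' difference signals inconsistent inputs and triggers a warning).
#'
#' @param snp_based_h2_pct genome-wide SNP-based heritability, percent, >= 0.
#' @param explained_pct heritability explained by known variants, percent,
#'   >= 0.
#' @return Remaining heritability in percent.
#' @export
remaining_h2 <- function(snp_based_h2_pct, explained_pct) {
  if (snp_based_h2_pct < 0 || explained_pct < 0) {
    stop("heritability percentages must be non-negative", call. = FALSE)
  }
  d <- snp_based_h2_pct - explained_pct
  if (d < 0) {
    warning("explained heritability exceeds the SNP-based total; ",
            "remaining floored at 0", call. = FALSE)
    d <- 0
  }
  d
}
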