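#' Case-control study design for power comparison
#'
#' @param n_cases,n_controls sample counts, >= 1.
#' @param prevalence_K lifetime disease prevalence in (0, 1).
#' @param snp_h2_liab liability-scale variance explained by the test SNP,
#'   in \[0, 1).
#' @param label free-text design label.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_cases, n_controls, prevalence_K,
                         snp_h2_liab = 0.0005, label = "") {
  if (n_cases < 1 || n_controls < 1) {
    stop("n_cases and n_controls must be >= 1", call. = FALSE)
  }
  if (!(prevalence_K > 0 && prevalence_K < 1)) {
    stop("prevalence must be in (0, 1)", call. = FALSE)
  }
  if (!(snp_h2_liab >= 0 && snp_h2_liab < 1)) {
    stop("SNP liability h2 must be in [0, 1)", call. = FALSE)
  }
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 prevalence_K = prevalence_K, snp_h2_liab = snp_h2_liab,
                 label = label),
            class = "study_design")
}

#' Standard-normal density at the liability threshold
#'
#' Height of the standard-normal density at the upper-K quantile, i.e.
#' `z = phi(Phi^-1(1 - K))` for prevalence K. This truncation ordinate
#' drives the liability-to-observed-scale transformation.
#'
#' @param K prevalence in (0, 1); vectorised.
#' @return `z`, the density at the threshold.
#' @export
truncation_z <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0 | K >= 1)) {
    stop("prevalence K must be in (0, 1)", call. = FALSE)
  }
  stats::dnorm(stats::qnorm(1 - K))
}

#' Liability-scale to observed-scale variance conversion under ascertainment
#'
#' Converts a SNP's liability-scale variance explained into the observed
#' (0/1 case-control) scale in an ascertained sample with case fraction P:
#' `h2_obs = h2_liab * z^2 * P(1-P) / (K(1-K))^2`, with `z = truncation_z(K)`.
#' This is the ascertainment-corrected transformation of the
#' liability-threshold model; the chi-square non-centrality of the
#' association test is `N * h2_obs`.
#'
#' @param h2_liab liability-scale variance explained, in \[0, 1).
#' @param K disease prevalence in (0, 1).
#' @param case_fraction_P proportion of cases in the sample, in (0, 1).
#' @return Observed-scale variance explained.
#' @export
liab_to_observed_h2 <- function(h2_liab, K, case_fraction_P) {
  if (any(h2_liab < 0 | h2_liab >= 1)) {
    stop("h2_liab must be in [0, 1)", call. = FALSE)
  }
  if (any(case_fraction_P <= 0 | case_fraction_P >= 1)) {
    stop("case fraction must be in (0, 1)", call. = FALSE)
  }
  z <- truncation_z(K)
  h2_liab * z^2 * case_fraction_P * (1 - case_fraction_P) /
    (K * (1 - K))^2
}

#' Non-centrality parameter for a case-control association test
#'
#' Expected non-centrality of the 1-df chi-square association statistic for
#' a SNP explaining `snp_h2_liab` of liability variance, in a study of the
#' given size, prevalence and (implied) case fraction. Linear in total N at
#' fixed K, P and h2.
#'
#' @param design a [study_design()].
#' @return List of class `power_result` with `ncp`, plus the pieces
#'   (`n_total`, `case_fraction`, `h2_obs`).
#' @export
ncp <- function(design) {
  stopifnot(inherits(design, "study_design"))
  n <- design$n_cases + design$n_controls
  P <- design$n_cases / n
  h2o <- liab_to_observed_h2(design$snp_h2_liab, design$prevalence_K, P)
  structure(list(ncp = n * h2o, n_total = n, case_fraction = P,
                 h2_obs = h2o, label = design$label),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("NCP = %.2f (N = %d, case fraction = %.3f)\n",
              x$ncp, x$n_total, x$case_fraction))
  invisible(x)
}

#' Detection power from a non-centrality parameter
#'
#' Probability that a noncentral chi-square(1, ncp) statistic exceeds the
#' central chi-square(1) critical value at level `alpha`.
#'
#' @param ncp non-negative non-centrality; vectorised.
#' @param alpha significance level in (0, 1).
#' @return Power in \[alpha, 1\].
#' @export
power_from_ncp <- function(ncp, alpha = 5e-8) {
  if (any(ncp < 0)) stop("ncp must be non-negative", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  crit <- stats::qchisq(alpha, df = 1, lower.tail = FALSE)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Fold difference in NCP between two designs
#'
#' Ratio ncp(a) / ncp(b) for the same per-SNP liability h2; used to compare
#' the effective power of GWAS of diseases with different prevalences.
#'
#' @param design_a,design_b [study_design()] objects.
#' @return The ratio (a over b).
#' @export
ncp_fold <- function(design_a, design_b) {
  nb <- ncp(design_b)$ncp
  if (nb <= 0) {
    stop("denominator design has zero NCP", call. = FALSE)
  }
  ncp(design_a)$ncp / nb
}

#' NCP table for a batch of designs
#'
#' @param designs data.frame with columns `label`, `n_cases`, `n_controls`,
#'   `prevalence` (proportions or percent-style values > 1 are rejected).
#' @param snp_h2_liab shared per-SNP liability h2 (default 0.0005, i.e.
#'   0.05%).
#' @return The input with columns `n_total` and `ncp` appended.
#' @export
ncp_table <- function(designs, snp_h2_liab = 0.0005) {
  need <- c("label", "n_cases", "n_controls", "prevalence")
  if (!all(need %in% names(designs))) {
    stop("designs needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  designs$n_total <- designs$n_cases + designs$n_controls
  designs$ncp <- vapply(seq_len(nrow(designs)), function(i) {
    ncp(study_design(designs$n_cases[i], designs$n_controls[i],
                     designs$prevalence[i], snp_h2_liab,
                     designs$label[i]))$ncp
  }, numeric(1))
  designs
}
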