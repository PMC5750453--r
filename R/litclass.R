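#' Classify a gene by literature co-citation history
#'
#' Three-group scheme based on counts of publications co-mentioning the gene
#' (or an alias) and allergy-related terms before and since a cutoff year:
#' group 1 if frequently co-cited (`n_before >= min_count`) before the
#' cutoff, else group 2 if frequently co-cited since (`n_since >=
#' min_count`), else group 3. Group 1 takes precedence, so an established
#' gene with few recent co-citations stays in group 1.
#'
#' @param n_before,n_since non-negative integer co-citation counts before /
#'   since the cutoff year; vectorised.
#' @param min_count "frequently" threshold (default 5, read as >= 5).
#' @return Integer group labels in \{1, 2, 3\}.
#' @export
classify_citation <- function(n_before, n_since, min_count = 5) {
  if (min_count < 1) stop("min_count must be >= 1", call. = FALSE)
  if (any(n_before < 0) || any(n_since < 0)) {
    stop("citation counts must be non-negative", call. = FALSE)
  }
  ifelse(n_before >= min_count, 1L,
         ifelse(n_since >= min_count, 2L, 3L))
}

#' Literature-group sizes over a gene table
#'
#' @param records data.frame with columns `GENE`, `N_BEFORE`, `N_SINCE`.
#' @param min_count passed to [classify_citation()].
#' @return List with `sizes` (named integer vector n1/n2/n3) and `table`
#'   (the input with a `GROUP` column appended).
#' @export
group_sizes <- function(records, min_count = 5) {
  need <- c("GENE", "N_BEFORE", "N_SINCE")
  if (!all(need %in% names(records))) {
    stop("records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(records$GENE)) {
    stop("duplicate gene in citation table: ",
         paste(unique(records$GENE[duplicated(records$GENE)]),
               collapse = ", "), call. = FALSE)
  }
  grp <- classify_citation(records$N_BEFORE, records$N_SINCE, min_count)
  records$GROUP <- grp
  list(
    sizes = c(n1 = sum(grp == 1L), n2 = sum(grp == 2L), n3 = sum(grp == 3L)),
    table = records
  )
}
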