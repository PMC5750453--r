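#' Read a summary-statistics table
#'
#' Canonical dialect: tab-separated with header `SNP, CHR, BP, EA, OA, EAF,
#' OR, P` (optionally `PMID` and extra columns), `.` for missing. Rows
#' failing validation (OR <= 0, P outside (0, 1], EAF outside (0, 1)) are
#' excluded and collected into an error report attached as attribute
#' `errors` — never silently dropped.
#'
#' @param path input file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return data.frame of validated records, with attribute `errors`
#'   (data.frame: row, reason), possibly empty.
#' @export
read_sumstats <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep, na.strings = ".",
                         stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- c("SNP", "EA", "OR", "P")
  miss <- setdiff(mandatory, names(d))
  if (length(miss)) {
    stop("format error: missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("EAF", "OR", "P")) {
    if (col %in% names(d)) d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  }
  bad <- character(nrow(d))
  bad[!is.na(d$OR) & d$OR <= 0] <- "OR <= 0"
  bad[is.na(d$OR)] <- "missing OR"
  bad[!is.na(d$P) & (d$P <= 0 | d$P > 1)] <- "P outside (0, 1]"
  bad[is.na(d$P)] <- "missing P"
  if ("EAF" %in% names(d)) {
    bad[!is.na(d$EAF) & (d$EAF <= 0 | d$EAF >= 1)] <- "EAF outside (0, 1)"
  }
  errors <- data.frame(row = which(bad != ""), reason = bad[bad != ""],
                       stringsAsFactors = FALSE)
  out <- d[bad == "", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

#' Write a summary-statistics table, optionally with liability columns
#'
#' @param d data.frame in the [read_sumstats()] dialect.
#' @param path output path.
#' @param add_h2 if `TRUE`, appends `VAR_G` and `H2_PCT` columns computed
#'   from `EAF` and `OR`.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(d, path, add_h2 = FALSE) {
  if (add_h2) {
    d$VAR_G <- variance_explained(d$EAF, d$OR)
    d$H2_PCT <- 100 * snp_h2(d$VAR_G)
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every named analysis constant in one place. Defaults are the
#' published values: clumping independence at r2 0.05, strong LD at r2 0.8,
#' family-wise alpha 0.05, 1 Mb cis window, 21472 genes x 1000 independent
#' SNPs for the eQTL Bonferroni correction, citation threshold 5 at cutoff
#' year 2007, LD Score intercept 1.073, per-SNP liability h2 of 0.05% for
#' power comparison, and a genome-wide SNP-based heritability of 14%.
#'
#' @param ... overrides for any default field.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    clump_r2 = 0.05,
    strong_ld_r2 = 0.8,
    alpha = 0.05,
    cis_window = 1e6,
    eqtl_gene_count = 21472,
    eqtl_indep_snps = 1000,
    min_citations = 5,
    cutoff_year = 2007,
    ld_intercept = 1.073,
    proxy_r2_min = 0.75,
    power_snp_h2 = 5e-4,
    snp_based_h2_pct = 14,
    replication_p_adjusted = TRUE,
    clump_window_bp = 1e6,
    seed = 1,
    out_dir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  .validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

.validate_config <- function(cfg) {
  stopifnot(
    cfg$clump_r2 > 0, cfg$clump_r2 < 1,
    cfg$strong_ld_r2 > 0, cfg$strong_ld_r2 < 1,
    cfg$alpha > 0, cfg$alpha < 1,
    cfg$cis_window > 0,
    cfg$eqtl_gene_count >= 1, cfg$eqtl_indep_snps >= 1,
    cfg$min_citations >= 1,
    cfg$ld_intercept > 0,
    cfg$power_snp_h2 >= 0, cfg$power_snp_h2 < 1,
    cfg$snp_based_h2_pct >= 0
  )
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' Configurations round-trip unchanged through serialization.
#'
#' @param path YAML file path.
#' @return [read_config()] returns a `pipeline_config`;
#'   [write_config()] returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full interpretation pipeline on the bundled tables
#'
#' Orchestrates the analysis stages in order: direction-aware Bonferroni
#' replication assessment of the reported variants, liability-scale
#' heritability accounting, NCP power comparison across designs,
#' distinct-target-gene count over the sentinel-eQTL assignments, and
#' citation-count gene classification. Every threshold actually applied is
#' logged via `message()` and echoed in the returned headline list. When
#' `config$out_dir` is set, per-stage TSV/JSON reports are written there.
#'
#' @param config a [pipeline_config()].
#' @param tables list of input tables in the shape of [asthma_fixtures()]
#'   (the default).
#' @return List with `headline` (key numbers: `n_tested`, `n_significant`,
#'   `pct_significant`, `total_h2_pct`, `median_h2_pct`,
#'   `remaining_h2_pct`, `ncp` named vector, `ncp_fold_scz_vs_asthma`,
#'   `n_target_genes`, `group_sizes`, `thresholds`) and the per-stage
#'   results (`replication`, `h2`, `power`, `targets`, `literature`).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         tables = asthma_fixtures()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  intercept <- if (isTRUE(config$replication_p_adjusted)) 1 else
    config$ld_intercept
  message(sprintf(
    "replication: alpha=%g over m=%d tests (threshold %.2g), intercept=%g",
    config$alpha, nrow(tables$table1),
    config$alpha / nrow(tables$table1), intercept))
  repl <- stage("replication", assess_replication(
    tables$table1, tables$table2, alpha = config$alpha,
    intercept = intercept, proxies = tables$proxies,
    proxy_r2_min = config$proxy_r2_min))

  message("liability accounting: h2 = var_g / (var_g + pi^2/3)")
  h2 <- stage("liability", summarize_h2(tables$table2))
  remaining <- remaining_h2(config$snp_based_h2_pct, h2$total_pct)

  message(sprintf("power: per-SNP liability h2 = %g", config$power_snp_h2))
  pow <- stage("power", {
    designs <- data.frame(label = tables$table3$LABEL,
                          n_cases = tables$table3$N_CASES,
                          n_controls = tables$table3$N_CONTROLS,
                          prevalence = tables$table3$PREVALENCE,
                          stringsAsFactors = FALSE)
    ncp_table(designs, snp_h2_liab = config$power_snp_h2)
  })
  scz <- match("Schizophrenia", pow$label)
  ast <- match("Asthma", pow$label)
  fold <- if (!is.na(scz) && !is.na(ast)) pow$ncp[scz] / pow$ncp[ast] else NA

  message(sprintf("target genes: strong LD r2 > %g, eQTL threshold %.2g",
                  config$strong_ld_r2,
                  config$alpha /
                    (config$eqtl_gene_count * config$eqtl_indep_snps)))
  targets <- stage("targets", distinct_genes(tables$table4))

  message(sprintf("literature: >= %d co-citations, cutoff year %d",
                  config$min_citations, config$cutoff_year))
  lit <- stage("literature", group_sizes(tables$table5,
                                         min_count = config$min_citations))

  headline <- list(
    n_tested = repl$summary$n_tested,
    n_significant = repl$summary$n_significant,
    pct_significant = repl$summary$pct_significant,
    total_h2_pct = h2$total_pct,
    median_h2_pct = h2$median_pct,
    remaining_h2_pct = remaining,
    ncp = stats::setNames(pow$ncp, pow$label),
    ncp_fold_scz_vs_asthma = fold,
    n_target_genes = targets$n,
    group_sizes = lit$sizes,
    thresholds = list(
      replication_p = repl$summary$threshold,
      eqtl_p = config$alpha /
        (config$eqtl_gene_count * config$eqtl_indep_snps),
      clump_r2 = config$clump_r2,
      strong_ld_r2 = config$strong_ld_r2,
      min_citations = config$min_citations,
      ld_intercept = config$ld_intercept
    )
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$out_dir
    write_replication(repl, file.path(od, "replication_verdicts.tsv"),
                      file.path(od, "replication_summary.json"))
    utils::write.table(h2$per_variant, file.path(od, "h2_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".")
    utils::write.table(pow, file.path(od, "ncp_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(lit$table, file.path(od, "literature_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(headline, file.path(od, "headline.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(headline = headline, replication = repl, h2 = h2, power = pow,
       targets = targets, literature = lit)
}
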