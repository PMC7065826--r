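#' Bundled example QTL tables
#'
#' Small plain-text QTL summary tables from a multifamily flour-quality
#' study of three wheat DH populations (Kinuhime/Kitahonami "KK",
#' Shunyou/Kitahonami "SK", Tohoku224/Kitahonami "TK"), shipped for
#' report-summary examples and tests:
#' `"single_population"` (flour yield, FlYd, and flour redness, Fla, QTLs
#' from per-population scans), `"multifamily"` (the joint-scan QTLs with
#' per-family segregation probabilities) and `"ideotype_regions"` (the
#' fixed QTL regions and published fixed-allele ladder of ten ideotypes).
#'
#' @param which One of `"single_population"`, `"multifamily"`,
#'   `"ideotype_regions"`.
#' @return A data frame.
#' @export
example_qtl_table <- function(which = c("single_population", "multifamily",
                                        "ideotype_regions")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0(switch(which,
         single_population = "qtl_single_population",
         multifamily = "qtl_multifamily",
         ideotype_regions = "ideotype_regions"), ".tsv"),
       package = "mfqtl", mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE)
}

#' Summarize a QTL report table
#'
#' Per trait (and per population, when a `population` column is present):
#' the number of QTLs, mean QTL intensity, cumulative contribution, and
#' mean absolute effect.
#'
#' @param report A QTL report data frame with at least `trait`,
#'   `intensity`, `contribution` and `effect` columns (e.g. from
#'   [call_qtls()], [read_qtl_report()] or [example_qtl_table()]).
#' @return Data frame with one row per trait (x population).
#' @export
summarize_qtl_reports <- function(report) {
  req <- c("trait", "intensity", "contribution", "effect")
  if (!all(req %in% names(report))) {
    stop("report needs columns: ", paste(req, collapse = ", "))
  }
  by <- list(trait = report$trait)
  if ("population" %in% names(report)) by$population <- report$population
  parts <- split(report, by, drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) {
    data.frame(trait = d$trait[1],
               population = if ("population" %in% names(d)) d$population[1] else NA,
               n_qtl = nrow(d),
               mean_intensity = mean(d$intensity),
               cum_contribution = sum(d$contribution),
               mean_abs_effect = mean(abs(d$effect)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
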