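# Group comparisons (Welch t, one-way ANOVA + Tukey HSD) and report
# bundling with the five-level significance-star labelling.

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. No multiple-comparison correction is applied.
#'
#' @param a,b Numeric vectors, each with at least two values.
#' @return A list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least two values", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate input: both groups have zero variance", call. = FALSE)
  }
  fit <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' @param groups Named list of at least three numeric vectors, each with at
#'   least two values.
#' @return A list with `F`, `p` and `pairwise` (a data.frame of pairwise
#'   comparisons with Tukey-adjusted p-values).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 3L) stop("need at least three groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs at least two values", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  tukey <- stats::TukeyHSD(fit)$group
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       pairwise = data.frame(comparison = rownames(tukey),
                             diff = tukey[, "diff"],
                             p_adj = tukey[, "p adj"],
                             row.names = NULL, stringsAsFactors = FALSE))
}

#' Significance-star labels
#'
#' Five levels: "ns" for p >= 0.05, then "*" (< 0.05), "**" (< 0.01),
#' "***" (< 0.001), "****" (< 0.0001).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
significance_stars <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[p < 0.0001] <- "****"
  out
}

#' Compare a metric between groups
#'
#' @param metric Metric name (for the report).
#' @param groups Named list of per-replicate values.
#' @param test "welch_t" (two groups) or "anova_tukey" (three or more).
#' @return A `group_comparison` list with the test statistics and star
#'   labels.
#' @export
group_comparison <- function(metric, groups,
                             test = c("welch_t", "anova_tukey")) {
  test <- match.arg(test)
  res <- if (test == "welch_t") {
    if (length(groups) != 2L) stop("welch_t compares exactly two groups",
                                   call. = FALSE)
    r <- welch_t(groups[[1]], groups[[2]])
    c(r, list(stars = significance_stars(r$p)))
  } else {
    r <- anova_tukey(groups)
    r$pairwise$stars <- significance_stars(r$pairwise$p_adj)
    c(r, list(stars = significance_stars(r$p)))
  }
  structure(list(metric = metric, test = test,
                 group_means = vapply(groups, mean, numeric(1)),
                 statistics = res),
            class = "group_comparison")
}

#' Assemble and optionally write an experiment report bundle
#'
#' Produces a single report list with full provenance (the manifest, echoed
#' verbatim, plus its MD5 hash) and, when `out_dir` is given, writes
#' `report.json` and a tidy `metrics.tsv` (replicate, metric, value).
#' Regenerating the report from the same inputs is byte-identical. Infinite
#' mismatch ratios are serialized as the string "Inf".
#'
#' @param manifest Named list of every parameter and seed of the run.
#' @param metrics Optional data.frame of per-replicate metrics (long or wide
#'   with a `replicate` column).
#' @param comparisons Optional list of [group_comparison()] results.
#' @param matrices Optional named list of `interaction_matrix` objects,
#'   summarized (dimensions, totals, status accounting) in the report.
#' @param out_dir Optional output directory.
#' @return The report list, invisibly when written.
#' @export
experiment_report <- function(manifest, metrics = NULL, comparisons = NULL,
                              matrices = NULL, out_dir = NULL) {
  manifest_json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                    null = "null")
  tmp <- tempfile()
  writeLines(as.character(manifest_json), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)

  matrix_summaries <- lapply(matrices, function(m) {
    md <- matrix_metadata(m)
    list(replicates = nrow(m), pairs = ncol(m), total = sum(m),
         method = md$method, temperature = md$temperature,
         rarefaction_depth = md$rarefaction_depth,
         status_counts = if (!is.null(md$status_counts))
           as.list(md$status_counts))
  })
  report <- list(manifest = manifest, manifest_md5 = hash,
                 matrices = matrix_summaries, metrics = metrics,
                 comparisons = lapply(comparisons, unclass))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    doc <- rapply(report, function(x) {
      if (is.numeric(x) && any(is.infinite(x))) {
        x <- as.character(x)
      }
      x
    }, how = "replace")
    jsonlite::write_json(doc, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    if (!is.null(metrics)) {
      long <- metrics
      if (!all(c("metric", "value") %in% names(long))) {
        vals <- setdiff(names(metrics), "replicate")
        long <- do.call(rbind, lapply(vals, function(v)
          data.frame(replicate = metrics$replicate, metric = v,
                     value = metrics[[v]], stringsAsFactors = FALSE)))
      }
      long$value <- ifelse(is.infinite(long$value), "Inf",
                           as.character(long$value))
      utils::write.table(long, file.path(out_dir, "metrics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(report))
  }
  report
}
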