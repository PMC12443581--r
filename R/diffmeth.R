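#' Differential-calling thresholds
#'
#' The study's calling rule: a transcript is called up (or down) when its
#' linear fold change strictly exceeds `fc_cut` (or falls below `1/fc_cut`)
#' *and* its p-value is below `p_cut`. By default the raw p-value is used,
#' with BH-adjusted values always reported alongside; set
#' `use_adjusted = TRUE` to gate on the adjusted value instead.
#'
#' @param fc_cut linear fold-change threshold, must be > 1 (default 1.5).
#' @param p_cut p-value threshold in (0, 1) (default 0.05).
#' @param use_adjusted gate significance on the BH-adjusted p-value?
#' @return A list of class `diff_thresholds`.
#' @export
diff_thresholds <- function(fc_cut = 1.5, p_cut = 0.05, use_adjusted = FALSE) {
  if (fc_cut <= 1) stop("fc_cut must be > 1")
  if (p_cut <= 0 || p_cut >= 1) stop("p_cut must lie in (0, 1)")
  structure(list(fc_cut = fc_cut, p_cut = p_cut,
                 use_adjusted = isTRUE(use_adjusted)),
            class = "diff_thresholds")
}

#' Two-group test on one transcript
#'
#' Log2 fold change (group-2 mean minus group-1 mean of the log2-scale
#' values) and a two-sided unpaired t-test p-value. The default is the
#' pooled-variance (Student) test: with three replicates per group the
#' Welch-Satterthwaite approximation is noticeably conservative, while the
#' pooled test is exactly calibrated when the two groups share a variance —
#' the usual working assumption for log-scale array intensities. Set
#' `var_equal = FALSE` for the Welch test. Degenerate inputs:
#' fewer than two finite values in a group gives a missing p-value; zero
#' within-group variance in both groups gives p = 1 for equal means and the
#' smallest representable positive p for unequal means (a forced difference,
#' flagged rather than fabricated as 0).
#'
#' @param values numeric vector of per-sample log2-scale values.
#' @param groups vector of group labels aligned with `values`.
#' @param group_levels length-2 character vector fixing which group is
#'   group 1 (the baseline) and group 2; default: order of first appearance.
#' @param var_equal pool the within-group variances (default `TRUE`)?
#' @return Named numeric vector `c(log2fc, p)`.
#' @export
two_group_test <- function(values, groups, group_levels = NULL,
                           var_equal = TRUE) {
  if (is.null(group_levels)) group_levels <- unique(as.character(groups))
  stopifnot(length(group_levels) == 2L)
  x <- values[groups == group_levels[1]]
  y <- values[groups == group_levels[2]]
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    fc <- if (length(x) && length(y)) mean(y) - mean(x) else NA_real_
    return(c(log2fc = fc, p = NA_real_))
  }
  lfc <- mean(y) - mean(x)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    p <- if (lfc == 0) 1 else .Machine$double.xmin
  } else {
    p <- stats::t.test(y, x, var.equal = var_equal)$p.value
  }
  c(log2fc = lfc, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sort ascending, take
#' `adj_i = min over j >= i of p_(j) * m / j` capped at 1, and return in the
#' input order. Missing p-values pass through as missing.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

classify_calls <- function(fc, p, thresholds) {
  cls <- rep("ns", length(fc))
  sig <- !is.na(p) & p < thresholds$p_cut & !is.na(fc)
  cls[sig & fc > thresholds$fc_cut] <- "up"
  cls[sig & fc < 1 / thresholds$fc_cut] <- "down"
  cls
}

#' Per-transcript differential test of m6A quantity or expression level
#'
#' Applies [two_group_test()] to every transcript of a normalized profile,
#' BH-adjusts the p-values, and classifies each transcript as `up`, `down`
#' or `ns` under `thresholds` (both the fold-change and the p-value criterion
#' must hold; the fold-change boundary is strict). "Up" means higher in
#' group 2; by default group 1 is the first group appearing in the sample
#' sheet (for simulated data: proliferative, so "up" = higher in involuting).
#'
#' @param profile a `NormalizedProfile`.
#' @param measure `"m6a"` or `"expression"`.
#' @param thresholds a [diff_thresholds()].
#' @param group_levels optional length-2 vector fixing the group order.
#' @param var_equal pooled-variance t-test (default) or Welch; see
#'   [two_group_test()].
#' @return data.frame of class `merip_diff` with columns `transcript_id`,
#'   `rna_class`, `measure`, `log2fc`, `fc`, `p`, `p_adj`, `class`.
#' @export
diff_test <- function(profile, measure = c("m6a", "expression"),
                      thresholds = diff_thresholds(), group_levels = NULL,
                      var_equal = TRUE) {
  stopifnot(inherits(profile, "NormalizedProfile"))
  measure <- match.arg(measure)
  mat <- if (measure == "m6a") m6a_quantity(profile)
         else expression_level(profile)
  groups <- profile$samples$group
  if (is.null(group_levels)) group_levels <- unique(as.character(groups))
  res <- t(apply(mat, 1, two_group_test, groups = groups,
                 group_levels = group_levels, var_equal = var_equal))
  n_failed <- sum(is.na(res[, "p"]))
  if (n_failed > 0)
    message(n_failed, " transcripts had fewer than two usable values in a ",
            "group; their p-value is NA and class 'ns'")
  out <- data.frame(transcript_id = profile$transcripts$transcript_id,
                    rna_class = profile$transcripts$rna_class,
                    measure = measure,
                    log2fc = res[, "log2fc"],
                    fc = 2^res[, "log2fc"],
                    p = res[, "p"],
                    p_adj = bh_adjust(res[, "p"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$class <- classify_calls(out$fc,
                              if (thresholds$use_adjusted) out$p_adj else out$p,
                              thresholds)
  structure(out, class = c("merip_diff", "data.frame"),
            thresholds = thresholds, group_levels = group_levels)
}

#' Re-classify differential results under new thresholds
#'
#' @param result a `merip_diff` data.frame (or any data.frame with `fc`, `p`,
#'   `p_adj` columns).
#' @param thresholds a [diff_thresholds()].
#' @return The input with its `class` column recomputed.
#' @export
reclassify <- function(result, thresholds = diff_thresholds()) {
  result$class <- classify_calls(
    result$fc, if (thresholds$use_adjusted) result$p_adj else result$p,
    thresholds)
  attr(result, "thresholds") <- thresholds
  result
}

# class-stratified grouping used in summaries: mRNA, lncRNA, and the four
# small non-coding classes pooled as sncRNA
rna_class_group <- function(rna_class) {
  ifelse(rna_class %in% c("mRNA", "lncRNA"), rna_class,
         ifelse(rna_class %in% RNA_CLASSES, "sncRNA", NA_character_))
}

#' Summary counts of differential calls per RNA-class group
#'
#' Counts of `up` / `down` / `ns` transcripts, stratified into mRNA, lncRNA,
#' and the pooled small non-coding RNAs (pri-miRNA + pre-miRNA + snoRNA +
#' snRNA).
#'
#' @param object a `merip_diff` result.
#' @param ... unused.
#' @return data.frame of counts, one row per (class group, call).
#' @export
summary.merip_diff <- function(object, ...) {
  grp <- rna_class_group(object$rna_class)
  tab <- as.data.frame(table(
    rna_class_group = factor(grp, levels = c("mRNA", "lncRNA", "sncRNA")),
    class = factor(object$class, levels = c("up", "down", "ns"))),
    stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab
}

#' @export
print.merip_diff <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat("Differential ", x$measure[1], " calls: ", nrow(x), " transcripts (",
      sum(x$class == "up"), " up, ", sum(x$class == "down"), " down; fc > ",
      th$fc_cut, ", ", if (th$use_adjusted) "BH-adjusted " else "", "p < ",
      th$p_cut, ")\n", sep = "")
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative (average linkage) clustering of samples using the
#' correlation distance 1 - Pearson r between sample profiles, with a k-group
#' cut. A constant sample profile has no defined correlation; such pairs are
#' assigned the maximal distance 1 with a warning.
#'
#' @param x a transcripts-x-samples numeric matrix, or a
#'   `NormalizedProfile` (then `measure` selects the matrix and `transcripts`
#'   optionally restricts to a transcript subset, e.g. the significant ones).
#' @param k number of clusters for the cut (default 2).
#' @param measure,transcripts see above (profile input only).
#' @param ... passed between methods.
#' @return List of class `merip_hclust`: `hclust` (the tree), `labels`
#'   (named cluster assignment of each sample), `newick` (the dendrogram as
#'   Newick text).
#' @export
hier_cluster <- function(x, k = 2, ...) UseMethod("hier_cluster")

#' @rdname hier_cluster
#' @export
hier_cluster.NormalizedProfile <- function(x, k = 2,
                                           measure = c("m6a", "expression"),
                                           transcripts = NULL, ...) {
  measure <- match.arg(measure)
  mat <- if (measure == "m6a") m6a_quantity(x) else expression_level(x)
  if (!is.null(transcripts)) mat <- mat[transcripts, , drop = FALSE]
  hier_cluster.default(mat, k = k)
}

#' @rdname hier_cluster
#' @export
hier_cluster.default <- function(x, k = 2, ...) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 samples")
  if (nrow(x) < 1L) stop("need at least 1 transcript")
  cm <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  if (anyNA(cm)) {
    warning("undefined sample correlations (constant profile?); ",
            "setting their distance to 1")
    cm[is.na(cm)] <- 0
  }
  d <- stats::as.dist(1 - cm)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, labels = labels,
                 newick = ape::write.tree(ape::as.phylo(hc))),
            class = "merip_hclust")
}

#' @export
print.merip_hclust <- function(x, ...) {
  cat("Sample clustering (1 - Pearson r, average linkage)\n")
  print(x$labels)
  cat(x$newick, "\n")
  invisible(x)
}

#' @export
plot.merip_hclust <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}

#' Volcano plot of a differential result
#'
#' @param x a `merip_diff` result.
#' @param ... passed to [plot()].
#' @export
plot.merip_diff <- function(x, ...) {
  th <- attr(x, "thresholds")
  col <- c(up = "firebrick", down = "steelblue", ns = "grey60")[x$class]
  plot(x$log2fc, -log10(x$p), col = col, pch = 16, cex = 0.4,
       xlab = "log2 fold change", ylab = "-log10 p", ...)
  graphics::abline(v = c(-1, 1) * log2(th$fc_cut), h = -log10(th$p_cut),
                   lty = 2, col = "grey40")
  invisible(x)
}
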