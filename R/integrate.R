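#' Join m6A and expression differential results; quadrant classification
#'
#' Inner-joins two per-transcript differential results on `transcript_id`
#' and assigns each transcript to a methylation-by-expression quadrant.
#' A quadrant is assigned only when *both* measures are significant under
#' `thresholds` (fold change strictly beyond the cut and p below the cut);
#' otherwise the transcript is `ns`. "hyper"/"hypo" refer to the m6A change,
#' "up"/"down" to the expression change — e.g. a transcript with increased
#' m6A but decreased expression is `hyper-down`.
#'
#' @param m6a,expr `merip_diff` results (or data.frames with
#'   `transcript_id`, `log2fc`, `fc`, `p`, `p_adj`).
#' @param thresholds a [diff_thresholds()] applied to both measures.
#' @return data.frame of class `merip_joint`: `transcript_id`, `rna_class`,
#'   `m6a_log2fc`, `m6a_p`, `expr_log2fc`, `expr_p`, `quadrant`.
#' @export
join_and_classify <- function(m6a, expr, thresholds = diff_thresholds()) {
  for (nm in c("m6a", "expr")) {
    d <- get(nm)
    if (anyDuplicated(d$transcript_id))
      stop("duplicate transcript_id in ", nm, " results")
  }
  a <- data.frame(transcript_id = m6a$transcript_id,
                  rna_class = if ("rna_class" %in% names(m6a))
                    m6a$rna_class else NA_character_,
                  m6a_log2fc = m6a$log2fc, m6a_fc = m6a$fc,
                  m6a_p = m6a$p, m6a_p_adj = m6a$p_adj,
                  stringsAsFactors = FALSE)
  b <- data.frame(transcript_id = expr$transcript_id,
                  expr_log2fc = expr$log2fc, expr_fc = expr$fc,
                  expr_p = expr$p, expr_p_adj = expr$p_adj,
                  stringsAsFactors = FALSE)
  j <- merge(a, b, by = "transcript_id", sort = FALSE)
  mc <- classify_calls(j$m6a_fc,
                       if (thresholds$use_adjusted) j$m6a_p_adj else j$m6a_p,
                       thresholds)
  ec <- classify_calls(j$expr_fc,
                       if (thresholds$use_adjusted) j$expr_p_adj else j$expr_p,
                       thresholds)
  quadrant <- rep("ns", nrow(j))
  both <- mc != "ns" & ec != "ns"
  quadrant[both] <- paste0(ifelse(mc[both] == "up", "hyper", "hypo"), "-",
                           ec[both])
  j$m6a_fc <- j$m6a_p_adj <- j$expr_fc <- j$expr_p_adj <- NULL
  j$quadrant <- quadrant
  structure(j, class = c("merip_joint", "data.frame"),
            thresholds = thresholds)
}

#' @export
print.merip_joint <- function(x, ...) {
  cat("Joint m6A x expression classification: ", nrow(x), " transcripts\n",
      sep = "")
  print(table(quadrant = x$quadrant))
  invisible(x)
}

#' Global association between m6A and expression fold changes
#'
#' Pearson and Spearman correlations (with two-sided p-values) between the
#' per-transcript m6A and expression log2 fold changes. By default all
#' joined transcripts enter; `significant_only = TRUE` restricts to
#' transcripts with an assigned quadrant.
#'
#' @param joined a `merip_joint` data.frame.
#' @param significant_only use only transcripts with a non-`ns` quadrant?
#' @return List of class `merip_assoc`: `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`, `n`.
#' @export
global_association <- function(joined, significant_only = FALSE) {
  d <- joined
  if (significant_only) d <- d[d$quadrant != "ns", , drop = FALSE]
  ok <- is.finite(d$m6a_log2fc) & is.finite(d$expr_log2fc)
  d <- d[ok, , drop = FALSE]
  if (nrow(d) < 3L)
    stop("need at least 3 transcripts with finite fold changes; got ",
         nrow(d))
  pe <- stats::cor.test(d$m6a_log2fc, d$expr_log2fc, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(d$m6a_log2fc, d$expr_log2fc, method = "spearman",
                    exact = FALSE))
  structure(list(pearson_r = unname(pe$estimate),
                 pearson_p = pe$p.value,
                 spearman_rho = unname(sp$estimate),
                 spearman_p = sp$p.value,
                 n = nrow(d)),
            class = "merip_assoc")
}

#' @export
print.merip_assoc <- function(x, ...) {
  cat(sprintf(
    "m6A-expression association over %d transcripts:\n  Pearson r = %.3f (p = %.3g)\n  Spearman rho = %.3f (p = %.3g)\n",
    x$n, x$pearson_r, x$pearson_p, x$spearman_rho, x$spearman_p))
  invisible(x)
}

#' Quadrant scatter plot of joint m6A / expression fold changes
#'
#' @param x a `merip_joint` data.frame.
#' @param ... passed to [plot()].
#' @export
plot.merip_joint <- function(x, ...) {
  col <- c("hyper-up" = "firebrick", "hyper-down" = "darkorange",
           "hypo-up" = "seagreen", "hypo-down" = "steelblue",
           ns = "grey70")[x$quadrant]
  plot(x$expr_log2fc, x$m6a_log2fc, col = col, pch = 16, cex = 0.4,
       xlab = "expression log2 fold change",
       ylab = "m6A log2 fold change", ...)
  graphics::abline(h = 0, v = 0, lty = 2, col = "grey40")
  invisible(x)
}
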