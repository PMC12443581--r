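#' MeRIP-qPCR percent input
#'
#' Enrichment of a target in the immunoprecipitated (MeRIP) fraction
#' relative to the total recovered material:
#' `%input = 2^-Ct_MeRIP / (2^-Ct_MeRIP + 2^-Ct_Sup) * 100`.
#' Computed as `100 / (1 + 2^(Ct_MeRIP - Ct_Sup))` for numerical stability;
#' strictly increasing in `Ct_Sup - Ct_MeRIP` and bounded in (0, 100).
#'
#' @param ct_merip,ct_sup Ct values (cycles) of the MeRIP and supernatant
#'   fractions; vectorized.
#' @return Percentages in (0, 100).
#' @export
percent_input <- function(ct_merip, ct_sup) {
  if (any(!is.finite(ct_merip)) || any(!is.finite(ct_sup)))
    stop("Ct values must be finite")
  100 / (1 + 2^(ct_merip - ct_sup))
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target - Ct_ref) - (Ct_target_cal - Ct_ref_cal)` and
#' `rel_expr = 2^-ddCt`, assuming amplification efficiency 2. Duplicate
#' wells must be averaged (arithmetic mean on the Ct scale) before calling;
#' [ddct_table()] does this for a whole plate. Invariant to a constant
#' plate-wide Ct offset.
#'
#' @param ct_target,ct_ref mean Cts of the target and reference gene in the
#'   condition of interest.
#' @param ct_target_cal,ct_ref_cal mean Cts in the calibrator condition.
#' @return data.frame with `ddct` and `rel_expr` (vectorized over inputs).
#' @export
ddct <- function(ct_target, ct_ref, ct_target_cal, ct_ref_cal) {
  cts <- cbind(ct_target, ct_ref, ct_target_cal, ct_ref_cal)
  if (any(!is.finite(cts)))
    stop("all four Ct values must be finite")
  dd <- (ct_target - ct_ref) - (ct_target_cal - ct_ref_cal)
  data.frame(ddct = dd, rel_expr = 2^-dd)
}

# arithmetic mean Ct over replicate wells, per (target, fraction, condition)
average_wells <- function(plate) {
  stats::aggregate(ct ~ target_id + fraction + condition, data = plate,
                   FUN = mean)
}

#' Relative expression table from a qPCR plate
#'
#' Averages duplicate wells on the Ct scale, then applies [ddct()] to every
#' target (other than the reference gene) and condition (other than the
#' calibrator). Only expression wells (`fraction == "none"`) are used.
#'
#' @param plate data.frame with columns `target_id`, `fraction`, `condition`,
#'   `ct` (the layout written by [simulate_qpcr_plate()]).
#' @param reference endogenous reference gene (default `"U6"`).
#' @param calibrator calibrator condition name (default `"calibrator"`).
#' @return data.frame: `target_id`, `condition`, `reference_gene`, `ddct`,
#'   `rel_expr`.
#' @export
ddct_table <- function(plate, reference = "U6", calibrator = "calibrator") {
  p <- plate[plate$fraction %in% "none", , drop = FALSE]
  if (!nrow(p)) stop("plate has no expression wells (fraction 'none')")
  if (!calibrator %in% p$condition)
    stop("calibrator condition '", calibrator, "' not found on the plate")
  if (!reference %in% p$target_id)
    stop("reference gene '", reference, "' not found on the plate")
  m <- average_wells(p)
  ct_of <- function(tg, cond) {
    v <- m$ct[m$target_id == tg & m$condition == cond]
    if (!length(v)) NA_real_ else v
  }
  conds <- setdiff(unique(m$condition), calibrator)
  targets <- setdiff(unique(m$target_id), reference)
  out <- expand.grid(target_id = targets, condition = conds,
                     stringsAsFactors = FALSE)
  res <- mapply(function(tg, cond) {
    cts <- c(ct_of(tg, cond), ct_of(reference, cond),
             ct_of(tg, calibrator), ct_of(reference, calibrator))
    if (any(!is.finite(cts)))
      stop("missing Ct for target '", tg, "' / reference '", reference,
           "' in condition '", cond, "' or calibrator '", calibrator, "'")
    unlist(ddct(cts[1], cts[2], cts[3], cts[4]))
  }, out$target_id, out$condition)
  out$reference_gene <- reference
  out$ddct <- res["ddct", ]
  out$rel_expr <- res["rel_expr", ]
  out
}

#' Percent-input table from a qPCR plate
#'
#' Averages duplicate wells, then computes [percent_input()] for every
#' (target, condition) that carries both a MeRIP and a Supernatant fraction.
#'
#' @inheritParams ddct_table
#' @return data.frame: `target_id`, `condition`, `ct_merip`, `ct_sup`,
#'   `pct_input`.
#' @export
percent_input_table <- function(plate) {
  p <- plate[plate$fraction %in% c("MeRIP", "Supernatant"), , drop = FALSE]
  if (!nrow(p)) stop("plate has no MeRIP/Supernatant wells")
  m <- average_wells(p)
  wide <- merge(m[m$fraction == "MeRIP", c("target_id", "condition", "ct")],
                m[m$fraction == "Supernatant",
                  c("target_id", "condition", "ct")],
                by = c("target_id", "condition"),
                suffixes = c("_merip", "_sup"))
  data.frame(target_id = wide$target_id, condition = wide$condition,
             ct_merip = wide$ct_merip, ct_sup = wide$ct_sup,
             pct_input = percent_input(wide$ct_merip, wide$ct_sup),
             stringsAsFactors = FALSE)
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty otherwise.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of star strings.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                         ifelse(p < 0.05, "*", ""))))
}

#' Group summary of relative-expression values
#'
#' Per-group mean, SD and n of biological-replicate relative expression
#' values, plus all pairwise two-sided Welch t-tests with significance
#' stars. Groups with a single replicate yield a missing p-value.
#'
#' @param rel_expr numeric vector of per-replicate relative expression.
#' @param groups group labels aligned with `rel_expr`.
#' @return List with `groups` (data.frame: group, n, mean, sd) and
#'   `comparisons` (data.frame: group1, group2, p, stars).
#' @export
summarize_groups <- function(rel_expr, groups) {
  groups <- as.character(groups)
  gl <- unique(groups)
  gs <- data.frame(
    group = gl,
    n = vapply(gl, function(g) sum(groups == g), integer(1)),
    mean = vapply(gl, function(g) mean(rel_expr[groups == g]), numeric(1)),
    sd = vapply(gl, function(g) stats::sd(rel_expr[groups == g]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  prs <- utils::combn(gl, 2)
  cmp <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(prs))) {
    x <- rel_expr[groups == prs[1, i]]
    y <- rel_expr[groups == prs[2, i]]
    if (length(x) >= 2 && length(y) >= 2 &&
        (stats::var(x) > 0 || stats::var(y) > 0)) {
      cmp$p[i] <- stats::t.test(x, y)$p.value
    } else if (length(x) < 2 || length(y) < 2) {
      message("group pair ", prs[1, i], " vs ", prs[2, i],
              " has a single replicate; p is NA")
    } else {
      cmp$p[i] <- if (mean(x) == mean(y)) 1 else .Machine$double.xmin
    }
  }
  cmp$stars <- p_stars(cmp$p)
  list(groups = gs, comparisons = cmp)
}
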