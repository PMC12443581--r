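#' Read gene sets in GMT format
#'
#' One term per line: term id, description, then the member gene symbols,
#' tab-separated. Symbols are uppercased for matching.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors (one per term), with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate term ids in GMT file")
  sets <- lapply(parts, function(x) unique(toupper(x[-(1:2)])))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2L), ids)
  sets
}

#' Over-representation analysis by Fisher's exact test
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected under random sampling from the universe, using the
#' one-sided (enrichment) hypergeometric tail — the one-sided Fisher exact
#' test on the 2x2 table (k, n-k, K-k, N-K-n+k). P-values are BH-adjusted
#' across all tested terms. Query genes absent from the universe are dropped
#' with a message; terms with no member in the universe are skipped.
#' When a `direction` is supplied, the up/down split of each overlap and the
#' bubble-plot z-score `(n_up - n_down)/sqrt(k)` are reported.
#'
#' @param query character vector of gene symbols (e.g. the differential
#'   genes).
#' @param sets named list of gene sets, as from [read_gmt()].
#' @param universe character vector of all assayable gene symbols (typically
#'   every annotated transcript retained after QC filtering).
#' @param direction optional named character vector mapping query genes to
#'   `"up"` or `"down"`.
#' @return data.frame of class `merip_ora`: `term_id`, `term_name`, `k`
#'   (overlap), `K` (set size in universe), `n` (query size in universe),
#'   `N` (universe size), `p`, `p_adj`, `n_up`, `n_down`, `z`, ordered by
#'   increasing p.
#' @export
fisher_ora <- function(query, sets, universe, direction = NULL) {
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("universe is empty")
  query <- unique(toupper(query))
  n_out <- sum(!query %in% universe)
  if (n_out > 0) {
    message("dropping ", n_out, " query genes absent from the universe")
    query <- query[query %in% universe]
  }
  if (!is.null(direction)) {
    names(direction) <- toupper(names(direction))
    if (!all(direction %in% c("up", "down")))
      stop("direction values must be 'up' or 'down'")
  }
  N <- length(universe)
  n <- length(query)
  desc <- attr(sets, "description")
  rows <- lapply(names(sets), function(id) {
    members <- unique(toupper(sets[[id]]))[unique(toupper(sets[[id]])) %in%
                                             universe]
    K <- length(members)
    if (K == 0L) return(NULL)
    hit <- query[query %in% members]
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    n_up <- n_down <- NA_integer_
    z <- NA_real_
    if (!is.null(direction)) {
      n_up <- sum(direction[hit] == "up", na.rm = TRUE)
      n_down <- sum(direction[hit] == "down", na.rm = TRUE)
      z <- if (k >= 1) bubble_zscore(n_up, n_down, k) else NA_real_
    }
    data.frame(term_id = id,
               term_name = if (!is.null(desc)) unname(desc[id]) else id,
               k = k, K = K, n = n, N = N, p = p,
               n_up = n_up, n_down = n_down, z = z,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no gene set has members in the universe")
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p), c("term_id", "term_name", "k", "K", "n", "N",
                             "p", "p_adj", "n_up", "n_down", "z")]
  rownames(out) <- NULL
  structure(out, class = c("merip_ora", "data.frame"))
}

#' Bubble-plot z-score of an enriched term
#'
#' Directional summary of a term's overlap with a differential gene list:
#' `z = (n_up - n_down) / sqrt(k)`, the convention used by GOplot-style
#' bubble plots (positive when the term's genes are mostly upregulated).
#'
#' @param n_up,n_down numbers of up- and downregulated genes in the overlap;
#'   `n_up + n_down` must not exceed `k`.
#' @param k total overlap count, at least 1.
#' @return Numeric z-score (vectorized).
#' @export
bubble_zscore <- function(n_up, n_down, k) {
  if (any(k < 1)) stop("k must be at least 1")
  if (any(n_up + n_down > k))
    stop("n_up + n_down must not exceed k")
  (n_up - n_down) / sqrt(k)
}

#' @export
print.merip_ora <- function(x, ...) {
  cat("Over-representation analysis: ", nrow(x), " terms tested, ",
      sum(x$p_adj < 0.05), " with BH-adjusted p < 0.05\n", sep = "")
  print(utils::head(as.data.frame(x), 10))
  invisible(x)
}
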