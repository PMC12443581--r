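#' Spike-in log2 mean for one sample and channel
#'
#' The per-sample normalization anchor: the arithmetic mean of log2 raw
#' intensities over the spike-in probes carrying positive signal in the
#' requested channel (equivalently, the log2 geometric mean of their raw
#' intensities). With `policy = "matched"` the Cy5 (IP) anchor uses only
#' positive spike-ins and the Cy3 (supernatant) anchor only negative ones;
#' the default `"all"` uses every spike-in with usable signal in the channel.
#'
#' @param x a `RawArraySet`.
#' @param sample sample id.
#' @param channel `"cy5"` (IP) or `"cy3"` (supernatant).
#' @param policy `"all"` or `"matched"`.
#' @return Scalar, log2 units.
#' @export
spikein_log2_mean <- function(x, sample, channel = c("cy5", "cy3"),
                              policy = c("all", "matched")) {
  stopifnot(inherits(x, "RawArraySet"))
  channel <- match.arg(channel)
  policy <- match.arg(policy)
  if (!sample %in% x$samples$sample_id)
    stop("unknown sample: ", sample)
  sp <- if (policy == "all") x$probes$spikein != "none"
        else x$probes$spikein == (if (channel == "cy5") "pos" else "neg")
  v <- x[[channel]][sp, sample]
  v <- v[is.finite(v) & v > 0]
  if (!length(v))
    stop("no usable spike-in signal for sample '", sample, "' in channel ",
         channel)
  mean(log2(v))
}

#' Spike-in normalize one channel
#'
#' Per probe and sample: `log2(raw) - spikein_log2_mean(sample, channel)`.
#' Missing raw intensities stay missing.
#'
#' @inheritParams spikein_log2_mean
#' @return Numeric matrix (probes x samples) of log2 normalized intensities.
#' @export
normalize_channel <- function(x, channel = c("cy5", "cy3"),
                              policy = c("all", "matched")) {
  stopifnot(inherits(x, "RawArraySet"))
  channel <- match.arg(channel)
  policy <- match.arg(policy)
  anchors <- vapply(x$samples$sample_id, function(s)
    spikein_log2_mean(x, s, channel, policy), numeric(1))
  sweep(log2(x[[channel]]), 2, anchors, "-")
}

#' Compute the normalized m6A-quantity / expression-level profile
#'
#' Runs spike-in normalization of both channels, collapses multiple probes
#' per transcript by the median of normalized values (per channel; an even
#' number of probes yields the mean of the central pair), and derives the two
#' per-transcript statistics: the m6A quantity (the normalized IP/Cy5
#' intensity) and the gene expression level (normalized IP/Cy5 plus
#' normalized supernatant/Cy3 intensity). Spike-in probes anchor the
#' normalization but are excluded from the transcript-level profile. Samples
#' without usable spike-in signal in either channel are dropped with a
#' warning.
#'
#' @inheritParams spikein_log2_mean
#' @return An object of class `NormalizedProfile`: a list with `transcripts`
#'   (annotation data.frame), `samples` (sample sheet), `ip_norm` and
#'   `sup_norm` (transcript x sample matrices, log2 units), and
#'   `spikein_log2_means` (sample x channel anchors).
#' @seealso [m6a_quantity()], [expression_level()]
#' @export
normalize_profile <- function(x, policy = c("all", "matched")) {
  stopifnot(inherits(x, "RawArraySet"))
  policy <- match.arg(policy)
  sids <- x$samples$sample_id
  anchor <- function(s, ch) tryCatch(spikein_log2_mean(x, s, ch, policy),
                                     error = function(e) NA_real_)
  a5 <- vapply(sids, anchor, numeric(1), ch = "cy5")
  a3 <- vapply(sids, anchor, numeric(1), ch = "cy3")
  usable <- is.finite(a5) & is.finite(a3)
  if (!any(usable))
    stop("no sample has usable spike-in signal in both channels")
  if (!all(usable)) {
    warning("dropping sample(s) without usable spike-ins: ",
            paste(sids[!usable], collapse = ", "))
    x <- structure(list(probes = x$probes,
                        samples = x$samples[usable, , drop = FALSE],
                        cy5 = x$cy5[, usable, drop = FALSE],
                        cy3 = x$cy3[, usable, drop = FALSE],
                        flags = x$flags[, usable, drop = FALSE]),
                   class = "RawArraySet")
    a5 <- a5[usable]; a3 <- a3[usable]
  }
  ip <- sweep(log2(x$cy5), 2, a5, "-")
  sup <- sweep(log2(x$cy3), 2, a3, "-")

  keep <- x$probes$spikein == "none"
  ip <- ip[keep, , drop = FALSE]
  sup <- sup[keep, , drop = FALSE]
  ann <- x$probes[keep, c("transcript_id", "gene_symbol", "rna_class")]

  tids <- unique(ann$transcript_id)
  if (length(tids) < nrow(ann)) {
    idx <- split(seq_len(nrow(ann)), factor(ann$transcript_id, levels = tids))
    collapse <- function(m) {
      out <- t(vapply(idx, function(i) {
        if (length(i) == 1L) m[i, ]
        else apply(m[i, , drop = FALSE], 2, stats::median, na.rm = TRUE)
      }, numeric(ncol(m))))
      out[!is.finite(out)] <- NA_real_
      rownames(out) <- tids
      out
    }
    ip <- collapse(ip)
    sup <- collapse(sup)
    ann <- ann[!duplicated(ann$transcript_id), , drop = FALSE]
  } else {
    rownames(ip) <- rownames(sup) <- tids
  }
  rownames(ann) <- NULL

  n_half <- sum(is.na(ip) != is.na(sup))
  if (n_half > 0)
    message(n_half, " transcript-sample pairs have only one usable channel; ",
            "their expression level is NA")
  structure(list(transcripts = ann, samples = x$samples,
                 ip_norm = ip, sup_norm = sup,
                 spikein_log2_means = data.frame(
                   sample_id = x$samples$sample_id, cy5 = a5, cy3 = a3,
                   row.names = NULL)),
            class = "NormalizedProfile")
}

#' @export
print.NormalizedProfile <- function(x, ...) {
  cat("NormalizedProfile: ", nrow(x$transcripts), " transcripts x ",
      nrow(x$samples), " samples\n", sep = "")
  print(table(x$transcripts$rna_class))
  invisible(x)
}

#' Per-transcript m6A quantity
#'
#' The methylation statistic of the assay: the spike-in-normalized log2
#' IP (Cy5) intensity, after probe-to-transcript collapse.
#'
#' @param profile a `NormalizedProfile`.
#' @return Numeric matrix, transcripts x samples, log2 units.
#' @export
m6a_quantity <- function(profile) {
  stopifnot(inherits(profile, "NormalizedProfile"))
  profile$ip_norm
}

#' Per-transcript gene expression level
#'
#' The abundance statistic of the assay: the sum of the spike-in-normalized
#' log2 IP (Cy5) and supernatant (Cy3) intensities. Defined only where both
#' channels are usable.
#'
#' @param profile a `NormalizedProfile`.
#' @return Numeric matrix, transcripts x samples, log2 units.
#' @export
expression_level <- function(profile) {
  stopifnot(inherits(profile, "NormalizedProfile"))
  profile$ip_norm + profile$sup_norm
}

#' @export
as.data.frame.NormalizedProfile <- function(x, ...) {
  m6a <- m6a_quantity(x)
  expr <- expression_level(x)
  colnames(m6a) <- paste0("m6a_", colnames(m6a))
  colnames(expr) <- paste0("expr_", colnames(expr))
  cbind(x$transcripts, as.data.frame(m6a), as.data.frame(expr),
        row.names = NULL)
}

#' Write a normalized profile as TSV
#'
#' One row per transcript: annotation columns, then per-sample
#' `m6a_<sample>` and `expr_<sample>` columns.
#'
#' @param profile a `NormalizedProfile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_normalized_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
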