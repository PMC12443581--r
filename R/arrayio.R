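#' Recognized RNA classes
#'
#' The closed vocabulary of RNA classes annotated on the array: protein-coding
#' mRNAs, long non-coding RNAs, and the four small non-coding classes
#' (pri-miRNA, pre-miRNA, snoRNA, snRNA) that are pooled as "sncRNA" in
#' class-stratified summaries.
#'
#' @format Character vector of length 6.
#' @export
RNA_CLASSES <- c("mRNA", "lncRNA", "pri-miRNA", "pre-miRNA", "snoRNA", "snRNA")

#' Construct a raw two-channel array set
#'
#' A `RawArraySet` holds probe annotation, the sample sheet, and the raw
#' Cy5 (IP channel) and Cy3 (supernatant channel) fluorescence intensities
#' with their per-probe-per-sample QC flags. Non-positive intensities carry no
#' usable signal for log2 arithmetic and are converted to `NA` (with a message
#' giving the count) rather than floored.
#'
#' @param probes data.frame with columns `probe_id` (unique), `transcript_id`,
#'   `gene_symbol`, `rna_class` (one of [RNA_CLASSES]; may be `NA` for
#'   spike-ins), `spikein` (one of `"pos"`, `"neg"`, `"none"`).
#' @param samples data.frame with columns `sample_id` (unique) and `group`;
#'   the groups must partition the samples into exactly two non-empty sets.
#' @param cy5,cy3 numeric matrices, probes x samples, raw fluorescence.
#' @param flags character matrix, probes x samples, entries `"P"` (present),
#'   `"M"` (marginal) or `"A"` (absent).
#' @return An object of class `RawArraySet`.
#' @seealso [read_raw_table()], [filter_by_flags()], [simulate_dataset()]
#' @export
raw_array_set <- function(probes, samples, cy5, cy3, flags) {
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need_p <- c("probe_id", "transcript_id", "gene_symbol", "rna_class", "spikein")
  miss <- setdiff(need_p, names(probes))
  if (length(miss))
    stop("probe table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("sample sheet needs columns 'sample_id' and 'group'")
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe_id in probe table")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample sheet")
  grp <- table(samples$group)
  if (length(grp) != 2L || any(grp == 0L))
    stop("sample groups must partition samples into exactly two non-empty sets")
  if (!all(probes$spikein %in% c("pos", "neg", "none")))
    stop("spikein must be one of 'pos', 'neg', 'none'")
  bad_class <- probes$spikein == "none" & !(probes$rna_class %in% RNA_CLASSES)
  if (any(bad_class))
    stop("unknown rna_class for probe(s): ",
         paste(utils::head(probes$probe_id[bad_class], 5), collapse = ", "))

  np <- nrow(probes); ns <- nrow(samples)
  cy5 <- as.matrix(cy5); cy3 <- as.matrix(cy3); flags <- as.matrix(flags)
  for (m in list(cy5, cy3, flags))
    if (!all(dim(m) == c(np, ns)))
      stop("intensity/flag matrices must be probes x samples (",
           np, " x ", ns, ")")
  if (!all(flags %in% c("P", "M", "A")))
    stop("flags must be 'P', 'M' or 'A'")
  storage.mode(cy5) <- "double"
  storage.mode(cy3) <- "double"
  n_bad <- sum(cy5 <= 0, na.rm = TRUE) + sum(cy3 <= 0, na.rm = TRUE)
  if (n_bad > 0) {
    cy5[cy5 <= 0] <- NA_real_
    cy3[cy3 <= 0] <- NA_real_
    message("set ", n_bad, " non-positive intensities to NA")
  }
  dimnames(cy5) <- dimnames(cy3) <- dimnames(flags) <-
    list(probes$probe_id, samples$sample_id)
  structure(
    list(probes = probes, samples = samples, cy5 = cy5, cy3 = cy3,
         flags = flags),
    class = "RawArraySet")
}

#' @export
print.RawArraySet <- function(x, ...) {
  grp <- table(x$samples$group)
  cat("RawArraySet: ", nrow(x$probes), " probes x ", nrow(x$samples),
      " samples\n", sep = "")
  cat("  groups: ", paste0(names(grp), " (n=", grp, ")", collapse = ", "),
      "\n", sep = "")
  cat("  spike-ins: ", sum(x$probes$spikein == "pos"), " positive, ",
      sum(x$probes$spikein == "neg"), " negative\n", sep = "")
  invisible(x)
}

#' Write a raw array set as a tab-delimited table
#'
#' One row per probe: `ProbeName`, `TranscriptID`, `GeneSymbol`, `RNAClass`,
#' `SpikeIn`, then for each sample the triplet `<sample>_Cy5_raw`,
#' `<sample>_Cy3_raw`, `<sample>_Flag`.
#'
#' @param x a `RawArraySet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raw_table <- function(x, path) {
  stopifnot(inherits(x, "RawArraySet"))
  out <- data.frame(ProbeName = x$probes$probe_id,
                    TranscriptID = x$probes$transcript_id,
                    GeneSymbol = x$probes$gene_symbol,
                    RNAClass = x$probes$rna_class,
                    SpikeIn = x$probes$spikein,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (sid in x$samples$sample_id) {
    out[[paste0(sid, "_Cy5_raw")]] <- x$cy5[, sid]
    out[[paste0(sid, "_Cy3_raw")]] <- x$cy3[, sid]
    out[[paste0(sid, "_Flag")]] <- x$flags[, sid]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a sample sheet
#'
#' Two-column TSV mapping `sample_id` to `group`.
#'
#' @param samples data.frame with `sample_id` and `group`.
#' @param path file path.
#' @return `write_sample_sheet()` returns `path` invisibly;
#'   `read_sample_sheet()` returns the sample data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples[, c("sample_id", "group")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(ss)))
    stop("sample sheet must have columns 'sample_id' and 'group'")
  ss
}

#' Read a raw two-channel intensity table
#'
#' Parses the tab-delimited dialect written by [write_raw_table()] (an
#' Agilent-Feature-Extraction-like layout). Intensity cells that are
#' non-positive or unparseable become missing values; a message reports how
#' many. Every sample in the sheet must have its `_Cy5_raw`, `_Cy3_raw` and
#' `_Flag` columns in the table.
#'
#' @param path path to the intensity TSV.
#' @param sample_sheet path to a sample-sheet TSV, or a data.frame with
#'   columns `sample_id` and `group`.
#' @return A `RawArraySet`.
#' @export
read_raw_table <- function(path, sample_sheet) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  ss <- if (is.character(sample_sheet)) read_sample_sheet(sample_sheet)
        else as.data.frame(sample_sheet, stringsAsFactors = FALSE)
  need <- c("ProbeName", "TranscriptID", "GeneSymbol", "RNAClass", "SpikeIn")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("intensity table lacks column(s): ", paste(miss, collapse = ", "))
  for (sid in ss$sample_id) {
    cols <- paste0(sid, c("_Cy5_raw", "_Cy3_raw", "_Flag"))
    miss <- setdiff(cols, names(tab))
    if (length(miss))
      stop("sample '", sid, "' in sheet but column(s) missing from table: ",
           paste(miss, collapse = ", "))
  }
  parse_chan <- function(suffix) {
    m <- vapply(ss$sample_id, function(sid)
      suppressWarnings(as.numeric(tab[[paste0(sid, suffix)]])),
      numeric(nrow(tab)))
    matrix(m, nrow = nrow(tab),
           dimnames = list(tab$ProbeName, ss$sample_id))
  }
  cy5 <- parse_chan("_Cy5_raw")
  cy3 <- parse_chan("_Cy3_raw")
  n_unparsed <- sum(is.na(cy5) & tab_has_value(tab, ss$sample_id, "_Cy5_raw")) +
    sum(is.na(cy3) & tab_has_value(tab, ss$sample_id, "_Cy3_raw"))
  if (n_unparsed > 0)
    message("set ", n_unparsed, " unparseable intensities to NA")
  flags <- vapply(ss$sample_id, function(sid) tab[[paste0(sid, "_Flag")]],
                  character(nrow(tab)))
  flags <- matrix(flags, nrow = nrow(tab),
                  dimnames = list(tab$ProbeName, ss$sample_id))
  rc <- tab$RNAClass
  rc[rc == "NA" | rc == ""] <- NA_character_
  probes <- data.frame(probe_id = tab$ProbeName,
                       transcript_id = tab$TranscriptID,
                       gene_symbol = tab$GeneSymbol,
                       rna_class = rc,
                       spikein = tab$SpikeIn,
                       stringsAsFactors = FALSE)
  raw_array_set(probes, ss, cy5, cy3, flags)
}

# cells that held non-empty, non-"NA" text (used to count unparseable entries)
tab_has_value <- function(tab, sids, suffix) {
  m <- vapply(sids, function(sid) {
    v <- tab[[paste0(sid, suffix)]]
    !(is.na(v) | v == "" | v == "NA")
  }, logical(nrow(tab)))
  matrix(m, nrow = nrow(tab))
}

#' Filter probes on QC flags
#'
#' Retains probes flagged present (`"P"`) or marginal (`"M"`) in at least
#' `min_present` samples, counted across all arrays. Spike-in probes are
#' always retained because downstream normalization needs them. Intensity
#' values are never altered, only the probe set.
#'
#' @param x a `RawArraySet`.
#' @param min_present minimum number of samples with a P or M flag
#'   (default 3).
#' @return A `RawArraySet` restricted to the retained probes.
#' @export
filter_by_flags <- function(x, min_present = 3) {
  stopifnot(inherits(x, "RawArraySet"))
  if (min_present > nrow(x$samples))
    stop("min_present (", min_present, ") exceeds the number of samples (",
         nrow(x$samples), ")")
  ok <- rowSums(x$flags == "P" | x$flags == "M") >= min_present
  keep <- ok | x$probes$spikein != "none"
  structure(
    list(probes = x$probes[keep, , drop = FALSE],
         samples = x$samples,
         cy5 = x$cy5[keep, , drop = FALSE],
         cy3 = x$cy3[keep, , drop = FALSE],
         flags = x$flags[keep, , drop = FALSE]),
    class = "RawArraySet")
}
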