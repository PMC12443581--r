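# Independent oracles used to check package computations.

# Literal Benjamini-Hochberg step-up definition: sort ascending,
# adj_i = min over j >= i of p_(j) * m / j, capped at 1, input order restored.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) min(1, ps[i:m] * m / (i:m)),
                numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric upper tail P(X >= k) by direct enumeration of the
# counting formula, for a 2x2 table with margins (K, N - K) x (n, N - n).
brute_hyper_tail <- function(k, K, n, N) {
  js <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Build a small RawArraySet by hand. `cy5`/`cy3` are matrices for the
# regular probes; spike-ins are appended with constant per-sample levels.
make_raw <- function(cy5, cy3, flags = NULL, groups = NULL,
                     spike5 = c(1024, 1024), spike3 = c(1024, 1024),
                     transcript_id = NULL, rna_class = NULL) {
  cy5 <- as.matrix(cy5)
  cy3 <- as.matrix(cy3)
  n <- nrow(cy5)
  ns <- ncol(cy5)
  if (is.null(flags)) flags <- matrix("P", n, ns)
  if (is.null(groups)) groups <- rep(c("g1", "g2"), length.out = ns)
  if (is.null(transcript_id)) transcript_id <- sprintf("T%02d", seq_len(n))
  if (is.null(rna_class)) rna_class <- rep("mRNA", n)
  n_sp <- length(spike5)
  stopifnot(length(spike3) == n_sp)
  probes <- data.frame(
    probe_id = c(sprintf("PR%02d", seq_len(n)),
                 sprintf("SP%02d", seq_len(n_sp))),
    transcript_id = c(transcript_id, sprintf("SP%02d", seq_len(n_sp))),
    gene_symbol = c(toupper(transcript_id), sprintf("SP%02d", seq_len(n_sp))),
    rna_class = c(rna_class, rep(NA_character_, n_sp)),
    spikein = c(rep("none", n), rep("pos", n_sp)),
    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("S%d", seq_len(ns)),
                        group = groups, stringsAsFactors = FALSE)
  raw_array_set(probes, samples,
                rbind(cy5, matrix(rep(spike5, ns), n_sp, ns)),
                rbind(cy3, matrix(rep(spike3, ns), n_sp, ns)),
                rbind(flags, matrix("P", n_sp, ns)))
}

# Hand-made differential result table for classification tests.
make_diff <- function(transcript_id, log2fc, p, measure = "m6a",
                      rna_class = "mRNA") {
  data.frame(transcript_id = transcript_id, rna_class = rna_class,
             measure = measure, log2fc = log2fc, fc = 2^log2fc, p = p,
             p_adj = bh_adjust(p), stringsAsFactors = FALSE)
}
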