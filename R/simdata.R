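# Global scanner-scale constant: with baseline log2 abundance ~ N(3, 1.2)
# and IP-capture fractions around 0.25, raw intensities land in the
# 10^2-10^5 range typical of a 16-bit scanner.
.SIM_SCALE <- 2000

#' Configuration for the synthetic MeRIP-array generator
#'
#' Describes a two-group (proliferative vs involuting), three-replicates-per-
#' group epitranscriptomic array experiment. The default transcript census is
#' the study design scaled to 10,000 probes while preserving the relative
#' abundance of the six RNA classes.
#'
#' @param n_transcripts named integer vector, transcripts per RNA class
#'   (names from [RNA_CLASSES]).
#' @param n_per_group replicate arrays per group.
#' @param frac_dm_up,frac_dm_down fraction of transcripts (per class) with a
#'   planted methylation gain / loss in group 2.
#' @param frac_de_up,frac_de_down fraction with a planted expression gain /
#'   loss in group 2.
#' @param dm_effect log-odds shift applied to the methylated fraction of DM
#'   transcripts. The default 1.5, combined with baseline fractions truncated
#'   to (0.05, 0.5), guarantees a true methylation ratio of at least 1.5.
#' @param de_effect log2 abundance shift for DE transcripts.
#' @param couple_dm_de if `TRUE`, planted expression changes are placed on the
#'   same transcripts as the methylation changes, with matching sign (used to
#'   emulate positive methylation-expression coupling).
#' @param noise_sd SD (log2 scale) of the multiplicative lognormal
#'   measurement noise; must be > 0.
#' @param n_spikein_pos,n_spikein_neg number of positive / negative spike-in
#'   control probes.
#' @param spikein_level fixed raw intensity budget of a spike-in probe.
#' @param frac_absent_flags probability that a probe-sample pair is flagged
#'   absent (`"A"`).
#' @param seed integer RNG seed; fixes the full output exactly.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = c(mRNA = 7525, lncRNA = 1914,
                                         `pri-miRNA` = 261, `pre-miRNA` = 172,
                                         snoRNA = 125, snRNA = 3),
                       n_per_group = 3,
                       frac_dm_up = 0, frac_dm_down = 0,
                       frac_de_up = 0, frac_de_down = 0,
                       dm_effect = 1.5, de_effect = 1,
                       couple_dm_de = FALSE,
                       noise_sd = 0.25,
                       n_spikein_pos = 8, n_spikein_neg = 8,
                       spikein_level = 2e4,
                       frac_absent_flags = 0.01,
                       seed = 1) {
  if (is.null(names(n_transcripts)) ||
      !all(names(n_transcripts) %in% RNA_CLASSES))
    stop("n_transcripts must be named with RNA classes from RNA_CLASSES")
  if (any(n_transcripts < 1) || n_per_group < 2 ||
      n_spikein_pos < 1 || n_spikein_neg < 1)
    stop("counts must be positive (n_per_group >= 2)")
  fr <- c(frac_dm_up, frac_dm_down, frac_de_up, frac_de_down,
          frac_absent_flags)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]")
  if (frac_dm_up + frac_dm_down > 1)
    stop("frac_dm_up + frac_dm_down exceeds 1")
  if (frac_de_up + frac_de_down > 1)
    stop("frac_de_up + frac_de_down exceeds 1")
  if (!couple_dm_de &&
      frac_dm_up + frac_dm_down + frac_de_up + frac_de_down > 1)
    stop("planted-effect fractions exceed 1: uncoupled DM and DE sets are ",
         "disjoint, so their fractions must sum to at most 1")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (spikein_level <= 0) stop("spikein_level must be > 0")
  structure(list(n_transcripts = n_transcripts, n_per_group = n_per_group,
                 frac_dm_up = frac_dm_up, frac_dm_down = frac_dm_down,
                 frac_de_up = frac_de_up, frac_de_down = frac_de_down,
                 dm_effect = dm_effect, de_effect = de_effect,
                 couple_dm_de = couple_dm_de, noise_sd = noise_sd,
                 n_spikein_pos = n_spikein_pos, n_spikein_neg = n_spikein_neg,
                 spikein_level = spikein_level,
                 frac_absent_flags = frac_absent_flags, seed = seed),
            class = "sim_config")
}

# Beta(shape1, shape2) truncated to (lo, hi) via the probability-integral
# transform, so one uniform draw per value keeps the RNG stream compact.
rbeta_trunc <- function(n, shape1, shape2, lo, hi) {
  u <- stats::runif(n, stats::pbeta(lo, shape1, shape2),
                    stats::pbeta(hi, shape1, shape2))
  stats::qbeta(u, shape1, shape2)
}

#' Simulate a MeRIP two-channel array dataset with known ground truth
#'
#' Generates raw Cy5 (IP) and Cy3 (supernatant) intensities under a
#' partition-of-signal model: a transcript with log2 abundance `E` and
#' methylated fraction `m` emits an expected IP intensity `A * 2^E * m` and
#' supernatant intensity `A * 2^E * (1 - m)`; each observed intensity is
#' further multiplied by independent lognormal noise `2^N(0, noise_sd^2)`.
#' Planted methylation changes shift `m` on the log-odds scale; planted
#' expression changes shift `E` on the log2 scale. Spike-in probes are
#' emitted at the fixed `spikein_level` split 90/10 between channels for
#' positive controls and entirely into the supernatant channel for negative
#' controls. The output is fully determined by `config` (including its seed).
#'
#' @param config a [sim_config()].
#' @return A list with components `raw` (a `RawArraySet`) and `truth` (a
#'   data.frame with the per-transcript generating parameters and
#'   `dm_label` / `de_label` in `{"up","down","null"}`; "up" means higher in
#'   group 2, the involuting phase).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cls <- rep(names(config$n_transcripts), config$n_transcripts)
  n <- length(cls)
  tid <- sprintf("TX%06d", seq_len(n))
  gene <- sprintf("GENE%06d", seq_len(n))

  e1 <- stats::rnorm(n, mean = 3, sd = 1.2)
  m1 <- rbeta_trunc(n, 2, 6, 0.05, 0.5)

  dm_dir <- integer(n)
  de_dir <- integer(n)
  offset <- 0L
  for (k in seq_along(config$n_transcripts)) {
    nc <- config$n_transcripts[[k]]
    idx <- offset + seq_len(nc)
    n_dmu <- round(config$frac_dm_up * nc)
    n_dmd <- round(config$frac_dm_down * nc)
    dm_dir[idx[seq_len(n_dmu)]] <- 1L
    dm_dir[idx[n_dmu + seq_len(n_dmd)]] <- -1L
    if (config$couple_dm_de) {
      de_dir[idx] <- dm_dir[idx]
    } else {
      n_deu <- round(config$frac_de_up * nc)
      n_ded <- round(config$frac_de_down * nc)
      # DE transcripts taken from the tail of the class so DM and DE sets
      # are disjoint (feasibility was checked by sim_config)
      de_dir[idx[nc + 1 - seq_len(n_deu)]] <- 1L
      de_dir[idx[nc - n_deu + 1 - seq_len(n_ded)]] <- -1L
    }
    offset <- offset + nc
  }

  e2 <- e1 + config$de_effect * de_dir
  m2 <- stats::plogis(stats::qlogis(m1) + config$dm_effect * dm_dir)

  groups <- c("proliferative", "involuting")
  ns <- config$n_per_group
  samples <- data.frame(
    sample_id = c(sprintf("prolif_%d", seq_len(ns)),
                  sprintf("involut_%d", seq_len(ns))),
    group = rep(groups, each = ns),
    stringsAsFactors = FALSE)
  nsamp <- 2L * ns

  cy5 <- matrix(NA_real_, n, nsamp)
  cy3 <- matrix(NA_real_, n, nsamp)
  flags <- matrix("P", n, nsamp)
  for (s in seq_len(nsamp)) {
    g2 <- samples$group[s] == "involuting"
    e <- if (g2) e2 else e1
    m <- if (g2) m2 else m1
    base <- .SIM_SCALE * 2^(e + stats::rnorm(n, 0, config$noise_sd))
    cy5[, s] <- base * m
    base <- .SIM_SCALE * 2^(e + stats::rnorm(n, 0, config$noise_sd))
    cy3[, s] <- base * (1 - m)
    flags[stats::runif(n) < config$frac_absent_flags, s] <- "A"
  }

  # spike-ins: fixed nominal intensities, always flagged present
  n_sp <- config$n_spikein_pos + config$n_spikein_neg
  sp_kind <- rep(c("pos", "neg"), c(config$n_spikein_pos,
                                    config$n_spikein_neg))
  sp_m <- ifelse(sp_kind == "pos", 0.9, 0)
  sp_cy5 <- matrix(rep(config$spikein_level * sp_m, nsamp), n_sp, nsamp)
  sp_cy3 <- matrix(rep(config$spikein_level * (1 - sp_m), nsamp), n_sp, nsamp)
  sp_cy5[sp_cy5 <= 0] <- NA_real_
  sp_id <- sprintf("SPIKE_%s_%02d", toupper(sp_kind),
                   c(seq_len(config$n_spikein_pos),
                     seq_len(config$n_spikein_neg)))

  probes <- data.frame(
    probe_id = c(paste0("P_", tid), sp_id),
    transcript_id = c(tid, sp_id),
    gene_symbol = c(gene, sp_id),
    rna_class = c(cls, rep(NA_character_, n_sp)),
    spikein = c(rep("none", n), sp_kind),
    stringsAsFactors = FALSE)

  raw <- raw_array_set(probes, samples,
                       rbind(cy5, sp_cy5), rbind(cy3, sp_cy3),
                       rbind(flags, matrix("P", n_sp, nsamp)))

  lab <- function(d) c("down", "null", "up")[d + 2L]
  truth <- data.frame(
    transcript_id = tid, rna_class = cls,
    abundance_log2_proliferative = e1, abundance_log2_involuting = e2,
    meth_fraction_proliferative = m1, meth_fraction_involuting = m2,
    dm_label = lab(dm_dir), de_label = lab(de_dir),
    stringsAsFactors = FALSE)
  list(raw = raw, truth = truth)
}

#' Simulate a qPCR plate with known relative quantities and %input
#'
#' Ct values follow `Ct = base_ct - log2(quantity) + N(0, sigma_ct)`, with
#' every reaction run in duplicate wells. For relative-expression targets the
#' plate carries a calibrator condition (quantity 1) and a test condition at
#' the requested relative quantity, plus the reference gene at quantity 1 in
#' both conditions. For MeRIP targets the %input is encoded by splitting the
#' quantity between the MeRIP and Supernatant fractions, so at `sigma_ct = 0`
#' the [percent_input()] formula recovers it exactly.
#'
#' @param targets character vector of target gene names.
#' @param rel_quantity named vector, true expression of each target in the
#'   test condition relative to the calibrator (omit or `NULL` for none).
#' @param pct_input named vector, true MeRIP %input per target in (0, 100)
#'   (omit or `NULL` for none).
#' @param reference endogenous reference gene name (default `"U6"`).
#' @param sigma_ct SD of the Ct measurement noise, in cycles.
#' @param base_ct Ct of a unit-quantity reaction.
#' @param n_replicate_wells wells per reaction (default 2, duplicate wells).
#' @param seed RNG seed.
#' @return data.frame with columns `well`, `target_id`, `fraction`
#'   (`"MeRIP"`, `"Supernatant"` or `"none"`), `condition`, `replicate`, `ct`.
#' @export
simulate_qpcr_plate <- function(targets, rel_quantity = NULL,
                                pct_input = NULL, reference = "U6",
                                sigma_ct = 0.2, base_ct = 22,
                                n_replicate_wells = 2, seed = 1) {
  set.seed(seed)
  rows <- list()
  if (!is.null(rel_quantity)) {
    if (is.null(names(rel_quantity)) ||
        !all(targets %in% names(rel_quantity)))
      stop("rel_quantity must be named for every target")
    if (any(rel_quantity <= 0)) stop("rel_quantity must be positive")
    for (tg in c(targets, reference)) for (cond in c("calibrator", "test")) {
      q <- if (tg == reference || cond == "calibrator") 1 else
        unname(rel_quantity[tg])
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = tg, fraction = "none", condition = cond,
        replicate = seq_len(n_replicate_wells),
        ct_true = base_ct - log2(q), stringsAsFactors = FALSE)
    }
  }
  if (!is.null(pct_input)) {
    if (is.null(names(pct_input)) || !all(targets %in% names(pct_input)))
      stop("pct_input must be named for every target")
    if (any(pct_input <= 0 | pct_input >= 100))
      stop("pct_input must lie strictly between 0 and 100")
    for (tg in targets) {
      p <- unname(pct_input[tg]) / 100
      for (fr in c("MeRIP", "Supernatant")) {
        q <- if (fr == "MeRIP") p else 1 - p
        rows[[length(rows) + 1L]] <- data.frame(
          target_id = tg, fraction = fr, condition = "test",
          replicate = seq_len(n_replicate_wells),
          ct_true = base_ct - log2(q), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    stop("provide rel_quantity and/or pct_input")
  plate <- do.call(rbind, rows)
  plate$ct <- plate$ct_true + stats::rnorm(nrow(plate), 0, sigma_ct)
  plate$ct_true <- NULL
  plate <- cbind(well = sprintf("W%03d", seq_len(nrow(plate))), plate)
  plate
}
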