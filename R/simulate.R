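#' Draw overdispersed read counts
#'
#' Samples from the negative binomial with mean `mu` and variance
#' `mu + eta * mu^lambda` via its gamma-Poisson mixture representation
#' (shape `mu^(2 - lambda) / eta`), which corresponds exactly to
#' [negbin_read_pmf]. `eta = 0` draws Poisson counts; `mu = 0` yields 0.
#'
#' @param n Number of draws.
#' @param mu Expected read count, recycled to length `n`.
#' @param params A [read_model_params] object.
#' @return Integer vector of length `n`.
#' @export
rnegbin_powerlaw <- function(n, mu, params) {
  params <- as_read_model_params(params)
  mu <- rep_len(mu, n)
  out <- integer(n)
  pos <- mu > 0
  if (!any(pos)) return(out)
  m <- mu[pos]
  size <- nb_size(m, params)
  pois <- !is.finite(size) | size > .size_poisson_cutoff
  draws <- integer(length(m))
  if (any(pois)) draws[pois] <- stats::rpois(sum(pois), m[pois])
  if (any(!pois)) {
    rate <- stats::rgamma(sum(!pois), shape = size[!pois],
                          rate = size[!pois] / m[!pois])
    draws[!pois] <- stats::rpois(sum(!pois), rate)
  }
  out[pos] <- draws
  out
}

#' Simulate two-step clonotype read counts
#'
#' For each draw, the number of sampled target cells is Poisson with rate
#' `f_body * t_samp`; conditional on it, the read count is negative
#' binomial with mean `(c_samp / t_samp) * r_e * t_read`. With
#' `sampling = FALSE` the sampling stage is bypassed and `f_body` is used
#' directly as the known in-sample frequency (the spike-in scenario).
#'
#' @param n_draws Number of independent draws.
#' @param f_body Clonotype frequency (body frequency, or sample frequency
#'   when `sampling = FALSE`).
#' @param t_samp Number of T cells in the sample (ignored when
#'   `sampling = FALSE`).
#' @param t_read Total sequencing reads.
#' @param params A [read_model_params] object.
#' @param seed Optional seed.
#' @param sampling Include the Poisson blood-sampling stage?
#' @return Integer vector of simulated read counts.
#' @export
simulate_read_counts <- function(n_draws, f_body, t_samp = NULL, t_read,
                                 params, seed = NULL, sampling = TRUE) {
  params <- as_read_model_params(params)
  if (!is.null(seed)) set.seed(seed)
  if (sampling) {
    check_sampling(f_body, t_samp)
    c_samp <- stats::rpois(n_draws, f_body * t_samp)
    mu <- (c_samp / t_samp) * params$r_e * t_read
  } else {
    mu <- rep(f_body * params$r_e * t_read, n_draws)
  }
  rnegbin_powerlaw(n_draws, mu, params)
}

#' Spike-in experiment design
#'
#' Describes a synthetic spike-in experiment: frequency tiers with a number
#' of clones each, replicates, chains and a background repertoire. The
#' defaults mirror a titration of 45 T-cell clones over nine frequency
#' tiers (1, 3, 10, 50, 300, 1000, 3000, 10000 and 50000 per million) with
#' five clones per tier, sequenced in six replicates, on a long-tailed
#' background of unknown clonotypes.
#'
#' @param tier_freqs Spike-in frequencies (fractions), one per tier.
#' @param clones_per_tier Clones in each tier (recycled).
#' @param n_replicates Replicates per set.
#' @param chains Chains to simulate, subset of `c("TRA", "TRB")`.
#' @param background_clones Number of background (non-spike-in) clonotypes.
#' @param background_exponent Power-law exponent of the background
#'   rank-frequency distribution.
#' @return An object of class `"spikein_design"`.
#' @export
spikein_design <- function(tier_freqs = c(1, 3, 10, 50, 300, 1000, 3000,
                                          10000, 50000) * 1e-6,
                           clones_per_tier = 5, n_replicates = 6,
                           chains = c("TRA", "TRB"),
                           background_clones = 400,
                           background_exponent = 2) {
  stopifnot(all(tier_freqs > 0), all(tier_freqs < 1), n_replicates >= 1,
            background_clones >= 0, all(chains %in% c("TRA", "TRB")))
  clones_per_tier <- rep_len(clones_per_tier, length(tier_freqs))
  if (sum(tier_freqs * clones_per_tier) > 1)
    stop("design frequencies sum to more than 1", call. = FALSE)
  structure(list(tier_freqs = tier_freqs,
                 clones_per_tier = clones_per_tier,
                 n_replicates = n_replicates, chains = chains,
                 background_clones = background_clones,
                 background_exponent = background_exponent),
            class = "spikein_design")
}

#' @export
print.spikein_design <- function(x, ...) {
  cat(sprintf(paste0("Spike-in design: %d clones over %d tiers, %d ",
                     "replicate(s), chains %s, %d background clonotypes\n"),
              sum(x$clones_per_tier), length(x$tier_freqs),
              x$n_replicates, paste(x$chains, collapse = "/"),
              x$background_clones))
  invisible(x)
}

# Random distinct CDR3 nucleotide sequences; lengths multiples of 3 in
# [24, 60] so the IMGT trim always leaves a long core.
random_cdr3s <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    len <- sample(seq(24, 60, by = 3), n, replace = TRUE)
    seqs <- vapply(len, function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
            collapse = ""), character(1))
    out <- unique(c(out, seqs))
  }
  out[seq_len(n)]
}

#' Simulate a pure calibration table
#'
#' Spike-in read counts at known sample frequencies (sampling stage
#' bypassed), in the layout [fit_read_model] consumes: one row per
#' clone x replicate with `f_samp` and `c_read`.
#'
#' @param design A [spikein_design].
#' @param params A [read_model_params] object (the simulation truth).
#' @param t_read Total reads per replicate.
#' @param seed Optional seed.
#' @param chain Chain label stored in the table.
#' @return Data frame with columns `f_samp`, `c_read`, `chain`, `set_id`,
#'   `replicate_id`, `clone_id`.
#' @export
simulate_calibration_data <- function(design, params, t_read, seed = NULL,
                                      chain = "TRB") {
  stopifnot(inherits(design, "spikein_design"))
  params <- as_read_model_params(params)
  if (!is.null(seed)) set.seed(seed)
  f <- rep(design$tier_freqs, design$clones_per_tier)
  n_clone <- length(f)
  out <- do.call(rbind, lapply(seq_len(design$n_replicates), function(r) {
    data.frame(f_samp = f,
               c_read = rnegbin_powerlaw(n_clone, f * params$r_e * t_read,
                                         params),
               chain = chain, set_id = "Set1",
               replicate_id = sprintf("rep%d", r),
               clone_id = sprintf("TCC%02d", seq_len(n_clone)))
  }))
  rownames(out) <- NULL
  out
}

#' Generate a full synthetic spike-in experiment
#'
#' Builds a spike-in reference (random distinct CDR3s per chain, tier
#' frequencies) and per-replicate clonotype tables with read counts drawn
#' from the calibrated read model, on top of a power-law background
#' repertoire. Optionally plants quality-control artefacts: clones dropped
#' from every replicate (to exercise the undetected-spike-in exclusion
#' rule), and a control set — spike-in mix only — contaminated with
#' exclusive low-count false positives and index-hopping false positives
#' carried over from the background at a fixed count ratio.
#'
#' @param design A [spikein_design].
#' @param params A [read_model_params] simulation truth.
#' @param t_read Total reads per replicate and chain.
#' @param seed Optional seed.
#' @param set_ids Character vector of experiment-set labels to simulate.
#' @param dropout_clones Number of spike-in clones forced to zero reads in
#'   every replicate of every set (all chains).
#' @param control_set Also generate a spike-in-only control set?
#' @param fp_exclusive_counts Integer read counts of planted
#'   control-exclusive false positives (per chain).
#' @param fp_hopping Number of background clonotypes leaking into the
#'   control set as index-hopping false positives (per chain).
#' @param hop_ratio Expected control-set count of a hopped clonotype as a
#'   fraction of its count elsewhere.
#' @param exact_totals Condition each replicate on exactly `t_read` reads
#'   by a multinomial redraw of the drawn counts.
#' @return A list of class `"spikein_experiment"` with elements
#'   `reference` (clone_id, chain, cdr3_nt_imgt, design_freq), `records`
#'   (clonotype rows: cdr3_nt, chain, read_count, read_fraction, set_id,
#'   replicate_id), `control_records` (or NULL), `dropped_clones`,
#'   `design`, `params`, `t_read`.
#' @export
generate_spikein_experiment <- function(design, params, t_read,
                                        seed = NULL, set_ids = "Set1",
                                        dropout_clones = 0,
                                        control_set = FALSE,
                                        fp_exclusive_counts = integer(0),
                                        fp_hopping = 0, hop_ratio = 0.01,
                                        exact_totals = FALSE) {
  stopifnot(inherits(design, "spikein_design"))
  params <- as_read_model_params(params)
  if (!is.null(seed)) set.seed(seed)
  f_spike <- rep(design$tier_freqs, design$clones_per_tier)
  n_clone <- length(f_spike)
  clone_ids <- sprintf("TCC%02d", seq_len(n_clone))
  dropped <- character(0)
  if (dropout_clones > 0)
    dropped <- sample(clone_ids, dropout_clones)

  reference <- do.call(rbind, lapply(design$chains, function(ch) {
    data.frame(clone_id = clone_ids, chain = ch,
               cdr3_nt_imgt = random_cdr3s(n_clone),
               design_freq = f_spike)
  }))

  # background repertoire: power-law rank-frequency, normalised to the
  # probability mass not taken by the spike-ins
  n_bg <- design$background_clones
  bg_mass <- max(1 - sum(f_spike), 0)
  bg_freq <- if (n_bg > 0) {
    w <- seq_len(n_bg)^(-design$background_exponent)
    bg_mass * w / sum(w)
  } else numeric(0)

  sim_chain_tables <- function(ch, sets, spike_f, include_bg) {
    ref_ch <- reference[reference$chain == ch, ]
    bg_cdr3 <- if (include_bg && n_bg > 0) {
      # pad so padding trim leaves >= 1 nt; distinct from spike CDR3s
      cand <- random_cdr3s(n_bg + n_clone)
      setdiff(cand, ref_ch$cdr3_nt_imgt)[seq_len(n_bg)]
    } else character(0)
    cdr3 <- c(ref_ch$cdr3_nt_imgt, bg_cdr3)
    freq <- c(spike_f, if (include_bg) bg_freq else numeric(0))
    zero <- ref_ch$clone_id %in% dropped
    do.call(rbind, lapply(sets, function(s) {
      do.call(rbind, lapply(seq_len(design$n_replicates), function(r) {
        cnt <- rnegbin_powerlaw(length(freq),
                                freq * params$r_e * t_read, params)
        cnt[c(zero, rep(FALSE, length(bg_cdr3)))] <- 0L
        if (exact_totals && sum(cnt) > 0)
          cnt <- as.integer(stats::rmultinom(1, t_read,
                                             prob = cnt / sum(cnt)))
        keep <- cnt > 0
        tot <- sum(cnt)
        data.frame(cdr3_nt = cdr3[keep], chain = ch,
                   read_count = cnt[keep],
                   read_fraction = if (tot > 0) cnt[keep] / tot else 0,
                   set_id = s, replicate_id = sprintf("rep%d", r),
                   bg_index = c(rep(NA_integer_, n_clone),
                                seq_along(bg_cdr3))[keep])
      }))
    }))
  }

  records <- do.call(rbind, lapply(design$chains, sim_chain_tables,
                                   sets = set_ids, spike_f = f_spike,
                                   include_bg = TRUE))

  control_records <- NULL
  if (control_set || length(fp_exclusive_counts) || fp_hopping > 0) {
    # control mix: spike-ins only, frequencies renormalised to sum to 1
    ctrl <- do.call(rbind, lapply(design$chains, sim_chain_tables,
                                  sets = "Control",
                                  spike_f = f_spike / sum(f_spike),
                                  include_bg = FALSE))
    extras <- list()
    for (ch in design$chains) {
      if (length(fp_exclusive_counts)) {
        extras[[paste0(ch, "_excl")]] <- data.frame(
          cdr3_nt = random_cdr3s(length(fp_exclusive_counts)),
          chain = ch, read_count = as.integer(fp_exclusive_counts),
          read_fraction = 0, set_id = "Control",
          replicate_id = "rep1", bg_index = NA_integer_)
      }
      if (fp_hopping > 0 && n_bg >= fp_hopping) {
        # index hopping: background clonotypes from the main sets leak in
        # at hop_ratio of their counts there
        main_ch <- records[records$chain == ch &
                             records$replicate_id == "rep1" &
                             records$set_id == set_ids[1] &
                             !is.na(records$bg_index), ]
        main_ch <- main_ch[order(-main_ch$read_count), ]
        src <- utils::head(main_ch, fp_hopping)
        hop_cnt <- stats::rpois(nrow(src),
                                pmax(src$read_count * hop_ratio, 0))
        keep <- hop_cnt > 0
        if (any(keep))
          extras[[paste0(ch, "_hop")]] <- data.frame(
            cdr3_nt = src$cdr3_nt[keep], chain = ch,
            read_count = as.integer(hop_cnt[keep]), read_fraction = 0,
            set_id = "Control", replicate_id = "rep1",
            bg_index = NA_integer_)
      }
    }
    control_records <- rbind(ctrl, do.call(rbind, extras))
    # recompute read fractions per chain x replicate
    for (ch in unique(control_records$chain)) {
      for (r in unique(control_records$replicate_id)) {
        sel <- control_records$chain == ch &
          control_records$replicate_id == r
        tot <- sum(control_records$read_count[sel])
        if (tot > 0)
          control_records$read_fraction[sel] <-
            control_records$read_count[sel] / tot
      }
    }
    rownames(control_records) <- NULL
    control_records$bg_index <- NULL
  }

  records$bg_index <- NULL
  rownames(records) <- NULL
  rownames(reference) <- NULL
  structure(list(reference = reference, records = records,
                 control_records = control_records,
                 dropped_clones = sort(dropped), design = design,
                 params = params, t_read = t_read),
            class = "spikein_experiment")
}

#' @export
print.spikein_experiment <- function(x, ...) {
  cat(sprintf(paste0("Synthetic spike-in experiment: %d reference ",
                     "entries, %d clonotype rows%s\n"),
              nrow(x$reference), nrow(x$records),
              if (is.null(x$control_records)) ""
              else sprintf(", %d control rows", nrow(x$control_records))))
  if (length(x$dropped_clones))
    cat("  planted dropouts:", paste(x$dropped_clones, collapse = ", "),
        "\n")
  invisible(x)
}

#' Write a synthetic experiment as MiXCR-style fixtures
#'
#' One clones-list TSV per chain x set x replicate (columns `cloneCount`,
#' `cloneFraction`, `nSeqCDR3`) plus the spike-in reference as
#' `reference.tsv`.
#'
#' @param experiment A [generate_spikein_experiment] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_spikein_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "spikein_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  all_rec <- rbind(experiment$records, experiment$control_records)
  key <- unique(all_rec[, c("chain", "set_id", "replicate_id")])
  for (i in seq_len(nrow(key))) {
    sel <- all_rec$chain == key$chain[i] &
      all_rec$set_id == key$set_id[i] &
      all_rec$replicate_id == key$replicate_id[i]
    tab <- data.frame(cloneCount = all_rec$read_count[sel],
                      cloneFraction = all_rec$read_fraction[sel],
                      nSeqCDR3 = all_rec$cdr3_nt[sel])
    p <- file.path(dir, sprintf("clones_%s_%s_%s.tsv", key$chain[i],
                                key$set_id[i], key$replicate_id[i]))
    utils::write.table(tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  pref <- file.path(dir, "reference.tsv")
  utils::write.table(experiment$reference, pref, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, pref))
}
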