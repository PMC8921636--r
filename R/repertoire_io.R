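#' Read a MiXCR-style clonotype table
#'
#' Parses a tab-separated clones list with (at least) a nucleotide-CDR3
#' column and a read-count column. Column names are configurable; the
#' defaults match common MiXCR exports. Rows with malformed counts or
#' non-ACGT CDR3 characters are dropped with a warning naming their line
#' numbers.
#'
#' @param path Path to the TSV file.
#' @param columns Named list mapping `count`, `cdr3` and (optionally)
#'   `fraction` to column names; for `cdr3` several candidates may be
#'   given and the first present is used.
#' @param chain,set_id,replicate_id Metadata labels attached to every row.
#' @return A data frame of clonotype records: `cdr3_nt`, `chain`,
#'   `read_count`, `read_fraction`, `set_id`, `replicate_id`.
#' @export
read_clonotype_table <- function(path,
                                 columns = list(
                                   count = "cloneCount",
                                   fraction = "cloneFraction",
                                   cdr3 = c("nSeqImputedCDR3",
                                            "nSeqCDR3")),
                                 chain = NA_character_,
                                 set_id = NA_character_,
                                 replicate_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(tab) == 0) stop("empty clonotype table: ", path, call. = FALSE)
  if (!columns$count %in% names(tab))
    stop("missing required count column '", columns$count, "' in ", path,
         call. = FALSE)
  cdr3_col <- intersect(columns$cdr3, names(tab))[1]
  if (is.na(cdr3_col))
    stop("missing required CDR3 column (tried: ",
         paste(columns$cdr3, collapse = ", "), ") in ", path,
         call. = FALSE)
  cnt <- suppressWarnings(as.numeric(tab[[columns$count]]))
  cdr3 <- toupper(as.character(tab[[cdr3_col]]))
  frac <- if (!is.null(columns$fraction) &&
              columns$fraction %in% names(tab))
    suppressWarnings(as.numeric(tab[[columns$fraction]]))
  else rep(NA_real_, nrow(tab))
  bad <- !is.finite(cnt) | cnt < 0 | cnt != floor(cnt) |
    is.na(cdr3) | cdr3 == "" | grepl("[^ACGT]", cdr3)
  if (any(bad)) {
    warning(sprintf("dropped %d malformed row(s) at line(s) %s of %s",
                    sum(bad),
                    paste(utils::head(which(bad) + 1L, 20), collapse = ", "),
                    basename(path)), call. = FALSE)
  }
  if (all(bad)) stop("no valid rows in ", path, call. = FALSE)
  data.frame(cdr3_nt = cdr3[!bad], chain = chain,
             read_count = as.integer(cnt[!bad]),
             read_fraction = frac[!bad], set_id = set_id,
             replicate_id = replicate_id)
}

#' Trim a MiXCR CDR3 to the IMGT junction convention
#'
#' Removes the first and last three nucleotides, converting a
#' MiXCR-delimited CDR3 to the IMGT boundary convention used by spike-in
#' references. Vectorised.
#'
#' @param cdr3_nt Nucleotide CDR3 string(s), length at least 7.
#' @return Trimmed string(s), six nucleotides shorter.
#' @examples
#' trim_cdr3_to_imgt("TGTGCAAGCTTT") # "GCAAGC"
#' @export
trim_cdr3_to_imgt <- function(cdr3_nt) {
  cdr3_nt <- as.character(cdr3_nt)
  if (any(is.na(cdr3_nt)) || any(nchar(cdr3_nt) < 7))
    stop("CDR3 shorter than 7 nt cannot be trimmed to a non-empty core",
         call. = FALSE)
  substr(cdr3_nt, 4L, nchar(cdr3_nt) - 3L)
}

#' Match clonotype records against a spike-in reference
#'
#' Exact nucleotide-CDR3 equality per chain identifies spike-ins; V-gene
#' or other annotations are not used. Duplicate library pairs (set labels
#' differing only in a trailing `a`/`b`) are merged by summing counts
#' before frequencies are computed. The measured frequency of a match is
#' its read count divided by the total chain reads of its set x replicate.
#' Spike-ins absent from a replicate are reported with count 0.
#'
#' @param records Clonotype records (as from [read_clonotype_table] or the
#'   simulator), one or more sets/replicates row-bound together.
#' @param reference Spike-in reference: `clone_id`, `chain`,
#'   `cdr3_nt_imgt`, `design_freq`.
#' @param trim Apply [trim_cdr3_to_imgt] to the records first?
#' @param merge_duplicates Merge `a`/`b` duplicate libraries (pattern
#'   `"[ab]$"` on `set_id`)?
#' @return A data frame with one row per clone x chain x set x replicate:
#'   `clone_id`, `chain`, `set_id`, `replicate_id`, `design_freq`,
#'   `read_count`, `measured_freq`, `detected`.
#' @export
match_spikeins <- function(records, reference, trim = FALSE,
                           merge_duplicates = TRUE) {
  stopifnot(all(c("cdr3_nt", "chain", "read_count", "set_id",
                  "replicate_id") %in% names(records)),
            all(c("clone_id", "chain", "cdr3_nt_imgt", "design_freq") %in%
                  names(reference)))
  dup <- duplicated(reference[, c("chain", "cdr3_nt_imgt")])
  if (any(dup))
    stop("duplicate reference CDR3s within a chain: ground truth is ",
         "ambiguous (", paste(unique(
           reference$cdr3_nt_imgt[dup]), collapse = ", "), ")",
         call. = FALSE)
  records$cdr3_nt <- if (trim) trim_cdr3_to_imgt(records$cdr3_nt)
  else as.character(records$cdr3_nt)
  if (merge_duplicates) {
    records$set_id <- sub("[ab]$", "", records$set_id)
    agg <- stats::aggregate(read_count ~ cdr3_nt + chain + set_id +
                              replicate_id, data = records, FUN = sum)
    records <- agg
  }
  # totals per chain x set x replicate, over ALL clonotypes
  tot <- stats::aggregate(read_count ~ chain + set_id + replicate_id,
                          data = records, FUN = sum)
  names(tot)[names(tot) == "read_count"] <- "total_reads"
  reps <- unique(records[, c("set_id", "replicate_id")])
  grid <- merge(reference, reps, by = NULL)
  m <- merge(grid, records,
             by.x = c("cdr3_nt_imgt", "chain", "set_id", "replicate_id"),
             by.y = c("cdr3_nt", "chain", "set_id", "replicate_id"),
             all.x = TRUE)
  m$read_count[is.na(m$read_count)] <- 0L
  m <- merge(m, tot, by = c("chain", "set_id", "replicate_id"),
             all.x = TRUE)
  m$measured_freq <- ifelse(m$total_reads > 0,
                            m$read_count / m$total_reads, 0)
  m$detected <- m$read_count > 0
  out <- m[order(m$clone_id, m$chain, m$set_id, m$replicate_id),
           c("clone_id", "chain", "set_id", "replicate_id", "design_freq",
             "read_count", "measured_freq", "detected")]
  rownames(out) <- NULL
  out
}

#' Exclude spike-ins undetected everywhere
#'
#' A spike-in chain sequence is fully undetected when it has zero reads in
#' every replicate of every set. At the default TCR level, failure of
#' either chain (TRA or TRB) excludes the whole clone from downstream
#' analysis; at the chain level only the failing chain's rows are removed.
#'
#' @param matched Output of [match_spikeins] (all sets row-bound).
#' @param by `"tcr"` (default) or `"chain"`.
#' @return A list with `retained` (filtered table) and `excluded` (data
#'   frame of excluded `clone_id`/`chain` combinations).
#' @export
exclude_fully_undetected <- function(matched, by = c("tcr", "chain")) {
  by <- match.arg(by)
  tot <- stats::aggregate(read_count ~ clone_id + chain, data = matched,
                          FUN = sum)
  zero <- tot[tot$read_count == 0, c("clone_id", "chain")]
  if (by == "tcr") {
    drop_clones <- unique(zero$clone_id)
    retained <- matched[!matched$clone_id %in% drop_clones, ]
  } else {
    key <- paste(matched$clone_id, matched$chain)
    retained <- matched[!key %in% paste(zero$clone_id, zero$chain), ]
  }
  rownames(retained) <- NULL
  rownames(zero) <- NULL
  list(retained = retained, excluded = zero)
}

#' Index of dispersion of measured frequencies
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean, a
#' scale-free measure of replicate-to-replicate variability of a
#' clonotype's measured frequency.
#'
#' @param frequencies Numeric vector of length >= 2 with positive mean.
#' @return A non-negative scalar.
#' @examples
#' dispersion_index(c(1, 2, 3)) # 0.5
#' @export
dispersion_index <- function(frequencies) {
  stopifnot(is.numeric(frequencies), length(frequencies) >= 2)
  m <- mean(frequencies)
  if (m <= 0) stop("dispersion index undefined for mean <= 0",
                   call. = FALSE)
  stats::sd(frequencies) / m
}

#' Log-log linearity of measured versus ground-truth frequencies
#'
#' Coefficient of determination of an ordinary least-squares fit of
#' `log10(measured)` on `log10(truth)`, restricted to detected points
#' (measured > 0); the number of excluded undetected points is attached as
#' an attribute.
#'
#' @param truth_freqs Known spike-in frequencies.
#' @param measured_freqs Measured frequencies (same length).
#' @return R-squared in `[0, 1]`, with attribute `n_undetected`.
#' @export
linearity_r2 <- function(truth_freqs, measured_freqs) {
  stopifnot(length(truth_freqs) == length(measured_freqs),
            all(truth_freqs > 0))
  det <- is.finite(measured_freqs) & measured_freqs > 0
  if (sum(det) < 3)
    stop("need >= 3 detected (measured > 0) pairs", call. = FALSE)
  fit <- stats::lm(log10(measured_freqs[det]) ~ log10(truth_freqs[det]))
  # summary.lm warns on an exactly collinear (perfect) fit; R2 = 1 is the
  # correct answer there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(r2, n_undetected = sum(!det))
}

#' False-positive and read-cutoff analysis of a control set
#'
#' In a control library expected to contain only the spike-in clonotypes,
#' every clonotype not matching the reference is a false positive. Each is
#' categorised as `"elsewhere"` (its CDR3 also occurs, same chain, in a
#' comparison set — the index-hopping signature) or `"exclusive"`.
#' Summaries report the false-positive read fraction per chain and, for
#' each read cutoff `c`, the fraction of false-positive sequences with
#' count `<= c` (i.e. removed by a `> c` detection rule). False positives
#' with counts above the largest spike-in count in the control are flagged
#' as outliers, never dropped.
#'
#' @param control_records Clonotype records of the control set.
#' @param reference Spike-in reference table.
#' @param other_records Records of one or more comparison sets.
#' @param cutoffs Integer read cutoffs to evaluate.
#' @param trim Apply [trim_cdr3_to_imgt] to both record tables first?
#' @return An object of class `"fp_report"`: list with `sequences` (per
#'   false positive: `cdr3_nt`, `chain`, `count_in_control`,
#'   `total_count_elsewhere`, `category`, `outlier`), `fp_rate_by_chain`
#'   (false-positive read fraction), `removal_fraction_by_cutoff` (one row
#'   per cutoff, overall and per chain; 1 by convention when there are no
#'   false positives).
#' @export
false_positive_analysis <- function(control_records, reference,
                                    other_records,
                                    cutoffs = c(1, 2, 5, 10, 18, 50),
                                    trim = FALSE) {
  if (is.null(control_records) || nrow(control_records) == 0)
    stop("empty control set", call. = FALSE)
  check_count(cutoffs, "cutoffs")
  ctrl <- control_records
  oth <- other_records
  if (trim) {
    ctrl$cdr3_nt <- trim_cdr3_to_imgt(ctrl$cdr3_nt)
    oth$cdr3_nt <- trim_cdr3_to_imgt(oth$cdr3_nt)
  }
  # collapse the control to one row per cdr3 x chain
  cc <- stats::aggregate(read_count ~ cdr3_nt + chain, data = ctrl,
                         FUN = sum)
  ref_key <- paste(reference$chain, reference$cdr3_nt_imgt)
  is_fp <- !paste(cc$chain, cc$cdr3_nt) %in% ref_key
  fp <- cc[is_fp, ]
  names(fp)[names(fp) == "read_count"] <- "count_in_control"
  elsewhere <- stats::aggregate(read_count ~ cdr3_nt + chain, data = oth,
                                FUN = sum)
  fp <- merge(fp, elsewhere, by = c("cdr3_nt", "chain"), all.x = TRUE)
  fp$total_count_elsewhere <- ifelse(is.na(fp$read_count), 0L,
                                     fp$read_count)
  fp$read_count <- NULL
  fp$category <- ifelse(fp$total_count_elsewhere > 0, "elsewhere",
                        "exclusive")
  if (any(!is_fp)) {
    max_spike <- stats::aggregate(read_count ~ chain, data = cc[!is_fp, ],
                                  FUN = max)
    fp <- merge(fp, max_spike, by = "chain", all.x = TRUE)
    fp$outlier <- !is.na(fp$read_count) &
      fp$count_in_control > fp$read_count
    fp$read_count <- NULL
  } else {
    fp$outlier <- FALSE
  }
  fp <- fp[order(fp$chain, -fp$count_in_control),
           c("cdr3_nt", "chain", "count_in_control",
             "total_count_elsewhere", "category", "outlier")]
  rownames(fp) <- NULL

  chains <- sort(unique(cc$chain))
  fp_rate <- vapply(chains, function(ch) {
    tot <- sum(cc$read_count[cc$chain == ch])
    if (tot == 0) return(0)
    sum(fp$count_in_control[fp$chain == ch]) / tot
  }, numeric(1))
  names(fp_rate) <- chains

  removal <- do.call(rbind, lapply(cutoffs, function(co) {
    row <- data.frame(cutoff = co,
                      overall = removal_fraction(fp$count_in_control, co))
    for (ch in chains)
      row[[ch]] <- removal_fraction(
        fp$count_in_control[fp$chain == ch], co)
    row
  }))

  structure(list(sequences = fp, fp_rate_by_chain = fp_rate,
                 removal_fraction_by_cutoff = removal),
            class = "fp_report")
}

removal_fraction <- function(counts, cutoff) {
  if (!length(counts)) return(1)  # nothing to remove: vacuously complete
  mean(counts <= cutoff)
}

#' @export
print.fp_report <- function(x, ...) {
  cat(sprintf("False-positive report: %d false-positive sequence(s)\n",
              nrow(x$sequences)))
  if (nrow(x$sequences)) {
    cat("  by category:",
        paste(sprintf("%s=%d", names(table(x$sequences$category)),
                      table(x$sequences$category)), collapse = ", "), "\n")
    if (any(x$sequences$outlier))
      cat(sprintf("  %d outlier(s) flagged (count above largest spike-in)\n",
                  sum(x$sequences$outlier)))
  }
  cat("  FP read fraction by chain:",
      paste(sprintf("%s=%.4g", names(x$fp_rate_by_chain),
                    x$fp_rate_by_chain), collapse = ", "), "\n")
  print(x$removal_fraction_by_cutoff, row.names = FALSE)
  invisible(x)
}

#' Write the per-clone matched table as TSV
#'
#' Frequencies in scientific notation, counts as integers.
#'
#' @param matched Output of [match_spikeins].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matched_table <- function(matched, path) {
  out <- matched
  out$design_freq <- format(out$design_freq, scientific = TRUE)
  out$measured_freq <- format(out$measured_freq, scientific = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
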