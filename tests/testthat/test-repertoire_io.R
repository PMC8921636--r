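make_clones_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("clonotype tables parse with the MiXCR column defaults", {
  tab <- data.frame(cloneCount = c(100L, 40L, 3L),
                    cloneFraction = c(100, 40, 3) / 143,
                    nSeqCDR3 = c("TGTGCAAGCTTTGGG", "TGTGCCAGCAGTTTC",
                                 "TGTGCTTTGAGTGCT"))
  p <- make_clones_tsv(tab)
  rec <- read_clonotype_table(p, chain = "TRB", set_id = "Set1",
                              replicate_id = "rep1")
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$read_count, c(100L, 40L, 3L))
  expect_equal(rec$chain, rep("TRB", 3))
})

test_that("missing columns and dirty rows are handled", {
  noc <- make_clones_tsv(data.frame(nSeqCDR3 = "TGTGCAAGC"))
  expect_error(read_clonotype_table(noc), "cloneCount")
  nocdr <- make_clones_tsv(data.frame(cloneCount = 5L))
  expect_error(read_clonotype_table(nocdr), "CDR3")
  dirty <- make_clones_tsv(data.frame(
    cloneCount = c(10L, 7L, 2L),
    nSeqCDR3 = c("TGTGCAAGCTTT", "TGTGNNAGCTTT", "TGTGCCAGCTTT")))
  expect_warning(rec <- read_clonotype_table(dirty), "malformed")
  expect_equal(nrow(rec), 2L)
  empty <- make_clones_tsv(data.frame(cloneCount = integer(0),
                                      nSeqCDR3 = character(0)))
  expect_error(read_clonotype_table(empty), "empty")
  expect_error(read_clonotype_table(tempfile()), "not found")
})

test_that("IMGT trimming removes exactly three nucleotides per end", {
  expect_equal(trim_cdr3_to_imgt("TGTGCAAGCTTT"), "GCAAGC")
  expect_equal(trim_cdr3_to_imgt("TGTAGCT"), "A")
  expect_error(trim_cdr3_to_imgt("TGTAGC"), "7")
  # vectorised, and trimming then matching equals matching pre-trimmed
  x <- c("TGTGCAAGCTTT", "TGTCCCAGGTTTAAA")
  expect_equal(nchar(trim_cdr3_to_imgt(x)), nchar(x) - 6L)
})

ref2 <- data.frame(clone_id = c("T1", "T2"), chain = "TRB",
                   cdr3_nt_imgt = c("GCAAGCGGG", "CCCAGGTTT"),
                   design_freq = c(1e-3, 1e-4))

test_that("spike-in matching merges a/b duplicate libraries and reports dropouts", {
  rec <- data.frame(
    cdr3_nt = c("GCAAGCGGG", "GCAAGCGGG", "AAATTTCCC", "AAATTTCCC"),
    chain = "TRB", read_count = c(40L, 60L, 400L, 500L),
    read_fraction = NA_real_,
    set_id = c("Set1a", "Set1b", "Set1a", "Set1b"),
    replicate_id = "rep1")
  m <- match_spikeins(rec, ref2)
  expect_equal(nrow(m), 2L)               # both reference clones reported
  r1 <- m[m$clone_id == "T1", ]
  expect_equal(r1$read_count, 100L)       # 40 (a) + 60 (b)
  expect_equal(r1$measured_freq, 100 / 1000)
  r2 <- m[m$clone_id == "T2", ]
  expect_equal(r2$read_count, 0L)
  expect_false(r2$detected)
  # frequencies never exceed the replicate total
  expect_true(all(m$measured_freq >= 0 & m$measured_freq <= 1))
  dupref <- rbind(ref2, data.frame(clone_id = "T3", chain = "TRB",
                                   cdr3_nt_imgt = "GCAAGCGGG",
                                   design_freq = 1e-5))
  expect_error(match_spikeins(rec, dupref), "ambiguous")
})

test_that("trim-then-match equals matching pre-trimmed records", {
  rec_raw <- data.frame(cdr3_nt = c("TGTGCAAGCGGGTTT", "TGTCCCAGGTTTTGC"),
                        chain = "TRB", read_count = c(10L, 20L),
                        read_fraction = NA_real_, set_id = "Set1",
                        replicate_id = "rep1")
  rec_pre <- rec_raw
  rec_pre$cdr3_nt <- trim_cdr3_to_imgt(rec_pre$cdr3_nt)
  m1 <- match_spikeins(rec_raw, ref2, trim = TRUE)
  m2 <- match_spikeins(rec_pre, ref2)
  expect_equal(m1, m2)
})

test_that("fully-undetected exclusion follows the TRA-or-TRB rule", {
  matched <- expand.grid(clone_id = c("T1", "T2", "T3"),
                         chain = c("TRA", "TRB"),
                         set_id = c("Set1", "Set2"),
                         replicate_id = c("rep1", "rep2"),
                         stringsAsFactors = FALSE)
  matched$read_count <- 50L
  # T2: TRA zero everywhere, TRB present -> whole TCR excluded at tcr level
  matched$read_count[matched$clone_id == "T2" &
                       matched$chain == "TRA"] <- 0L
  # T3: each chain detected in just a single replicate of one set ->
  # neither chain is fully undetected, so the clone is retained
  matched$read_count[matched$clone_id == "T3"] <- 0L
  matched$read_count[matched$clone_id == "T3" & matched$chain == "TRA" &
                       matched$set_id == "Set2" &
                       matched$replicate_id == "rep2"] <- 1L
  matched$read_count[matched$clone_id == "T3" & matched$chain == "TRB" &
                       matched$set_id == "Set1" &
                       matched$replicate_id == "rep1"] <- 1L
  out <- exclude_fully_undetected(matched)
  expect_false("T2" %in% out$retained$clone_id)
  expect_true(all(c("T1", "T3") %in% out$retained$clone_id))
  expect_false("T3" %in% out$excluded$clone_id)
  # at chain level only the failing chain rows disappear
  out_ch <- exclude_fully_undetected(matched, by = "chain")
  expect_true(any(out_ch$retained$clone_id == "T2" &
                    out_ch$retained$chain == "TRB"))
  expect_false(any(out_ch$retained$clone_id == "T2" &
                     out_ch$retained$chain == "TRA"))
  # the rule never removes a chain with a nonzero read anywhere
  expect_true("T3" %in% out_ch$retained$clone_id)
})

test_that("dispersion index is sd/mean and scale-free", {
  expect_equal(dispersion_index(c(5, 5, 5, 5)), 0)
  expect_equal(dispersion_index(c(1, 2, 3)), 0.5)
  x <- c(2, 3, 7, 9)
  expect_equal(dispersion_index(x), dispersion_index(100 * x))
  expect_error(dispersion_index(c(0, 0)), "mean")
})

test_that("log-log linearity R2 behaves on exact, scaled and noisy data", {
  truth <- rep(c(1e-6, 1e-5, 1e-4, 1e-3), each = 3)
  expect_equal(as.numeric(linearity_r2(truth, truth)), 1)
  expect_equal(as.numeric(linearity_r2(truth, 2 * truth)), 1)
  set.seed(4)
  noisy <- truth * 10^rnorm(length(truth), 0, 0.15)
  r2 <- linearity_r2(truth, noisy)
  expect_gt(r2, 0.9)
  expect_lt(r2, 1)
  # undetected points are excluded and counted
  noisy[1:2] <- 0
  expect_equal(attr(linearity_r2(truth, noisy), "n_undetected"), 2L)
  expect_error(linearity_r2(truth[1:3], c(0, 0, 1e-5)), "detected")
})

test_that("false-positive analysis categorises and removes by cutoff", {
  ctrl <- data.frame(
    cdr3_nt = c("GCAAGCGGG", sprintf("AAACCCGG%d", 1:10), "TTTGGGCCC"),
    chain = "TRB",
    read_count = c(5000L, 1:10, 200L),
    read_fraction = NA_real_, set_id = "Control", replicate_id = "rep1")
  other <- data.frame(cdr3_nt = "TTTGGGCCC", chain = "TRB",
                      read_count = 20000L, read_fraction = NA_real_,
                      set_id = "Set1", replicate_id = "rep1")
  rep <- false_positive_analysis(ctrl, ref2, other, cutoffs = c(5, 10, 300))
  expect_s3_class(rep, "fp_report")
  expect_equal(nrow(rep$sequences), 11L)  # 10 exclusive + 1 elsewhere
  expect_equal(sum(rep$sequences$category == "elsewhere"), 1L)
  rm <- rep$removal_fraction_by_cutoff
  # 10 planted FPs with counts 1..10: cutoff 5 removes half of the
  # exclusive ones, 5/11 overall
  expect_equal(rm$overall[rm$cutoff == 5], 5 / 11)
  expect_true(all(diff(rm$overall) >= 0))
  expect_equal(rm$overall[rm$cutoff == 300], 1)
  # fp read-rate: non-spike reads / total reads
  expect_equal(unname(rep$fp_rate_by_chain["TRB"]),
               (sum(1:10) + 200) / (5000 + sum(1:10) + 200))
  # control containing only reference sequences: no FPs, removal 1
  clean <- ctrl[1, ]
  rep0 <- false_positive_analysis(clean, ref2, other, cutoffs = 5)
  expect_equal(nrow(rep0$sequences), 0L)
  expect_equal(rep0$removal_fraction_by_cutoff$overall, 1)
  expect_error(false_positive_analysis(ctrl[0, ], ref2, other), "empty")
})

test_that("index-hopping false positives show the linear count trend", {
  des <- spikein_design(n_replicates = 2, background_clones = 300)
  expr <- generate_spikein_experiment(des, default_truth(), t_read = 1e6,
                                      seed = 21, fp_hopping = 40,
                                      hop_ratio = 0.01)
  rep <- false_positive_analysis(expr$control_records, expr$reference,
                                 expr$records)
  hop <- rep$sequences[rep$sequences$category == "elsewhere" &
                         rep$sequences$count_in_control > 3, ]
  expect_gt(nrow(hop), 10)
  fit <- lm(log10(count_in_control) ~ log10(total_count_elsewhere),
            data = hop)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.25)
})

test_that("measured frequencies track the simulated truth end to end", {
  des <- spikein_design(n_replicates = 2)
  expr <- generate_spikein_experiment(des, default_truth(), t_read = 1e6,
                                      seed = 31)
  m <- match_spikeins(expr$records, expr$reference)
  agg <- aggregate(measured_freq ~ clone_id + chain + design_freq,
                   data = m, FUN = mean)
  r2 <- linearity_r2(agg$design_freq, agg$measured_freq)
  expect_gt(r2, 0.8)
  # per-replicate frequencies sum to at most 1
  tot <- aggregate(measured_freq ~ chain + set_id + replicate_id,
                   data = m, FUN = sum)
  expect_true(all(tot$measured_freq <= 1 + 1e-12))
})
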