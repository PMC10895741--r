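# Amplicon quantification: alignment bookkeeping, the read-level efficiency
# statistic, allele tables and chimera classification, all against the
# generator's exact ledger (error-free pools) or binomial bounds.

test_that("perfect reads align cleanly and deletions/indels are policed", {
  tg <- simulate_amplicon(seed = 3)
  amp <- tg$amplicon_seq
  reads <- data.frame(id = paste0("r", 1:10), seq = amp,
                      qual = strrep("I", nchar(amp)))
  pp <- align_reads(reads, tg)
  expect_identical(pp$aligned_reads, 10L)
  expect_identical(unname(pp$discarded), c(0L, 0L))
  # base counts at every position sum to aligned reads
  expect_true(all(colSums(pp$counts) == 10L))
  # a read equal to the reverse complement is counted on the - orientation
  rc <- data.frame(id = "rc", seq = revcomp(amp), qual = strrep("I", nchar(amp)))
  pp_rc <- align_reads(rbind(reads, rc), tg)
  expect_identical(pp_rc$aligned_reads, 11L)
  expect_identical(pp_rc$orientation[11], "-")
  expect_true(all(pp_rc$counts[c("A","C","G","T"), 1] ==
                    pp$counts[c("A","C","G","T"), 1] +
                    (c("A","C","G","T") == substring(amp, 1, 1))))
  # junk reads are discarded for low identity
  junk <- data.frame(id = "junk", seq = strrep("ACGT", 57), qual = strrep("I", 228))
  pp_j <- align_reads(rbind(reads, junk), tg)
  expect_identical(unname(pp_j$discarded["low_identity"]), 1L)
  # a deletion inside the protospacer discards the read as window_indel
  g <- tg$guide
  del <- paste0(substring(amp, 1, g$start + 4), substring(amp, g$start + 7, nchar(amp)))
  pp_d <- align_reads(rbind(reads, data.frame(id = "del", seq = del,
                                              qual = strrep("I", nchar(del)))), tg)
  expect_identical(unname(pp_d$discarded["window_indel"]), 1L)
  expect_identical(pp_d$aligned_reads, 10L)
  expect_error(align_reads(reads[0, ], tg), "empty")
})

test_that("error-free programmed pools are recovered exactly from the ledger", {
  pool <- make_pool(rates = c("4" = 0.3, "6" = 0.6), n_reads = 200, seed = 11)
  tg <- pool$target
  pp <- align_reads(pool$reads, tg)
  expect_identical(pp$aligned_reads, 200L)
  rep <- editing_efficiency(pp, tg)
  truth <- pool$truth$position_counts
  expect_equal(unname(rep$per_position[c("A4", "A6", "A7")]),
               unname(round(100 * truth[c("4", "6", "7")] / 200, 1)))
  expect_identical(rep$site_efficiency,
                   beditr:::round_half_up(100 * pool$truth$site_count / 200, 1))
  # per-position counts equal the simulator's bookkeeping exactly
  lay <- beditr:::editable_layout(tg)
  for (i in seq_along(lay$proto_pos)) {
    p <- lay$amp_pos[i]
    expect_identical(unname(pp$counts[lay$to, p]),
                     unname(as.numeric(truth[as.character(lay$proto_pos[i])])))
  }
})

test_that("efficiency arithmetic and classification edge cases", {
  tg <- simulate_amplicon(seed = 3)
  amp <- tg$amplicon_seq
  lay <- beditr:::editable_layout(tg)
  edited <- amp
  substring(edited, lay$amp_pos[2], lay$amp_pos[2]) <- lay$to  # A6 -> G
  reads <- data.frame(id = paste0("r", 1:10),
                      seq = c(rep(edited, 9), amp),
                      qual = strrep("I", nchar(amp)))
  rep <- editing_efficiency(align_reads(reads, tg), tg)
  expect_identical(unname(rep$per_position["A6"]), 90.0)
  expect_identical(rep$site_efficiency, 90.0)
  # nothing edited -> all zero, unedited
  wt <- data.frame(id = paste0("r", 1:10), seq = amp, qual = strrep("I", nchar(amp)))
  rep0 <- editing_efficiency(align_reads(wt, tg), tg)
  expect_true(all(rep0$per_position == 0))
  expect_identical(rep0$classification, "unedited")
  # low-quality bases drop out of numerator and denominator
  lowq <- strrep("I", nchar(amp))
  substring(lowq, lay$amp_pos[2], lay$amp_pos[2]) <- "#"  # Q2 at the A6 column
  mixed <- rbind(data.frame(id = "lq", seq = edited, qual = lowq), wt)
  rep_lq <- editing_efficiency(align_reads(mixed, tg), tg)
  expect_identical(unname(rep_lq$per_position["A6"]), 0.0)
  expect_identical(unname(rep_lq$position_denominators["A6"]), 10L)
  expect_identical(unname(rep_lq$position_denominators["A4"]), 11L)
})

test_that("programmed rates are recovered within binomial bounds at n = 1000", {
  tg <- simulate_amplicon(seed = 17, editable = 4:8)
  rates <- c("4" = 0.05, "5" = 0.25, "6" = 0.50, "7" = 0.75, "8" = 0.95)
  pool <- simulate_amplicon_reads(tg, n_reads = 1000, rates = rates, seed = 1)
  rep <- editing_efficiency(align_reads(pool$reads, tg), tg)
  est <- rep$per_position[paste0("A", names(rates))]
  expect_true(all(abs(est - 100 * rates) < 3))
  # and exactly equal to the ledger's realised fractions (error-free pool)
  expect_equal(unname(est),
               unname(round(100 * pool$truth$position_counts / 1000, 1)))
})

test_that("allele tables recover programmed mixtures and label edits", {
  tg <- simulate_amplicon(seed = 3)
  # all-reference pool: single WT allele at frequency 1
  amp <- tg$amplicon_seq
  wt <- data.frame(id = paste0("r", 1:20), seq = amp, qual = strrep("I", nchar(amp)))
  tab <- build_allele_table(align_reads(wt, tg), tg)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$edit_label, "WT")
  expect_identical(tab$frequency, 1)
  # 70/30 two-allele mixture recovered within the binomial 99% CI
  mix <- data.frame(subset = c("4", "4+6"), freq = c(0.7, 0.3))
  pool <- simulate_amplicon_reads(tg, n_reads = 400, alleles = mix, seed = 23)
  tab2 <- build_allele_table(align_reads(pool$reads, tg), tg)
  expect_identical(nrow(tab2), 2L)
  expect_setequal(tab2$edit_label, c("A4G", "A4G;A6G"))
  ci <- stats::qbinom(c(0.005, 0.995), 400, 0.7) / 400
  f_top <- tab2$frequency[tab2$edit_label == "A4G"]
  expect_gte(f_top, ci[1]); expect_lte(f_top, ci[2])
  expect_lt(abs(sum(tab2$frequency) - 1), 1e-9)
  # frequencies match the generator's realised allele counts exactly
  ak <- pool$truth$allele_counts
  expect_identical(tab2$read_count[tab2$edit_label == "A4G"], unname(ak[["4"]]))
})

test_that("sample classification follows the allele-fraction thresholds", {
  tg <- simulate_amplicon(seed = 3)
  classify <- function(mix, n = 300, seed = 5) {
    pool <- simulate_amplicon_reads(tg, n_reads = n, alleles = mix, seed = seed)
    classify_sample(build_allele_table(align_reads(pool$reads, tg), tg))
  }
  expect_identical(classify(data.frame(subset = "", freq = 1)), "unedited")
  expect_identical(classify(data.frame(subset = c("4", ""), freq = c(0.95, 0.05))),
                   "homogeneous")
  expect_identical(classify(data.frame(subset = c("4", "4+6", ""),
                                       freq = c(0.60, 0.35, 0.05))), "chimeric")
})

test_that("count conservation and orientation invariance hold on simulated pools", {
  pool <- make_pool(rates = c("4" = 0.4, "7" = 0.2), n_reads = 150, seed = 31)
  tg <- pool$target
  pp <- align_reads(pool$reads, tg)
  expect_identical(pp$aligned_reads + sum(pp$discarded), 150L)
  rep_f <- editing_efficiency(pp, tg)
  flipped <- pool$reads
  flipped$seq <- revcomp(flipped$seq)
  flipped$qual <- vapply(flipped$qual, function(q) intToUtf8(rev(utf8ToInt(q))),
                         character(1), USE.NAMES = FALSE)
  rep_r <- editing_efficiency(align_reads(flipped, tg), tg)
  expect_identical(rep_f$per_position, rep_r$per_position)
  expect_identical(rep_f$site_efficiency, rep_r$site_efficiency)
  expect_identical(rep_f$classification, rep_r$classification)
})
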