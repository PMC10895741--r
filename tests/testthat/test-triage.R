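# SNV off-target triage: background subtraction, editor-compatible
# filtering, predicted-site intersection, region annotation, summary
# percentages.

mk_set <- function(pos, ref = "A", alt = "G", sample = "edited", level = "DNA") {
  snv_set(data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt),
          sample, level)
}

test_that("background subtraction is an allele-aware set difference", {
  target <- snv_set(data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                               ref = c("A", "A", "T"), alt = c("G", "G", "C")))
  ctrl <- snv_set(data.frame(chrom = "chr1", pos = c(200L, 300L),
                             ref = c("A", "T"), alt = c("C", "C")),
                  sample = "negative")
  out <- subtract_background(target, ctrl)
  # pos 300 removed (same allele); pos 200 kept: control has a different alt
  expect_identical(out$records$pos, c(100L, 200L))
  # mixing levels is refused
  rna <- mk_set(1L, level = "RNA", sample = "negative")
  expect_error(subtract_background(target, rna), "mix")
  # control order never changes the result
  c1 <- mk_set(c(100L, 150L), sample = "negative")
  c2 <- mk_set(c(200L, 250L), sample = "wild_type")
  expect_identical(subtract_background(target, list(c1, c2)),
                   subtract_background(target, list(c2, c1)))
})

test_that("editor-compatible filtering keeps the deamination signatures only", {
  s <- snv_set(data.frame(chrom = "chr1", pos = 1:4,
                          ref = c("A", "C", "T", "G"),
                          alt = c("G", "T", "C", "A")))
  abe <- filter_editor_compatible(s, editor_profile("GhABE8e"))
  expect_identical(abe$records[, c("ref", "alt")],
                   data.frame(ref = c("A", "T"), alt = c("G", "C")))
  cbe <- filter_editor_compatible(s, editor_profile("CBE"))
  expect_identical(cbe$records[, c("ref", "alt")],
                   data.frame(ref = c("C", "G"), alt = c("T", "A")))
  empty <- snv_set(data.frame(chrom = character(0), pos = integer(0),
                              ref = character(0), alt = character(0)))
  expect_length(filter_editor_compatible(empty, editor_profile("GhABE8e")), 0L)
})

test_that("predicted-site intersection respects footprint boundaries", {
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 123))
  inside <- mk_set(c(101L, 110L, 123L))
  outside <- mk_set(c(100L, 124L))
  expect_identical(intersect_predicted(inside, iv)$count, 3L)
  expect_identical(intersect_predicted(outside, iv)$count, 0L)
})

test_that("region annotation assigns exactly one category per SNV by priority", {
  sim <- simulate_genome(seed = 7)
  feats <- sim$features
  g1 <- feats[feats$type == "gene", ][1, ]
  cds1 <- feats[feats$type == "CDS" & feats$parent == "mRNA1", ][1, ]
  utr <- feats[feats$type == "five_prime_UTR" & feats$parent == "mRNA1", ]
  intron_pos <- feats[feats$type == "CDS" & feats$parent == "mRNA1", ]$end[1] + 10L
  s <- mk_set(c(cds1$start + 1L,       # exonic
                utr$start + 1L,        # UTR
                intron_pos,            # in gene span, not exon/UTR
                g1$start - 100L,       # upstream (gene 1 is + strand)
                g1$end + 100L,         # downstream
                g1$end + 5000L))       # intergenic
  ann <- annotate_regions(s, feats)
  expect_identical(ann$categories,
                   c("upstream2kb", "UTR", "exonic", "intronic", "downstream2kb",
                     "intergenic"))
  expect_identical(sum(ann$counts), 6L)
  expect_true(all(ann$counts <= 1L))
})

test_that("cross-level sharing counts identical variants once", {
  dna <- mk_set(c(10L, 20L, 30L))
  rna <- mk_set(c(20L, 30L, 40L), level = "RNA")
  expect_identical(cross_level_shared(dna, rna)$count, 2L)
  expect_identical(cross_level_shared(dna, mk_set(100L, level = "RNA"))$count, 0L)
  expect_identical(cross_level_shared(dna, mk_set(c(10L, 20L, 30L), level = "RNA"))$count, 3L)
})

test_that("summary percentages reproduce printed filtered-to-total ratios", {
  # the WGS/WTS scale ratios these reporting conventions come from
  expect_identical(triage_percent(4395, 1274475, digits = 2), 0.34)
  expect_identical(triage_percent(4413, 1277374, digits = 2), 0.35)
  expect_identical(triage_percent(55, 20664, digits = 1), 0.3)
  expect_identical(triage_percent(1727, 1277374, digits = 1), 0.1)
  expect_identical(triage_percent(0, 100), 0)
  expect_true(is.na(triage_percent(5, 0)))
  # round-half-up, not round-half-even
  expect_identical(triage_percent(345, 100000, digits = 2), 0.35)
})

test_that("the full pipeline recovers a simulated design's ledger", {
  sim <- simulate_genome(seed = 3)
  prof <- editor_profile("GhABE8e")
  des <- simulate_snv_design(sim, seed = 4, n_shared = 200L,
                             n_private = c(edited = 40L, vector_only = 30L,
                                           negative = 20L, wild_type = 20L))
  sets <- des$sets
  sub <- subtract_background(sets$edited, list(sets$negative, sets$wild_type))
  expect_identical(sub$records$pos, sort(des$truth$private$edited$pos))
  comp <- filter_editor_compatible(sub, prof)
  expect_identical(length(comp),
                   sum(des$truth$private$edited$class %in% c("A>G", "T>C")))
  # pipeline monotonicity
  iv <- site_intervals(enumerate_offtargets(sim$genome, sim$truth$guide$protospacer,
                                            prof, 2), prof, flank = 10)
  ov <- intersect_predicted(comp, iv)
  expect_gte(length(sub), length(comp))
  expect_gte(length(comp), ov$count)
  # report invariants
  tr <- run_triage(sets$edited, sets$vector_only, sets$negative, sets$wild_type,
                   prof, sites = iv, feats = sim$features)
  expect_true(all(tr$filtered_snvs <= tr$total_snvs))
  expect_identical(sum(tr$region_category_counts), tr$filtered_snvs[["edited"]])
})

test_that("SNVs placed away from all predicted sites never intersect them", {
  sim <- simulate_genome(seed = 19)
  prof <- editor_profile("GhABE8e")
  sites <- enumerate_offtargets(sim$genome, sim$truth$guide$protospacer, prof, 2)
  iv <- site_intervals(sites, prof, flank = 20)
  des <- simulate_snv_design(sim, seed = 20, n_shared = 100L,
                             n_private = c(edited = 200L, vector_only = 10L,
                                           negative = 10L, wild_type = 10L),
                             avoid = iv)
  sub <- subtract_background(des$sets$edited,
                             list(des$sets$negative, des$sets$wild_type))
  expect_identical(intersect_predicted(sub, iv)$count, 0L)
})
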