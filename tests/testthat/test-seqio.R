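# FASTA / FASTQ / VCF / GFF3 I/O contracts: normalisation, validation,
# deterministic round trips, and the 1-based inclusive coordinate convention
# at both sequence boundaries.

test_that("FASTA loading uppercases, validates and rejects duplicate ids", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "acgt"), p)
  g <- read_genome(p)
  expect_identical(g, c(a = "ACGT"))

  writeLines(c(">a", "ACGT", ">a", "GG"), p)
  expect_error(read_genome(p), "duplicate")

  writeLines(c("ACGT", ">a", "ACGT"), p)
  expect_error(read_genome(p), "line 1")

  writeLines(c(">a", "ACXT"), p)
  expect_error(read_genome(p), "illegal")
})

test_that("FASTA written by the generator round-trips byte-identically", {
  set.seed(42)
  g <- c(chrA = random_seq(157), chrB = random_seq(80))
  p1 <- withr::local_tempfile(fileext = ".fa")
  p2 <- withr::local_tempfile(fileext = ".fa")
  write_genome(g, p1)
  write_genome(read_genome(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(read_genome(p2), g)
})

test_that("FASTQ round trip preserves sequence/quality pairing and rejects ambiguity", {
  reads <- data.frame(id = c("r1", "r2"), seq = c("ACGTN", "TTTTT"),
                      qual = c("IIII!", "#IIII"))
  p <- withr::local_tempfile(fileext = ".fq")
  write_reads(reads, p)
  back <- read_reads(p)
  expect_identical(back, reads)

  writeLines(c("@r1", "ACRT", "+", "IIII"), p)
  expect_error(read_reads(p), "concrete")
})

test_that("VCF loading splits multi-allelics, keeps only SNVs and counts drops", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
                     collapse = "\t"),
               "chr1\t100\t.\tA\tG\t.\t.\t.",
               "chr1\t200\t.\tC\tA,T\t.\t.\t.",
               "chr1\t300\t.\tG\tAT\t.\t.\t.",
               "chr1\t400\t.\tTA\tT\t.\t.\t."), p)
  s <- read_snvs(p, "edited")
  expect_s3_class(s, "snv_set")
  expect_identical(s$records$pos, c(100L, 200L, 200L))
  expect_identical(s$records$alt, c("G", "A", "T"))
  expect_identical(s$dropped, 2L)
})

test_that("simulated SNV sets round-trip through VCF exactly", {
  sim <- simulate_genome(seed = 5, genome_length = 20000L, n_genes = 2L)
  des <- simulate_snv_design(sim, seed = 5, n_shared = 30L,
                             n_private = c(edited = 20L, vector_only = 10L,
                                           negative = 5L, wild_type = 5L))
  p <- withr::local_tempfile(fileext = ".vcf")
  write_snvs(des$sets$edited, p)
  back <- read_snvs(p, "edited")
  expect_identical(back$records, des$sets$edited$records)
  expect_length(back, 50L)
})

test_that("GFF3 CDS models follow strand convention and match the generator", {
  g <- c(chr1 = "ATGAAACCCGGGTTTTAG")
  feats <- data.frame(seq_id = "chr1",
                      type = c("gene", "mRNA", "CDS"),
                      start = c(1L, 1L, 1L), end = c(18L, 18L, 18L),
                      strand = "+", phase = c(NA, NA, 0L),
                      id = c("g1", "m1", "c1"), parent = c(NA, "g1", "m1"))
  p <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feats, p)
  back <- read_features(p)
  expect_identical(back$type, feats$type)
  expect_identical(back$start, feats$start)
  cm <- cds_models(back, g)
  expect_identical(cm$m1$spliced_seq, "ATGAAACCCGGGTTTTAG")
  expect_identical(cm$m1$codon_count, 6L)
  expect_true(cm$m1$complete)

  # minus strand, two segments: transcript order reverses genomic order
  g2 <- c(chr1 = revcomp("ATGAAACCCGGGTTTTAG"))
  feats2 <- data.frame(seq_id = "chr1", type = c("CDS", "CDS"),
                       start = c(1L, 13L), end = c(12L, 18L), strand = "-",
                       phase = c(NA_integer_, NA_integer_),
                       id = c("c1", "c2"), parent = "m1")
  cm2 <- cds_model("m1", feats2, g2)
  expect_identical(cm2$spliced_seq, "ATGAAACCCGGGTTTTAG")
  # the genomically-last segment comes first in transcript orientation
  expect_identical(cm2$segments$start[1], 13L)
})

test_that("synthetic gene models reproduce the generator's stored CDS strings", {
  sim <- simulate_genome(seed = 21)
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genome(sim$genome, fa)
  write_gff3(sim$features, gff)
  cm <- cds_models(read_features(gff), read_genome(fa))
  expect_length(cm, 5L)
  for (m in names(cm)) {
    expect_identical(cm[[m]]$spliced_seq, sim$truth$cds_seqs[[m]])
    expect_true(cm[[m]]$complete)
  }
})

test_that("CDS without a Parent is rejected and off-frame length warns", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\t.\tCDS\t1\t9\t.\t+\t0\tID=c1"), p)
  expect_error(read_features(p), "Parent")
  g <- c(chr1 = "ATGAAACC")
  feats <- data.frame(seq_id = "chr1", type = "CDS", start = 1L, end = 8L,
                      strand = "+", phase = 0L, id = "c1", parent = "m1")
  expect_warning(cds_model("m1", feats, g), "divisible by 3")
})

test_that("coordinates are 1-based inclusive at both sequence boundaries", {
  # a guide flush against position 1 and one flush against the sequence end
  prof <- editor_profile("GhABE8e")
  proto <- strrep("C", 19)
  seq <- paste0("A", proto, "TGG")  # protospacer at 1..20, PAM 21..23
  seq <- paste0(seq, strrep("G", 4))
  cands <- scan_guides(c(chr = seq), prof)
  expect_true(any(cands$start == 1L & cands$strand == "+"))
  L <- nchar(seq)
  # minus-strand guide whose protospacer ends exactly at position L
  seq2 <- paste0(strrep("T", 5), "CCA", revcomp(paste0("A", proto)))
  cands2 <- scan_guides(c(chr = seq2), prof)
  expect_true(any(cands2$end == nchar(seq2) & cands2$strand == "-"))
  # SNV at position 1 and at position L land inside intervals that touch them
  iv <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 5))
  s <- snv_set(data.frame(chrom = "chr", pos = c(1L, 5L, 6L), ref = "A", alt = "G"))
  expect_identical(intersect_predicted(s, iv)$count, 2L)
})
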