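# Mismatch-tolerant, PAM-aware enumeration of candidate off-target loci
# (Cas-OFFinder-style): every genomic window on either strand whose PAM
# matches the profile pattern and whose protospacer is within a Hamming
# distance budget of the guide. Bulges (DNA/RNA indels) are not modelled.

#' Enumerate candidate off-target sites for a guide
#'
#' Scans both strands of every sequence in `genome` for windows whose PAM
#' matches `profile$pam` (IUPAC semantics; an N in the genome matches no
#' pattern letter) and whose protospacer differs from the guide at no more
#' than `max_mismatches` positions (Hamming distance; genome N counts as a
#' mismatch). The on-target locus itself is retained but flagged `on_target`
#' when the guide's own coordinates are known, so it can be removed before
#' off-target analysis.
#'
#' @param genome named character vector of reference sequences.
#' @param guide either a protospacer string or one row of [scan_guides()]
#'   output (whose coordinates then identify the on-target locus).
#' @param profile an [editor_profile()]; the guide length must equal
#'   `profile$protospacer_len`.
#' @param max_mismatches Hamming budget over the protospacer (default 4).
#' @return data.frame sorted by (chrom, start, strand) with columns `chrom`,
#'   `start`, `end` (protospacer, 1-based inclusive, forward strand),
#'   `strand`, `site_seq` (strand-oriented), `pam`, `mismatches`,
#'   `mismatch_positions` (comma-joined protospacer coordinates),
#'   `on_target`.
#' @export
enumerate_offtargets <- function(genome, guide, profile, max_mismatches = 4L) {
  stopifnot(inherits(profile, "editor_profile"))
  max_mismatches <- as.integer(max_mismatches)
  plen <- profile$protospacer_len
  if (max_mismatches < 0L || max_mismatches > plen)
    stop("max_mismatches must be in 0..protospacer_len")
  locus <- NULL
  if (is.data.frame(guide)) {
    stopifnot(nrow(guide) == 1L)
    locus <- guide
    guide <- guide$protospacer
  }
  if (nchar(guide) != plen)
    stop("guide length ", nchar(guide), " != profile protospacer_len ", plen)
  if (grepl("[^ACGT]", guide)) stop("guide must be concrete ACGT")
  pamlen <- nchar(profile$pam)
  gchars <- strsplit(guide, "")[[1]]

  one_strand <- function(chrom, oriented, strand, L) {
    hits <- Biostrings::matchPattern(guide, Biostrings::DNAString(oriented),
                                     max.mismatch = max_mismatches,
                                     with.indels = FALSE, fixed = TRUE)
    s <- Biostrings::start(hits)
    if (length(s) == 0L) return(NULL)
    if (profile$pam_side == "three_prime") {
      pam_lo <- s + plen; pam_hi <- s + plen + pamlen - 1L
    } else {
      pam_lo <- s - pamlen; pam_hi <- s - 1L
    }
    inb <- pam_lo >= 1L & pam_hi <= L
    s <- s[inb]; pam_lo <- pam_lo[inb]; pam_hi <- pam_hi[inb]
    if (length(s) == 0L) return(NULL)
    pam <- substring(oriented, pam_lo, pam_hi)
    keep <- iupac_match(pam, profile$pam)
    s <- s[keep]; pam <- pam[keep]
    if (length(s) == 0L) return(NULL)
    site_seq <- substring(oriented, s, s + plen - 1L)
    mmpos <- lapply(site_seq, function(ss) which(strsplit(ss, "")[[1]] != gchars))
    if (strand == "+") {
      fstart <- s
    } else {
      fstart <- L - (s + plen - 1L) + 1L
    }
    data.frame(chrom = chrom, start = fstart, end = fstart + plen - 1L,
               strand = strand, site_seq = site_seq, pam = pam,
               mismatches = lengths(mmpos), mismatch_positions = int_csv(mmpos),
               stringsAsFactors = FALSE)
  }

  per_chrom <- lapply(names(genome), function(chrom) {
    seq <- toupper(genome[[chrom]])
    L <- nchar(seq)
    rbind(one_strand(chrom, seq, "+", L),
          one_strand(chrom, revcomp(seq), "-", L))
  })
  res <- do.call(rbind, per_chrom)
  if (is.null(res) || nrow(res) == 0L) {
    res <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), site_seq = character(0),
                      pam = character(0), mismatches = integer(0),
                      mismatch_positions = character(0), stringsAsFactors = FALSE)
  }
  res$on_target <- logical(nrow(res))
  if (!is.null(locus) && nrow(res)) {
    res$on_target <- res$mismatches == 0L & res$chrom == locus$target_id &
      res$start == locus$start & res$strand == locus$strand
  }
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge off-target site footprints into an interval set
#'
#' The footprint of a site is its protospacer plus PAM, extended by `flank`
#' on both sides; overlapping or touching footprints are merged. The result
#' supports the overlap queries of the SNV triage (Venn intersection of SNVs
#' with predicted sites).
#'
#' @param sites [enumerate_offtargets()] output.
#' @param profile the [editor_profile()] used (locates the PAM side).
#' @param flank extra bases on each side (default 0).
#' @return a [GenomicRanges::GRanges] of merged, sorted intervals.
#' @export
site_intervals <- function(sites, profile, flank = 0L) {
  flank <- as.integer(flank)
  if (nrow(sites) == 0L) return(GenomicRanges::GRanges())
  pamlen <- nchar(sites$pam)
  pam_3p_fwd <- (profile$pam_side == "three_prime") == (sites$strand == "+")
  lo <- ifelse(pam_3p_fwd, sites$start, sites$start - pamlen)
  hi <- ifelse(pam_3p_fwd, sites$end + pamlen, sites$end)
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(pmax(1L, lo - flank), hi + flank))
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}
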