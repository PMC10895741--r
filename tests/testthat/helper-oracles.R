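# Independent oracles used across the suite. These deliberately re-derive
# results from first principles (per-offset enumeration, literal window
# arithmetic, a different translation engine) and never share code with the
# implementation paths they check.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

IUPAC1 <- function(code) strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]]

oracle_pam_ok <- function(pam_seq, pattern) {
  pc <- strsplit(pam_seq, "")[[1]]
  tc <- strsplit(pattern, "")[[1]]
  length(pc) == length(tc) && all(mapply(function(b, code) b %in% IUPAC1(code), pc, tc))
}

# Literal per-offset guide scan: every forward-strand protospacer interval on
# both strands, tested one by one against the profile definition.
oracle_scan_guides <- function(seq, profile, target_id = "ref") {
  plen <- profile$protospacer_len
  pamlen <- nchar(profile$pam)
  L <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    for (start in seq_len(max(0L, L - plen + 1L))) {
      end <- start + plen - 1L
      fwd <- substring(seq, start, end)
      proto <- if (strand == "+") fwd else revcomp(fwd)
      if (grepl("[^ACGT]", proto)) next
      pam3 <- (profile$pam_side == "three_prime") == (strand == "+")
      pam_iv <- if (pam3) c(end + 1L, end + pamlen) else c(start - pamlen, start - 1L)
      if (pam_iv[1] < 1L || pam_iv[2] > L) next
      pam_fwd <- substring(seq, pam_iv[1], pam_iv[2])
      pam <- if (strand == "+") pam_fwd else revcomp(pam_fwd)
      if (!oracle_pam_ok(pam, profile$pam)) next
      w <- profile$window[1]:profile$window[2]
      ed <- w[strsplit(proto, "")[[1]][w] == profile$edit_from]
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = target_id, start = start, end = end, strand = strand,
        protospacer = proto, pam = pam, editable = paste(ed, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out <- out[order(out$target_id, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# All-windows Hamming scan for off-target sites: every offset on both strands
# is scored position by position against the guide, then PAM-checked.
oracle_offtargets <- function(genome, guide, profile, max_mm) {
  plen <- profile$protospacer_len
  pamlen <- nchar(profile$pam)
  gch <- strsplit(guide, "")[[1]]
  pch <- strsplit(profile$pam, "")[[1]]
  rows <- list()
  for (chrom in names(genome)) {
    for (strand in c("+", "-")) {
      seq <- if (strand == "+") genome[[chrom]] else revcomp(genome[[chrom]])
      ch <- strsplit(seq, "")[[1]]
      L <- length(ch)
      n_off <- L - plen + 1L
      if (n_off < 1L) next
      mmc <- integer(n_off)
      for (i in seq_len(plen)) mmc <- mmc + (ch[i:(i + n_off - 1L)] != gch[i])
      for (s in which(mmc <= max_mm)) {
        pam_iv <- if (profile$pam_side == "three_prime")
          c(s + plen, s + plen + pamlen - 1L) else c(s - pamlen, s - 1L)
        if (pam_iv[1] < 1L || pam_iv[2] > L) next
        if (!all(mapply(function(b, code) b %in% IUPAC1(code),
                        ch[pam_iv[1]:pam_iv[2]], pch))) next
        site <- paste(ch[s:(s + plen - 1L)], collapse = "")
        fstart <- if (strand == "+") s else L - (s + plen - 1L) + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = fstart, end = fstart + plen - 1L,
          strand = strand, site_seq = site,
          pam = paste(ch[pam_iv[1]:pam_iv[2]], collapse = ""),
          mismatches = mmc[s],
          mismatch_positions = paste(which(ch[s:(s + plen - 1L)] != gch), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), site_seq = character(0),
                      pam = character(0), mismatches = integer(0),
                      mismatch_positions = character(0)))
  out <- out[order(out$chrom, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# Total covered length of a set of intervals, by position painting.
oracle_union_length <- function(starts, ends, L) {
  covered <- rep(FALSE, L)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  sum(covered)
}

# Plant a string into a genome at a 1-based offset.
plant <- function(seq, fragment, at) {
  paste0(substring(seq, 1, at - 1L), fragment,
         substring(seq, at + nchar(fragment), nchar(seq)))
}

# A small deterministic amplicon + read pool shared by several tests.
make_pool <- function(rates = c("4" = 0.3, "6" = 0.6), n_reads = 200L,
                      seed = 11L, amp_seed = 3L, editable = c(4L, 6L, 7L), ...) {
  tg <- simulate_amplicon(seed = amp_seed, editable = editable)
  pool <- simulate_amplicon_reads(tg, n_reads = n_reads, rates = rates,
                                  seed = seed, ...)
  pool
}
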