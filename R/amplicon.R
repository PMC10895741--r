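# Amplicon deep-sequencing quantification of base-editing outcomes:
# global alignment of reads to the amplicon, per-position base counts,
# the read-level efficiency statistic (percentage of reads carrying the
# target conversion), allele tables over the guide window, and chimera
# classification.

#' Describe an amplicon and its guide
#'
#' @param amplicon_seq the amplicon reference sequence.
#' @param guide one row of [scan_guides()] output with coordinates relative
#'   to the amplicon (`target_id` is the amplicon id).
#' @param profile the [editor_profile()] used for the scan.
#' @return object of class `amplicon_target`.
#' @export
amplicon_target <- function(amplicon_seq, guide, profile) {
  stopifnot(is.data.frame(guide), nrow(guide) == 1L, inherits(profile, "editor_profile"))
  amplicon_seq <- toupper(amplicon_seq)
  sub <- substring(amplicon_seq, guide$start, guide$end)
  if (guide$strand == "-") sub <- revcomp(sub)
  if (sub != guide$protospacer)
    stop("guide protospacer does not occur in the amplicon at the stated coordinates")
  structure(list(amplicon_seq = amplicon_seq, guide = guide, profile = profile),
            class = "amplicon_target")
}

phred_values <- function(qual_strings) {
  lapply(qual_strings, function(q) utf8ToInt(q) - 33L)
}

# Per-read projection of a global alignment onto amplicon coordinates:
# base (A/C/G/T/N, "-" for deletion) and Phred value at every amplicon
# position, plus insertion start positions.
project_alignment <- function(aligned_read, aligned_amp, qual) {
  pa <- strsplit(aligned_read, "")[[1]]
  sa <- strsplit(aligned_amp, "")[[1]]
  read_idx <- cumsum(pa != "-")
  cols <- which(sa != "-")
  base <- pa[cols]
  qv <- rep(NA_integer_, length(cols))
  has_base <- pa[cols] != "-"
  qv[has_base] <- qual[read_idx[cols][has_base]]
  ins_cols <- which(sa == "-")
  ins_start <- integer(0)
  if (length(ins_cols)) {
    run_start <- ins_cols[c(TRUE, diff(ins_cols) > 1L)]
    amp_idx <- cumsum(sa != "-")
    ins_start <- amp_idx[run_start] + 1L  # insertion sits before this amplicon position
  }
  list(base = base, qual = qv, ins_start = ins_start)
}

#' Align amplicon reads and tally per-position base counts
#'
#' Each read is globally aligned (Needleman-Wunsch; match +1, mismatch -1,
#' gap open -5, gap extend -1) to the amplicon in both orientations and the
#' better-scoring orientation kept, with minus-orientation reads
#' reverse-complemented before tallying. Reads below the identity threshold
#' are discarded (`low_identity`); reads whose alignment places an indel
#' inside the quantification window (the protospacer span) are discarded and
#' tallied separately (`window_indel` -- candidate Cas-independent events),
#' since an adenine base editor is not expected to create indels and only
#' substitution outcomes are quantified.
#'
#' @param reads data.frame from [read_reads()].
#' @param target an [amplicon_target()].
#' @param min_match_frac minimum identity (matches / max(read, amplicon
#'   length)) to keep a read (default 0.75).
#' @return object of class `position_profile`: per-position counts of
#'   A/C/G/T/N/deletion (summing to `aligned_reads` at every position),
#'   insertion starts, and the per-read base/quality matrices used by the
#'   downstream statistics.
#' @export
align_reads <- function(reads, target, min_match_frac = 0.75) {
  stopifnot(inherits(target, "amplicon_target"))
  if (nrow(reads) == 0L) stop("empty read pool")
  amp <- target$amplicon_seq
  A <- nchar(amp)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
  aln_of <- function(seqs) Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs), amp, substitutionMatrix = sm,
    gapOpening = 5, gapExtension = 1, type = "global")
  fwd <- aln_of(reads$seq)
  rc <- aln_of(revcomp(reads$seq))
  use_rc <- Biostrings::score(rc) > Biostrings::score(fwd)
  seqs <- ifelse(use_rc, revcomp(reads$seq), reads$seq)
  quals <- reads$qual
  quals[use_rc] <- vapply(quals[use_rc], function(q)
    intToUtf8(rev(utf8ToInt(q))), character(1))
  best <- aln_of(seqs)  # realign the chosen orientation as one batch
  identity <- Biostrings::nmatch(best) / pmax(nchar(seqs), A)
  keep_id <- identity >= min_match_frac
  win <- sort(c(target$guide$start, target$guide$end))
  ap <- as.character(Biostrings::alignedPattern(best))
  as_ <- as.character(Biostrings::alignedSubject(best))
  qnum <- phred_values(quals)

  n <- nrow(reads)
  base_rows <- vector("list", n)
  qual_rows <- vector("list", n)
  ins_all <- integer(0)
  window_indel <- logical(n)
  for (r in which(keep_id)) {
    pr <- project_alignment(ap[r], as_[r], qnum[[r]])
    del_in_win <- any(pr$base[win[1]:win[2]] == "-")
    ins_in_win <- any(pr$ins_start > win[1] & pr$ins_start <= win[2])
    if (del_in_win || ins_in_win) {
      window_indel[r] <- TRUE
      next
    }
    base_rows[[r]] <- pr$base
    qual_rows[[r]] <- pr$qual
    ins_all <- c(ins_all, pr$ins_start)
  }
  kept <- which(keep_id & !window_indel)
  if (length(kept) == 0L) stop("no reads survived filtering")
  base_mat <- do.call(rbind, base_rows[kept])
  qual_mat <- do.call(rbind, qual_rows[kept])
  counts <- vapply(seq_len(A), function(p) {
    b <- base_mat[, p]
    c(A = sum(b == "A"), C = sum(b == "C"), G = sum(b == "G"),
      T = sum(b == "T"), N = sum(b == "N"), del = sum(b == "-"))
  }, numeric(6))
  ins_start <- tabulate(ins_all, nbins = A + 1L)[seq_len(A)]
  structure(list(
    counts = counts, ins_start = ins_start,
    aligned_reads = length(kept),
    discarded = c(low_identity = sum(!keep_id), window_indel = sum(window_indel)),
    base_mat = base_mat, qual_mat = qual_mat,
    read_ids = reads$id[kept], orientation = ifelse(use_rc, "-", "+")[kept],
    target = target), class = "position_profile")
}

#' @export
print.position_profile <- function(x, ...) {
  cat(sprintf("<position_profile> %d aligned reads over %d bp (discarded: %s)\n",
              x$aligned_reads, ncol(x$counts),
              paste(names(x$discarded), x$discarded, sep = "=", collapse = ", ")))
  invisible(x)
}

# Amplicon coordinates of the guide's editable positions and the base the
# editor installs there in amplicon-forward orientation.
editable_layout <- function(target) {
  g <- target$guide
  prof <- target$profile
  pos <- parse_int_csv(g$editable)[[1]]
  amp_pos <- if (length(pos)) protospacer_to_genomic(g, pos) else integer(0)
  fwd <- g$strand == "+"
  list(proto_pos = pos, amp_pos = amp_pos,
       from = if (fwd) prof$edit_from else comp_base(prof$edit_from),
       to = if (fwd) prof$edit_to else comp_base(prof$edit_to))
}

#' Editing efficiency report for an amplicon
#'
#' Per-position efficiency is the percentage of reads carrying the installed
#' base at that editable window position; the site-level efficiency is the
#' percentage of reads with at least one window conversion (reads, not
#' events, are counted, matching how deep-sequencing editing efficiencies
#' are reported). Bases below `min_qual` at an editable position remove the
#' read from that position's numerator and denominator, so per-position
#' denominators can differ. Percentages are rounded half-up to one decimal.
#'
#' @param profile a [align_reads()] result.
#' @param target the same [amplicon_target()].
#' @param min_qual Phred threshold for a base call to count (default 20).
#' @param min_allele_frac passed to [classify_sample()] for the
#'   classification field.
#' @return object of class `editing_report`: `per_position` (named vector,
#'   names like `"A6"` in protospacer coordinates), `site_efficiency`,
#'   `classification`, read counts.
#' @export
editing_efficiency <- function(profile, target, min_qual = 20L, min_allele_frac = 0.05) {
  stopifnot(inherits(profile, "position_profile"), profile$aligned_reads > 0L)
  lay <- editable_layout(target)
  per_pos <- numeric(0)
  denom <- integer(0)
  edited_any <- rep(FALSE, profile$aligned_reads)
  if (length(lay$amp_pos)) {
    per_pos <- vapply(seq_along(lay$amp_pos), function(i) {
      p <- lay$amp_pos[i]
      q <- profile$qual_mat[, p]
      elig <- !is.na(q) & q >= min_qual
      if (!any(elig)) return(NA_real_)
      100 * sum(profile$base_mat[elig, p] == lay$to) / sum(elig)
    }, numeric(1))
    denom <- vapply(lay$amp_pos, function(p) {
      q <- profile$qual_mat[, p]
      sum(!is.na(q) & q >= min_qual)
    }, integer(1))
    for (i in seq_along(lay$amp_pos)) {
      p <- lay$amp_pos[i]
      q <- profile$qual_mat[, p]
      elig <- !is.na(q) & q >= min_qual
      edited_any <- edited_any | (elig & profile$base_mat[, p] == lay$to)
    }
    names(per_pos) <- names(denom) <- paste0(target$profile$edit_from, lay$proto_pos)
  }
  site <- 100 * sum(edited_any) / profile$aligned_reads
  tab <- build_allele_table(profile, target)
  cls <- classify_sample(tab, min_allele_frac = min_allele_frac)
  structure(list(per_position = round_half_up(per_pos, 1),
                 position_denominators = denom,
                 site_efficiency = round_half_up(site, 1),
                 classification = cls,
                 aligned_reads = profile$aligned_reads,
                 discarded = profile$discarded),
            class = "editing_report")
}

#' @export
print.editing_report <- function(x, ...) {
  cat(sprintf("<editing_report> %d reads aligned; site efficiency %.1f%%; %s\n",
              x$aligned_reads, x$site_efficiency, x$classification))
  if (length(x$per_position)) {
    cat("  per-position efficiency (%):\n")
    print(x$per_position)
  }
  invisible(x)
}

#' Tabulate alleles over the guide window
#'
#' Reads are keyed by their aligned bases across the protospacer extended by
#' `window_pad` on each side; each distinct string is one allele. Alleles are
#' labelled by the editable-window conversions they carry (protospacer
#' coordinates, e.g. `"A4G;A6G"`; `"WT"` when none). When a [cds_model()] and
#' the amplicon's genomic offset are supplied, each allele additionally gets
#' its protein-level consequence label.
#'
#' @param profile a [align_reads()] result.
#' @param target the same [amplicon_target()].
#' @param window_pad bases added on each side of the protospacer (default 5).
#' @param cds optional [cds_model()] on the chromosome the amplicon derives
#'   from.
#' @param amplicon_offset genomic coordinate of amplicon position 1 minus 1
#'   (i.e. genomic = amplicon + offset); used with `cds`.
#' @return data.frame of class `allele_table`, rows sorted by descending
#'   `read_count` then `allele_seq`, with `frequency` summing to 1 over
#'   aligned reads.
#' @export
build_allele_table <- function(profile, target, window_pad = 5L, cds = NULL,
                               amplicon_offset = 0L) {
  stopifnot(inherits(profile, "position_profile"), profile$aligned_reads > 0L)
  g <- target$guide
  A <- ncol(profile$counts)
  win <- max(1L, g$start - window_pad):min(A, g$end + window_pad)
  allele <- apply(profile$base_mat[, win, drop = FALSE], 1L, paste, collapse = "")
  tab <- table(allele)
  out <- data.frame(allele_seq = names(tab), read_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$read_count, out$allele_seq), , drop = FALSE]
  out$frequency <- out$read_count / profile$aligned_reads
  lay <- editable_layout(target)
  win_idx <- match(lay$amp_pos, win)
  labels <- vapply(out$allele_seq, function(a) {
    ch <- strsplit(a, "")[[1]]
    hit <- which(!is.na(win_idx) & ch[win_idx] == lay$to)
    if (length(hit) == 0L) return("WT")
    paste(paste0(target$profile$edit_from, lay$proto_pos[hit],
                 target$profile$edit_to), collapse = ";")
  }, character(1))
  out$edit_label <- unname(labels)
  if (!is.null(cds)) {
    out$consequence <- vapply(seq_len(nrow(out)), function(i) {
      ch <- strsplit(out$allele_seq[i], "")[[1]]
      hit <- which(!is.na(win_idx) & ch[win_idx] == lay$to)
      if (length(hit) == 0L) return("WT")
      gpos <- lay$amp_pos[hit] + amplicon_offset
      cpos <- genomic_to_cds(cds, gpos)
      coding <- !is.na(cpos)
      if (!any(coding)) return("noncoding")
      from_cds <- if (cds$strand == "+") lay$from else comp_base(lay$from)
      to_cds <- if (cds$strand == "+") lay$to else comp_base(lay$to)
      cons <- predict_consequence(cds, data.frame(cds_position = cpos[coding],
                                                  from = from_cds, to = to_cds))
      paste(cons$label, collapse = "+")
    }, character(1))
  }
  rownames(out) <- NULL
  class(out) <- c("allele_table", "data.frame")
  out
}

#' Classify a sample from its allele table
#'
#' Allele rows are aggregated by edit genotype (`edit_label`) before applying
#' the thresholds, so sequencing-error singletons of the same genotype count
#' together. The sample is `unedited` when no non-reference genotype reaches
#' `min_allele_frac`; `homogeneous` when exactly one does and it carries at
#' least 90% of reads; otherwise `chimeric` (the typical outcome for primary
#' regenerants, whose cells carry a mixture of editing genotypes).
#'
#' @param table an [build_allele_table()] result.
#' @param min_allele_frac detection threshold for a genotype (default 0.05).
#' @return one of `"unedited"`, `"homogeneous"`, `"chimeric"`.
#' @export
classify_sample <- function(table, min_allele_frac = 0.05) {
  stopifnot(nrow(table) > 0L)
  freq <- tapply(table$frequency, table$edit_label, sum)
  nonwt <- freq[names(freq) != "WT"]
  big <- nonwt[nonwt >= min_allele_frac]
  if (length(big) == 0L) return("unedited")
  if (length(big) == 1L && big[[1]] >= 0.9) return("homogeneous")
  "chimeric"
}
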