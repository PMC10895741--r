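# Genome/transcriptome SNV off-target triage over the four-sample design
# (edited / vector-only positive control / negative regenerant / wild type):
# background subtraction, editor-compatible mutation filtering, intersection
# with predicted off-target sites, region annotation and summary percentages.

#' Subtract background SNVs observed in control samples
#'
#' Removes from `target` every record whose (chrom, pos, ref, alt) appears in
#' any control set. Subtraction is allele-aware: a different alt allele at
#' the same position is not the same background event and is retained. The
#' result does not depend on the order of the controls.
#'
#' @param target an [snv_set()] (e.g. the edited or vector-only sample).
#' @param controls list of [snv_set()]s used as background (e.g. the negative
#'   regenerant and the wild type); must be at the same level as `target`.
#' @return the filtered [snv_set()].
#' @export
subtract_background <- function(target, controls) {
  stopifnot(inherits(target, "snv_set"))
  if (inherits(controls, "snv_set")) controls <- list(controls)
  for (ctl in controls) {
    stopifnot(inherits(ctl, "snv_set"))
    if (ctl$level != target$level)
      stop("cannot mix ", target$level, " and ", ctl$level, " SNV sets")
  }
  bg <- unlist(lapply(controls, function(ctl) snv_key(ctl$records)))
  keep <- !snv_key(target$records) %in% bg
  snv_set(target$records[keep, , drop = FALSE], target$sample, target$level,
          target$dropped)
}

#' Keep only editor-compatible SNVs
#'
#' An adenine base editor deaminates A on either strand, which appears on the
#' forward strand as A->G or T->C; only those two classes can be editor
#' footprints, so all others are removed before off-target interpretation
#' (likewise C->T / G->A for a cytosine editor).
#'
#' @param set an [snv_set()].
#' @param profile an [editor_profile()].
#' @return the filtered [snv_set()].
#' @export
filter_editor_compatible <- function(set, profile) {
  stopifnot(inherits(set, "snv_set"), inherits(profile, "editor_profile"))
  r <- set$records
  keep <- (r$ref == profile$edit_from & r$alt == profile$edit_to) |
    (r$ref == comp_base(profile$edit_from) & r$alt == comp_base(profile$edit_to))
  snv_set(r[keep, , drop = FALSE], set$sample, set$level, set$dropped)
}

#' Intersect SNVs with predicted off-target site footprints
#'
#' @param set an [snv_set()].
#' @param intervals merged site intervals from [site_intervals()].
#' @return list with `records` (the overlapping rows) and `count` (the Venn
#'   overlap count).
#' @export
intersect_predicted <- function(set, intervals) {
  stopifnot(inherits(set, "snv_set"), methods::is(intervals, "GRanges"))
  r <- set$records
  if (nrow(r) == 0L || length(intervals) == 0L)
    return(list(records = r[0, , drop = FALSE], count = 0L))
  snv_gr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$pos, r$pos))
  hit <- IRanges::overlapsAny(snv_gr, intervals)
  list(records = r[hit, , drop = FALSE], count = sum(hit))
}

#' Assign each SNV to one genomic region category
#'
#' Categories, assigned with priority exonic > UTR > intronic > upstream >
#' downstream > intergenic: exonic = within a CDS; UTR = within an annotated
#' 5'/3' UTR; intronic = within a gene span but neither; upstream/downstream
#' = within `upstream_bp`/`downstream_bp` of the gene boundary, strand-aware.
#'
#' @param set an [snv_set()].
#' @param feats feature data.frame from [read_features()].
#' @param upstream_bp,downstream_bp flank sizes (default 2000).
#' @return list with `categories` (per-record character vector) and `counts`
#'   (named vector over all six categories, summing to the set size).
#' @export
annotate_regions <- function(set, feats, upstream_bp = 2000L, downstream_bp = 2000L) {
  stopifnot(inherits(set, "snv_set"))
  r <- set$records
  cats <- c("exonic", "UTR", "intronic", "upstream2kb", "downstream2kb", "intergenic")
  if (nrow(r) == 0L)
    return(list(categories = character(0),
                counts = stats::setNames(integer(length(cats)), cats)))
  gr_of <- function(d) {
    if (nrow(d) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(d$seq_id, IRanges::IRanges(d$start, d$end))
  }
  genes <- feats[feats$type == "gene", , drop = FALSE]
  up <- genes; dn <- genes
  plus <- genes$strand == "+"
  up$start <- ifelse(plus, pmax(1L, genes$start - upstream_bp), genes$end + 1L)
  up$end <- ifelse(plus, genes$start - 1L, genes$end + upstream_bp)
  dn$start <- ifelse(plus, genes$end + 1L, pmax(1L, genes$start - downstream_bp))
  dn$end <- ifelse(plus, genes$end + downstream_bp, genes$start - 1L)
  up <- up[up$start <= up$end, , drop = FALSE]
  dn <- dn[dn$start <= dn$end, , drop = FALSE]
  layers <- list(
    exonic = gr_of(feats[feats$type == "CDS", , drop = FALSE]),
    UTR = gr_of(feats[feats$type %in% c("five_prime_UTR", "three_prime_UTR"), , drop = FALSE]),
    intronic = gr_of(genes),
    upstream2kb = gr_of(up),
    downstream2kb = gr_of(dn))
  snv_gr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$pos, r$pos))
  cat_vec <- rep("intergenic", nrow(r))
  for (nm in rev(names(layers))) {  # apply lowest priority first, overwrite upward
    hit <- IRanges::overlapsAny(snv_gr, layers[[nm]])
    cat_vec[hit] <- nm
  }
  counts <- vapply(cats, function(cc) sum(cat_vec == cc), integer(1))
  list(categories = cat_vec, counts = counts)
}

#' Count SNVs shared between the DNA and RNA level
#'
#' Variants present in both the WGS and the WTS call set of the same plant
#' are transcribed DNA variants, not RNA off-target edits; the triage flags
#' them rather than attributing them to the deaminase acting on RNA.
#'
#' @param dna,rna [snv_set()]s at DNA and RNA level.
#' @return list with `records` (shared records, DNA representation) and
#'   `count`.
#' @export
cross_level_shared <- function(dna, rna) {
  stopifnot(inherits(dna, "snv_set"), inherits(rna, "snv_set"))
  shared <- snv_key(dna$records) %in% snv_key(rna$records)
  list(records = dna$records[shared, , drop = FALSE], count = sum(shared))
}

#' Percentage of total SNVs surviving the triage filters
#'
#' Rounded half-up to `digits` decimals, the convention used when such
#' filtered-to-total ratios are reported (two decimals for DNA, one for
#' RNA). Undefined (NA) when `total` is zero.
#'
#' @param filtered,total SNV counts.
#' @param digits decimals to report.
#' @return numeric percentage (e.g. `0.34` for 4395 of 1274475).
#' @export
triage_percent <- function(filtered, total, digits = 2L) {
  if (total == 0) return(NA_real_)
  round_half_up(100 * filtered / total, digits)
}

#' Run the full SNV off-target triage
#'
#' Pipeline over the four-sample design: subtract the background observed in
#' the negative and wild-type samples from the edited and vector-only
#' samples, restrict to editor-compatible classes, intersect with predicted
#' off-target site footprints, annotate genomic regions, and report summary
#' counts and percentages.
#'
#' @param edited,vector_only,negative,wild_type [snv_set()]s at one level.
#' @param profile an [editor_profile()].
#' @param sites merged intervals from [site_intervals()], or `NULL` to skip
#'   the intersection.
#' @param feats feature table from [read_features()], or `NULL` to skip
#'   region annotation.
#' @param digits decimals for the percent-of-total (default 2 for DNA, 1 for
#'   RNA).
#' @param upstream_bp,downstream_bp flanks for [annotate_regions()].
#' @return object of class `triage_report`.
#' @export
run_triage <- function(edited, vector_only, negative, wild_type, profile,
                       sites = NULL, feats = NULL,
                       digits = if (edited$level == "DNA") 2L else 1L,
                       upstream_bp = 2000L, downstream_bp = 2000L) {
  controls <- list(negative, wild_type)
  samples <- list(edited = edited, vector_only = vector_only)
  total <- vapply(samples, length, integer(1))
  filtered_sets <- lapply(samples, function(s)
    filter_editor_compatible(subtract_background(s, controls), profile))
  filtered <- vapply(filtered_sets, length, integer(1))
  pct <- vapply(seq_along(samples), function(i)
    triage_percent(filtered[i], total[i], digits), numeric(1))
  names(pct) <- names(samples)
  overlap <- if (!is.null(sites))
    vapply(filtered_sets, function(s) intersect_predicted(s, sites)$count, integer(1))
  else NULL
  shared <- sum(snv_key(filtered_sets$edited$records) %in%
                  snv_key(filtered_sets$vector_only$records))
  region <- if (!is.null(feats))
    annotate_regions(filtered_sets$edited, feats, upstream_bp, downstream_bp)$counts
  else NULL
  structure(list(level = edited$level, total_snvs = total,
                 filtered_snvs = filtered, percent_of_total = pct,
                 overlap_with_predicted = overlap,
                 shared_between_samples = shared,
                 region_category_counts = region,
                 filtered_sets = filtered_sets),
            class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  cat(sprintf("<triage_report> level=%s\n", x$level))
  for (s in names(x$total_snvs)) {
    cat(sprintf("  %s: %d total SNVs -> %d editor-compatible after background subtraction (%s%%)\n",
                s, x$total_snvs[[s]], x$filtered_snvs[[s]],
                format(x$percent_of_total[[s]])))
  }
  if (!is.null(x$overlap_with_predicted))
    cat("  overlap with predicted sites:",
        paste(names(x$overlap_with_predicted), x$overlap_with_predicted,
              sep = "=", collapse = ", "), "\n")
  cat("  shared between edited and vector-only:", x$shared_between_samples, "\n")
  if (!is.null(x$region_category_counts)) {
    cat("  region categories (edited):\n")
    print(x$region_category_counts)
  }
  invisible(x)
}
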