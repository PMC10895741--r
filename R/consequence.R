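# Coding-sequence models and codon/amino-acid consequence prediction.
#
# A cds_model is the spliced coding sequence of one mRNA together with its
# genomic segments, so that edits can be mapped genome -> CDS -> codon ->
# amino acid. Translation uses the standard nuclear genetic code (cotton
# nuclear genes; no organellar tables).

#' Build a CDS model from segments and a genome
#'
#' @param cds_id identifier (usually the mRNA id).
#' @param segments data.frame with columns `seq_id`, `start`, `end`, `strand`
#'   (one strand per model); genomic 1-based inclusive, non-overlapping.
#' @param genome named sequence vector (see [read_genome()]).
#' @return object of class `cds_model` with the spliced sequence in
#'   transcript (5'->3') orientation, its codon count, and a `complete` flag
#'   (length divisible by 3 and starting ATG).
#' @export
cds_model <- function(cds_id, segments, genome) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("seq_id", "start", "end", "strand") %in% names(segments)),
            length(unique(segments$strand)) == 1L,
            length(unique(segments$seq_id)) == 1L,
            all(segments$start <= segments$end))
  strand <- segments$strand[1]
  segments <- segments[order(segments$start), ]
  if (any(segments$end[-nrow(segments)] >= segments$start[-1]))
    stop("CDS segments of '", cds_id, "' overlap")
  # transcript order: genomic order on +, reversed on -
  if (strand == "-") segments <- segments[rev(seq_len(nrow(segments))), ]
  chrom_seq <- genome[[segments$seq_id[1]]]
  if (is.null(chrom_seq)) stop("sequence ", segments$seq_id[1], " not in genome")
  pieces <- substring(chrom_seq, pmin(segments$start, segments$end),
                      pmax(segments$start, segments$end))
  if (strand == "-") pieces <- revcomp(pieces)
  spliced <- paste(pieces, collapse = "")
  complete <- nchar(spliced) %% 3L == 0L && substring(spliced, 1, 3) == "ATG"
  if (nchar(spliced) %% 3L != 0L)
    warning("CDS '", cds_id, "' length ", nchar(spliced), " not divisible by 3; flagged partial")
  structure(list(cds_id = cds_id, segments = segments, strand = strand,
                 spliced_seq = spliced,
                 codon_count = nchar(spliced) %/% 3L,
                 complete = complete),
            class = "cds_model")
}

#' @export
print.cds_model <- function(x, ...) {
  cat(sprintf("<cds_model> %s (%s strand): %d nt, %d codons, %s\n",
              x$cds_id, x$strand, nchar(x$spliced_seq), x$codon_count,
              if (x$complete) "complete" else "partial"))
  invisible(x)
}

#' Derive CDS models for every mRNA in a feature table
#'
#' @param feats feature data.frame from [read_features()].
#' @param genome named sequence vector.
#' @return named list of [cds_model()] objects, one per mRNA with CDS
#'   features, in mRNA id order.
#' @export
cds_models <- function(feats, genome) {
  cds <- feats[feats$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) return(list())
  by_mrna <- split(cds, cds$parent)
  out <- lapply(names(by_mrna), function(m)
    cds_model(m, by_mrna[[m]][, c("seq_id", "start", "end", "strand")], genome))
  stats::setNames(out, names(by_mrna))[order(names(by_mrna))]
}

#' Map a CDS position to its codon
#'
#' Positions are 1-based from the first base of the start codon, so positions
#' 1--3 are codon 1. For example CDS positions 157 and 158 both fall in codon
#' 53 (offsets 1 and 2).
#'
#' @param cds a [cds_model()] (or anything with a `spliced_seq` field).
#' @param cds_position 1-based position within the spliced CDS.
#' @return list with `codon_index` (1-based) and `offset` (1, 2 or 3).
#' @export
#' @examples
#' \dontrun{map_to_codon(cds, 157)  # codon 53, offset 1}
map_to_codon <- function(cds, cds_position) {
  cds_position <- as.integer(cds_position)
  n <- nchar(cds$spliced_seq)
  if (any(cds_position < 1L | cds_position > n))
    stop("cds_position out of range 1..", n)
  list(codon_index = (cds_position - 1L) %/% 3L + 1L,
       offset = (cds_position - 1L) %% 3L + 1L)
}

translate_codon <- function(codon) {
  if (grepl("[^ACGT]", codon)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[codon])
}

classify_codon_change <- function(codon_index, ref_aa, alt_aa, ref_codon) {
  if (identical(ref_aa, alt_aa)) return("synonymous")
  if (codon_index == 1L && ref_codon == "ATG") return("start_loss")
  if (identical(alt_aa, "*")) return("nonsense")
  if (identical(ref_aa, "*")) return("stop_loss")
  "missense"
}

#' Predict codon-level consequences of a set of CDS edits
#'
#' Edits landing in the same codon are applied jointly before translation, so
#' a double edit such as AAA -> GGA is reported as the single substitution
#' K -> G rather than two partial changes. The result does not depend on the
#' order in which edits are supplied.
#'
#' @param cds a [cds_model()].
#' @param edits data.frame with columns `cds_position` (1-based), `from`,
#'   `to`. Each `from` must match the CDS sequence at its position (guards
#'   against stale coordinates).
#' @return data.frame with one row per affected codon: `cds_id`,
#'   `codon_index`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `klass`,
#'   `label` (e.g. `"K53G"`), ordered by codon index.
#' @export
predict_consequence <- function(cds, edits) {
  edits <- as.data.frame(edits)
  stopifnot(all(c("cds_position", "from", "to") %in% names(edits)), nrow(edits) > 0L)
  edits$cds_position <- as.integer(edits$cds_position)
  n <- nchar(cds$spliced_seq)
  if (any(edits$cds_position < 1L | edits$cds_position > n))
    stop("edit position out of CDS range 1..", n)
  have <- substring(cds$spliced_seq, edits$cds_position, edits$cds_position)
  bad <- which(have != edits$from)
  if (length(bad))
    stop("reference mismatch at CDS position ", edits$cds_position[bad[1]],
         ": expected ", edits$from[bad[1]], ", CDS has ", have[bad[1]])
  if (anyDuplicated(edits$cds_position)) stop("duplicate edit positions")
  idx <- (edits$cds_position - 1L) %/% 3L + 1L
  out <- lapply(sort(unique(idx)), function(ci) {
    cstart <- (ci - 1L) * 3L + 1L
    ref_codon <- substring(cds$spliced_seq, cstart, cstart + 2L)
    alt <- strsplit(ref_codon, "")[[1]]
    sel <- idx == ci
    alt[edits$cds_position[sel] - cstart + 1L] <- edits$to[sel]
    alt_codon <- paste(alt, collapse = "")
    ref_aa <- translate_codon(ref_codon)
    alt_aa <- translate_codon(alt_codon)
    klass <- classify_codon_change(ci, ref_aa, alt_aa, ref_codon)
    data.frame(cds_id = cds$cds_id, codon_index = ci, ref_codon = ref_codon,
               alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
               klass = klass, label = paste0(ref_aa, ci, alt_aa),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Map a genomic position on the model's chromosome to a 1-based CDS position,
# or NA when it falls outside the CDS segments.
genomic_to_cds <- function(cds, gpos) {
  seg <- cds$segments
  vapply(as.integer(gpos), function(p) {
    off <- 0L
    for (i in seq_len(nrow(seg))) {
      w <- seg$end[i] - seg$start[i] + 1L
      if (p >= seg$start[i] && p <= seg$end[i]) {
        within <- if (cds$strand == "+") p - seg$start[i] + 1L else seg$end[i] - p + 1L
        return(off + within)
      }
      off <- off + w
    }
    NA_integer_
  }, integer(1))
}

#' Enumerate bystander-edit outcomes of a guide over a CDS
#'
#' For a guide with k editable window positions there are 2^k - 1 non-empty
#' combinations of edits the editor can install; each is mapped onto the CDS
#' and summarised as a protein-level label in the field's usual style, e.g.
#' `"K53G+S78G"` for a double substitution. Window positions outside the CDS
#' contribute no protein change; a combination whose edits are all
#' non-coding is labelled `"noncoding"`.
#'
#' @param candidate one guide row from [scan_guides()].
#' @param profile the guide's [editor_profile()].
#' @param cds a [cds_model()] on the same reference.
#' @param max_positions refuse combinatorial blow-up beyond this many editable
#'   positions (default 6).
#' @return data.frame with columns `subset` (protospacer positions joined by
#'   `+`), `n_edits`, `label`, `klass` (worst class across affected codons:
#'   start_loss > nonsense > stop_loss > missense > synonymous > noncoding).
#' @export
enumerate_bystanders <- function(candidate, profile, cds, max_positions = 6L) {
  pos <- parse_int_csv(candidate$editable)[[1]]
  if (length(pos) == 0L) stop("candidate has no editable positions")
  if (length(pos) > max_positions)
    stop(length(pos), " editable positions exceeds max_positions = ", max_positions,
         "; raise max_positions to enumerate ", 2^length(pos) - 1, " combinations")
  gpos <- protospacer_to_genomic(candidate, pos)
  # forward-strand change installed by the editor at each position
  from_fwd <- if (candidate$strand == "+") profile$edit_from else comp_base(profile$edit_from)
  to_fwd <- if (candidate$strand == "+") profile$edit_to else comp_base(profile$edit_to)
  cpos <- genomic_to_cds(cds, gpos)
  # on a - strand gene the CDS base is the complement of the forward base
  from_cds <- ifelse(cds$strand == "+", from_fwd, comp_base(from_fwd))
  to_cds <- ifelse(cds$strand == "+", to_fwd, comp_base(to_fwd))
  klass_rank <- c(start_loss = 6, nonsense = 5, stop_loss = 4, missense = 3,
                  synonymous = 2, noncoding = 1)
  subsets <- unlist(lapply(seq_along(pos), function(k)
    utils::combn(seq_along(pos), k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(sel) {
    coding <- sel[!is.na(cpos[sel])]
    if (length(coding) == 0L) {
      label <- "noncoding"; klass <- "noncoding"
    } else {
      cons <- predict_consequence(cds, data.frame(cds_position = cpos[coding],
                                                  from = from_cds, to = to_cds))
      label <- paste(cons$label, collapse = "+")
      klass <- names(which.max(klass_rank[cons$klass]))
    }
    data.frame(subset = paste(pos[sel], collapse = "+"), n_edits = length(sel),
               label = label, klass = klass, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
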