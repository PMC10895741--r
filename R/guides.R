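# Guide scanning and design: find every protospacer+PAM occurrence of an
# editor profile on both strands of a reference, annotate which window
# positions are editable, install chosen window edits, and rank candidates.
#
# Protospacer coordinates are counted 1..protospacer_len from the 5' end of
# the protospacer, so that for a 3'-PAM editor the PAM occupies positions
# protospacer_len+1 .. protospacer_len+nchar(pam) (21-23 for a 20-nt Cas9
# guide); for a 5'-PAM editor the PAM sits immediately 5' of position 1.

# Scan one oriented sequence; returns protospacer start positions (1-based on
# the oriented sequence), protospacer and PAM strings.
scan_oriented <- function(seq, profile) {
  plen <- profile$protospacer_len
  pamlen <- nchar(profile$pam)
  full <- plen + pamlen
  L <- nchar(seq)
  empty <- data.frame(pstart = integer(0), protospacer = character(0),
                      pam = character(0), stringsAsFactors = FALSE)
  if (L < full) return(empty)
  i <- seq_len(L - full + 1L)
  if (profile$pam_side == "three_prime") {
    pstart <- i
    pam <- substring(seq, i + plen, i + full - 1L)
  } else {
    pstart <- i + pamlen
    pam <- substring(seq, i, i + pamlen - 1L)
  }
  proto <- substring(seq, pstart, pstart + plen - 1L)
  keep <- iupac_match(pam, profile$pam) & !grepl("[^ACGT]", proto)
  data.frame(pstart = pstart[keep], protospacer = proto[keep], pam = pam[keep],
             stringsAsFactors = FALSE)
}

editable_in_window <- function(protospacer, profile) {
  lo <- profile$window[1]; hi <- profile$window[2]
  lapply(protospacer, function(p) {
    w <- lo:hi
    w[substring(p, w, w) == profile$edit_from]
  })
}

#' Scan a reference for base-editor guide candidates
#'
#' Reports every protospacer+PAM occurrence of the profile on both strands.
#' `start`/`end` are the 1-based inclusive forward-strand coordinates of the
#' protospacer (the PAM is adjacent on the profile's PAM side); `protospacer`
#' and `pam` are given strand-oriented (5'->3' on the guide's strand).
#' `editable` lists the window positions whose base equals the editor's
#' substrate (e.g. the adenines at positions 4--10 for an ABE8e-class
#' editor), comma-separated in protospacer coordinates.
#'
#' @param ref named character vector of reference sequences (one or more), or
#'   a single unnamed sequence (then `target_id` is used).
#' @param profile an [editor_profile()].
#' @param require_editable drop candidates with no editable window position.
#' @param target_id id used when `ref` is unnamed.
#' @return data.frame of candidates sorted by (target_id, start, strand) with
#'   columns `guide_id`, `target_id`, `start`, `end`, `strand`, `protospacer`,
#'   `pam`, `profile`, `editable`.
#' @export
scan_guides <- function(ref, profile, require_editable = FALSE, target_id = "ref") {
  stopifnot(inherits(profile, "editor_profile"))
  ids <- names(ref) %||% rep(target_id, length(ref))
  if (is.null(names(ref)) && length(ref) > 1L)
    ids <- paste0(target_id, seq_along(ref))
  per_ref <- lapply(seq_along(ref), function(k) {
    seq <- toupper(ref[[k]])
    L <- nchar(seq)
    plen <- profile$protospacer_len
    fwd <- scan_oriented(seq, profile)
    rev <- scan_oriented(revcomp(seq), profile)
    res <- rbind(
      if (nrow(fwd)) data.frame(start = fwd$pstart, end = fwd$pstart + plen - 1L,
                                strand = "+", protospacer = fwd$protospacer,
                                pam = fwd$pam, stringsAsFactors = FALSE),
      if (nrow(rev)) data.frame(start = L - (rev$pstart + plen - 1L) + 1L,
                                end = L - rev$pstart + 1L,
                                strand = "-", protospacer = rev$protospacer,
                                pam = rev$pam, stringsAsFactors = FALSE))
    if (is.null(res) || nrow(res) == 0L) return(NULL)
    res$target_id <- ids[k]
    res
  })
  res <- do.call(rbind, per_ref)
  empty <- data.frame(guide_id = character(0), target_id = character(0),
                      start = integer(0), end = integer(0), strand = character(0),
                      protospacer = character(0), pam = character(0),
                      profile = character(0), editable = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(res) || nrow(res) == 0L) return(empty)
  res$profile <- profile$name
  res$editable <- int_csv(editable_in_window(res$protospacer, profile))
  if (require_editable) res <- res[res$editable != "", , drop = FALSE]
  if (nrow(res) == 0L) return(empty)
  res <- res[order(res$target_id, res$start, res$strand), , drop = FALSE]
  res$guide_id <- paste0(res$target_id, ":", res$start, res$strand)
  rownames(res) <- NULL
  res[, c("guide_id", "target_id", "start", "end", "strand", "protospacer",
          "pam", "profile", "editable")]
}

# Forward-strand genomic coordinate of protospacer position(s).
protospacer_to_genomic <- function(candidate, pos) {
  pos <- as.integer(pos)
  if (candidate$strand == "+") candidate$start + pos - 1L else candidate$end - pos + 1L
}

#' Install window edits into the reference sequence
#'
#' Applies the editor's conversion at the chosen protospacer positions and
#' returns the edited forward-strand reference. For a minus-strand guide an
#' A->G edit surfaces as T->C on the forward strand.
#'
#' @param ref_seq the reference sequence the candidate was scanned from.
#' @param candidate one row of [scan_guides()] output.
#' @param profile the [editor_profile()] used for the scan.
#' @param positions non-empty subset of the candidate's editable positions
#'   (protospacer coordinates).
#' @return the edited sequence (single string).
#' @export
apply_window_edits <- function(ref_seq, candidate, profile, positions) {
  positions <- as.integer(positions)
  editable <- parse_int_csv(candidate$editable)[[1]]
  if (length(positions) == 0L) stop("positions must be a non-empty subset of editable positions")
  if (!all(positions %in% editable))
    stop("position(s) ", paste(setdiff(positions, editable), collapse = ","),
         " not in the candidate's editable set {", candidate$editable, "}")
  gpos <- protospacer_to_genomic(candidate, positions)
  from_fwd <- if (candidate$strand == "+") profile$edit_from else comp_base(profile$edit_from)
  to_fwd <- if (candidate$strand == "+") profile$edit_to else comp_base(profile$edit_to)
  chars <- strsplit(ref_seq, "")[[1]]
  stopifnot(all(chars[gpos] == from_fwd))
  chars[gpos] <- to_fwd
  paste(chars, collapse = "")
}

#' Rank guide candidates
#'
#' Deterministic score: `w_editable * (number of editable window positions) +
#' w_polyT * (protospacer contains TTTT) + w_gc * (GC fraction in [0.3, 0.7])`.
#' A TTTT run is penalised because it terminates Pol-III transcription from
#' U6-type promoters; the GC band rewards typical well-behaved guides. Ties
#' are broken by (start, strand), so the order is invariant under input
#' shuffling.
#'
#' @param candidates [scan_guides()] output.
#' @param weights named numeric vector with entries `editable`, `polyT`, `gc`.
#' @return the candidates with a `score` column, sorted by decreasing score.
#' @export
rank_guides <- function(candidates, weights = c(editable = 1.0, polyT = -2.0, gc = 0.5)) {
  stopifnot(all(c("editable", "polyT", "gc") %in% names(weights)))
  if (nrow(candidates) == 0L) {
    candidates$score <- numeric(0)
    return(candidates)
  }
  n_edit <- lengths(parse_int_csv(candidates$editable))
  has_t4 <- grepl("TTTT", candidates$protospacer, fixed = TRUE)
  gc <- vapply(strsplit(candidates$protospacer, ""), function(ch)
    mean(ch %in% c("G", "C")), numeric(1))
  gc_ok <- gc >= 0.3 & gc <= 0.7
  candidates$score <- weights[["editable"]] * n_edit +
    weights[["polyT"]] * as.numeric(has_t4) + weights[["gc"]] * as.numeric(gc_ok)
  o <- order(-candidates$score, candidates$target_id, candidates$start, candidates$strand)
  candidates <- candidates[o, , drop = FALSE]
  rownames(candidates) <- NULL
  candidates
}
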