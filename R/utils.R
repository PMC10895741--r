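# Shared low-level helpers: complementation, IUPAC matching, rounding.

IUPAC_NT <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Reverse complement of nucleotide strings
#'
#' Vectorised over its input; IUPAC ambiguity codes are complemented per the
#' standard pairing (R<->Y, K<->M, B<->V, D<->H; S, W, N self-complementary).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

comp_base <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  unname(map[x])
}

# Round half away from zero (the reporting convention used throughout: 0.345 -> 0.35
# at two decimals), as opposed to base round()'s round-half-even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Letters matched by each IUPAC pattern code. An 'N' (unknown) base in a subject
# sequence matches no pattern letter, including pattern N: membership is tested
# against these concrete expansions only.
.iupac_cache <- new.env(parent = emptyenv())
iupac_expansion <- function(code) {
  v <- .iupac_cache[[code]]
  if (is.null(v)) {
    m <- Biostrings::IUPAC_CODE_MAP
    if (!code %in% names(m)) stop("not an IUPAC nucleotide code: ", code)
    v <- strsplit(m[[code]], "")[[1]]
    assign(code, v, envir = .iupac_cache)
  }
  v
}

# Vectorised IUPAC pattern match: does each element of `seqs` (concrete bases,
# possibly containing N) match `pattern` (IUPAC) position by position?
iupac_match <- function(seqs, pattern) {
  k <- nchar(pattern)
  if (length(seqs) == 0L) return(logical(0))
  stopifnot(all(nchar(seqs) == k))
  pat <- strsplit(pattern, "")[[1]]
  ok <- rep(TRUE, length(seqs))
  for (i in seq_len(k)) {
    allowed <- iupac_expansion(pat[i])
    ok <- ok & substring(seqs, i, i) %in% allowed
  }
  ok
}

check_pam_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) < 1L)
    stop("PAM pattern must be a single non-empty string")
  bad <- setdiff(strsplit(pattern, "")[[1]], IUPAC_NT)
  if (length(bad))
    stop("malformed PAM pattern '", pattern, "': illegal character(s) ",
         paste(bad, collapse = ", "))
  invisible(pattern)
}

# Split "4,6,10" -> integer vector; "" -> integer(0). Inverse of int_csv().
parse_int_csv <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE),
         function(p) if (length(p) == 0L || identical(p, "")) integer(0) else as.integer(p))
}

int_csv <- function(x) vapply(x, function(v) paste(v, collapse = ","), character(1))

`%||%` <- function(a, b) if (is.null(a)) b else a
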