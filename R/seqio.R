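# Sequence/variant/feature I/O under fixed conventions.
#
# All coordinates inside the package are 1-based inclusive, the native
# convention of FASTA/VCF/GFF3 and of the Bioconductor interval machinery used
# throughout; no internal re-basing occurs. Reference sequences are uppercased
# on load and may contain IUPAC ambiguity codes; reads must be concrete
# (ACGT/N only). Writers emit deterministic plain text so that
# write(read(x)) == normalise(x).

#' Read a reference FASTA into a named sequence vector
#'
#' Sequences are uppercased (soft-masked lowercase is treated as sequence);
#' only IUPAC nucleotide codes are accepted. Duplicate record ids are an
#' error, as is any structural problem (reported with its line number).
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences, one per record.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("FASTA format error: empty file ", path)
  if (!startsWith(lines[nonblank[1]], ">"))
    stop("FASTA format error at line ", nonblank[1], ": expected '>' header")
  bad <- grep(paste0("[^", paste(IUPAC_NT, collapse = ""), "]"),
              toupper(lines[!startsWith(lines, ">")]))
  if (length(bad)) {
    seq_lines <- which(!startsWith(lines, ">"))
    stop("FASTA format error at line ", seq_lines[bad[1]],
         ": illegal sequence character")
  }
  dss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(ids))
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(dss) == 0L))
    stop("FASTA format error: empty sequence for id ",
         ids[Biostrings::width(dss) == 0L][1])
  stats::setNames(toupper(as.character(dss)), ids)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @export
write_genome <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read amplicon reads from FASTQ
#'
#' Qualities are Phred+33. Reads must consist of concrete bases (ACGT or N);
#' ambiguity codes are rejected, since read counting needs concrete bases.
#'
#' @param path path to a FASTQ file.
#' @return data.frame with columns `id`, `seq`, `qual` (Phred+33 strings).
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fq <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  seqs <- toupper(as.character(fq))
  quals <- as.character(S4Vectors::mcols(fq)$qualities)
  if (any(grepl("[^ACGTN]", seqs)))
    stop("read with non-concrete base (only ACGT/N allowed in reads)")
  data.frame(id = sub("\\s.*$", "", names(fq)), seq = unname(seqs),
             qual = unname(quals), stringsAsFactors = FALSE)
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @export
write_reads <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)),
            all(nchar(reads$seq) == nchar(reads$qual)))
  out <- rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Construct an SNV set
#'
#' A named collection of single-nucleotide variants from one sample of the
#' four-sample off-target design (edited / vector_only / negative / wild_type),
#' at either the DNA (WGS) or RNA (WTS) level. Records are unique by
#' (chrom, pos, ref, alt).
#'
#' @param records data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single concrete bases, ref != alt).
#' @param sample sample label.
#' @param level `"DNA"` or `"RNA"`.
#' @param dropped count of non-SNV rows dropped during parsing (bookkeeping).
#' @return object of class `snv_set`.
#' @export
snv_set <- function(records, sample = "edited", level = c("DNA", "RNA"), dropped = 0L) {
  level <- match.arg(level)
  records <- as.data.frame(records)[, c("chrom", "pos", "ref", "alt")]
  records$pos <- as.integer(records$pos)
  stopifnot(all(records$ref %in% c("A", "C", "G", "T")),
            all(records$alt %in% c("A", "C", "G", "T")),
            all(records$ref != records$alt))
  key <- snv_key(records)
  if (anyDuplicated(key)) records <- records[!duplicated(key), ]
  records <- records[order(records$chrom, records$pos, records$ref, records$alt), ]
  rownames(records) <- NULL
  structure(list(sample = sample, level = level, records = records,
                 dropped = as.integer(dropped)),
            class = "snv_set")
}

snv_key <- function(records) paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")

#' @export
print.snv_set <- function(x, ...) {
  cat(sprintf("<snv_set> sample=%s level=%s: %d SNVs (%d non-SNV rows dropped on load)\n",
              x$sample, x$level, nrow(x$records), x$dropped))
  invisible(x)
}

#' @export
length.snv_set <- function(x) nrow(x$records)

#' Read single-nucleotide variants from a VCF
#'
#' Multi-allelic rows are split into one record per ALT allele. Only
#' single-base REF/ALT pairs are retained; indels and multi-nucleotide
#' variants are dropped and counted (`$dropped` on the returned set).
#'
#' @param path path to a VCF (v4.x) file.
#' @param sample sample label to attach.
#' @param level `"DNA"` or `"RNA"`.
#' @return an [snv_set()].
#' @export
read_snvs <- function(path, sample = "edited", level = c("DNA", "RNA")) {
  level <- match.arg(level)
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(snv_set(data.frame(chrom = character(0), pos = integer(0),
                              ref = character(0), alt = character(0)),
                   sample, level, 0L))
  if (any(is.na(fix$CHROM)) || any(is.na(fix$POS)) ||
      any(is.na(fix$REF)) || any(is.na(fix$ALT)))
    stop("VCF format error: missing CHROM/POS/REF/ALT in ", path)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  long <- data.frame(chrom = rep(fix$CHROM, n_alt),
                     pos = rep(as.integer(fix$POS), n_alt),
                     ref = rep(toupper(fix$REF), n_alt),
                     alt = toupper(unlist(alts)),
                     stringsAsFactors = FALSE)
  is_snv <- nchar(long$ref) == 1L & nchar(long$alt) == 1L &
    long$ref %in% c("A", "C", "G", "T") & long$alt %in% c("A", "C", "G", "T") &
    long$ref != long$alt
  snv_set(long[is_snv, , drop = FALSE], sample, level, dropped = sum(!is_snv))
}

#' Write an SNV set as a minimal VCF v4.2
#'
#' @param x an [snv_set()].
#' @param path output path.
#' @export
write_snvs <- function(x, path) {
  stopifnot(inherits(x, "snv_set"))
  r <- x$records
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=beditr;sample=", x$sample, ";level=", x$level),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
                     collapse = "\t")), con)
  if (nrow(r))
    writeLines(paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".", sep = "\t"), con)
  invisible(path)
}

#' Read gene features from GFF3
#'
#' Returns the feature table restricted to the types the toolkit consumes
#' (gene, mRNA, CDS, exon, UTRs), with `parent` resolved from the GFF3
#' `Parent` attribute. CDS features must carry a Parent.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns `seq_id`, `type`, `start`, `end`, `strand`,
#'   `phase`, `id`, `parent`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- c("gene", "mRNA", "CDS", "exon", "five_prime_UTR", "three_prime_UTR")
  gr <- gr[as.character(gr$type) %in% keep]
  parent <- if (is.null(gr$Parent)) rep(NA_character_, length(gr))
  else vapply(as.list(gr$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
              character(1))
  feats <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    phase = if (!is.null(gr$phase)) as.integer(gr$phase) else NA_integer_,
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = parent,
    stringsAsFactors = FALSE)
  stopifnot(all(feats$start <= feats$end))
  if (any(feats$type == "CDS" & is.na(feats$parent)))
    stop("GFF3 error: CDS feature without a Parent attribute in ", path)
  feats
}

#' Write a feature table as GFF3
#'
#' Deterministic output: features in input order, attributes limited to
#' ID/Parent.
#'
#' @param feats feature data.frame as returned by [read_features()].
#' @param path output path.
#' @export
write_gff3 <- function(feats, path) {
  attr_col <- ifelse(is.na(feats$parent) | feats$parent == "",
                     paste0("ID=", feats$id),
                     paste0("ID=", feats$id, ";Parent=", feats$parent))
  lines <- paste(feats$seq_id, "beditr", feats$type, feats$start, feats$end, ".",
                 feats$strand, ifelse(is.na(feats$phase), ".", feats$phase),
                 attr_col, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
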