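# Closed-loop synthetic data: genomes with planted guide and off-target
# sites and CDS-bearing gene models, amplicon read pools with programmed
# per-position conversion rates (or allele mixtures), and four-sample SNV
# designs with shared background plus sample-private variants. Every
# generator records a truth ledger that the analysis modules must
# reproduce -- exactly when the error rate is zero, within binomial bounds
# otherwise.

# Run code under a private RNG stream: seeds the generator, restores
# whatever random state the caller had.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Random in-frame CDS: ATG + (n_codons - 2) sense codons + TAA.
random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(names(Biostrings::GENETIC_CODE), stops)
  paste0("ATG", paste(sample(sense, n_codons - 2L, TRUE), collapse = ""), "TAA")
}

# One concrete instance of an IUPAC pattern (first expansion letter of each code).
pam_instance <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]], function(p) iupac_expansion(p)[1],
               character(1)), collapse = "")
}

# Protospacer whose editable window set is exactly `editable`: edit_from at
# those positions, anything but edit_from elsewhere in the window.
planted_protospacer <- function(profile, editable) {
  stopifnot(all(editable >= profile$window[1] & editable <= profile$window[2]))
  other <- setdiff(c("A", "C", "G", "T"), profile$edit_from)
  p <- sample(c("A", "C", "G", "T"), profile$protospacer_len, TRUE)
  w <- profile$window[1]:profile$window[2]
  p[w] <- sample(other, length(w), TRUE)
  p[editable] <- profile$edit_from
  paste(p, collapse = "")
}

# protospacer+PAM in genomic forward orientation for planting.
site_with_pam <- function(protospacer, pam, profile, strand) {
  oriented <- if (profile$pam_side == "three_prime")
    paste0(protospacer, pam) else paste0(pam, protospacer)
  if (strand == "+") oriented else revcomp(oriented)
}

mutate_protospacer <- function(protospacer, n_mismatch) {
  ch <- strsplit(protospacer, "")[[1]]
  at <- sample(length(ch), n_mismatch)
  for (i in at) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  list(seq = paste(ch, collapse = ""), positions = sort(at))
}

#' Simulate a genome with gene models and planted guide/off-target sites
#'
#' Generates one chromosome of random sequence carrying (i) `n_genes`
#' two-exon genes on alternating strands, each with UTRs, an intron and an
#' in-frame CDS (the first gene's CDS is fixed at 525 bp, emulating a short
#' single-ORF target gene); (ii) one guide site for `profile` with a chosen
#' editable-position layout; and (iii) off-target copies of that protospacer
#' carrying the requested mismatch counts, placed on alternating strands.
#' Planted elements never overlap. Deterministic under `seed`.
#'
#' @param seed integer seed for the generator's private RNG stream.
#' @param genome_length chromosome length (default 100 kb).
#' @param n_genes number of genes (default 5).
#' @param profile [editor_profile()] for the planted sites.
#' @param guide_editable protospacer positions planted as editable.
#' @param offtarget_mismatches integer vector: one planted off-target site
#'   per entry, with that many protospacer mismatches.
#' @param chrom chromosome name.
#' @return list of class `sim_genome`: `genome` (named vector), `features`
#'   (GFF3-style table), and `truth` ledger (per-gene CDS strings, the
#'   planted guide locus, the planted off-target loci).
#' @export
simulate_genome <- function(seed = 1L, genome_length = 100000L, n_genes = 5L,
                            profile = editor_profile("GhABE8e"),
                            guide_editable = c(4L, 6L, 7L),
                            offtarget_mismatches = c(1L, 2L, 2L),
                            chrom = "chr1") {
  with_seed(seed, {
    base_vec <- sample(c("A", "C", "G", "T"), genome_length, TRUE)
    occupied <- rep(FALSE, genome_length)
    feats <- list(); truth_genes <- list(); cds_seqs <- character(0)

    # --- genes, evenly spread over the first ~80% of the chromosome
    slots <- floor(seq(0.05, 0.75, length.out = n_genes) * genome_length)
    for (gi in seq_len(n_genes)) {
      n_codons <- if (gi == 1L) 175L else sample(60:120, 1L)
      cds <- random_cds(n_codons)
      c1 <- (sample(10:(n_codons - 10L), 1L)) * 3L  # split point, in-frame by construction of phase
      c1 <- c1 + sample(0:2, 1L)                    # allow non-codon-aligned splits
      u5 <- sample(60:120, 1L); u3 <- sample(50:100, 1L); ilen <- sample(80:150, 1L)
      region <- paste0(random_dna(u5), substring(cds, 1L, c1), random_dna(ilen),
                       substring(cds, c1 + 1L, nchar(cds)), random_dna(u3))
      len <- nchar(region)
      strand <- if (gi %% 2L == 1L) "+" else "-"
      o <- slots[gi]
      if (any(occupied[o:(o + len - 1L)])) stop("planted gene overlaps another element")
      occupied[o:(o + len - 1L)] <- TRUE
      ins <- if (strand == "+") region else revcomp(region)
      base_vec[o:(o + len - 1L)] <- strsplit(ins, "")[[1]]
      # transcript-local intervals -> genomic
      t2g <- function(a, b) {
        if (strand == "+") c(o + a - 1L, o + b - 1L) else c(o + len - b, o + len - a)
      }
      iv_u5 <- t2g(1L, u5)
      iv_c1 <- t2g(u5 + 1L, u5 + c1)
      iv_c2 <- t2g(u5 + c1 + ilen + 1L, u5 + c1 + ilen + (nchar(cds) - c1))
      iv_u3 <- t2g(u5 + c1 + ilen + nchar(cds) - c1 + 1L, len)
      gid <- paste0("gene", gi); mid <- paste0("mRNA", gi)
      phase2 <- (3L - c1 %% 3L) %% 3L
      feats[[length(feats) + 1L]] <- data.frame(
        seq_id = chrom,
        type = c("gene", "mRNA", "five_prime_UTR", "CDS", "CDS", "three_prime_UTR"),
        start = c(o, o, iv_u5[1], iv_c1[1], iv_c2[1], iv_u3[1]),
        end = c(o + len - 1L, o + len - 1L, iv_u5[2], iv_c1[2], iv_c2[2], iv_u3[2]),
        strand = strand,
        phase = c(NA, NA, NA, 0L, phase2, NA),
        id = c(gid, mid, paste0(mid, c(".utr5", ".cds1", ".cds2", ".utr3"))),
        parent = c(NA, gid, mid, mid, mid, mid),
        stringsAsFactors = FALSE)
      cds_seqs[[mid]] <- cds
      truth_genes[[gid]] <- list(strand = strand, start = o, end = o + len - 1L,
                                 cds_len = nchar(cds))
    }

    # --- planted guide + off-target sites in the free tail
    pam <- pam_instance(profile$pam)
    protospacer <- planted_protospacer(profile, guide_editable)
    site_len <- profile$protospacer_len + nchar(pam)
    place <- function(fwd_site) {
      repeat {
        s <- sample(genome_length - site_len, 1L)
        if (!any(occupied[s:(s + site_len - 1L)])) break
      }
      occupied[s:(s + site_len - 1L)] <<- TRUE
      base_vec[s:(s + site_len - 1L)] <<- strsplit(fwd_site, "")[[1]]
      s
    }
    g_start <- place(site_with_pam(protospacer, pam, profile, "+"))
    proto_start <- if (profile$pam_side == "three_prime") g_start else g_start + nchar(pam)
    guide_truth <- list(protospacer = protospacer, pam = pam, chrom = chrom,
                        start = proto_start, end = proto_start + profile$protospacer_len - 1L,
                        strand = "+", editable = guide_editable)
    ot <- lapply(seq_along(offtarget_mismatches), function(i) {
      mut <- mutate_protospacer(protospacer, offtarget_mismatches[i])
      strand <- if (i %% 2L == 1L) "+" else "-"
      s <- place(site_with_pam(mut$seq, pam, profile, strand))
      ps <- if (profile$pam_side == "three_prime") {
        if (strand == "+") s else s + nchar(pam)
      } else {
        if (strand == "+") s + nchar(pam) else s
      }
      data.frame(chrom = chrom, start = ps, end = ps + profile$protospacer_len - 1L,
                 strand = strand, site_seq = mut$seq,
                 mismatches = offtarget_mismatches[i],
                 mismatch_positions = int_csv(list(mut$positions)),
                 stringsAsFactors = FALSE)
    })
    feats_df <- do.call(rbind, feats)
    structure(list(
      genome = stats::setNames(paste(base_vec, collapse = ""), chrom),
      features = feats_df,
      profile = profile,
      truth = list(genes = truth_genes, cds_seqs = cds_seqs, guide = guide_truth,
                   offtargets = do.call(rbind, ot)),
      seed = seed), class = "sim_genome")
  })
}

#' Simulate an amplicon carrying one guide site
#'
#' A random amplicon (default 230 bp, the typical size of the PCR products
#' sequenced in editing experiments) with a planted protospacer+PAM whose
#' editable window set is exactly `editable`.
#'
#' @param seed integer seed.
#' @param profile [editor_profile()].
#' @param length amplicon length.
#' @param editable protospacer positions planted as editable.
#' @param guide_start amplicon position of protospacer base 1.
#' @return an [amplicon_target()].
#' @export
simulate_amplicon <- function(seed = 1L, profile = editor_profile("GhABE8e"),
                              length = 230L, editable = c(4L, 6L, 7L),
                              guide_start = 100L) {
  with_seed(seed, {
    pam <- pam_instance(profile$pam)
    protospacer <- planted_protospacer(profile, editable)
    amp <- strsplit(random_dna(length), "")[[1]]
    fwd_site <- site_with_pam(protospacer, pam, profile, "+")
    s0 <- if (profile$pam_side == "three_prime") guide_start else guide_start - nchar(pam)
    stopifnot(s0 >= 1L, s0 + nchar(fwd_site) - 1L <= length)
    amp[s0:(s0 + nchar(fwd_site) - 1L)] <- strsplit(fwd_site, "")[[1]]
    amp <- paste(amp, collapse = "")
    cands <- scan_guides(stats::setNames(amp, "amplicon"), profile)
    g <- cands[cands$start == guide_start & cands$strand == "+", , drop = FALSE]
    stopifnot(nrow(g) == 1L)
    amplicon_target(amp, g, profile)
  })
}

#' Simulate an amplicon read pool with programmed editing
#'
#' Two modes. Rate mode (`rates`): each read converts each editable position
#' independently with its programmed probability -- the Bernoulli model of a
#' polyclonal cell pool. Allele mode (`alleles`): each read is drawn from a
#' fixed mixture of edit genotypes (subsets of editable positions), the model
#' of a chimeric regenerant. Sequencing errors are added per base with
#' probability `epsilon` (uniform among the three other bases); base
#' qualities are constant Q40. The truth ledger records each read's
#' installed edits and the realised per-position counts, so with
#' `epsilon = 0` the downstream [align_reads()] tallies must match exactly.
#'
#' @param target an [amplicon_target()] (e.g. from [simulate_amplicon()]).
#' @param n_reads pool size.
#' @param rates named numeric vector, names = editable protospacer positions.
#' @param alleles data.frame with columns `subset` (protospacer positions
#'   joined by `+`, `""` for wild type) and `freq` (summing to 1).
#' @param epsilon per-base sequencing error rate (default 0).
#' @param seed integer seed.
#' @return list: `reads` (data.frame for [align_reads()]), `truth` ledger
#'   with `edit_sets`, `position_counts` (realised reads carrying each
#'   editable conversion), `site_count` (reads with >= 1 conversion),
#'   `allele_counts`.
#' @export
simulate_amplicon_reads <- function(target, n_reads = 200L, rates = NULL,
                                    alleles = NULL, epsilon = 0, seed = 1L) {
  stopifnot(inherits(target, "amplicon_target"), xor(is.null(rates), is.null(alleles)))
  lay <- editable_layout(target)
  with_seed(seed, {
    if (!is.null(rates)) {
      pos <- as.integer(names(rates))
      if (!all(pos %in% lay$proto_pos))
        stop("programmed rate for non-editable position(s): ",
             paste(setdiff(pos, lay$proto_pos), collapse = ","))
      if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
      edit_sets <- lapply(seq_len(n_reads), function(i)
        pos[stats::runif(length(pos)) < rates])
    } else {
      stopifnot(all(c("subset", "freq") %in% names(alleles)),
                abs(sum(alleles$freq) - 1) < 1e-9)
      subsets <- lapply(strsplit(alleles$subset, "+", fixed = TRUE),
                        function(p) as.integer(p[nzchar(p)]))
      if (!all(unlist(subsets) %in% lay$proto_pos))
        stop("allele subset contains a non-editable position")
      pick <- sample.int(nrow(alleles), n_reads, TRUE, prob = alleles$freq)
      edit_sets <- subsets[pick]
    }
    amp_chars <- strsplit(target$amplicon_seq, "")[[1]]
    A <- length(amp_chars)
    seqs <- vapply(edit_sets, function(es) {
      ch <- amp_chars
      if (length(es)) ch[lay$amp_pos[match(es, lay$proto_pos)]] <- lay$to
      paste(ch, collapse = "")
    }, character(1))
    if (epsilon > 0) {
      seqs <- vapply(seqs, function(s) {
        ch <- strsplit(s, "")[[1]]
        err <- which(stats::runif(A) < epsilon)
        for (i in err) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    qual <- strrep("I", A)  # Phred+33 'I' = Q40
    reads <- data.frame(id = paste0("read", seq_len(n_reads)), seq = unname(seqs),
                        qual = qual, stringsAsFactors = FALSE)
    position_counts <- vapply(lay$proto_pos, function(p)
      sum(vapply(edit_sets, function(es) p %in% es, logical(1))), integer(1))
    names(position_counts) <- lay$proto_pos
    allele_key <- vapply(edit_sets, function(es) paste(sort(es), collapse = "+"),
                         character(1))
    list(reads = reads,
         truth = list(edit_sets = edit_sets, position_counts = position_counts,
                      site_count = sum(lengths(edit_sets) > 0L),
                      allele_counts = table(allele_key)),
         target = target)
  })
}

# Paint every genomic position with its region category, by the same
# priority order the annotator uses (exonic > UTR > intronic > upstream >
# downstream > intergenic).
region_map <- function(feats, genome_length, upstream_bp = 2000L, downstream_bp = 2000L) {
  cat_vec <- rep("intergenic", genome_length)
  paint <- function(d, label) {
    for (i in seq_len(nrow(d)))
      cat_vec[max(1L, d$start[i]):min(genome_length, d$end[i])] <<- label
  }
  genes <- feats[feats$type == "gene", , drop = FALSE]
  plus <- genes$strand == "+"
  up <- data.frame(start = ifelse(plus, genes$start - upstream_bp, genes$end + 1L),
                   end = ifelse(plus, genes$start - 1L, genes$end + upstream_bp))
  dn <- data.frame(start = ifelse(plus, genes$end + 1L, genes$start - downstream_bp),
                   end = ifelse(plus, genes$end + downstream_bp, genes$start - 1L))
  paint(dn[dn$start <= dn$end, , drop = FALSE], "downstream2kb")
  paint(up[up$start <= up$end, , drop = FALSE], "upstream2kb")
  paint(genes, "intronic")
  paint(feats[feats$type %in% c("five_prime_UTR", "three_prime_UTR"), , drop = FALSE], "UTR")
  paint(feats[feats$type == "CDS", , drop = FALSE], "exonic")
  cat_vec
}

#' Simulate the four-sample SNV off-target design
#'
#' Draws a set of background SNVs shared by all four samples (edited,
#' vector-only positive control, negative regenerant, wild type) plus
#' sample-private SNVs, with a configurable mutation-class mix, and returns
#' the four call sets together with the ground truth. All positions are
#' distinct, so background subtraction must recover exactly the private
#' records. The private SNVs of the edited sample can be pinned to region
#' categories and/or kept away from given intervals (e.g. predicted
#' off-target site footprints).
#'
#' @param sim a [simulate_genome()] result.
#' @param seed integer seed.
#' @param n_shared background SNVs present in all four samples (default 300).
#' @param n_private named integer vector of private counts per sample.
#' @param class_mix named proportions over mutation classes (`"A>G"` etc.).
#' @param level `"DNA"` or `"RNA"`.
#' @param region_counts optional named counts over region categories for the
#'   edited sample's private SNVs (overrides `n_private["edited"]`).
#' @param avoid optional [GenomicRanges::GRanges]; no private edited SNV is
#'   placed inside.
#' @return list: `sets` (named list of four [snv_set()]s), `truth` ledger
#'   with `shared`, `private` (per sample, with class), and for the edited
#'   sample the planted region `categories`.
#' @export
simulate_snv_design <- function(sim, seed = 1L, n_shared = 300L,
                                n_private = c(edited = 50L, vector_only = 40L,
                                              negative = 30L, wild_type = 30L),
                                class_mix = c("A>G" = 0.25, "T>C" = 0.25,
                                              "C>T" = 0.25, "G>A" = 0.25),
                                level = c("DNA", "RNA"),
                                region_counts = NULL, avoid = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(sim, "sim_genome"), abs(sum(class_mix) - 1) < 1e-9)
  chrom <- names(sim$genome)
  L <- nchar(sim$genome[[1]])
  base_vec <- strsplit(sim$genome[[1]], "")[[1]]
  with_seed(seed, {
    available <- rep(TRUE, L)
    if (!is.null(avoid) && length(avoid)) {
      av <- IRanges::ranges(avoid)
      for (i in seq_along(av))
        available[IRanges::start(av)[i]:min(L, IRanges::end(av)[i])] <- FALSE
    }
    draw <- function(n, from_bases, within = NULL) {
      pool <- which(available & base_vec %in% from_bases)
      if (!is.null(within)) pool <- intersect(pool, within)
      if (length(pool) < n) stop("requested SNVs exceed available positions")
      p <- sample(pool, n)
      available[p] <<- FALSE
      p
    }
    make_records <- function(n, within = NULL) {
      if (n == 0L)
        return(data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                          alt = character(0), class = character(0)))
      cls <- sample(names(class_mix), n, TRUE, prob = class_mix)
      from <- substring(cls, 1L, 1L)
      to <- substring(cls, 3L, 3L)
      pos <- integer(n)
      for (b in unique(from)) {
        sel <- from == b
        pos[sel] <- draw(sum(sel), b, within)
      }
      o <- order(pos)
      data.frame(chrom = chrom, pos = pos[o], ref = from[o], alt = to[o],
                 class = cls[o], stringsAsFactors = FALSE)
    }
    shared <- make_records(n_shared)
    samples <- c("edited", "vector_only", "negative", "wild_type")
    categories <- NULL
    private <- list()
    for (s in samples) {
      if (s == "edited" && !is.null(region_counts)) {
        cat_vec <- region_map(sim$features, L)
        recs <- do.call(rbind, lapply(names(region_counts), function(cc) {
          r <- make_records(region_counts[[cc]], within = which(cat_vec == cc))
          if (nrow(r)) r$category <- cc
          r
        }))
        recs <- recs[order(recs$pos), , drop = FALSE]
        categories <- recs$category
        private[[s]] <- recs
      } else {
        private[[s]] <- make_records(n_private[[s]])
      }
    }
    base_cols <- c("chrom", "pos", "ref", "alt")
    sets <- lapply(samples, function(s)
      snv_set(rbind(shared[base_cols], private[[s]][base_cols]), s, level))
    names(sets) <- samples
    list(sets = sets,
         truth = list(shared = shared, private = private, categories = categories),
         seed = seed)
  })
}
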