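#' Build a validated gene model
#'
#' A gene model is the coordinate frame every other operation maps into: the
#' genomic sequence of a single gene (coding strand, 5'->3'), its ordered
#' exon intervals, and the position of the A of the ATG start codon. All
#' internal genomic coordinates are 0-based half-open; HGVS cDNA anchors are
#' 1-based per the HGVS standard.
#'
#' @param name Gene name (single string).
#' @param sequence Nucleotide sequence over \{A,C,G,T,N\}, any case; stored
#'   upper-cased. May be given as a character vector of lines.
#' @param exons Two-column matrix or data frame of exon intervals
#'   (start, end), 0-based half-open, sorted ascending, non-overlapping,
#'   non-empty, contained in the sequence.
#' @param start_codon_offset 0-based offset of the A of ATG; must fall inside
#'   an exon.
#' @return An object of class `gene_model`: a list with fields `gene_name`,
#'   `sequence`, `exons` (integer matrix), `start_codon_offset`, plus cached
#'   exonic offset vectors used by the coordinate converters.
#' @examples
#' m <- gene_model("TOY", strrep("ACGT", 50), cbind(0, 200), 50)
#' m$start_codon_offset
#' @export
gene_model <- function(name, sequence, exons, start_codon_offset) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    g4_abort("g4snp_construction_error", "gene name must be a non-empty string")
  sequence <- toupper(paste(sequence, collapse = ""))
  if (grepl("[^ACGTN]", sequence))
    g4_abort("g4snp_alphabet_error", sprintf(
      "sequence of '%s' contains characters outside {A,C,G,T,N}", name))
  n <- nchar(sequence)

  exons <- as.matrix(exons)
  if (ncol(exons) != 2L || nrow(exons) < 1L || anyNA(exons))
    g4_abort("g4snp_construction_error", "exons must be a non-empty 2-column (start, end) table")
  storage.mode(exons) <- "integer"
  dimnames(exons) <- list(NULL, c("start", "end"))
  if (any(exons[, "start"] >= exons[, "end"]))
    g4_abort("g4snp_construction_error", "every exon must be non-empty (start < end)")
  if (any(exons < 0L) || any(exons[, "end"] > n))
    g4_abort("g4snp_construction_error", "exon intervals must lie within [0, sequence length)")
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons[, "start"], strictly = TRUE))
      g4_abort("g4snp_construction_error", "exons must be sorted by ascending start")
    if (any(exons[-nrow(exons), "end"] > exons[-1L, "start"]))
      g4_abort("g4snp_construction_error", "exons must not overlap")
  }

  start_codon_offset <- as.integer(start_codon_offset)
  if (length(start_codon_offset) != 1L || is.na(start_codon_offset))
    g4_abort("g4snp_construction_error", "start_codon_offset must be a single integer")
  in_exon <- exons[, "start"] <= start_codon_offset & start_codon_offset < exons[, "end"]
  if (!any(in_exon))
    g4_abort("g4snp_construction_error",
             "start codon must lie inside an exon (it falls in an intron or flank)")

  exonic <- unlist(lapply(seq_len(nrow(exons)), function(i)
    seq.int(exons[i, "start"], exons[i, "end"] - 1L)), use.names = FALSE)

  structure(
    list(
      gene_name = name,
      sequence = sequence,
      exons = exons,
      start_codon_offset = start_codon_offset,
      # caches: genomic offsets of coding bases c.1.. and 5'UTR bases c.-1..
      # (transcript order; utr5 reversed so index M is the offset of c.-M)
      coding_offsets = exonic[exonic >= start_codon_offset],
      utr5_offsets = rev(exonic[exonic < start_codon_offset])
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d bp, %d exon(s), ATG at offset %d (%d coding bases)\n",
              x$gene_name, nchar(x$sequence), nrow(x$exons),
              x$start_codon_offset, length(x$coding_offsets)))
  invisible(x)
}

# intron intervals (0-based half-open) between consecutive exons; 0-row matrix
# for single-exon models
introns_of <- function(model) {
  ex <- model$exons
  if (nrow(ex) < 2L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  cbind(start = ex[-nrow(ex), "end"], end = ex[-1L, "start"])
}

#' Construct a cDNA position descriptor
#'
#' The structured form of an HGVS cDNA position: region kind, anchor and
#' intronic offset, without the substitution bases. `cdna_to_genomic()`
#' accepts either a full [parse_hgvs_cdna()] variant or a bare descriptor.
#'
#' @param region One of `"coding"`, `"intronic"`, `"utr5"`, `"utr3"`.
#' @param anchor Coding base number (>= 1) for coding/intronic/utr3 regions;
#'   <= -1 for utr5. Intronic descriptors anchored to a 5'UTR exon-terminal
#'   base (which plain HGVS substitution grammar cannot express) carry a
#'   negative anchor.
#' @param intron_offset Signed offset into the intron; nonzero iff
#'   `region == "intronic"`.
#' @return A list of class `cdna_descriptor`.
#' @export
cdna_descriptor <- function(region, anchor, intron_offset = 0L) {
  region <- match.arg(region, c("coding", "intronic", "utr5", "utr3"))
  anchor <- as.integer(unname(anchor))
  intron_offset <- as.integer(unname(intron_offset))
  if ((intron_offset != 0L) != (region == "intronic"))
    g4_abort("g4snp_construction_error",
             "intron_offset must be nonzero exactly when region is intronic")
  if (region == "utr5" && anchor > -1L)
    g4_abort("g4snp_construction_error", "utr5 anchors are <= -1")
  if (region %in% c("coding", "utr3") && anchor < 1L)
    g4_abort("g4snp_construction_error", "coding/utr3 anchors are >= 1")
  structure(list(region = region, anchor = anchor, intron_offset = intron_offset),
            class = "cdna_descriptor")
}

# genomic offset of an anchor base: coding base K (anchor K >= 1) or 5'UTR
# base c.-M (anchor -M); errors when out of range
anchor_offset <- function(model, anchor) {
  if (anchor >= 1L) {
    cp <- model$coding_offsets
    if (anchor > length(cp))
      g4_abort("g4snp_range_error", sprintf(
        "coding anchor %d exceeds the %d coding-exon bases of '%s'",
        anchor, length(cp), model$gene_name))
    cp[[anchor]]
  } else {
    m <- -anchor
    u5 <- model$utr5_offsets
    if (m <= length(u5)) {
      u5[[m]]
    } else {
      # beyond the transcribed 5'UTR: continue contiguously upstream of exon 1
      off <- model$exons[1L, "start"] - (m - length(u5))
      if (off < 0L)
        g4_abort("g4snp_coordinate_error", sprintf(
          "5'UTR anchor -%d reaches %d bp past the start of the supplied sequence",
          m, -off))
      off
    }
  }
}

#' Convert an HGVS cDNA position to a genomic location (SNP locator core)
#'
#' Walks the exon structure to turn a cDNA anchor into a 0-based offset in
#' the gene sequence and the signed distance from the start codon (the A of
#' ATG is distance 0; negative = upstream). Coding base K is the K-th coding
#' base along the spliced exons starting at the ATG; intronic `c.K+N` /
#' `c.K-N` steps N genomic bases off an exon-terminal coding base; 5'UTR
#' `c.-M` counts upstream along the spliced transcript and, past the first
#' exon, continues contiguously into the upstream genomic flank (this is what
#' reaches promoter variants); 3'UTR `c.*M` counts downstream of the last
#' exonic base.
#'
#' @param model A [gene_model()].
#' @param variant A parsed [parse_hgvs_cdna()] variant or a
#'   [cdna_descriptor()].
#' @return A list of class `genomic_location` with fields `offset` (0-based)
#'   and `distance_from_start_codon` (`offset - start_codon_offset`).
#' @examples
#' m <- gene_model("TOY", strrep("A", 30), rbind(c(0, 10), c(20, 30)), 2)
#' cdna_to_genomic(m, parse_hgvs_cdna("c.9A>T"))$offset   # 20
#' @export
cdna_to_genomic <- function(model, variant) {
  stopifnot(inherits(model, "gene_model"))
  if (!all(c("region", "anchor", "intron_offset") %in% names(variant)))
    g4_abort("g4snp_construction_error",
             "variant must be a parsed HGVS variant or a cdna_descriptor")
  region <- variant$region
  anchor <- as.integer(variant$anchor)
  ioff <- as.integer(variant$intron_offset)
  n <- nchar(model$sequence)
  ex <- model$exons

  offset <- switch(region,
    coding = anchor_offset(model, anchor),
    utr5 = anchor_offset(model, anchor),
    utr3 = {
      last <- ex[nrow(ex), "end"] - 1L  # last exonic (coding) base
      off <- last + anchor
      if (off >= n)
        g4_abort("g4snp_coordinate_error", sprintf(
          "3'UTR anchor *%d reaches past the end of the supplied sequence", anchor))
      off
    },
    intronic = {
      pos <- anchor_offset(model, anchor)
      i_exon <- which(ex[, "start"] <= pos & pos < ex[, "end"])
      if (ioff > 0L) {
        if (pos != ex[i_exon, "end"] - 1L)
          g4_abort("g4snp_structure_error", sprintf(
            "'+%d' offset requires anchor base %d to be the last base of its exon; gene model and variant disagree",
            ioff, anchor))
        if (i_exon == nrow(ex))
          g4_abort("g4snp_coordinate_error",
                   "'+' intronic offset from the last exon points past the gene, not into an intron")
        off <- pos + ioff
        if (off >= ex[i_exon + 1L, "start"])
          g4_abort("g4snp_coordinate_error", sprintf(
            "intronic offset +%d overshoots the %d bp intron", ioff,
            ex[i_exon + 1L, "start"] - ex[i_exon, "end"]))
        off
      } else {
        if (pos != ex[i_exon, "start"])
          g4_abort("g4snp_structure_error", sprintf(
            "'%d' offset requires anchor base %d to be the first base of its exon; gene model and variant disagree",
            ioff, anchor))
        if (i_exon == 1L)
          g4_abort("g4snp_coordinate_error",
                   "'-' intronic offset from the first exon points upstream of the gene, not into an intron")
        off <- pos + ioff
        if (off < ex[i_exon - 1L, "end"])
          g4_abort("g4snp_coordinate_error", sprintf(
            "intronic offset %d overshoots the %d bp intron", ioff,
            ex[i_exon, "start"] - ex[i_exon - 1L, "end"]))
        off
      }
    }
  )

  offset <- as.integer(unname(offset))
  structure(
    list(offset = offset,
         distance_from_start_codon = offset - model$start_codon_offset),
    class = "genomic_location"
  )
}

#' @export
print.genomic_location <- function(x, ...) {
  cat(sprintf("<genomic_location> offset %d (%+d from start codon)\n",
              x$offset, x$distance_from_start_codon))
  invisible(x)
}

#' Classify a genomic offset as a cDNA position descriptor
#'
#' Exact inverse of [cdna_to_genomic()] on its reachable range: every offset
#' of the sequence is classifiable (coding, intronic, 5'UTR -- including the
#' contiguous upstream flank -- or 3'UTR). Intronic bases follow the HGVS
#' midpoint rule: the 5' half of an intron is anchored `+N` to the preceding
#' exon's last base, the 3' half `-N` to the following exon's first base; an
#' odd intron's middle base goes to the `+` side.
#'
#' @param model A [gene_model()].
#' @param offset 0-based offset, `0 <= offset < nchar(sequence)`.
#' @return A [cdna_descriptor()].
#' @export
genomic_to_cdna <- function(model, offset) {
  stopifnot(inherits(model, "gene_model"))
  offset <- as.integer(offset)
  n <- nchar(model$sequence)
  if (length(offset) != 1L || is.na(offset) || offset < 0L || offset >= n)
    g4_abort("g4snp_coordinate_error",
             sprintf("offset must lie in [0, %d)", n))
  ex <- model$exons
  sco <- model$start_codon_offset

  i_exon <- which(ex[, "start"] <= offset & offset < ex[, "end"])
  if (length(i_exon) == 1L) {
    if (offset >= sco)
      return(cdna_descriptor("coding", match(offset, model$coding_offsets)))
    return(cdna_descriptor("utr5", -match(offset, model$utr5_offsets)))
  }
  if (offset < ex[1L, "start"]) {
    m <- length(model$utr5_offsets) + (ex[1L, "start"] - offset)
    return(cdna_descriptor("utr5", -m))
  }
  if (offset >= ex[nrow(ex), "end"])
    return(cdna_descriptor("utr3", offset - (ex[nrow(ex), "end"] - 1L)))

  ins <- introns_of(model)
  k <- which(ins[, "start"] <= offset & offset < ins[, "end"])
  s <- ins[k, "start"]; e <- ins[k, "end"]
  i <- offset - s
  if (i < ceiling((e - s) / 2)) {
    left <- s - 1L  # last base of preceding exon
    anc <- if (left >= sco) match(left, model$coding_offsets)
           else -match(left, model$utr5_offsets)
    cdna_descriptor("intronic", anc, i + 1L)
  } else {
    right <- e      # first base of following exon
    anc <- if (right >= sco) match(right, model$coding_offsets)
           else -match(right, model$utr5_offsets)
    cdna_descriptor("intronic", anc, offset - e)
  }
}

#' Check the HGVS reference base against the gene sequence
#'
#' The base the locator lands on should equal the variant's stated reference
#' base; a mismatch usually means a stale transcript, a minus-strand gene
#' supplied un-reverse-complemented, or a wrong gene model. Lenient by
#' default (a warning-level finding in the returned report); strict mode
#' turns a mismatch into an error. An N at the target position is reported
#' as `"indeterminate"`, never as a silent match.
#'
#' @param model A [gene_model()].
#' @param loc The [cdna_to_genomic()] location of `variant`.
#' @param variant The parsed variant whose `ref_base` is checked.
#' @param strict If `TRUE`, a mismatch raises a reference-mismatch error.
#' @return A list of class `ref_check` with fields `status` (`"match"`,
#'   `"mismatch"`, `"indeterminate"`), `expected`, `observed`, `offset`.
#' @export
verify_ref_base <- function(model, loc, variant, strict = FALSE) {
  stopifnot(inherits(model, "gene_model"))
  observed <- substr(model$sequence, loc$offset + 1L, loc$offset + 1L)
  expected <- toupper(variant$ref_base)
  status <- if (observed == "N") "indeterminate"
            else if (observed == expected) "match"
            else "mismatch"
  if (strict && status != "match")
    g4_abort("g4snp_ref_mismatch_error", sprintf(
      "reference base check failed at offset %d: variant says %s, sequence has %s",
      loc$offset, expected, observed))
  structure(list(status = status, expected = expected, observed = observed,
                 offset = loc$offset),
            class = "ref_check")
}
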