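toy <- function() gene_model("TOY", strrep("A", 30), rbind(c(0, 10), c(20, 30)), 2)

test_that("construction validates exon structure, start codon and alphabet", {
  m <- gene_model("OK", strrep("ACGT", 50), cbind(0, 200), 50)
  expect_s3_class(m, "gene_model")
  expect_identical(m$start_codon_offset, 50L)
  expect_length(m$coding_offsets, 150L)

  seq30 <- strrep("A", 30)
  expect_error(gene_model("X", seq30, rbind(c(0, 10), c(5, 20)), 2),
               class = "g4snp_construction_error")   # overlap
  expect_error(gene_model("X", seq30, rbind(c(20, 30), c(0, 10)), 2),
               class = "g4snp_construction_error")   # unsorted
  expect_error(gene_model("X", seq30, rbind(c(0, 10), c(20, 30)), 15),
               class = "g4snp_construction_error")   # ATG in intron
  expect_error(gene_model("X", seq30, rbind(c(10, 10)), 2),
               class = "g4snp_construction_error")   # empty exon
  expect_error(gene_model("X", seq30, rbind(c(0, 40)), 2),
               class = "g4snp_construction_error")   # exon past sequence
  expect_error(gene_model("X", "ACGU", cbind(0, 4), 0),
               class = "g4snp_alphabet_error")
})

test_that("cdna_to_genomic walks exons for coding, intronic and UTR anchors", {
  m <- toy()  # exons [0,10)+[20,30), ATG at 2; coding 2..9 then 20..29
  cases <- list(
    list(cdna_descriptor("coding", 1), 2L),    # c.1 = the A of ATG
    list(cdna_descriptor("coding", 8), 9L),    # last base of exon 1
    list(cdna_descriptor("coding", 9), 20L),   # first base of exon 2
    list(cdna_descriptor("intronic", 8, 1), 10L),
    list(cdna_descriptor("intronic", 9, -1), 19L),
    list(cdna_descriptor("utr5", -1), 1L),
    list(cdna_descriptor("utr5", -2), 0L),
    list(cdna_descriptor("utr3", 1), NA)       # no 3' flank: coordinate error
  )
  for (cs in cases[1:7]) {
    loc <- cdna_to_genomic(m, cs[[1]])
    expect_identical(loc$offset, cs[[2]])
    expect_identical(loc$distance_from_start_codon, cs[[2]] - 2L)
  }
  expect_error(cdna_to_genomic(m, cases[[8]][[1]]),
               class = "g4snp_coordinate_error")
})

test_that("cdna_to_genomic rejects out-of-range and structurally illegal anchors", {
  m <- toy()
  expect_error(cdna_to_genomic(m, cdna_descriptor("coding", 19)),
               class = "g4snp_range_error")           # only 18 coding bases
  expect_error(cdna_to_genomic(m, cdna_descriptor("intronic", 5, 1)),
               class = "g4snp_structure_error")       # c.5 not exon-terminal
  expect_error(cdna_to_genomic(m, cdna_descriptor("intronic", 9, -2000)),
               class = "g4snp_coordinate_error")      # overshoots the intron
  expect_error(cdna_to_genomic(m, cdna_descriptor("intronic", 8, 11)),
               class = "g4snp_coordinate_error")      # lands inside exon 2
  expect_error(cdna_to_genomic(m, cdna_descriptor("intronic", 18, 1)),
               class = "g4snp_coordinate_error")      # '+' off the last exon
  expect_error(cdna_to_genomic(m, cdna_descriptor("utr5", -100)),
               class = "g4snp_coordinate_error")      # past sequence start
})

test_that("genomic_to_cdna classifies every offset and inverts the locator", {
  m <- toy()
  d <- genomic_to_cdna(m, 2L)
  expect_identical(c(d$region, d$anchor), c("coding", 1L))
  d <- genomic_to_cdna(m, 19L)
  expect_identical(list(d$region, d$anchor, d$intron_offset),
                   list("intronic", 9L, -1L))
  d <- genomic_to_cdna(m, 10L)
  expect_identical(list(d$region, d$anchor, d$intron_offset),
                   list("intronic", 8L, 1L))
  d <- genomic_to_cdna(m, 1L)
  expect_identical(c(d$region, d$anchor), c("utr5", -1L))
  expect_error(genomic_to_cdna(m, 30L), class = "g4snp_coordinate_error")

  labels <- oracle_label_all(m)
  for (off in 0:29) {
    d <- genomic_to_cdna(m, off)
    expect_identical(d$region, labels$region[off + 1L])
    expect_identical(d$anchor, labels$anchor[off + 1L])
    expect_identical(d$intron_offset, labels$intron_offset[off + 1L])
    expect_identical(cdna_to_genomic(m, d)$offset, off)
  }
})

test_that("mapping a paper-style intron-acceptor variant lands immediately 5' of its exon", {
  # c.506-1G>A: one base upstream of coding base 506, which must be the
  # first coding base of its exon. Build a model where that holds and check
  # the structural relationship rather than any absolute coordinate.
  set.seed(42)
  exons <- rbind(c(100, 300), c(400, 700), c(800, 1000), c(1100, 1400))
  seq <- random_dna(1500)
  m <- gene_model("CYPLIKE", seq, exons, 130)
  # coding bases: exon1 has 170 (130..299), exon2 300, exon3 200; c.506 is
  # inside exon 3? 170+300 = 470 < 506 <= 670 -> exon 3... c.506 must be
  # exon-first for a -1 offset, so anchor to exon 3's first coding base 471.
  ref <- substr(seq, 800, 800)  # base at offset 799, the last intron base
  alt <- setdiff(c("A", "T"), ref)[[1L]]
  v <- parse_hgvs_cdna(sprintf("c.471-1%s>%s", ref, alt))
  loc <- cdna_to_genomic(m, v)
  expect_identical(loc$offset, 799L)                      # last intron base
  expect_identical(cdna_to_genomic(m, cdna_descriptor("coding", 471))$offset, 800L)
})

test_that("verify_ref_base reports match, mismatch and indeterminate N", {
  m <- gene_model("T", "ATGC", cbind(0, 4), 0)
  v_match <- parse_hgvs_cdna("c.3G>A")
  loc <- cdna_to_genomic(m, v_match)
  expect_identical(verify_ref_base(m, loc, v_match)$status, "match")

  v_mis <- parse_hgvs_cdna("c.3A>T")
  expect_identical(verify_ref_base(m, loc, v_mis)$status, "mismatch")
  expect_error(verify_ref_base(m, loc, v_mis, strict = TRUE),
               class = "g4snp_ref_mismatch_error")

  mn <- gene_model("T", "ATNC", cbind(0, 4), 0)
  expect_identical(verify_ref_base(mn, loc, v_match)$status, "indeterminate")
  expect_identical(verify_ref_base(mn, loc, v_mis)$status, "indeterminate")
})

test_that("coordinate conversion is monotone and agrees with the label oracle on random models", {
  set.seed(101)
  for (rep in 1:8) {
    m <- random_model()
    labels <- oracle_label_all(m)
    # oracle equivalence on a sample of bases
    for (off in sample(nchar(m$sequence), 200L) - 1L) {
      d <- genomic_to_cdna(m, off)
      expect_identical(oracle_offset_of(labels, d), off)
      expect_identical(cdna_to_genomic(m, d)$offset, off)
    }
    # monotone in the coding anchor
    anchors <- sort(sample(length(m$coding_offsets), 20L))
    offs <- vapply(anchors, function(a)
      cdna_to_genomic(m, cdna_descriptor("coding", a))$offset, integer(1))
    expect_false(is.unsorted(offs, strictly = TRUE))
    # monotone in the 5'UTR anchor (more negative = further upstream)
    m_max <- length(m$utr5_offsets) + m$exons[1L, 1L]
    us <- sort(sample(m_max, min(20L, m_max)))
    offs <- vapply(us, function(u)
      cdna_to_genomic(m, cdna_descriptor("utr5", -u))$offset, integer(1))
    expect_false(is.unsorted(rev(offs), strictly = TRUE))
  }
})
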