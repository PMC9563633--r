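mk_regions <- function(starts, width = 21L, seqname = "G") {
  if (length(starts) == 0L) return(g4snp:::empty_g4_regions())
  df <- data.frame(seqname = seqname, start = as.integer(starts),
                   end = as.integer(starts) + width, width = width,
                   strand = "+", sequence = strrep("G", width),
                   score = 1.5, max_window_score = 1.7,
                   stringsAsFactors = FALSE)
  class(df) <- c("g4_regions", "data.frame")
  df
}

flat_model <- function(n = 4000L) gene_model("G", strrep("A", n), cbind(0L, n), 100L)

test_that("G4 distance from the start codon is the signed start difference", {
  m <- flat_model()
  expect_identical(g4_distance_from_start_codon(m, list(start = 100L, end = 130L)), 0L)
  expect_identical(g4_distance_from_start_codon(m, list(start = 40L, end = 70L)), -60L)
  expect_identical(g4_distance_from_start_codon(m, list(start = 250L, end = 280L)), 150L)
  expect_error(g4_distance_from_start_codon(m, list(start = 3990L, end = 4020L)),
               class = "g4snp_coordinate_error")
})

test_that("nearest_g4 takes the minimum start distance and breaks ties upstream", {
  m <- flat_model()
  snp <- 600L  # distance d = 500 from ATG
  g4s <- mk_regions(c(590L, 603L, 700L))  # start distances d-10, d+3, d+100
  ann <- nearest_g4(snp, g4s, m)
  expect_identical(ann$g4$start, 603L)
  expect_identical(ann$distance, 3L)
  expect_identical(ann$relation, "downstream")
  expect_identical(ann$mode, "start_only")

  tie <- mk_regions(c(595L, 605L))  # both 5 away: upstream one wins
  expect_identical(nearest_g4(snp, tie, m)$g4$start, 595L)

  expect_error(nearest_g4(snp, mk_regions(integer(0)), m),
               class = "g4snp_no_regions_error")
})

test_that("interval mode reports overlap as distance 0 and gaps to the nearer edge", {
  m <- flat_model()
  g4s <- mk_regions(c(500L, 1000L))
  inside <- nearest_g4(510L, g4s, m, mode = "interval")
  expect_identical(inside$distance, 0L)
  expect_identical(inside$relation, "overlapping")

  before <- nearest_g4(490L, g4s, m, mode = "interval")
  expect_identical(before$distance, 10L)
  expect_identical(before$relation, "downstream")

  after <- nearest_g4(530L, g4s, m, mode = "interval")
  expect_identical(after$distance, 530L - 520L)  # gap from last base at 520
  expect_identical(after$relation, "upstream")
})

test_that("nearest_g4 matches the brute-force oracle on random configurations", {
  set.seed(19)
  m <- flat_model(10000L)
  for (i in 1:200) {
    k <- sample(1:8, 1L)
    g4s <- mk_regions(sort(sample(0:9900, k)), width = sample(15:40, 1L))
    off <- sample(0:9999, 1L)
    for (mode in c("start_only", "interval")) {
      got <- nearest_g4(off, g4s, m, mode = mode)
      want <- oracle_nearest(off, g4s, mode)
      expect_identical(got$g4$start, g4s$start[[want$index]])
      expect_identical(got$distance, want$distance)
      expect_identical(got$distance == 0L, got$relation == "overlapping")
      if (mode == "interval")
        expect_identical(got$distance == 0L,
                         got$g4$start <= off && off < got$g4$end)
    }
  }
})

test_that("adding a strictly farther region never changes the result", {
  set.seed(23)
  m <- flat_model(10000L)
  for (i in 1:50) {
    g4s <- mk_regions(sort(sample(0:9000, 3L)))
    off <- sample(0:9999, 1L)
    base <- nearest_g4(off, g4s, m)
    far_start <- off + base$distance + sample(100:500, 1L)
    if (far_start + 21L <= 10000L) {
      g4s2 <- rbind(g4s, mk_regions(far_start))
      class(g4s2) <- class(g4s)
      aug <- nearest_g4(off, g4s2, m)
      expect_identical(aug$g4$start, base$g4$start)
      expect_identical(aug$distance, base$distance)
    }
  }
})

test_that("annotate_variants produces one sorted row per variant and checks ref bases", {
  set.seed(29)
  seq <- random_dna(3000)
  m <- gene_model("G", seq, rbind(c(400L, 800L), c(1000L, 1600L)), 430L)
  g4s <- mk_regions(c(200L, 1800L))
  vars <- c("c.300A>T", "c.10A>T", "c.-20C>T")
  # rewrite refs to match the sequence so no warnings fire
  vars <- vapply(vars, function(tx) {
    v <- parse_hgvs_cdna(tx)
    off <- cdna_to_genomic(m, v)$offset
    ref <- substr(seq, off + 1L, off + 1L)
    alt <- setdiff(c("A", "T"), ref)[[1L]]
    sub("[ACGT]>[ACGT]$", paste0(ref, ">", alt), tx)
  }, character(1))
  out <- expect_silent(annotate_variants(m, unname(vars), g4s))
  expect_identical(nrow(out), 3L)
  expect_identical(out$variant, sort(out$variant))  # order-independent output
  expect_true(all(out$ref_check == "match"))
  expect_identical(out$mode, rep("start_only", 3L))

  # a wrong ref base warns but still annotates
  bad <- sub("^(c\\.300.)(.)>(.)$", "\\1", vars[[1]])
  v1 <- parse_hgvs_cdna(vars[[1]])
  wrong_ref <- setdiff(c("A", "C", "G", "T"),
                       c(v1$ref_base, v1$alt_base))[[1L]]
  bad_tx <- sprintf("c.300%s>%s", wrong_ref, v1$alt_base)
  expect_warning(out2 <- annotate_variants(m, bad_tx, g4s),
                 class = "g4snp_ref_mismatch_warning")
  expect_identical(out2$ref_check, "mismatch")
})
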