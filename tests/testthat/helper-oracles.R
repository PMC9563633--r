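# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (per-base loops, exhaustive scans) and share no code
# with the implementation paths they check.

# Label every base of a model by a straight linear scan: walk the exons in
# transcript order counting coding/5'UTR indices, split each intron at its
# midpoint, and extend contiguously into the flanks.
oracle_label_all <- function(model) {
  n <- nchar(model$sequence)
  ex <- model$exons
  sco <- model$start_codon_offset
  region <- character(n); anchor <- integer(n); ioff <- integer(n)

  # exonic bases in transcript order
  tx <- integer(0)
  for (i in seq_len(nrow(ex))) tx <- c(tx, ex[i, 1L]:(ex[i, 2L] - 1L))
  k_atg <- which(tx == sco)
  ci <- 0L
  for (k in k_atg:length(tx)) {
    ci <- ci + 1L
    region[tx[k] + 1L] <- "coding"; anchor[tx[k] + 1L] <- ci
  }
  ui <- 0L
  if (k_atg > 1L) for (k in (k_atg - 1L):1L) {
    ui <- ui + 1L
    region[tx[k] + 1L] <- "utr5"; anchor[tx[k] + 1L] <- -ui
  }
  # upstream flank: contiguous continuation of the 5'UTR count
  if (ex[1L, 1L] > 0L) for (off in (ex[1L, 1L] - 1L):0L) {
    ui <- ui + 1L
    region[off + 1L] <- "utr5"; anchor[off + 1L] <- -ui
  }
  # downstream flank: 3'UTR count from the last exonic base
  last <- ex[nrow(ex), 2L] - 1L
  if (last + 1L < n) for (off in (last + 1L):(n - 1L)) {
    region[off + 1L] <- "utr3"; anchor[off + 1L] <- off - last
  }
  # introns: midpoint split, middle base of an odd intron goes to the + side
  if (nrow(ex) > 1L) for (i in seq_len(nrow(ex) - 1L)) {
    s <- ex[i, 2L]; e <- ex[i + 1L, 1L]
    for (off in s:(e - 1L)) {
      if ((off - s) < ceiling((e - s) / 2)) {
        region[off + 1L] <- "intronic"
        anchor[off + 1L] <- anchor[s]       # label of preceding exon's last base
        ioff[off + 1L] <- off - s + 1L
      } else {
        region[off + 1L] <- "intronic"
        anchor[off + 1L] <- anchor[e + 1L]  # label of following exon's first base
        ioff[off + 1L] <- off - e
      }
    }
  }
  data.frame(offset = 0:(n - 1L), region = region, anchor = anchor,
             intron_offset = ioff, stringsAsFactors = FALSE)
}

# Oracle locator: look a descriptor up in the exhaustive base-label table.
oracle_offset_of <- function(labels, desc) {
  hit <- labels$region == desc$region & labels$anchor == desc$anchor &
    labels$intron_offset == desc$intron_offset
  stopifnot(sum(hit) == 1L)
  labels$offset[hit]
}

# Direct run-length scoring by a character-by-character scan.
oracle_base_scores <- function(s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  n <- length(ch); out <- integer(n); i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && ch[j + 1L] == ch[i]) j <- j + 1L
    len <- j - i + 1L
    out[i:j] <- if (ch[i] == "G") min(len, 4L) else if (ch[i] == "C") -min(len, 4L) else 0L
    i <- j + 1L
  }
  out
}

# Naive per-window summation.
oracle_window_means <- function(scores, window) {
  n <- length(scores)
  if (n < window) return(numeric(0))
  vapply(seq_len(n - window + 1L),
         function(i) mean(scores[i:(i + window - 1L)]), numeric(1))
}

# Brute-force nearest region with the smaller-start tie rule.
oracle_nearest <- function(off, g4s, mode) {
  best <- NA_integer_; bestd <- Inf
  for (i in seq_len(nrow(g4s))) {
    s <- g4s$start[[i]]; e <- g4s$end[[i]]
    d <- if (mode == "start_only") abs(off - s)
         else if (s <= off && off < e) 0L
         else if (off < s) s - off
         else off - (e - 1L)
    if (d < bestd || (d == bestd && s < g4s$start[[best]])) { best <- i; bestd <- d }
  }
  list(index = best, distance = as.integer(bestd))
}

# A random gene model drawn from the ambient RNG stream.
random_model <- function(name = "RND") {
  n_exons <- sample(1:5, 1L)
  utr5 <- sample(5:25, 1L)
  simulate_gene(n_exons = n_exons,
                exon_len_range = c(utr5 + 10L, 120L),
                intron_len_range = c(30L, 150L),
                flank_len = sample(60:300, 1L),
                gc_content = stats::runif(1L, 0.3, 0.6),
                utr5_len = utr5, name = name)
}

# A random *canonical* legal descriptor for a model (canonical = intronic
# offsets on the near side of the midpoint, the form genomic_to_cdna emits).
random_descriptor <- function(model) {
  ex <- model$exons; n <- nchar(model$sequence)
  regions <- c("coding", "utr5")
  if (ex[nrow(ex), 2L] < n) regions <- c(regions, "utr3")
  if (nrow(ex) > 1L) regions <- c(regions, "intronic")
  region <- sample(regions, 1L)
  if (region == "coding")
    return(cdna_descriptor("coding", sample(length(model$coding_offsets), 1L)))
  if (region == "utr5")
    return(cdna_descriptor("utr5",
      -sample(length(model$utr5_offsets) + ex[1L, 1L], 1L)))
  if (region == "utr3")
    return(cdna_descriptor("utr3", sample(n - ex[nrow(ex), 2L], 1L)))
  k <- sample(nrow(ex) - 1L, 1L)
  L <- ex[k + 1L, 1L] - ex[k, 2L]
  if (stats::runif(1L) < 0.5) {
    anc <- match(ex[k, 2L] - 1L, model$coding_offsets)
    cdna_descriptor("intronic", anc, sample(ceiling(L / 2), 1L))
  } else {
    anc <- match(ex[k + 1L, 1L], model$coding_offsets)
    cdna_descriptor("intronic", anc, -sample(floor(L / 2), 1L))
  }
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

expect_same_descriptor <- function(got, want) {
  testthat::expect_identical(
    list(got$region, got$anchor, got$intron_offset),
    list(want$region, want$anchor, want$intron_offset))
}

# Random region tables for dialect round-trip tests.
random_g4_tables <- function(n_genes) {
  tabs <- list()
  for (g in seq_len(n_genes)) {
    k <- sample(0:5, 1L)
    starts <- sort(sample(1:5000, k))
    rows <- lapply(starts, function(s) {
      w <- sample(20:40, 1L)
      data.frame(seqname = sprintf("G%d", g), start = s, end = s + w,
                 width = w, strand = "+",
                 sequence = random_dna(w),
                 score = round(stats::runif(1L, -2.5, 2.5), 6L),
                 max_window_score = NA_real_, stringsAsFactors = FALSE)
    })
    df <- if (k == 0L) g4snp:::empty_g4_regions() else do.call(rbind, rows)
    df$strand <- ifelse(df$score >= 0, "+", "-")
    class(df) <- c("g4_regions", "data.frame")
    tabs[[sprintf("G%d", g)]] <- df
  }
  tabs
}
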