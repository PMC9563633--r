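#' Per-base G4Hunter-style scores
#'
#' Each base in a maximal run of n consecutive G's scores `+min(n, 4)`; each
#' base in a maximal run of n consecutive C's scores `-min(n, 4)`; A, T and
#' N score 0 (N breaks G/C runs). The score rewards both G-richness and
#' G-skewness: runs of G on the given strand push the local mean up, runs of
#' C (i.e. G on the opposite strand) push it down.
#'
#' @param sequence Nucleotide string over \{A,C,G,T,N\}, any case.
#' @return Integer vector, one score per base.
#' @examples
#' base_scores("GGGTTAGGG")  # 3 3 3 0 0 0 3 3 3
#' @export
base_scores <- function(sequence) {
  sequence <- toupper(paste(sequence, collapse = ""))
  if (grepl("[^ACGTN]", sequence))
    g4_abort("g4snp_alphabet_error", "sequence contains characters outside {A,C,G,T,N}")
  if (!nzchar(sequence)) return(integer(0))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  r <- rle(chars)
  run_score <- ifelse(r$values == "G", pmin(r$lengths, 4L),
               ifelse(r$values == "C", -pmin(r$lengths, 4L), 0L))
  rep(as.integer(run_score), r$lengths)
}

#' Sliding-window means of per-base scores
#'
#' The arithmetic mean of `scores[i .. i + window - 1]` for every window
#' start; exactly `length(scores) - window + 1` values. A sequence shorter
#' than the window yields an empty result with a warning, not an error.
#'
#' @param scores Integer vector from [base_scores()].
#' @param window Window width in bases (default 25, the conventional
#'   G4Hunter default).
#' @return Numeric vector of window means.
#' @export
window_scores <- function(scores, window = 25L) {
  window <- as.integer(window)
  if (window < 1L)
    g4_abort("g4snp_config_error", "window must be >= 1")
  n <- length(scores)
  if (n < window) {
    g4_warn("g4snp_short_sequence_warning",
            sprintf("sequence (%d) shorter than window (%d): no windows", n, window))
    return(numeric(0))
  }
  cs <- c(0, cumsum(as.numeric(scores)))
  (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
}

#' Predict G-quadruplex-forming regions
#'
#' Scores the sequence with [base_scores()], slides a window of means, keeps
#' windows whose |mean| reaches the threshold, and merges same-sign windows
#' that overlap or abut into maximal regions. A region's `score` is the mean
#' of the per-base scores over the merged span; `max_window_score` is the
#' most extreme window mean inside it. Positive scores mean the given strand
#' is G-rich; negative scores mean the opposite strand is (the sequence is
#' C-rich here). Opposite-sign windows never merge.
#'
#' @param seqname Name for the sequence (gene name).
#' @param sequence Nucleotide string.
#' @param window Window width (default 25).
#' @param threshold Minimum |window mean| to call a hit (default 1.2, the
#'   conventional G4Hunter default).
#' @return A data frame of class `g4_regions` sorted by start, with columns
#'   `seqname`, `start` (0-based), `end` (exclusive), `width`, `strand`
#'   (`"+"` G-rich / `"-"` C-rich), `sequence`, `score`, `max_window_score`.
#'   Zero rows when nothing passes the threshold.
#' @examples
#' find_g4_regions("toy", paste0(strrep("AT", 15), "GGGTTAGGGTTAGGGTTAGGG",
#'                               strrep("AT", 15)), window = 21, threshold = 1)
#' @export
find_g4_regions <- function(seqname, sequence, window = 25L, threshold = 1.2) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    g4_abort("g4snp_config_error", "threshold must be a single positive number")
  sequence <- toupper(paste(sequence, collapse = ""))
  sc <- base_scores(sequence)
  wm <- window_scores(sc, window)
  if (length(wm) == 0L) return(empty_g4_regions())

  one_sign <- function(idx, positive) {
    if (length(idx) == 0L) return(NULL)
    merged <- IRanges::reduce(IRanges::IRanges(start = idx, width = window))
    st <- IRanges::start(merged); en <- IRanges::end(merged)  # 1-based inclusive
    out <- lapply(seq_along(st), function(j) {
      span <- st[[j]]:en[[j]]
      w_in <- st[[j]]:(en[[j]] - window + 1L)  # window starts fully inside
      list(start = st[[j]] - 1L, end = en[[j]],
           score = mean(sc[span]),
           max_window_score = if (positive) max(wm[w_in]) else min(wm[w_in]))
    })
    out
  }

  hits <- c(one_sign(which(wm >= threshold), TRUE),
            one_sign(which(wm <= -threshold), FALSE))
  if (length(hits) == 0L) return(empty_g4_regions())

  df <- data.frame(
    seqname = seqname,
    start = vapply(hits, `[[`, integer(1), "start"),
    end = vapply(hits, `[[`, integer(1), "end"),
    stringsAsFactors = FALSE
  )
  df$width <- df$end - df$start
  df$score <- vapply(hits, `[[`, numeric(1), "score")
  df$strand <- ifelse(df$score >= 0, "+", "-")
  df$sequence <- substring(sequence, df$start + 1L, df$end)
  df$max_window_score <- vapply(hits, `[[`, numeric(1), "max_window_score")
  df <- df[order(df$start, df$end), c("seqname", "start", "end", "width",
                                      "strand", "sequence", "score",
                                      "max_window_score")]
  rownames(df) <- NULL
  class(df) <- c("g4_regions", "data.frame")
  df
}

empty_g4_regions <- function() {
  df <- data.frame(seqname = character(0), start = integer(0), end = integer(0),
                   width = integer(0), strand = character(0),
                   sequence = character(0), score = numeric(0),
                   max_window_score = numeric(0), stringsAsFactors = FALSE)
  class(df) <- c("g4_regions", "data.frame")
  df
}

reverse_complement <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}
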