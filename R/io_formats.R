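# Readers and writers for the tool's plain-text dialects, plus standard
# FASTA/BED/TSV. Two dialects come from the original workflow:
#   * the G4 table ("modified G4Hunter" layout): per-gene blocks, each
#     introduced by a marker line `NAME >`, followed by whitespace-separated
#     rows seqnames/start/end/sequence/score (start 1-based inclusive in the
#     file, converted to 0-based internally; an `end` column may be absent,
#     in which case it is derived from the sequence length; unknown trailing
#     columns are ignored);
#   * the SNP results file: per-gene blocks with a bare gene-name line
#     followed by `variant<TAB>distance` lines (distance = signed bp from
#     the start codon, as printed by the locator).
# All readers reject malformed rows with the line number rather than
# silently skipping them.

num_to_text <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else as.character(v)
  }, character(1))
}

#' Read a gene sequence from a FASTA file
#'
#' Standard (multi-line) FASTA via Biostrings. The first record is used
#' unless `record` names another; the header text after `>` becomes the
#' default gene name.
#'
#' @param path FASTA file path.
#' @param record Optional record name to select.
#' @return A list with fields `name` and `sequence` (upper-cased).
#' @export
read_gene_fasta <- function(path, record = NULL) {
  if (!file.exists(path))
    g4_abort("g4snp_io_error", sprintf("file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L)
    g4_abort("g4snp_format_error", sprintf("no FASTA records in %s", path))
  idx <- 1L
  if (!is.null(record)) {
    idx <- match(record, names(set))
    if (is.na(idx))
      g4_abort("g4snp_format_error",
               sprintf("no FASTA record named '%s' in %s", record, path))
  }
  list(name = strsplit(names(set)[[idx]], "\\s+")[[1L]][[1L]],
       sequence = toupper(as.character(set[[idx]])))
}

#' Write a gene model's sequence as FASTA
#' @param model A [gene_model()].
#' @param path Output path.
#' @export
write_gene_fasta <- function(model, path) {
  set <- Biostrings::DNAStringSet(model$sequence)
  names(set) <- model$gene_name
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a gene-structure sidecar (TSV or JSON)
#'
#' TSV form: lines `exon <start> <end>` (0-based half-open) plus one line
#' `start_codon <offset>`. JSON form: object with keys `exons` (list of
#' [start, end] pairs) and `start_codon_offset`. Detected by the first
#' non-whitespace character.
#'
#' @param path Sidecar path.
#' @return A list with `exons` (2-column integer matrix) and
#'   `start_codon_offset`.
#' @export
read_gene_structure <- function(path) {
  if (!file.exists(path))
    g4_abort("g4snp_io_error", sprintf("file not found: %s", path))
  txt <- readLines(path, warn = FALSE)
  first <- sub("^\\s*", "", paste(txt, collapse = "\n"))
  if (startsWith(first, "{")) {
    obj <- jsonlite::fromJSON(paste(txt, collapse = "\n"))
    ex <- obj$exons
    if (is.list(ex)) ex <- do.call(rbind, ex)
    ex <- matrix(as.integer(ex), ncol = 2L)
    return(list(exons = ex, start_codon_offset = as.integer(obj$start_codon_offset)))
  }
  exons <- list(); sco <- NULL
  for (i in seq_along(txt)) {
    line <- trimws(txt[[i]])
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "[[:space:]]+")[[1L]]
    if (f[[1L]] == "exon" && length(f) >= 3L) {
      s <- suppressWarnings(as.integer(f[[2L]])); e <- suppressWarnings(as.integer(f[[3L]]))
      if (is.na(s) || is.na(e))
        g4_abort("g4snp_format_error", sprintf("%s line %d: bad exon bounds", path, i))
      exons[[length(exons) + 1L]] <- c(s, e)
    } else if (f[[1L]] == "start_codon" && length(f) >= 2L) {
      sco <- suppressWarnings(as.integer(f[[2L]]))
      if (is.na(sco))
        g4_abort("g4snp_format_error", sprintf("%s line %d: bad start_codon offset", path, i))
    } else {
      g4_abort("g4snp_format_error",
               sprintf("%s line %d: expected 'exon <start> <end>' or 'start_codon <offset>'", path, i))
    }
  }
  if (length(exons) == 0L || is.null(sco))
    g4_abort("g4snp_format_error",
             sprintf("%s: sidecar needs at least one exon line and a start_codon line", path))
  list(exons = do.call(rbind, exons), start_codon_offset = sco)
}

#' Write a gene-structure sidecar
#' @param model A [gene_model()].
#' @param path Output path; `.json` extension selects the JSON form.
#' @export
write_gene_structure <- function(model, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(exons = unname(apply(model$exons, 1L, function(r) as.integer(r),
                                     simplify = FALSE)),
                start_codon_offset = model$start_codon_offset)
    jsonlite::write_json(obj, path, auto_unbox = TRUE)
  } else {
    lines <- c(sprintf("exon\t%d\t%d", model$exons[, "start"], model$exons[, "end"]),
               sprintf("start_codon\t%d", model$start_codon_offset))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a load-gene-model convenience pair
#'
#' Reads `<fasta>` and its structure sidecar and builds the [gene_model()].
#' @param fasta_path FASTA path.
#' @param structure_path Sidecar path; defaults to the FASTA path with its
#'   extension replaced by `.structure.tsv`.
#' @param name Optional gene-name override (default: FASTA header).
#' @export
read_gene_model <- function(fasta_path,
                            structure_path = sub("\\.[^.]+$", ".structure.tsv", fasta_path),
                            name = NULL) {
  fa <- read_gene_fasta(fasta_path)
  st <- read_gene_structure(structure_path)
  gene_model(if (is.null(name)) fa$name else name, fa$sequence,
             st$exons, st$start_codon_offset)
}

is_marker_line <- function(line) grepl("^\\S+\\s*>\\s*$", line)

#' Read a per-gene G4 table (modified-G4Hunter dialect)
#'
#' @param path Table path.
#' @return Named list (one entry per gene block) of `g4_regions` data
#'   frames, starts converted to 0-based, sequences upper-cased.
#' @export
read_g4_table <- function(path) {
  if (!file.exists(path))
    g4_abort("g4snp_io_error", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (all(!nzchar(trimws(lines))))
    g4_abort("g4snp_format_error", sprintf("%s: empty G4 table", path))
  out <- list()
  gene <- NULL
  rows <- list()
  flush_gene <- function() {
    if (is.null(gene)) return()
    df <- if (length(rows) == 0L) empty_g4_regions() else {
      d <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
      d$width <- d$end - d$start
      d$strand <- ifelse(d$score >= 0, "+", "-")
      d$max_window_score <- NA_real_
      d <- d[order(d$start, d$end),
             c("seqname", "start", "end", "width", "strand", "sequence",
               "score", "max_window_score")]
      rownames(d) <- NULL
      class(d) <- c("g4_regions", "data.frame")
      d
    }
    out[[gene]] <<- df
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    if (is_marker_line(line)) {
      flush_gene()
      gene <- sub("\\s*>\\s*$", "", line)
      rows <- list()
      next
    }
    f <- strsplit(line, "[[:space:]]+")[[1L]]
    if (identical(tolower(f[[1L]]), "seqnames")) next  # optional header row
    if (is.null(gene))
      g4_abort("g4snp_format_error", sprintf(
        "%s line %d: data row before any 'NAME >' gene marker", path, i))
    if (length(f) < 4L)
      g4_abort("g4snp_format_error", sprintf(
        "%s line %d: expected at least seqnames/start/sequence/score", path, i))
    start1 <- suppressWarnings(as.integer(f[[2L]]))
    if (is.na(start1) || start1 < 1L)
      g4_abort("g4snp_format_error", sprintf(
        "%s line %d: start '%s' is not a positive integer", path, i, f[[2L]]))
    has_end <- length(f) >= 5L && grepl("^[0-9]+$", f[[3L]])
    seq_col <- if (has_end) f[[4L]] else f[[3L]]
    score_col <- if (has_end) f[[5L]] else f[[4L]]
    score <- suppressWarnings(as.numeric(score_col))
    if (is.na(score))
      g4_abort("g4snp_format_error", sprintf(
        "%s line %d: score '%s' is not a number", path, i, score_col))
    seq_u <- toupper(seq_col)
    end0 <- if (has_end) as.integer(f[[3L]]) else start1 - 1L + nchar(seq_u)
    rows[[length(rows) + 1L]] <- list(seqname = f[[1L]], start = start1 - 1L,
                                      end = end0, sequence = seq_u, score = score)
  }
  flush_gene()
  if (length(out) == 0L)
    g4_abort("g4snp_format_error", sprintf("%s: no gene blocks found", path))
  out
}

#' Write a per-gene G4 table (modified-G4Hunter dialect)
#'
#' Canonical layout: for each gene a `NAME >` marker line, a header row, and
#' tab-separated rows `seqnames start end sequence score` with 1-based
#' inclusive starts. [read_g4_table()] of the output reproduces the input
#' structures; write-read-write is byte-identical.
#'
#' @param tables Named list of `g4_regions` data frames (names = genes).
#' @param path Output path.
#' @export
write_g4_table <- function(tables, path) {
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    g4_abort("g4snp_format_error", "tables must be a named list (names = gene names)")
  lines <- character(0)
  for (gene in names(tables)) {
    df <- tables[[gene]]
    lines <- c(lines, sprintf("%s >", gene),
               "seqnames\tstart\tend\tsequence\tscore")
    if (nrow(df) > 0L) {
      df <- df[order(df$start, df$end), , drop = FALSE]
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t%s",
                                df$seqname, df$start + 1L, df$end,
                                df$sequence, num_to_text(df$score)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a SNP-locator results file
#'
#' @param path Results-file path.
#' @return Data frame with columns `gene`, `variant`, `distance` (signed bp
#'   from the start codon).
#' @export
read_snp_results <- function(path) {
  if (!file.exists(path))
    g4_abort("g4snp_io_error", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  gene <- NULL
  recs <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    f <- strsplit(line, "[[:space:]]+")[[1L]]
    if (length(f) == 1L) { gene <- f[[1L]]; next }
    if (length(f) != 2L)
      g4_abort("g4snp_format_error", sprintf(
        "%s line %d: expected 'gene' or 'variant distance'", path, i))
    if (is.null(gene))
      g4_abort("g4snp_format_error", sprintf(
        "%s line %d: variant line before any gene-name line", path, i))
    d <- suppressWarnings(as.integer(f[[2L]]))
    if (is.na(d) || !grepl("^[+-]?[0-9]+$", f[[2L]]))
      g4_abort("g4snp_format_error", sprintf(
        "%s line %d: distance '%s' is not an integer", path, i, f[[2L]]))
    recs[[length(recs) + 1L]] <- data.frame(gene = gene, variant = f[[1L]],
                                            distance = d, stringsAsFactors = FALSE)
  }
  if (length(recs) == 0L)
    return(data.frame(gene = character(0), variant = character(0),
                      distance = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Write a SNP-locator results file
#'
#' One gene-name line per gene block, then `variant<TAB>distance` lines.
#' Write-read-write is byte-identical.
#'
#' @param records Data frame with columns `gene`, `variant`, `distance`.
#' @param path Output path.
#' @export
write_snp_results <- function(records, path) {
  stopifnot(all(c("gene", "variant", "distance") %in% names(records)))
  lines <- character(0)
  for (gene in unique(records$gene)) {
    sub <- records[records$gene == gene, , drop = FALSE]
    lines <- c(lines, gene, sprintf("%s\t%d", sub$variant, sub$distance))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write G4 regions as BED6
#'
#' 0-based half-open; the BED score column is `|score| * 250` clamped to
#' 1000 (a G4Hunter-style score of 4 maps to 1000); strand `+` for G-rich,
#' `-` for C-rich regions.
#'
#' @param g4s A `g4_regions` data frame.
#' @param path Output path.
#' @export
write_bed6 <- function(g4s, path) {
  if (nrow(g4s) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   g4s$seqname, g4s$start, g4s$end,
                   sprintf("G4_%d", seq_len(nrow(g4s))),
                   pmin(1000L, as.integer(round(abs(g4s$score) * 250))),
                   g4s$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write an annotation table as TSV
#' @param annotations Data frame from [annotate_variants()] or the CLI.
#' @param path Output path ("" for stdout).
#' @export
write_annotation_tsv <- function(annotations, path = "") {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
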