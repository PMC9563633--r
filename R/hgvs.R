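#' Parse an HGVS cDNA substitution
#'
#' Accepts the five single-nucleotide substitution forms of HGVS cDNA
#' notation: coding `c.100A>T`, intronic `c.88+2T>C` / `c.506-1G>A`, 5'UTR
#' `c.-45C>T`, and 3'UTR `c.*12G>A`. An optional leading transcript
#' identifier (`NM_000000.0:`) is stripped; whitespace is tolerated; base
#' case is normalized to upper. Everything else is rejected loudly:
#' deletions, insertions, duplications and delins raise an
#' unsupported-variant error naming the operator, protein-level (`p.`) and
#' genomic-level (`g.`) descriptions raise a wrong-level error, and other
#' malformed strings raise a parse error.
#'
#' Whether a `+`/`-` intronic offset is legal for its anchor (it must attach
#' to an exon-terminal coding base) depends on the gene model and is checked
#' in [cdna_to_genomic()], not here.
#'
#' @param text One HGVS cDNA substitution string.
#' @return A list of class `c("hgvs_variant", "cdna_descriptor")` with fields
#'   `raw`, `region`, `anchor`, `intron_offset`, `ref_base`, `alt_base`.
#' @examples
#' parse_hgvs_cdna("c.506-1G>A")
#' parse_hgvs_cdna("NM_000106.6:c.100A>T")$region
#' @export
parse_hgvs_cdna <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    g4_abort("g4snp_parse_error", "variant must be a single string")
  raw <- text
  s <- gsub("[[:space:]]+", "", text)
  s <- sub("^[A-Za-z][A-Za-z0-9_.]*:", "", s)  # optional transcript id

  if (grepl("^[pg]\\.", s))
    g4_abort("g4snp_wrong_level_error", sprintf(
      "'%s' is a %s-level description; this tool takes cDNA-level (c.) variants",
      raw, substr(s, 1L, 1L)))
  if (!grepl("^c\\.", s))
    g4_abort("g4snp_parse_error",
             sprintf("cannot parse '%s': expected a 'c.' prefix", raw))
  body <- substr(s, 3L, nchar(s))

  for (op in c("delins", "del", "ins", "dup", "inv")) {
    if (grepl(op, body, ignore.case = TRUE))
      g4_abort("g4snp_unsupported_variant_error", sprintf(
        "'%s' uses the '%s' operator; only single-nucleotide substitutions are supported",
        raw, op))
  }
  if (grepl("_", body, fixed = TRUE))
    g4_abort("g4snp_unsupported_variant_error", sprintf(
      "'%s' describes a range ('_'); only single-nucleotide substitutions are supported", raw))

  pat <- "^(\\*|-)?([0-9]+)([+-][0-9]+)?([ACGTacgt])>([ACGTacgt])$"
  m <- regmatches(body, regexec(pat, body))[[1L]]
  if (length(m) == 0L)
    g4_abort("g4snp_parse_error",
             sprintf("cannot parse '%s': offending token '%s'", raw, body))
  prefix <- m[[2L]]; num <- as.integer(m[[3L]]); offtok <- m[[4L]]
  ref <- toupper(m[[5L]]); alt <- toupper(m[[6L]])

  if (ref == alt)
    g4_abort("g4snp_parse_error", sprintf(
      "'%s' is not a substitution: reference and alternate base are both %s", raw, ref))
  if (num == 0L)
    g4_abort("g4snp_parse_error", sprintf("'%s': HGVS positions are 1-based, 0 is not legal", raw))

  ioff <- if (nzchar(offtok)) as.integer(offtok) else 0L
  if (ioff != 0L && nzchar(prefix))
    g4_abort("g4snp_unsupported_variant_error", sprintf(
      "'%s': intronic offsets on UTR anchors are not supported", raw))

  region <- if (ioff != 0L) "intronic"
            else if (prefix == "-") "utr5"
            else if (prefix == "*") "utr3"
            else "coding"
  anchor <- if (prefix == "-") -num else num

  structure(
    list(raw = raw, region = region, anchor = anchor, intron_offset = ioff,
         ref_base = ref, alt_base = alt),
    class = c("hgvs_variant", "cdna_descriptor")
  )
}

#' Format a variant or descriptor back to canonical HGVS cDNA text
#'
#' The canonical string re-parses to an identical structure. For a bare
#' [cdna_descriptor()] only the position part (`c.506-1`) is produced.
#'
#' @param x An `hgvs_variant` or `cdna_descriptor`.
#' @return A single string.
#' @export
format_hgvs <- function(x) {
  pos <- switch(x$region,
    coding = sprintf("%d", x$anchor),
    utr5 = sprintf("-%d", -x$anchor),
    utr3 = sprintf("*%d", x$anchor),
    intronic = {
      base <- if (x$anchor >= 1L) sprintf("%d", x$anchor) else sprintf("-%d", -x$anchor)
      sprintf("%s%+d", base, x$intron_offset)
    }
  )
  if (!is.null(x$ref_base))
    sprintf("c.%s%s>%s", pos, x$ref_base, x$alt_base)
  else
    sprintf("c.%s", pos)
}

#' @export
print.hgvs_variant <- function(x, ...) {
  cat(sprintf("<hgvs_variant> %s  [%s, anchor %d%s, %s>%s]\n",
              format_hgvs(x), x$region, x$anchor,
              if (x$intron_offset != 0L) sprintf("%+d", x$intron_offset) else "",
              x$ref_base, x$alt_base))
  invisible(x)
}

#' Read a plain-text variants file
#'
#' One variant per line, optionally preceded by a gene name and a tab
#' (`gene<TAB>c.100A>T`). Blank lines and `#` comment lines are skipped.
#'
#' @param path File path.
#' @return A data frame with columns `gene` (NA when absent) and `variant`.
#' @export
read_variants_file <- function(path) {
  if (!file.exists(path))
    g4_abort("g4snp_io_error", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  gene <- rep(NA_character_, length(lines))
  variant <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "\t")[[1L]]
    if (length(f) >= 2L) {
      gene[[i]] <- f[[1L]]; variant[[i]] <- f[[2L]]
    } else {
      variant[[i]] <- f[[1L]]
    }
  }
  data.frame(gene = gene, variant = variant, stringsAsFactors = FALSE)
}
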