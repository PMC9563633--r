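#' Distance of a G4 region's start from the start codon
#'
#' Signed, on the same convention as [cdna_to_genomic()]: `g4_start -
#' start_codon_offset`, negative when the region starts upstream of the ATG.
#'
#' @param model A [gene_model()].
#' @param g4 A one-row `g4_regions` data frame, or a list/row with fields
#'   `start` and `end`.
#' @return Signed integer distance.
#' @export
g4_distance_from_start_codon <- function(model, g4) {
  stopifnot(inherits(model, "gene_model"))
  n <- nchar(model$sequence)
  start <- as.integer(g4$start); end <- as.integer(g4$end)
  if (start < 0L || end > n || start >= end)
    g4_abort("g4snp_coordinate_error", sprintf(
      "G4 interval [%d, %d) lies outside the %d bp sequence", start, end, n))
  unname(start - model$start_codon_offset)
}

#' Find the overlapping or nearest G4 region for a located variant
#'
#' Two distance modes. `start_only` reproduces the published procedure:
#' every G4's start is expressed as a distance from the start codon, the
#' absolute difference to the variant's distance is computed, and the
#' minimum is taken -- so the distance is `|snp_offset - g4_start|`.
#' `interval` treats each region as an interval: distance 0 with relation
#' `overlapping` when the variant lies inside `[start, end)`, otherwise the
#' gap in bases to the nearer region edge. Ties are broken by smaller
#' genomic start, so the output is deterministic.
#'
#' @param snp A `genomic_location` from [cdna_to_genomic()], or a bare
#'   0-based offset.
#' @param g4s A `g4_regions` data frame (from [find_g4_regions()] or
#'   [read_g4_table()]); must be non-empty.
#' @param model The [gene_model()] the coordinates live on.
#' @param mode `"start_only"` (default) or `"interval"`.
#' @param variant Optional parsed variant, carried into the annotation.
#' @return A list of class `g4_annotation`: `gene_name`, `variant`,
#'   `snp_location`, `g4` (the chosen one-row region), `distance`
#'   (non-negative integer), `relation` (`"overlapping"`, `"upstream"`,
#'   `"downstream"` -- the G4 relative to the SNP), `mode`.
#' @export
nearest_g4 <- function(snp, g4s, model, mode = c("start_only", "interval"),
                       variant = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "gene_model"))
  if (is.numeric(snp))
    snp <- structure(list(offset = as.integer(snp),
                          distance_from_start_codon =
                            as.integer(snp) - model$start_codon_offset),
                     class = "genomic_location")
  if (is.null(g4s) || nrow(g4s) == 0L)
    g4_abort("g4snp_no_regions_error",
             sprintf("no G4 regions supplied for '%s' (distinct from 'no overlap')",
                     model$gene_name))
  off <- snp$offset

  if (mode == "start_only") {
    d <- abs(off - g4s$start)
  } else {
    inside <- g4s$start <= off & off < g4s$end
    d <- ifelse(inside, 0L,
         ifelse(off < g4s$start, g4s$start - off, off - (g4s$end - 1L)))
  }
  ord <- order(d, g4s$start)
  best <- ord[[1L]]
  dist <- as.integer(d[[best]])
  relation <- if (dist == 0L) "overlapping"
              else if (g4s$start[[best]] > off) "downstream"
              else "upstream"

  structure(
    list(gene_name = model$gene_name, variant = variant, snp_location = snp,
         g4 = g4s[best, , drop = FALSE], distance = dist,
         relation = relation, mode = mode),
    class = "g4_annotation"
  )
}

#' @export
print.g4_annotation <- function(x, ...) {
  v <- if (!is.null(x$variant)) format_hgvs(x$variant) else "<offset>"
  cat(sprintf(
    "<g4_annotation> %s %s @ offset %d (%+d from ATG): %s G4 [%d, %d) score %.3f, distance %d (%s mode)\n",
    x$gene_name, v, x$snp_location$offset,
    x$snp_location$distance_from_start_codon, x$relation,
    x$g4$start, x$g4$end, x$g4$score, x$distance, x$mode))
  invisible(x)
}

#' Annotate a batch of variants with their nearest G4 regions
#'
#' Parses, locates and annotates each variant against one gene model and one
#' region set. Output rows are sorted by variant text so batch results are
#' independent of input order.
#'
#' @param model A [gene_model()].
#' @param variants Character vector of HGVS cDNA strings, or a list of
#'   parsed variants.
#' @param g4s A non-empty `g4_regions` data frame.
#' @param mode Distance mode, see [nearest_g4()].
#' @param strict_ref Passed to [verify_ref_base()]; lenient by default, with
#'   a warning on mismatch.
#' @return Data frame with columns `gene`, `variant`, `snp_offset`,
#'   `snp_distance_from_ATG`, `g4_start`, `g4_end`, `g4_score`, `distance`,
#'   `relation`, `mode`, `ref_check`.
#' @export
annotate_variants <- function(model, variants, g4s,
                              mode = c("start_only", "interval"),
                              strict_ref = FALSE) {
  mode <- match.arg(mode)
  if (is.character(variants)) variants <- lapply(variants, parse_hgvs_cdna)
  rows <- lapply(variants, function(v) {
    loc <- cdna_to_genomic(model, v)
    chk <- verify_ref_base(model, loc, v, strict = strict_ref)
    if (chk$status == "mismatch")
      g4_warn("g4snp_ref_mismatch_warning", sprintf(
        "%s %s: reference base %s does not match sequence base %s at offset %d",
        model$gene_name, format_hgvs(v), chk$expected, chk$observed, chk$offset))
    ann <- nearest_g4(loc, g4s, model, mode = mode, variant = v)
    data.frame(
      gene = model$gene_name, variant = format_hgvs(v),
      snp_offset = loc$offset,
      snp_distance_from_ATG = loc$distance_from_start_codon,
      g4_start = ann$g4$start, g4_end = ann$g4$end, g4_score = ann$g4$score,
      distance = ann$distance, relation = ann$relation, mode = ann$mode,
      ref_check = chk$status, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$variant), , drop = FALSE]
  rownames(out) <- NULL
  out
}
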