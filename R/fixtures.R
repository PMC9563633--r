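# Synthetic-data generator: random multi-exon gene models with planted
# G-quadruplex motifs and planted variants carrying ground-truth genomic
# positions, so the whole locate -> scan -> annotate pipeline is testable
# with no external downloads.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

random_bases <- function(n, gc_content) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc_content) / 2, gc_content / 2,
                  gc_content / 2, (1 - gc_content) / 2))
}

#' Simulate a random multi-exon gene model
#'
#' Background sequence is i.i.d. with the requested GC content; exon and
#' intron lengths are drawn uniformly from their ranges; the gene is padded
#' by `flank_len` bases on both sides (the 5' flank is what upstream/
#' promoter variants land in); the start codon is placed `utr5_len` bases
#' into exon 1 and a literal ATG is written there. Reproducible given
#' `seed`. Defaults emulate a compact human gene: 4 exons of 80-200 bp,
#' introns of 60-300 bp, 400 bp flanks, 40% GC, a 30 bp exonic 5'UTR.
#'
#' @param n_exons Number of exons (>= 1).
#' @param exon_len_range,intron_len_range Length ranges (min, max), bp.
#' @param flank_len Flank padding either side of the gene, bp.
#' @param gc_content Background GC fraction in (0, 1).
#' @param utr5_len Bases of exon 1 upstream of the ATG.
#' @param seed Optional integer seed (global RNG state is restored).
#' @param name Gene name.
#' @return A validated [gene_model()].
#' @export
simulate_gene <- function(n_exons = 4L, exon_len_range = c(80L, 200L),
                          intron_len_range = c(60L, 300L), flank_len = 400L,
                          gc_content = 0.4, utr5_len = 30L, seed = NULL,
                          name = "SYNTH1") {
  if (n_exons < 1L || any(exon_len_range < 1L) || any(intron_len_range < 1L) ||
      flank_len < 0L || gc_content <= 0 || gc_content >= 1)
    g4_abort("g4snp_config_error", "invalid simulation geometry")
  if (exon_len_range[[1L]] < utr5_len + 3L)
    g4_abort("g4snp_config_error", sprintf(
      "exon 1 (>= %d bp) cannot hold a %d bp 5'UTR plus the ATG",
      exon_len_range[[1L]], utr5_len))
  with_seed(seed, {
    exon_lens <- sample(seq.int(exon_len_range[[1L]], exon_len_range[[2L]]),
                        n_exons, replace = TRUE)
    intron_lens <- if (n_exons > 1L)
      sample(seq.int(intron_len_range[[1L]], intron_len_range[[2L]]),
             n_exons - 1L, replace = TRUE) else integer(0)
    total <- 2L * flank_len + sum(exon_lens) + sum(intron_lens)
    chars <- random_bases(total, gc_content)

    exons <- matrix(0L, nrow = n_exons, ncol = 2L,
                    dimnames = list(NULL, c("start", "end")))
    cur <- flank_len
    for (i in seq_len(n_exons)) {
      exons[i, ] <- c(cur, cur + exon_lens[[i]])
      cur <- cur + exon_lens[[i]] + if (i < n_exons) intron_lens[[i]] else 0L
    }
    sco <- flank_len + utr5_len
    chars[(sco + 1L):(sco + 3L)] <- c("A", "T", "G")
    gene_model(name, paste(chars, collapse = ""), exons, sco)
  })
}

planted_g4s_of <- function(model) {
  p <- attr(model, "planted_g4s")
  if (is.null(p))
    data.frame(start = integer(0), end = integer(0),
               orientation = character(0), stringsAsFactors = FALSE)
  else p
}

#' Plant a G4-forming motif into a gene model
#'
#' Splices the motif (default: the human telomeric repeat, a canonical
#' quadruplex former) in place over existing bases, so all coordinates stay
#' fixed; minus orientation plants the reverse complement, which the scanner
#' reports with a negative score. The truth interval is recorded in the
#' model's `planted_g4s` attribute.
#'
#' @param model A [gene_model()].
#' @param at_offset 0-based start of the planted motif.
#' @param motif Motif sequence (plus orientation).
#' @param orientation `"+"` or `"-"`.
#' @return The updated model, with the truth row appended to
#'   `attr(model, "planted_g4s")`.
#' @export
plant_g4 <- function(model, at_offset, motif = "GGGTTAGGGTTAGGGTTAGGG",
                     orientation = c("+", "-")) {
  stopifnot(inherits(model, "gene_model"))
  orientation <- match.arg(orientation)
  at_offset <- as.integer(at_offset)
  motif <- toupper(motif)
  len <- nchar(motif)
  n <- nchar(model$sequence)
  if (at_offset < 0L || at_offset + len > n)
    g4_abort("g4snp_coordinate_error",
             sprintf("motif interval [%d, %d) outside the %d bp sequence",
                     at_offset, at_offset + len, n))
  prev <- planted_g4s_of(model)
  if (any(at_offset < prev$end & prev$start < at_offset + len))
    g4_abort("g4snp_plant_error", sprintf(
      "motif at [%d, %d) overlaps a previously planted motif",
      at_offset, at_offset + len))
  planted <- if (orientation == "+") motif else reverse_complement(motif)
  seq2 <- model$sequence
  substr(seq2, at_offset + 1L, at_offset + len) <- planted
  out <- gene_model(model$gene_name, seq2, model$exons, model$start_codon_offset)
  attr(out, "planted_g4s") <- rbind(
    prev, data.frame(start = at_offset, end = at_offset + len,
                     orientation = orientation, stringsAsFactors = FALSE))
  out
}

# largest-remainder apportionment of n among the mix proportions
apportion <- function(n, mix) {
  k <- floor(n * mix)
  rem <- n - sum(k)
  if (rem > 0L) {
    frac <- n * mix - k
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1L
  }
  as.integer(k)
}

#' Plant variants with known genomic truth
#'
#' Draws `n` positions from the gene model's region classes per `region_mix`
#' (coding exon, intron, exonic 5'UTR, upstream flank -- mirroring a spread
#' over exons, introns and 5' regulatory regions), names each as an HGVS
#' cDNA substitution whose reference base is the model's actual base at the
#' truth offset, and returns the truth table. Positions inside planted G4
#' intervals are avoided unless `allow_in_g4`. The sequence is never
#' modified, so planted-G4 scanner truth stays valid; alternate bases are
#' chosen from \{A, T\} so even a hypothetical application of the variant
#' would not create a G/C run.
#'
#' @param model A [gene_model()] (ATG in exon 1 for intronic planting).
#' @param n Number of variants.
#' @param region_mix Named proportions over
#'   `c("exon", "intron", "utr5", "upstream")`; must sum to 1.
#' @param seed Optional integer seed.
#' @param allow_in_g4 Permit variants inside planted G4 intervals.
#' @return Data frame with columns `hgvs`, `region`, `offset` (truth),
#'   `distance` (truth, signed from ATG).
#' @export
plant_variants <- function(model, n,
                           region_mix = c(exon = 0.25, intron = 0.25,
                                          utr5 = 0.25, upstream = 0.25),
                           seed = NULL, allow_in_g4 = FALSE) {
  stopifnot(inherits(model, "gene_model"))
  if (abs(sum(region_mix) - 1) > 1e-8)
    g4_abort("g4snp_config_error", "region_mix proportions must sum to 1")
  classes <- names(region_mix)
  if (!all(classes %in% c("exon", "intron", "utr5", "upstream")))
    g4_abort("g4snp_config_error",
             "region_mix names must be among exon/intron/utr5/upstream")

  ex <- model$exons
  ins <- introns_of(model)
  g4s <- planted_g4s_of(model)
  in_g4 <- function(off) any(g4s$start <= off & off < g4s$end)

  pools <- list(
    exon = model$coding_offsets,
    intron = if (nrow(ins) > 0L)
      unlist(lapply(seq_len(nrow(ins)), function(i)
        seq.int(ins[i, "start"], ins[i, "end"] - 1L)), use.names = FALSE)
      else integer(0),
    utr5 = model$utr5_offsets,
    upstream = if (ex[1L, "start"] > 0L) seq.int(0L, ex[1L, "start"] - 1L)
               else integer(0)
  )
  if (!allow_in_g4)
    pools <- lapply(pools, function(p) p[!vapply(p, in_g4, logical(1))])

  counts <- apportion(n, region_mix)
  for (i in seq_along(classes)) {
    if (counts[[i]] > length(pools[[classes[[i]]]]))
      g4_abort("g4snp_config_error", sprintf(
        "model has only %d candidate positions in region class '%s' (need %d)",
        length(pools[[classes[[i]]]]), classes[[i]], counts[[i]]))
  }

  with_seed(seed, {
    rows <- list()
    for (i in seq_along(classes)) {
      cls <- classes[[i]]
      if (counts[[i]] == 0L) next
      offs <- sample(pools[[cls]], counts[[i]], replace = FALSE)
      for (off in offs) {
        desc <- genomic_to_cdna(model, off)
        ref <- substr(model$sequence, off + 1L, off + 1L)
        alt <- setdiff(c("A", "T"), ref)[[1L]]
        hgvs <- sprintf("%s%s>%s", format_hgvs(desc), ref, alt)
        rows[[length(rows) + 1L]] <- data.frame(
          hgvs = hgvs, region = cls, offset = off,
          distance = off - model$start_codon_offset, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a complete multi-gene validation fixture
#'
#' Builds `n_genes` random gene models, plants two telomeric-repeat G4
#' motifs per gene (one in the upstream flank, orientation `+`; one mid
#' intron 1, alternating orientation), and plants `n_variants` total
#' variants spread evenly over the genes with the default region mix
#' (exon / intron / 5'UTR / upstream). The 4-gene, 31-variant default
#' mirrors a validation set of 31 substitutions spanning all four region
#' classes.
#'
#' @param n_genes Number of genes.
#' @param n_variants Total variants across genes.
#' @param seed Integer seed (all randomness derives from it).
#' @return A list of class `g4_fixture`: `models` (named list),
#'   `variants` (truth data frame with a `gene` column),
#'   `planted_g4s` (truth data frame with a `gene` column), `seed`.
#' @export
simulate_fixture_set <- function(n_genes = 4L, n_variants = 31L, seed = 1L) {
  with_seed(seed, {
    models <- list()
    var_rows <- list()
    g4_rows <- list()
    per_gene <- apportion(n_variants, rep(1 / n_genes, n_genes))
    for (g in seq_len(n_genes)) {
      nm <- sprintf("SYNTHG%d", g)
      m <- simulate_gene(name = nm)
      up_at <- m$exons[1L, "start"] - 150L
      ins <- introns_of(m)
      intr_at <- ins[1L, "start"] + (ins[1L, "end"] - ins[1L, "start"] - 21L) %/% 2L
      m <- plant_g4(m, up_at, orientation = "+")
      m <- plant_g4(m, intr_at, orientation = if (g %% 2L == 0L) "-" else "+")
      vars <- plant_variants(m, per_gene[[g]])
      vars <- cbind(gene = nm, vars, stringsAsFactors = FALSE)
      g4t <- cbind(gene = nm, planted_g4s_of(m), stringsAsFactors = FALSE)
      models[[nm]] <- m
      var_rows[[g]] <- vars
      g4_rows[[g]] <- g4t
    }
    structure(list(models = models,
                   variants = do.call(rbind, var_rows),
                   planted_g4s = do.call(rbind, g4_rows),
                   seed = seed),
              class = "g4_fixture")
  })
}

#' Write a fixture set to disk
#'
#' Emits, per gene, `<gene>.fa` and `<gene>.structure.tsv`; plus
#' `variants.tsv` (gene TAB hgvs), and `truth.tsv` / `g4_truth.tsv` with the
#' planted ground truth.
#'
#' @param fixture A [simulate_fixture_set()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(fixture, dir) {
  stopifnot(inherits(fixture, "g4_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(fixture$models)) {
    m <- fixture$models[[nm]]
    write_gene_fasta(m, file.path(dir, paste0(nm, ".fa")))
    write_gene_structure(m, file.path(dir, paste0(nm, ".structure.tsv")))
  }
  writeLines(sprintf("%s\t%s", fixture$variants$gene, fixture$variants$hgvs),
             file.path(dir, "variants.tsv"))
  utils::write.table(fixture$variants, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$planted_g4s, file.path(dir, "g4_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
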