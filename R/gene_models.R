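# Gene structures, sequence stores, and coordinate arithmetic.
#
# Conventions (used by every module):
#   * all internal coordinates are 0-based half-open [start, end);
#   * GFF3 I/O converts to/from 1-based inclusive at the boundary;
#   * exon/block matrices have columns start,end and rows in transcription
#     order (ascending for "+" genes, descending for "-" genes);
#   * all transcript-level arithmetic happens in mRNA coordinates after
#     strand resolution.

#' Construct a gene model
#'
#' A gene model is one gene in one species: its genomic exon chain and
#' annotated coding region. Introns are the gaps between consecutive exons.
#'
#' @param gene_id Gene identifier (unique within an analysis).
#' @param species Species name.
#' @param chrom Chromosome / scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param exons Integer matrix with columns `start`,`end` (0-based half-open),
#'   rows in transcription order.
#' @param cds_start,cds_end Genomic bounds (0-based half-open) of the coding
#'   region, including the stop codon.
#' @param subfamily Optional subfamily label.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, species, chrom, strand, exons,
                       cds_start, cds_end, subfamily = NA_character_) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  g <- structure(list(gene_id = gene_id, species = species, chrom = chrom,
                      strand = strand, exons = exons,
                      cds_start = as.integer(cds_start),
                      cds_end = as.integer(cds_end),
                      subfamily = subfamily),
                 class = "gene_model")
  validate_gene_model(g)
  g
}

validate_gene_model <- function(g) {
  ex <- g$exons
  if (!g$strand %in% c("+", "-")) sv_stop("strand must be '+' or '-'", "structural_error")
  if (any(ex[, "end"] <= ex[, "start"]))
    sv_stop(sprintf("gene %s: exon with end <= start", g$gene_id), "structural_error")
  gen <- ex[order(ex[, "start"]), , drop = FALSE]
  if (nrow(gen) > 1 && any(gen[-1, "start"] < gen[-nrow(gen), "end"]))
    sv_stop(sprintf("gene %s: overlapping exons", g$gene_id), "structural_error")
  # transcription order check
  ord <- order(ex[, "start"])
  want <- if (g$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  if (!identical(ord, want))
    sv_stop(sprintf("gene %s: exons not in transcription order", g$gene_id),
            "structural_error")
  if (nrow(gen) > 1) {
    gaps <- gen[-1, "start"] - gen[-nrow(gen), "end"]
    if (any(gaps < 4L))
      sv_stop(sprintf("gene %s: intron shorter than 4 nt", g$gene_id),
              "structural_error")
  }
  # CDS must be covered by exons
  if (g$cds_end <= g$cds_start)
    sv_stop(sprintf("gene %s: empty CDS", g$gene_id), "structural_error")
  cov <- interval_coverage(gen, g$cds_start, g$cds_end)
  gapped <- cds_gap_uncovered(gen, g$cds_start, g$cds_end)
  if (gapped)
    sv_stop(sprintf("gene %s: CDS not contained in exons", g$gene_id),
            "structural_error")
  invisible(cov)
}

# total exon-covered length within [s, e)
interval_coverage <- function(gen_sorted, s, e) {
  lo <- pmax(gen_sorted[, "start"], s)
  hi <- pmin(gen_sorted[, "end"], e)
  sum(pmax(0L, hi - lo))
}

# TRUE if any part of [s,e) falls outside exons *and* outside introns'
# legitimate gaps — i.e. CDS bounds must land inside exons.
cds_gap_uncovered <- function(gen_sorted, s, e) {
  in_exon <- function(p) any(gen_sorted[, "start"] <= p & p < gen_sorted[, "end"])
  !(in_exon(s) && in_exon(e - 1L))
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s strand %s; %d exon(s), CDS [%d,%d)\n",
              x$gene_id, x$species, x$chrom,
              paste0("[", min(x$exons), ",", max(x$exons), ")"),
              x$strand, nrow(x$exons), x$cds_start, x$cds_end))
  invisible(x)
}

#' Genomic locus spanned by a gene model
#' @param gene A `gene_model`.
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
gene_locus <- function(gene) {
  c(start = min(gene$exons[, "start"]), end = max(gene$exons[, "end"]))
}

#' Introns of a gene model
#'
#' @param gene A `gene_model`.
#' @return Integer matrix (columns `start`,`end`, genomic 0-based half-open)
#'   with one row per intron, rows in transcription order; intron ordinals
#'   used throughout the package are 0-based row indices into this matrix.
#' @export
gene_introns <- function(gene) {
  ex <- gene$exons
  n <- nrow(ex)
  if (n < 2) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  if (gene$strand == "+") {
    cbind(start = ex[-n, "end"], end = ex[-1, "start"])
  } else {
    cbind(start = ex[-1, "end"], end = ex[-n, "start"])
  }
}

## ---- sequence store -------------------------------------------------------

#' Read a genome (or any nucleotide FASTA) into a named character vector
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write named sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    writeLines(paste0(">", nm), con)
    if (nchar(s) == 0L) next
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an (aligned or unaligned) protein FASTA
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

revcomp <- function(x) {
  vapply(chartr("ACGTNacgtn", "TGCANtgcan", x),
         function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

# substring in 0-based half-open coordinates (vectorized over start/end)
seq_slice <- function(seq, start, end) substring(seq, start + 1L, end)

## ---- GFF3 -----------------------------------------------------------------

#' Read gene models from GFF3
#'
#' Expects gene/mRNA/exon/CDS features (one mRNA per gene; the first is taken
#' if several). 1-based inclusive GFF coordinates are converted to the
#' package's 0-based half-open convention, and minus-strand exon lists are
#' returned in transcription order. `species` and `subfamily` attributes on
#' the gene feature are carried through when present.
#'
#' @param path GFF3 file.
#' @return Named list of [gene_model()] objects.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tr <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == gid, , drop = FALSE]
    if (nrow(tr) == 0L) next
    tid <- tr$ID[1]
    ex <- df[df$type == "exon" & !is.na(df$Parent) & df$Parent == tid, , drop = FALSE]
    cds <- df[df$type == "CDS" & !is.na(df$Parent) & df$Parent == tid, , drop = FALSE]
    if (nrow(ex) == 0L || nrow(cds) == 0L)
      sv_stop(sprintf("gene %s: missing exon or CDS features", gid), "structural_error")
    strand <- as.character(genes$strand[i])
    exm <- cbind(start = ex$start - 1L, end = ex$end)
    exm <- exm[order(exm[, "start"]), , drop = FALSE]
    if (strand == "-") exm <- exm[rev(seq_len(nrow(exm))), , drop = FALSE]
    species <- if ("species" %in% names(genes)) genes$species[i] else NA_character_
    subfam <- if ("subfamily" %in% names(genes)) genes$subfamily[i] else NA_character_
    out[[gid]] <- gene_model(
      gene_id = gid,
      species = species %||% NA_character_,
      chrom = as.character(genes$seqnames[i]),
      strand = strand,
      exons = exm,
      cds_start = min(cds$start) - 1L,
      cds_end = max(cds$end),
      subfamily = subfam %||% NA_character_)
  }
  out
}

#' Write gene models as GFF3
#'
#' Deterministic writer (no timestamps): identical models give byte-identical
#' files. Round-trips losslessly through [read_gff()].
#'
#' @param models List of `gene_model`.
#' @param path Output path.
#' @export
write_gff <- function(models, path) {
  lines <- "##gff-version 3"
  for (g in models) {
    loc <- gene_locus(g)
    attrs <- sprintf("ID=%s", g$gene_id)
    if (!is.na(g$species)) attrs <- paste0(attrs, ";species=", g$species)
    if (!is.na(g$subfamily)) attrs <- paste0(attrs, ";subfamily=", g$subfamily)
    tid <- paste0(g$gene_id, ".t1")
    row <- function(type, s, e, att, phase = ".")
      sprintf("%s\tsplicevo\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              g$chrom, type, s + 1L, e, g$strand, phase, att)
    lines <- c(lines,
               row("gene", loc["start"], loc["end"], attrs),
               row("mRNA", loc["start"], loc["end"],
                   sprintf("ID=%s;Parent=%s", tid, g$gene_id)))
    ex <- g$exons[order(g$exons[, "start"]), , drop = FALSE]
    for (k in seq_len(nrow(ex)))
      lines <- c(lines, row("exon", ex[k, "start"], ex[k, "end"],
                            paste0("Parent=", tid)))
    # CDS = exon pieces intersected with [cds_start, cds_end)
    phase_run <- 0L
    cds_rows <- character(0)
    exo <- if (g$strand == "+") ex else ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    for (k in seq_len(nrow(exo))) {
      s <- max(exo[k, "start"], g$cds_start); e <- min(exo[k, "end"], g$cds_end)
      if (e <= s) next
      cds_rows <- c(cds_rows, row("CDS", s, e, paste0("Parent=", tid),
                                  phase = as.character((3L - phase_run %% 3L) %% 3L)))
      phase_run <- phase_run + (e - s)
    }
    if (g$strand == "-") cds_rows <- rev(cds_rows)
    lines <- c(lines, cds_rows)
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- isoforms -------------------------------------------------------------

#' Construct an isoform
#'
#' An isoform is an ordered chain of genomic blocks forming one mature mRNA.
#'
#' @param parent Parent gene id.
#' @param chrom,strand Genomic placement.
#' @param blocks Matrix (`start`,`end`; 0-based half-open) in transcription
#'   order.
#' @param cds_offset Position of the start codon in mRNA coordinates
#'   (`NA` when the start codon was excised by the event).
#' @param polyA_truncated `TRUE` for transcripts ended by early
#'   polyadenylation.
#' @param ref_stop Genomic position (0-based, strand-aware first nt) of the
#'   annotated stop codon; used to recognize the reference stop during NMD
#'   classification.
#' @param isoform_id Optional identifier.
#' @return Object of class `isoform`.
#' @export
isoform <- function(parent, chrom, strand, blocks, cds_offset,
                    polyA_truncated = FALSE, ref_stop = NA_integer_,
                    isoform_id = NA_character_) {
  blocks <- matrix(as.integer(blocks), ncol = 2,
                   dimnames = list(NULL, c("start", "end")))
  if (any(blocks[, "end"] <= blocks[, "start"]))
    sv_stop("isoform block with end <= start", "structural_error")
  structure(list(parent = parent, chrom = chrom, strand = strand,
                 blocks = blocks, cds_offset = cds_offset,
                 polyA_truncated = isTRUE(polyA_truncated),
                 ref_stop = ref_stop, isoform_id = isoform_id),
            class = "isoform")
}

#' mRNA length of an isoform
#' @param iso An `isoform`.
#' @export
isoform_length <- function(iso) sum(iso$blocks[, "end"] - iso$blocks[, "start"])

#' Exon–exon junction positions of an isoform
#'
#' @param iso An `isoform`.
#' @return Integer vector of mRNA coordinates (nt from the mRNA 5' end) at
#'   which consecutive blocks meet: the cumulative partial sums of block
#'   lengths, excluding the total. Empty for single-block isoforms.
#' @export
enumerate_junctions <- function(iso) {
  lens <- iso$blocks[, "end"] - iso$blocks[, "start"]
  if (length(lens) < 2) return(integer(0))
  as.integer(cumsum(lens)[-length(lens)])
}

#' Extract the spliced (mature mRNA) sequence of an isoform
#'
#' Blocks are concatenated in transcription order; minus-strand blocks are
#' reverse-complemented.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param iso An `isoform`.
#' @return Nucleotide string whose length equals the sum of block lengths.
#' @export
spliced_sequence <- function(genome, iso) {
  chrseq <- genome[[iso$chrom]]
  if (is.null(chrseq)) sv_stop(paste("unknown chromosome", iso$chrom), "range_error")
  if (any(iso$blocks[, "start"] < 0L) || any(iso$blocks[, "end"] > nchar(chrseq)))
    sv_stop("isoform block out of chromosome bounds", "range_error")
  pieces <- seq_slice(chrseq, iso$blocks[, "start"], iso$blocks[, "end"])
  if (iso$strand == "-") pieces <- revcomp(pieces)
  paste(pieces, collapse = "")
}

## ---- translation ----------------------------------------------------------

# Scan an open reading frame from a 0-based mRNA offset. Returns the protein
# (stop excluded), whether a stop was reached, and the mRNA coordinate of the
# first nt 3' of the stop codon (NA when translation ran off the end).
scan_orf <- function(mrna, cds_offset) {
  n <- nchar(mrna)
  if (cds_offset + 3L > n) sv_stop("cds_offset leaves no room for a codon", "range_error")
  starts <- seq.int(cds_offset + 1L, n - 2L, by = 3L)
  codons <- substring(mrna, starts, starts + 2L)
  aa <- unname(GENCODE[codons])
  aa[is.na(aa)] <- "X"
  stop_i <- which(aa == "*")[1]
  if (is.na(stop_i)) {
    list(protein = paste(aa, collapse = ""), has_stop = FALSE,
         stop_mrna_pos = NA_integer_)
  } else {
    list(protein = paste(aa[seq_len(stop_i - 1L)], collapse = ""),
         has_stop = TRUE,
         stop_mrna_pos = as.integer(cds_offset + 3L * stop_i))
  }
}

#' Translate an mRNA from a start offset
#'
#' Standard genetic code; translation stops at the first stop codon, which is
#' excluded from the returned protein. A transcript with no in-frame stop
#' before the mRNA end is flagged with a warning and the partial protein is
#' returned (attribute `nonstop = TRUE`).
#'
#' @param mrna Nucleotide string.
#' @param cds_offset 0-based position of the first codon nt.
#' @return Amino-acid string; attribute `nonstop` is `TRUE` when no stop
#'   codon was found.
#' @export
translate_mrna <- function(mrna, cds_offset = 0L) {
  orf <- scan_orf(mrna, cds_offset)
  out <- orf$protein
  attr(out, "nonstop") <- !orf$has_stop
  if (!orf$has_stop) warning("non-stop transcript: no stop codon before mRNA end")
  out
}

## ---- proteins -------------------------------------------------------------

#' Trim proteins at a supplied domain boundary
#'
#' Sequences are truncated at `trim_end` (e.g. the end of the second RNA
#' recognition motif); downstream alignment should consume only trimmed
#' sequences so that divergent C-termini do not distort the tree.
#'
#' @param records Data frame with columns `gene_id`, `sequence`, `trim_end`
#'   (residue index, 1-based inclusive end).
#' @return The same data frame with truncated `sequence`.
#' @export
trim_proteins <- function(records) {
  stopifnot(all(c("gene_id", "sequence", "trim_end") %in% names(records)))
  for (i in seq_len(nrow(records))) {
    te <- records$trim_end[i]
    if (is.na(te))
      sv_stop(sprintf("protein %s: trim_end not set", records$gene_id[i]),
              "config_error")
    if (te > nchar(records$sequence[i]))
      sv_stop(sprintf("protein %s: trim_end %d exceeds length %d",
                      records$gene_id[i], te, nchar(records$sequence[i])),
              "config_error")
  }
  records$sequence <- substr(records$sequence, 1L, records$trim_end)
  records
}

#' Productive protein of a gene model
#'
#' Splices all reference exons, translates from the annotated start, and
#' checks that translation is clean (no internal stop surprises).
#'
#' @param genome Sequence store.
#' @param gene A `gene_model`.
#' @return Amino-acid string.
#' @export
gene_protein <- function(genome, gene) {
  iso <- build_isoform(gene, NULL)
  translate_mrna(spliced_sequence(genome, iso), iso$cds_offset)
}
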