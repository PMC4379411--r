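# Intron positions as phylogenetic characters.
#
# An intron interrupting a coding sequence is summarized as (codon_index,
# phase): codon_index is the 0-based index of the codon the intron precedes
# or interrupts, phase the number of CDS nt of that codon 5' of the intron.
# Projected through each gene's gap pattern onto a protein multiple
# alignment, shared (column, phase) keys become binary presence/absence
# characters across the family.

#' Intron positions of a gene in protein (codon, phase) coordinates
#'
#' @param gene A [gene_model()].
#' @return Data frame with one row per CDS-interrupting intron: `gene_id`,
#'   `intron_index` (0-based ordinal within the gene, in transcription
#'   order), `codon_index`, `phase`, `genomic_start`, `genomic_end`.
#'   Attribute `n_utr_introns` counts introns lying entirely within UTRs
#'   (excluded from the table).
#' @export
intron_sites <- function(gene) {
  ex <- gene$exons
  introns <- gene_introns(gene)
  # coding nt per exon, transcription order
  lo <- pmax(ex[, "start"], gene$cds_start)
  hi <- pmin(ex[, "end"], gene$cds_end)
  coding <- pmax(0L, hi - lo)
  cds_len <- sum(coding)
  if (cds_len %% 3L != 0L)
    sv_stop(sprintf("gene %s: CDS length %d not divisible by 3",
                    gene$gene_id, cds_len), "structural_error")
  n_utr <- 0L
  rows <- list()
  if (nrow(introns) > 0) {
    up <- cumsum(coding)  # coding nt 5' of intron i = up[i]
    for (i in seq_len(nrow(introns))) {
      cu <- up[i]
      if (cu <= 0L || cu >= cds_len) { n_utr <- n_utr + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene$gene_id,
        intron_index = i - 1L,
        codon_index = cu %/% 3L,
        phase = cu %% 3L,
        genomic_start = introns[i, "start"],
        genomic_end = introns[i, "end"],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), intron_index = integer(0),
               codon_index = integer(0), phase = integer(0),
               genomic_start = integer(0), genomic_end = integer(0))
  attr(out, "n_utr_introns") <- n_utr
  out
}

#' Anchor intron sites to protein alignment columns
#'
#' Each site's `codon_index` is mapped to its alignment column through the
#' gene's own gap pattern. Sites beyond the (trimmed) alignment row are
#' dropped and counted.
#'
#' @param sites Data frame as returned by [intron_sites()] (possibly several
#'   genes row-bound).
#' @param msa Named character vector of aligned (gapped) protein sequences;
#'   names must cover all `gene_id`s in `sites`.
#' @param proteins Optional named vector of ungapped (trimmed) proteins used
#'   to verify that each MSA row matches its protein.
#' @return Data frame `gene_id`, `column` (0-based), `phase`, `intron_index`;
#'   attribute `n_dropped` counts sites beyond the trim boundary.
#' @export
anchor_sites <- function(sites, msa, proteins = NULL) {
  out <- list(); dropped <- 0L
  for (gid in unique(sites$gene_id)) {
    row <- msa[[gid]]
    if (is.null(row)) sv_stop(paste("gene missing from MSA:", gid), "input_error")
    chars <- strsplit(row, "", fixed = TRUE)[[1]]
    nongap <- which(chars != "-")
    if (!is.null(proteins)) {
      ungapped <- paste(chars[nongap], collapse = "")
      if (!identical(ungapped, unname(proteins[[gid]])))
        sv_stop(paste("MSA row does not match protein for gene", gid), "input_error")
    }
    ss <- sites[sites$gene_id == gid, , drop = FALSE]
    keep <- ss$codon_index < length(nongap)
    dropped <- dropped + sum(!keep)
    ss <- ss[keep, , drop = FALSE]
    if (nrow(ss) == 0L) next
    out[[gid]] <- data.frame(gene_id = gid,
                             column = nongap[ss$codon_index + 1L] - 1L,
                             phase = ss$phase,
                             intron_index = ss$intron_index,
                             stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), column = integer(0),
               phase = integer(0), intron_index = integer(0))
  rownames(res) <- NULL
  attr(res, "n_dropped") <- dropped
  res
}

#' Build the binary intron character matrix
#'
#' Anchored sites sharing a phase and lying within `window` columns of each
#' other (single-linkage chaining) are merged into one character, keyed by
#' the smallest member column. Characters whose key column is mostly gap are
#' flagged low-confidence.
#'
#' @param anchored Output of [anchor_sites()].
#' @param window Column tolerance for merging (default 0 = exact match).
#' @param max_gap_fraction Characters whose column has a gap fraction above
#'   this are flagged `low_confidence`.
#' @param msa Optional MSA (needed for gap fractions; without it no character
#'   is flagged).
#' @return List of class `intron_character_matrix`: `characters` (data frame
#'   `key`, `column`, `phase`, `low_confidence`), `matrix` (binary, genes x
#'   characters, colnames `col<idx>_p<phase>`), `gene_ids`, and
#'   `assignment` mapping each anchored site to its character key.
#' @export
build_character_matrix <- function(anchored, window = 0L,
                                   max_gap_fraction = 0.5, msa = NULL) {
  genes <- unique(anchored$gene_id)
  chars <- list()     # per phase: data.frame(column, key)
  assign_key <- character(nrow(anchored))
  for (ph in sort(unique(anchored$phase))) {
    idx <- which(anchored$phase == ph)
    cols <- sort(unique(anchored$column[idx]))
    if (!length(cols)) next
    breaks <- c(0L, which(diff(cols) > window), length(cols))
    for (b in seq_len(length(breaks) - 1L)) {
      members <- cols[(breaks[b] + 1L):breaks[b + 1L]]
      key <- sprintf("col%d_p%d", min(members), ph)
      chars[[key]] <- list(column = min(members), phase = ph)
      assign_key[idx[anchored$column[idx] %in% members]] <- key
    }
  }
  keys <- names(chars)
  m <- matrix(0L, nrow = length(genes), ncol = length(keys),
              dimnames = list(genes, keys))
  if (nrow(anchored))
    m[cbind(anchored$gene_id, assign_key)] <- 1L
  gapfrac <- rep(NA_real_, length(keys))
  if (!is.null(msa) && length(keys)) {
    almat <- do.call(rbind, strsplit(unname(msa[genes]), "", fixed = TRUE))
    for (k in seq_along(keys))
      gapfrac[k] <- mean(almat[, chars[[keys[k]]]$column + 1L] == "-")
  }
  characters <- data.frame(
    key = keys,
    column = vapply(chars, function(x) x$column, 0L),
    phase = vapply(chars, function(x) x$phase, 0L),
    low_confidence = !is.na(gapfrac) & gapfrac > max_gap_fraction,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(characters = characters, matrix = m, gene_ids = genes,
                 assignment = data.frame(anchored, key = assign_key,
                                         stringsAsFactors = FALSE)),
            class = "intron_character_matrix")
}

#' Classify a gene into a subfamily by shared intron characters
#'
#' The query's character profile is compared with each named reference
#' profile by Jaccard similarity; the best-scoring label wins. Ties, and
#' queries sharing nothing with any reference, are `"unclassified"`.
#'
#' @param query Character vector of character keys present in the gene.
#' @param references Named list of reference key vectors.
#' @return List with `label` and `score`.
#' @export
classify_subfamily <- function(query, references) {
  if (length(references) < 1) sv_stop("need at least one reference profile", "input_error")
  if (length(query) == 0) return(list(label = "unclassified", score = 0))
  sims <- vapply(references, function(ref) {
    u <- length(union(query, ref))
    if (u == 0) 0 else length(intersect(query, ref)) / u
  }, 0)
  best <- max(sims)
  if (best == 0 || sum(sims == best) > 1) return(list(label = "unclassified", score = best))
  list(label = names(sims)[which.max(sims)], score = best)
}

#' Write an intron character matrix as TSV
#' @param icm An `intron_character_matrix`.
#' @param path Output path (rows = genes, columns = `col<idx>_p<phase>`).
#' @export
write_character_matrix <- function(icm, path) {
  df <- data.frame(gene_id = rownames(icm$matrix), icm$matrix,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
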