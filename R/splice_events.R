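# Alternative-splicing event calling and NMD classification.
#
# Events are called from spliced EST-like alignments (BED12 blocks) against a
# reference gene model. Three kinds are in scope, mirroring what EST evidence
# can show at homologous intron positions: a cassette exon spliced inside a
# reference intron, retention of a whole intron, and early polyadenylation
# terminating a transcript inside an intron or novel exon. Alt-5'/alt-3'
# splice-site usage is out of scope.

## ---- EST I/O --------------------------------------------------------------

#' Read spliced EST alignments from BED12
#'
#' A polyA-terminated read is flagged by `";pA=1"` carried in the BED name
#' field.
#'
#' @param path BED12 file.
#' @return List of ESTs; each is a list with `name`, `chrom`, `strand`,
#'   `blocks` (genomic-ascending matrix, 0-based half-open), `polyA`.
#' @export
read_ests <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  bl <- rtracklayer::blocks(gr)
  nms <- gr$name
  if (is.null(nms)) nms <- paste0("est", seq_along(gr))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  strands <- as.character(GenomicRanges::strand(gr))
  pA <- grepl(";pA=1", nms, fixed = TRUE)
  allb <- unlist(bl, use.names = FALSE)
  lens <- S4Vectors::elementNROWS(bl)
  f <- rep.int(seq_along(lens), lens)
  ssp <- split(GenomicRanges::start(allb) - 1L, f)
  esp <- split(GenomicRanges::end(allb), f)
  lapply(seq_along(lens), function(i)
    list(name = nms[i], chrom = chroms[i], strand = strands[i],
         blocks = cbind(start = ssp[[i]], end = esp[[i]]),
         polyA = pA[i]))
}

#' Write spliced alignments as BED12 (deterministic)
#' @param ests List of ESTs as in [read_ests()].
#' @param path Output path.
#' @export
write_ests <- function(ests, path) {
  lines <- vapply(ests, function(e) {
    b <- e$blocks[order(e$blocks[, "start"]), , drop = FALSE]
    s <- min(b[, "start"]); en <- max(b[, "end"])
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            e$chrom, s, en, e$name, e$strand, s, en, nrow(b),
            paste0(paste(b[, "end"] - b[, "start"], collapse = ","), ","),
            paste0(paste(b[, "start"] - s, collapse = ","), ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

## ---- event calling --------------------------------------------------------

#' Call alternative-splicing events from ESTs against a gene model
#'
#' * `CASSETTE_EXON`: an internal EST block lies strictly inside a reference
#'   intron and its flanking junctions match the host intron's donor and
#'   acceptor exon edges exactly.
#' * `INTRON_RETENTION`: one EST block spans an entire intron with at least
#'   `min_overhang` nt aligned on each flanking exon.
#' * `ALT_POLYA`: a polyA-flagged EST ends inside an intron (including inside
#'   a novel exon).
#'
#' Events are deduplicated with support counts; retention events adjacent to
#' a called cassette exon are flagged, since partially processed transcripts
#' often retain the introns flanking a regulated exon.
#'
#' @param ests List of ESTs ([read_ests()]).
#' @param gene A [gene_model()].
#' @param min_overhang Minimum exonic anchor for retention calls (nt).
#' @return Data frame `kind`, `gene_id`, `host_intron` (0-based ordinal),
#'   `start`, `end` (genomic), `support`, `adjacent_to_cassette`. Attribute
#'   `n_skipped` counts ESTs outside the locus/strand.
#' @export
call_events <- function(ests, gene, min_overhang = 10L) {
  introns <- gene_introns(gene)                     # transcription order
  ig <- introns[order(introns[, "start"]), , drop = FALSE]
  # map genomic-ascending intron row -> transcription ordinal (0-based)
  ord_of <- function(s) which(introns[, "start"] == s) - 1L
  loc <- gene_locus(gene)
  found <- list(); skipped <- 0L
  for (e in ests) {
    if (e$chrom != gene$chrom || e$strand != gene$strand ||
        max(e$blocks[, "end"]) <= loc["start"] ||
        min(e$blocks[, "start"]) >= loc["end"]) { skipped <- skipped + 1L; next }
    b <- e$blocks[order(e$blocks[, "start"]), , drop = FALSE]
    nb <- nrow(b)
    if (nrow(introns)) {
      for (k in seq_len(nb)) {
        # retention: block covers whole intron plus exonic overhangs
        sp <- which(b[k, "start"] <= introns[, "start"] - min_overhang &
                    b[k, "end"] >= introns[, "end"] + min_overhang)
        for (i in sp)
          found[[length(found) + 1L]] <- c("INTRON_RETENTION", i - 1L,
                                           introns[i, "start"], introns[i, "end"])
        # cassette: internal block strictly inside an intron, flanks matching
        if (k > 1L && k < nb) {
          inside <- which(introns[, "start"] < b[k, "start"] &
                          b[k, "end"] < introns[, "end"])
          for (i in inside) {
            if (b[k - 1L, "end"] == introns[i, "start"] &&
                b[k + 1L, "start"] == introns[i, "end"])
              found[[length(found) + 1L]] <- c("CASSETTE_EXON", i - 1L,
                                               b[k, "start"], b[k, "end"])
          }
        }
      }
      if (e$polyA) {
        t <- if (gene$strand == "+") max(b[, "end"]) - 1L else min(b[, "start"])
        i <- which(introns[, "start"] <= t & t < introns[, "end"])
        if (length(i) == 1L)
          found[[length(found) + 1L]] <- c("ALT_POLYA", i - 1L, t, t + 1L)
      }
    }
  }
  if (!length(found)) {
    out <- data.frame(kind = character(0), gene_id = character(0),
                      host_intron = integer(0), start = integer(0),
                      end = integer(0), support = integer(0),
                      adjacent_to_cassette = logical(0))
    attr(out, "n_skipped") <- skipped
    return(out)
  }
  fm <- do.call(rbind, found)
  key <- apply(fm, 1, paste, collapse = ":")
  tab <- table(key)
  uf <- fm[!duplicated(key), , drop = FALSE]
  ukey <- key[!duplicated(key)]
  out <- data.frame(kind = uf[, 1], gene_id = gene$gene_id,
                    host_intron = as.integer(uf[, 2]),
                    start = as.integer(uf[, 3]), end = as.integer(uf[, 4]),
                    support = as.integer(tab[ukey]),
                    stringsAsFactors = FALSE)
  cas_hosts <- out$host_intron[out$kind == "CASSETTE_EXON"]
  out$adjacent_to_cassette <- out$kind == "INTRON_RETENTION" &
    vapply(out$host_intron, function(h) any(abs(h - cas_hosts) <= 1L), TRUE)
  out <- out[order(out$host_intron, out$kind, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

## ---- isoform construction -------------------------------------------------

# mRNA coordinate of a genomic position within an isoform's blocks (blocks in
# transcription order); NA if not covered.
genomic_to_mrna <- function(blocks, strand, gpos) {
  off <- 0L
  for (k in seq_len(nrow(blocks))) {
    s <- blocks[k, "start"]; e <- blocks[k, "end"]
    if (s <= gpos && gpos < e) {
      return(off + if (strand == "+") gpos - s else e - 1L - gpos)
    }
    off <- off + (e - s)
  }
  NA_integer_
}

mrna_to_genomic <- function(blocks, strand, pos) {
  off <- 0L
  for (k in seq_len(nrow(blocks))) {
    len <- blocks[k, "end"] - blocks[k, "start"]
    if (pos < off + len) {
      d <- pos - off
      return(if (strand == "+") blocks[k, "start"] + d
             else blocks[k, "end"] - 1L - d)
    }
    off <- off + len
  }
  NA_integer_
}

ref_stop_genomic <- function(gene) {
  if (gene$strand == "+") gene$cds_end - 3L else gene$cds_start + 2L
}

ref_start_genomic <- function(gene) {
  if (gene$strand == "+") gene$cds_start else gene$cds_end - 1L
}

to_transcription_order <- function(blocks, strand) {
  blocks <- blocks[order(blocks[, "start"]), , drop = FALSE]
  if (strand == "-") blocks <- blocks[rev(seq_len(nrow(blocks))), , drop = FALSE]
  blocks
}

#' Build the isoform implied by a splice event
#'
#' With `event = NULL` the productive reference isoform (all exons) is
#' returned. A cassette event inserts the novel exon into the chain; a
#' retention event fuses the flanking exons across the intron (removing that
#' junction); an early-polyA event truncates the transcript at the polyA
#' position, extending the preceding exon into the intron (and through a
#' companion cassette exon when `cassette` is supplied and contains the
#' terminus).
#'
#' @param gene A [gene_model()].
#' @param event One row of [call_events()] output (or `NULL`).
#' @param cassette Optional cassette event row used to resolve an ALT_POLYA
#'   terminus that falls inside a novel exon.
#' @return An [isoform()]; `cds_offset` is `NA` when the start codon is not
#'   contained in the blocks.
#' @export
build_isoform <- function(gene, event = NULL, cassette = NULL) {
  ex <- gene$exons  # transcription order
  exg <- ex[order(ex[, "start"]), , drop = FALSE]
  introns <- gene_introns(gene)
  kind <- if (is.null(event)) "REFERENCE" else event$kind
  if (!is.null(event) && !identical(event$gene_id, gene$gene_id))
    sv_stop("event does not belong to this gene", "input_error")
  polyA <- FALSE
  if (kind == "REFERENCE") {
    blocks <- exg
  } else if (kind == "CASSETTE_EXON") {
    blocks <- rbind(exg, c(event$start, event$end))
    blocks <- blocks[order(blocks[, 1]), , drop = FALSE]
  } else if (kind == "INTRON_RETENTION") {
    i <- event$host_intron + 1L
    s <- introns[i, "start"]; e <- introns[i, "end"]
    keep <- !(exg[, "end"] == s | exg[, "start"] == e)
    fused <- c(exg[exg[, "end"] == s, "start"], exg[exg[, "start"] == e, "end"])
    blocks <- rbind(exg[keep, , drop = FALSE], fused)
    blocks <- blocks[order(blocks[, 1]), , drop = FALSE]
  } else if (kind == "ALT_POLYA") {
    polyA <- TRUE
    t <- event$start  # last transcribed nt
    # exons fully upstream of the terminus in transcription coords
    if (gene$strand == "+") {
      up <- exg[exg[, "end"] <= t + 1L, , drop = FALSE]
      host_exon_end <- max(up[, "end"])
      ext_start <- host_exon_end
      if (!is.null(cassette) && cassette$start <= t && t < cassette$end) {
        blocks <- rbind(up, c(cassette$start, t + 1L))
      } else {
        up[which.max(up[, "end"]), "end"] <- t + 1L
        blocks <- up
      }
    } else {
      up <- exg[exg[, "start"] >= t, , drop = FALSE]
      if (!is.null(cassette) && cassette$start <= t && t < cassette$end) {
        blocks <- rbind(c(t, cassette$end), up)
      } else {
        up[which.min(up[, "start"]), "start"] <- t
        blocks <- up
      }
    }
    blocks <- blocks[order(blocks[, 1]), , drop = FALSE]
  } else sv_stop(paste("unknown event kind:", kind), "input_error")
  blocks <- to_transcription_order(blocks, gene$strand)
  cds_off <- genomic_to_mrna(blocks, gene$strand, ref_start_genomic(gene))
  isoform(parent = gene$gene_id, chrom = gene$chrom, strand = gene$strand,
          blocks = blocks, cds_offset = cds_off, polyA_truncated = polyA,
          ref_stop = ref_stop_genomic(gene),
          isoform_id = paste0(gene$gene_id, ":", tolower(kind),
                              if (!is.null(event)) paste0("_i", event$host_intron) else ""))
}

## ---- NMD classification ---------------------------------------------------

#' Classify an isoform as an NMD target
#'
#' Implements the junction rule for premature-termination-codon recognition:
#' translation is scanned from the start codon; if the stop codon lies at
#' least `threshold_nt` nt (default 50) upstream of the last exon–exon
#' junction, the transcript is an NMD target. A stop in the last exon escapes
#' (`ESCAPE_LAST_EXON`, or `ESCAPE_TRUNCATED` for polyA-truncated
#' transcripts, which lack downstream junctions by construction and are
#' predicted to yield truncated protein). The annotated reference stop is
#' always `PRODUCTIVE`. A transcript whose start codon was excised gets
#' verdict `no_start`; one with no stop before the transcript end gets
#' `ESCAPE_TRUNCATED` when polyA-truncated and `no_stop` otherwise.
#'
#' The distance is measured from the first nt 3' of the stop codon to the
#' last junction, both in mRNA coordinates.
#'
#' @param iso An [isoform()].
#' @param genome Sequence store.
#' @param threshold_nt Junction-rule threshold (nt). The rule is a config
#'   knob: NMD determinants differ between lineages (fungal NMD in
#'   particular), so the threshold is deliberately pluggable.
#' @return Object of class `nmd_call`: `verdict` (`NMD_TARGET`, `PRODUCTIVE`,
#'   `ESCAPE_LAST_EXON`, `ESCAPE_TRUNCATED`, `no_start`, `no_stop`),
#'   `stop_mrna_pos` (first nt 3' of the stop codon), `last_junction`,
#'   `distance`.
#' @export
classify_nmd <- function(iso, genome, threshold_nt = 50L) {
  mk <- function(verdict, stop_pos = NA_integer_, lj = NA_integer_, d = NA_integer_)
    structure(list(isoform_id = iso$isoform_id, verdict = verdict,
                   stop_mrna_pos = stop_pos, last_junction = lj, distance = d),
              class = "nmd_call")
  if (is.na(iso$cds_offset)) return(mk("no_start"))
  mrna <- spliced_sequence(genome, iso)
  junctions <- enumerate_junctions(iso)
  orf <- scan_orf(mrna, iso$cds_offset)
  if (!orf$has_stop)
    return(mk(if (iso$polyA_truncated) "ESCAPE_TRUNCATED" else "no_stop"))
  sp <- orf$stop_mrna_pos
  lj <- if (length(junctions)) max(junctions) else NA_integer_
  # reference stop is productive by definition
  stop_first_nt_gen <- mrna_to_genomic(iso$blocks, iso$strand, sp - 3L)
  if (!is.na(iso$ref_stop) && identical(stop_first_nt_gen, iso$ref_stop))
    return(mk("PRODUCTIVE", sp, lj, if (is.na(lj)) NA_integer_ else lj - sp))
  downstream <- length(junctions) && any(junctions >= sp)
  if (!downstream)
    return(mk(if (iso$polyA_truncated) "ESCAPE_TRUNCATED" else "ESCAPE_LAST_EXON",
              sp, lj, if (is.na(lj)) NA_integer_ else lj - sp))
  d <- lj - sp
  mk(if (d >= threshold_nt) "NMD_TARGET" else "PRODUCTIVE", sp, lj, d)
}

#' @export
print.nmd_call <- function(x, ...) {
  cat(sprintf("<nmd_call> %s: %s (stop at %s, last junction %s, distance %s)\n",
              x$isoform_id %||% "?", x$verdict, x$stop_mrna_pos,
              x$last_junction, x$distance))
  invisible(x)
}

## ---- NMD-inhibition stabilization -----------------------------------------

#' Compare isoform fractions between wild-type and NMD-deficient conditions
#'
#' For each isoform, its fraction of the gene's total is computed in each
#' condition (pseudocount 0.5 added to every count); the fold change is the
#' NMD-deficient fraction over the wild-type fraction, and an isoform is
#' called stabilized when the fold change reaches `min_fold`. Isoforms absent
#' from one condition's table are treated as count 0 there.
#'
#' @param counts Data frame with columns `gene_id`, `isoform_id`,
#'   `count_wt`, `count_nmd_deficient` (missing entries 0).
#' @param min_fold Stabilization threshold on the fraction fold change.
#' @return Data frame adding `fraction_wt`, `fraction_nmd_deficient`,
#'   `fold_change`, `stabilized`.
#' @export
stabilization_report <- function(counts, min_fold = 2.0) {
  stopifnot(all(c("gene_id", "isoform_id", "count_wt", "count_nmd_deficient")
                %in% names(counts)))
  counts$count_wt[is.na(counts$count_wt)] <- 0
  counts$count_nmd_deficient[is.na(counts$count_nmd_deficient)] <- 0
  out <- list()
  for (g in unique(counts$gene_id)) {
    cc <- counts[counts$gene_id == g, , drop = FALSE]
    if (sum(cc$count_wt) <= 0 || sum(cc$count_nmd_deficient) <= 0)
      sv_stop(sprintf("gene %s has zero total counts in one condition", g),
              "input_error")
    wt <- cc$count_wt + 0.5
    nd <- cc$count_nmd_deficient + 0.5
    cc$fraction_wt <- wt / sum(wt)
    cc$fraction_nmd_deficient <- nd / sum(nd)
    cc$fold_change <- cc$fraction_nmd_deficient / cc$fraction_wt
    cc$stabilized <- cc$fold_change >= min_fold
    out[[g]] <- cc
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## ---- in-silico RT-PCR -----------------------------------------------------

#' Virtual RT-PCR across a set of isoforms
#'
#' Each primer must match its isoform's mature mRNA exactly (forward primer
#' as-is, reverse primer as the reverse complement); junction-spanning
#' primers therefore only amplify isoforms containing that junction —
#' the trick used to assay processed mRNA while excluding pre-mRNA. The
#' product length is the distance between the primers' outer ends.
#'
#' @param isoforms List of [isoform()] objects.
#' @param genome Sequence store.
#' @param fwd,rev Primer sequences (>= 15 nt), 5'->3'.
#' @return Data frame `isoform_id`, `product_length` (`NA` when no product),
#'   `status` (`ok`, `no_product`, `ambiguous`).
#' @export
virtual_rt_pcr <- function(isoforms, genome, fwd, rev) {
  if (nchar(fwd) < 15 || nchar(rev) < 15)
    sv_stop("primers must be at least 15 nt", "input_error")
  rev_rc <- revcomp(rev)
  rows <- lapply(isoforms, function(iso) {
    mrna <- spliced_sequence(genome, iso)
    fhit <- gregexpr(fwd, mrna, fixed = TRUE)[[1]]
    rhit <- gregexpr(rev_rc, mrna, fixed = TRUE)[[1]]
    fhit <- fhit[fhit > 0]; rhit <- rhit[rhit > 0]
    if (length(fhit) > 1 || length(rhit) > 1)
      return(data.frame(isoform_id = iso$isoform_id,
                        product_length = NA_integer_, status = "ambiguous"))
    if (length(fhit) == 0 || length(rhit) == 0 ||
        rhit + nchar(rev_rc) - 1L <= fhit)
      return(data.frame(isoform_id = iso$isoform_id,
                        product_length = NA_integer_, status = "no_product"))
    data.frame(isoform_id = iso$isoform_id,
               product_length = as.integer(rhit + nchar(rev_rc) - fhit),
               status = "ok")
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
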