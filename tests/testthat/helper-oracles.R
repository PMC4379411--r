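# Independent oracles: deliberately naive, loop-based reimplementations of
# the stated rules, sharing no code path with the package internals.

CODON_TABLE <- Biostrings::GENETIC_CODE

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# codon-by-codon translation, stopping at (and excluding) the first stop
oracle_translate <- function(mrna, offset) {
  out <- character(0)
  i <- offset + 1
  while (i + 2 <= nchar(mrna)) {
    aa <- CODON_TABLE[[substr(mrna, i, i + 2)]]
    if (aa == "*") return(list(protein = paste(out, collapse = ""), stop_after = i + 2))
    out <- c(out, aa)
    i <- i + 3
  }
  list(protein = paste(out, collapse = ""), stop_after = NA)
}

# linear-scan NMD rule: splice, translate, list junctions, compare distance
oracle_nmd <- function(iso, genome, threshold = 50) {
  chrseq <- genome[[iso$chrom]]
  pieces <- character(0)
  for (k in seq_len(nrow(iso$blocks)))
    pieces <- c(pieces, substr(chrseq, iso$blocks[k, 1] + 1, iso$blocks[k, 2]))
  if (iso$strand == "-") pieces <- vapply(pieces, oracle_revcomp, "")
  mrna <- paste(pieces, collapse = "")
  lens <- iso$blocks[, 2] - iso$blocks[, 1]
  junc <- integer(0); acc <- 0
  for (k in seq_len(length(lens) - 1)) { acc <- acc + lens[k]; junc <- c(junc, acc) }
  if (is.na(iso$cds_offset)) return("no_start")
  tr <- oracle_translate(mrna, iso$cds_offset)
  if (is.na(tr$stop_after))
    return(if (iso$polyA_truncated) "ESCAPE_TRUNCATED" else "no_stop")
  stop_pos <- tr$stop_after  # first nt after the stop codon (0-based = value)
  if (!is.na(iso$ref_stop)) {
    # genomic coordinate of the stop codon's first nt
    p <- stop_pos - 3  # 0-based mRNA index of stop codon start
    rem <- p; gpos <- NA
    for (k in seq_len(nrow(iso$blocks))) {
      if (rem < lens[k]) {
        gpos <- if (iso$strand == "+") iso$blocks[k, 1] + rem
                else iso$blocks[k, 2] - 1 - rem
        break
      }
      rem <- rem - lens[k]
    }
    if (identical(gpos, iso$ref_stop)) return("PRODUCTIVE")
  }
  down <- junc[junc >= stop_pos]
  if (length(down) == 0)
    return(if (iso$polyA_truncated) "ESCAPE_TRUNCATED" else "ESCAPE_LAST_EXON")
  if (max(junc) - stop_pos >= threshold) "NMD_TARGET" else "PRODUCTIVE"
}

# exhaustive Dollo: enumerate every internal-node state assignment with at
# most one 0->1 edge (root presence counts as the single gain), minimize the
# number of 1->0 edges
oracle_dollo_cost <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  root <- ntip + 1
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    st <- integer(ntip + nint)
    st[seq_len(ntip)] <- states[tree$tip.label]
    st[ntip + seq_len(nint)] <- bitwAnd(bitwShiftR(mask, seq_len(nint) - 1), 1)
    gains <- 0; losses <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- st[tree$edge[e, 1]]; c <- st[tree$edge[e, 2]]
      if (p == 0 && c == 1) gains <- gains + 1
      if (p == 1 && c == 0) losses <- losses + 1
    }
    total_gains <- gains + st[root]      # root presence = gain on the stem
    if (total_gains != 1) next
    if (losses < best) best <- losses
  }
  best
}

# naive maximal perfect-identity runs by column scan
oracle_runs <- function(aln, min_len) {
  m <- do.call(rbind, strsplit(unname(aln), ""))
  n <- ncol(m)
  out <- list(); start <- NA
  for (j in seq_len(n + 1)) {
    ok <- j <= n && length(unique(m[, j])) == 1 && m[1, j] != "-"
    if (ok && is.na(start)) start <- j
    if (!ok && !is.na(start)) {
      if (j - start >= min_len)
        out[[length(out) + 1]] <- c(start - 1, j - 1)
      start <- NA
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  d <- as.data.frame(do.call(rbind, out))
  names(d) <- c("start", "end")
  d
}

# naive per-column pair-agreement profile (no smoothing)
oracle_profile_raw <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln), ""))
  n <- nrow(m)
  vapply(seq_len(ncol(m)), function(j) {
    agree <- 0; tot <- 0
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      tot <- tot + 1
      if (m[a, j] != "-" && m[a, j] == m[b, j]) agree <- agree + 1
    }
    agree / tot
  }, 0)
}

oracle_pdist <- function(msa) {
  n <- length(msa)
  chars <- strsplit(unname(msa), "")
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    num <- 0; den <- 0
    for (k in seq_len(length(chars[[i]]))) {
      a <- chars[[i]][k]; b <- chars[[j]][k]
      if (a != "-" && b != "-") { den <- den + 1; if (a != b) num <- num + 1 }
    }
    d[i, j] <- d[j, i] <- num / den
  }
  d
}

## ---- random generators ----------------------------------------------------

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# a random (not necessarily biologically sensible) isoform + genome
rand_isoform <- function() {
  nb <- sample(1:6, 1)
  lens <- sample(30:240, nb, replace = TRUE)
  gaps <- sample(10:80, nb, replace = TRUE)
  starts <- cumsum(c(sample(0:50, 1), head(lens + gaps, -1)))
  blocks <- cbind(start = starts, end = starts + lens)
  chromlen <- max(blocks) + 50
  strand <- sample(c("+", "-"), 1)
  if (strand == "-") blocks <- blocks[rev(seq_len(nrow(blocks))), , drop = FALSE]
  genome <- c(chrZ = rand_seq(chromlen))
  iso <- isoform("gX", "chrZ", strand, blocks,
                 cds_offset = sample(0:(sum(lens) - 10), 1),
                 polyA_truncated = runif(1) < 0.3)
  list(iso = iso, genome = genome)
}

# random rooted binary tree with 0/1 leaf states (at least one 1)
rand_tree_states <- function(n) {
  tr <- ape::rtree(n, rooted = TRUE)
  repeat {
    st <- stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    if (sum(st) >= 1) break
  }
  list(tree = tr, states = st)
}

# gene carrying a retained-intron isoform (prefer the fungal-like locus;
# branch-wise intron loss can occasionally remove its host intron)
pick_retention_gene <- function(sim, prefer = "fungus_A") {
  with_ret <- unique(sim$catalog$gene_id[sim$catalog$kind == "RETENTION"])
  if (prefer %in% with_ret) prefer else with_ret[1]
}

# small deterministic gene for unit tests: 3 exons, CDS length 282 (94 codons)
toy_gene <- function(strand = "+") {
  exons <- cbind(start = c(0L, 200L, 400L), end = c(100L, 300L, 500L))
  if (strand == "-") exons <- exons[3:1, , drop = FALSE]
  gene_model("toy", "sp", "chrT", strand, exons, cds_start = 10L, cds_end = 492L)
}
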