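# Sampling observable data (ESTs, abundances) from a simulated family, plus
# truth serialization and the bundled scenarios.

# post-degradation isoform mixture weights for one gene in one condition
condition_weights <- function(cat_g, condition, cfg) {
  w <- cat_g$weight
  if (condition == "wt") w[cat_g$nmd_target] <- w[cat_g$nmd_target] * (1 - cfg$nmd_efficiency)
  if (sum(w) <= 0) sv_stop("degenerate isoform mixture", "config_error")
  w / sum(w)
}

# genomic blocks (genomic-ascending) of mRNA window [a, b) of an isoform
mrna_window_blocks <- function(iso, a, b) {
  lens <- iso$blocks[, "end"] - iso$blocks[, "start"]
  off <- c(0L, cumsum(lens))
  keep <- list()
  for (k in seq_len(nrow(iso$blocks))) {
    lo <- max(a, off[k]); hi <- min(b, off[k + 1L])
    if (hi <= lo) next
    if (iso$strand == "+") {
      s <- iso$blocks[k, "start"] + (lo - off[k])
      keep[[length(keep) + 1L]] <- c(s, s + (hi - lo))
    } else {
      e <- iso$blocks[k, "end"] - (lo - off[k])
      keep[[length(keep) + 1L]] <- c(e - (hi - lo), e)
    }
  }
  m <- do.call(rbind, keep)
  m <- m[order(m[, 1]), , drop = FALSE]
  colnames(m) <- c("start", "end")
  m
}

#' Sample EST-like spliced alignments from a simulated family
#'
#' Per gene, `n_ests` reads are drawn from the isoform mixture; in the
#' wild-type condition, NMD-target isoform weights are first thinned by
#' `nmd_efficiency`. A fraction of reads is full-length, the rest cover a
#' uniformly positioned window; reads from early-polyA isoforms are anchored
#' at the transcript 3' end and flagged `";pA=1"`.
#'
#' @param sim A [simulate_family()] result.
#' @param condition `"wt"` or `"nmd_deficient"`.
#' @param seed RNG seed (defaults derive from the simulation seed so the two
#'   conditions differ).
#' @param n_ests Reads per gene (default from config).
#' @return List of ESTs in the [read_ests()] structure.
#' @export
emit_ests <- function(sim, condition = c("wt", "nmd_deficient"),
                      seed = NULL, n_ests = NULL) {
  condition <- match.arg(condition)
  cfg <- sim$config
  if (is.null(seed)) seed <- cfg$seed + if (condition == "wt") 7001L else 7002L
  if (is.null(n_ests)) n_ests <- cfg$n_ests
  set.seed(seed)
  ests <- list()
  for (gid in names(sim$models)) {
    cat_g <- sim$catalog[sim$catalog$gene_id == gid, , drop = FALSE]
    w <- condition_weights(cat_g, condition, cfg)
    if (n_ests < 1L) next
    draws <- sample(cat_g$isoform_id, n_ests, replace = TRUE, prob = w)
    for (j in seq_len(n_ests)) {
      iso <- sim$isoforms[[draws[j]]]
      L <- isoform_length(iso)
      is_pa <- cat_g$kind[match(draws[j], cat_g$isoform_id)] == "POLYA"
      full <- runif(1) < cfg$full_length_rate
      wlen <- if (full) L else min(cfg$est_len, L)
      if (is_pa) { a <- L - wlen; b <- L }
      else { a <- sample.int(L - wlen + 1L, 1L) - 1L; b <- a + wlen }
      ests[[length(ests) + 1L]] <- list(
        name = paste0(draws[j], "|", j, if (is_pa) ";pA=1" else ""),
        chrom = iso$chrom, strand = iso$strand,
        blocks = mrna_window_blocks(iso, a, b), polyA = is_pa)
    }
  }
  ests
}

#' Per-isoform abundance tables for two conditions
#'
#' Multinomial counts per gene and condition; NMD-target isoforms are thinned
#' by `nmd_efficiency` in the wild type only. With `deterministic = TRUE`
#' the exact expected counts are returned instead of sampling.
#'
#' @param sim A [simulate_family()] result.
#' @param n_reads Reads per gene per condition.
#' @param deterministic Return expected counts instead of multinomial draws.
#' @param seed RNG seed.
#' @return Data frame `gene_id`, `isoform_id`, `kind`, `nmd_target`,
#'   `count_wt`, `count_nmd_deficient`.
#' @export
emit_abundances <- function(sim, n_reads = NULL, deterministic = FALSE,
                            seed = NULL) {
  cfg <- sim$config
  if (is.null(n_reads)) n_reads <- cfg$n_reads
  if (is.null(seed)) seed <- cfg$seed + 7003L
  set.seed(seed)
  rows <- list()
  for (gid in names(sim$models)) {
    cat_g <- sim$catalog[sim$catalog$gene_id == gid, , drop = FALSE]
    w_wt <- condition_weights(cat_g, "wt", cfg)
    w_nd <- condition_weights(cat_g, "nmd_deficient", cfg)
    cnt <- function(w) if (deterministic) w * n_reads else
      as.numeric(rmultinom(1, n_reads, w))
    rows[[gid]] <- data.frame(gene_id = gid, isoform_id = cat_g$isoform_id,
                              kind = cat_g$kind, nmd_target = cat_g$nmd_target,
                              count_wt = cnt(w_wt),
                              count_nmd_deficient = cnt(w_nd),
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

## ---- truth serialization --------------------------------------------------

#' Write simulation ground truth as JSON
#' @param truth The `truth` element of a [simulate_family()] result.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read simulation ground truth back from JSON
#' @param path JSON file written by [write_truth()].
#' @return Truth list with the original data frames.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("genes", "introns", "events", "branch_log"))
    x[[f]] <- as.data.frame(x[[f]], stringsAsFactors = FALSE)
  x
}

#' Write all simulator outputs to a directory
#'
#' Emits `genomes.fa`, `models.gff3`, `proteins.fa`, `msa.fa`,
#' `ests_wt.bed` / `ests_nmd_deficient.bed`, `abundances.tsv`,
#' `gene_tree.nwk`, `species_tree.nwk`, and `truth.json` — all deterministic
#' plain-text formats.
#'
#' @param sim A [simulate_family()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$genomes, file.path(dir, "genomes.fa"))
  write_gff(sim$models, file.path(dir, "models.gff3"))
  write_fasta(sim$proteins, file.path(dir, "proteins.fa"))
  write_fasta(sim$msa, file.path(dir, "msa.fa"))
  write_ests(emit_ests(sim, "wt"), file.path(dir, "ests_wt.bed"))
  write_ests(emit_ests(sim, "nmd_deficient"),
             file.path(dir, "ests_nmd_deficient.bed"))
  ab <- emit_abundances(sim)
  write.table(ab, file.path(dir, "abundances.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(sim$truth$gene_tree, file.path(dir, "gene_tree.nwk"))
  writeLines(sim$truth$species_tree, file.path(dir, "species_tree.nwk"))
  write_truth(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

## ---- bundled scenarios ----------------------------------------------------

#' The bundled SRSF-like replacement scenario
#'
#' A synthetic analogue of the SRSF4/5/6 family history: an ancestral
#' SRSF5-like gene with a poison exon in its fifth (long) intron, conserved
#' across 12 species including a fungal outgroup; a chordate-stem duplication
#' whose new copy loses the host intron (and with it the ancestral event)
#' while rebuilding its gene structure and gaining a replacement poison exon
#' before the vertebrate-stem duplication; and a mammal-only birth of a third
#' event in the youngest copy.
#'
#' @param seed RNG seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
srsf_scenario <- function(seed = 1L, ...) {
  sim_config(
    seed = seed,
    ancestral_poisons = list(list(group = "anc", host = 5L)),
    duplications = list(
      list(branch = "chordates", copy = "A", new_copy = "B")),
    script = c(
      # structure churn in the new chordate copy: the ancestral host intron
      # (and two others) are lost, new introns gained
      lapply(c("i5", "i2", "i6"), function(id)
        list(branch = "chordates", copy = "B", action = "intron_loss",
             intron = id)),
      lapply(1:3, function(i)
        list(branch = "chordates", copy = "B", action = "intron_gain")),
      list(
        # the replacement event is born before the second duplication, so the
        # two youngest copies share it (homologous poison exons)
        list(branch = "vertebrates", copy = "B", action = "poison_birth",
             group = "g2"),
        list(branch = "vertebrates", copy = "B", action = "duplicate",
             new_copy = "C"),
        list(branch = "mammals", copy = "C", action = "poison_birth",
             group = "g3"))),
    regime = "REPLACEMENT", ...)
}

#' Scenario generator for the three origin-model regimes
#'
#' Builds a randomized scripted scenario under the requested generating
#' regime on the default species tree with the default duplications:
#' * `SINGLE_ORIGIN`: one ancestral poison exon, never lost;
#' * `INDEPENDENT`: two births on disjoint clades (one in the ancestral copy,
#'   one in the youngest duplicate), no ancestral event;
#' * `REPLACEMENT`: an ancestral event plus a scripted loss coupled to a
#'   compensating birth on one random internal branch.
#'
#' @param regime One of `SINGLE_ORIGIN`, `INDEPENDENT`, `REPLACEMENT`.
#' @param seed RNG seed (drives both the scripted branch/host choices and the
#'   simulation itself).
#' @param ... Overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
regime_config <- function(regime = c("SINGLE_ORIGIN", "INDEPENDENT", "REPLACEMENT"),
                          seed = 1L, ...) {
  regime <- match.arg(regime)
  set.seed(seed + 5000L)
  dups <- list(list(branch = "chordates", copy = "A", new_copy = "B"),
               list(branch = "vertebrates", copy = "B", new_copy = "C"))
  # internal branches strictly within the animal clade (>= 2 species below)
  a_branches <- c("bilateria", "ecdysozoa", "deuterostomia", "chordates",
                  "vertebrates", "tetrapods", "amniotes", "mammals",
                  "euarchontoglires")
  c_branches <- c("tetrapods", "amniotes", "mammals", "euarchontoglires")
  host_a <- sample(2:5, 1L)   # interior ancestral introns are safe hosts
  if (regime == "SINGLE_ORIGIN") {
    sim_config(seed = seed, duplications = dups,
               ancestral_poisons = list(list(group = "anc", host = host_a)),
               regime = regime, ...)
  } else if (regime == "INDEPENDENT") {
    hosts <- sample(2:6, 2L)   # distinct hosts so the two groups cannot merge
    sim_config(seed = seed, duplications = dups,
               script = list(
                 list(branch = sample(a_branches, 1L), copy = "A",
                      action = "poison_birth", group = "grpA",
                      host = paste0("i", hosts[1]),
                      avoid = paste0("i", hosts[2])),
                 list(branch = sample(c_branches, 1L), copy = "C",
                      action = "poison_birth", group = "grpC",
                      host = paste0("i", hosts[2]),
                      avoid = paste0("i", hosts[1]))),
               regime = regime, ...)
  } else {
    br <- sample(a_branches, 1L)
    sim_config(seed = seed, duplications = dups,
               ancestral_poisons = list(list(group = "anc", host = host_a)),
               script = list(
                 list(branch = br, copy = "A", action = "poison_death",
                      group = "anc"),
                 # the replacement must land in a different intron, else it
                 # would be indistinguishable from the ancestral event
                 list(branch = br, copy = "A", action = "poison_birth",
                      group = "grpNew", avoid = paste0("i", host_a))),
               regime = regime, ...)
  }
}
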