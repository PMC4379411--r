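# Gene-family evolution simulator with ground truth.
#
# Emulates an SRSF4/5/6-like family: one ancestral 8-exon gene evolving down
# a deep species tree with two nested duplications, branch-wise intron gain
# and loss, and poison-exon birth/death/replacement. Every event is logged so
# downstream inference (intron characters, event calls, NMD verdicts, Dollo
# histories, origin-model verdicts) can be scored against truth.
#
# Deliberate simplifications (see the methods vignette): coding sequence
# evolves by stop-rejecting nucleotide substitution with no indels, so family
# proteins stay equal-length and the identity alignment is exact; poison
# exons are copied without substitution, emulating their extreme sequence
# constraint (ultraconservation); intron interiors carry an early stop block
# covering all three frames so that intron retention always introduces a
# premature termination codon, as observed for the fungal retained intron.

BASES <- c("A", "C", "G", "T")
SENSE_CODONS <- setdiff(names(GENCODE)[GENCODE != "*"], "")
INTRON_STOP_BLOCK <- "TAAATAAATAA"  # stop codon in every frame within 11 nt

#' Simulation configuration
#'
#' Defaults define the study conditions: a 12-species opisthokont-like tree
#' with a fungal outgroup, duplications on the chordate and vertebrate stems,
#' an 8-exon ancestral gene, log-normal intron lengths, and EST/abundance
#' sampling with NMD-dependent degradation in the wild type.
#'
#' @param seed Integer RNG seed; identical config + seed gives byte-identical
#'   outputs.
#' @param species_tree Newick string with labeled internal nodes (branch ids).
#' @param n_codons Ancestral CDS length in codons (excluding the stop).
#' @param n_exons Ancestral exon count (introns = `n_exons - 1`).
#' @param utr_len Length of the 5' and 3' UTRs (nt).
#' @param intron_meanlog,intron_sdlog Log-normal intron length prior (ln nt).
#' @param min_intron_len Floor on intron length (nt).
#' @param long_intron_len Length of the designated "long" intron (the
#'   ancestral poison-exon host), exercising the length-percentile report.
#' @param poison_len Poison cassette exon length (nt; `3k + 1` so inclusion
#'   also shifts the downstream frame).
#' @param substitution_rate Substitutions per site per unit branch length.
#' @param intron_gain_rate,intron_loss_rate Events per branch length.
#' @param poison_birth_rate,poison_death_rate Events per branch length
#'   (scripted scenarios use 0 and place events explicitly).
#' @param replacement_coupling Probability that a poison death is coupled to
#'   a compensating birth on the same branch.
#' @param inclusion_rate,retention_rate,polyA_rate Isoform mixture weights
#'   per poison exon (cassette inclusion, host-intron retention, early
#'   polyadenylation inside the exon).
#' @param nmd_efficiency Fraction of NMD-target transcripts degraded in the
#'   wild type (0 in the NMD-deficient condition).
#' @param n_ests ESTs sampled per gene per condition.
#' @param est_len EST window length (nt); `full_length_rate` of reads span
#'   the whole transcript.
#' @param full_length_rate Fraction of full-length reads.
#' @param n_reads Reads per gene per condition for abundance tables.
#' @param nmd_threshold_nt Junction-rule threshold the simulator guarantees
#'   for truth NMD targets (with `nmd_margin` nt to spare).
#' @param nmd_margin Safety margin (nt) on the junction rule at event birth.
#' @param duplications List of scripted duplications
#'   (`list(branch=, copy=, new_copy=)`).
#' @param script List of scripted events applied in order on their branches;
#'   each is `list(branch=, copy=, action=)` with action-specific fields
#'   (`action` in `poison_birth`, `poison_death`, `intron_gain`,
#'   `intron_loss`).
#' @param ancestral_poisons List of `list(group=, host=)` poison exons
#'   present in the ancestor (`host` = 1-based ancestral intron index).
#' @param regime Generating regime label recorded in truth
#'   (`SINGLE_ORIGIN`, `INDEPENDENT`, `REPLACEMENT`, or `NONE`).
#' @param spacer_len Intergenic spacer on the synthetic chromosomes (nt).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       species_tree = default_species_tree(),
                       n_codons = 360L, n_exons = 8L, utr_len = 25L,
                       intron_meanlog = 4.0, intron_sdlog = 0.6,
                       min_intron_len = 20L, long_intron_len = 320L,
                       poison_len = 211L,
                       substitution_rate = 0.06,
                       intron_gain_rate = 0.02, intron_loss_rate = 0.02,
                       poison_birth_rate = 0, poison_death_rate = 0,
                       replacement_coupling = 0,
                       inclusion_rate = 0.25, retention_rate = 0.15,
                       polyA_rate = 0.05,
                       nmd_efficiency = 0.8,
                       n_ests = 300L, est_len = 400L, full_length_rate = 0.2,
                       n_reads = 2000L,
                       nmd_threshold_nt = 50L, nmd_margin = 10L,
                       duplications = list(), script = list(),
                       ancestral_poisons = list(),
                       regime = "NONE", spacer_len = 300L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_exons >= 2, cfg$n_codons >= 50,
            all(c(inclusion_rate, retention_rate, polyA_rate,
                  nmd_efficiency, replacement_coupling) >= 0),
            inclusion_rate + retention_rate + polyA_rate < 0.5)
  class(cfg) <- "sim_config"
  cfg
}

#' Default 12-species opisthokont-like species tree
#' @return Newick string with labeled internal nodes.
#' @export
default_species_tree <- function() {
  paste0("(fungus:1.0,(anemone:0.9,((worm:0.7,fly:0.7)ecdysozoa:0.2,",
         "(urchin:0.75,(lancelet:0.65,(zebrafish:0.5,(frog:0.4,(chicken:0.3,",
         "(dog:0.2,(mouse:0.1,human:0.1)euarchontoglires:0.1)mammals:0.1)",
         "amniotes:0.1)tetrapods:0.1)vertebrates:0.15)chordates:0.1)",
         "deuterostomia:0.15)bilateria:0.2)metazoa:0.1)root;")
}

## ---- low-level sequence helpers -------------------------------------------

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rand_cds <- function(n_codons) {
  paste(c("ATG", sample(SENSE_CODONS, n_codons - 1L, replace = TRUE)),
        collapse = "")
}

# intron: GT + stop block (stop in all 3 frames) + random interior + AG
make_intron_seq <- function(cfg, len = NULL) {
  if (is.null(len))
    len <- max(cfg$min_intron_len, round(rlnorm(1, cfg$intron_meanlog, cfg$intron_sdlog)))
  len <- as.integer(len)
  paste0("GT", INTRON_STOP_BLOCK, rand_dna(len - 15L), "AG")
}

# mutate n positions of seq, never touching `protect` (1-based), and (for
# coding sequence) never creating a stop codon in the productive frame
mutate_seq <- function(seq, n, protect = integer(0), coding = FALSE) {
  if (n <= 0L || nchar(seq) <= length(protect)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ok <- setdiff(seq_along(ch), protect)
  pos <- sample(ok, min(n, length(ok)), replace = TRUE)
  for (p in pos) {
    for (try in 1:10) {
      nb <- sample(setdiff(BASES, ch[p]), 1)
      if (coding) {
        ci <- (p - 1L) %/% 3L
        cod <- ch[(ci * 3L + 1L):(ci * 3L + 3L)]
        cod[(p - 1L) %% 3L + 1L] <- nb
        if (GENCODE[[paste(cod, collapse = "")]] == "*") next
      }
      ch[p] <- nb
      break
    }
  }
  paste(ch, collapse = "")
}

## ---- lineage state --------------------------------------------------------

# a gene lineage: copy label, UTRs, CDS (no stop), ordered introns; each
# intron: id, cds_pos (nt offset into CDS+stop where it sits), seq5, and an
# optional poison exon (group, seq, stop_off) followed by seq3
new_lineage <- function(copy, cfg) {
  cds <- rand_cds(cfg$n_codons)
  n_int <- cfg$n_exons - 1L
  cds_len <- nchar(cds) + 3L
  # roughly even positions with random phase jitter, all interior
  base <- round(seq_len(n_int) * cds_len / cfg$n_exons)
  pos <- pmin(pmax(base + sample(-5:5, n_int, replace = TRUE), 6L), cds_len - 6L)
  while (any(duplicated(pos))) pos <- pos + cumsum(duplicated(pos)) * 3L
  introns <- lapply(seq_len(n_int), function(k) {
    len <- if (k == 5L && n_int >= 5L) cfg$long_intron_len else NULL
    list(id = paste0("i", k), cds_pos = as.integer(sort(pos)[k]),
         seq5 = make_intron_seq(cfg, len), exon = NULL, seq3 = NULL)
  })
  list(copy = copy, utr5 = rand_dna(cfg$utr_len), cds = cds,
       utr3 = rand_dna(cfg$utr_len), introns = introns)
}

lineage_intron_positions <- function(lin) {
  vapply(lin$introns, function(i) i$cds_pos, 0L)
}

# exon-chain lengths of the productive transcript (transcription order)
exon_chain_lengths <- function(lin, cfg) {
  pos <- lineage_intron_positions(lin)
  cds_len <- nchar(lin$cds) + 3L
  bounds <- c(0L, pos, cds_len)
  lens <- diff(bounds)
  lens[1] <- lens[1] + cfg$utr_len
  lens[length(lens)] <- lens[length(lens)] + cfg$utr_len
  lens
}

# can intron k host a poison exon whose cassette and retention isoforms both
# satisfy the junction rule with margin?
poison_host_ok <- function(lin, k, cfg) {
  pos <- lineage_intron_positions(lin)
  K <- length(pos)
  if (k >= K) return(FALSE)                 # need a downstream junction
  lens <- exon_chain_lengths(lin, cfg)
  total <- sum(lens)
  need <- cfg$nmd_threshold_nt + cfg$nmd_margin
  stop_cas <- cfg$utr_len + pos[k] + 8L     # worst-case in-exon stop end
  lastj_cas <- total + cfg$poison_len - lens[length(lens)]
  ilen <- nchar(intron_full_seq(lin$introns[[k]]))
  stop_ret <- cfg$utr_len + pos[k] + 16L    # stop block ends within 16 nt
  lastj_ret <- total + ilen - lens[length(lens)]
  (lastj_cas - stop_cas >= need) && (lastj_ret - stop_ret >= need)
}

intron_full_seq <- function(intr) {
  if (is.null(intr$exon)) intr$seq5
  else paste0(intr$seq5, intr$exon$seq, intr$seq3)
}

add_poison <- function(lin, k, group, cfg) {
  p <- lin$introns[[k]]$cds_pos %% 3L
  f <- (3L - p) %% 3L
  s <- f + 3L                               # 0-based offset of the stop codon
  ex <- strsplit(rand_dna(cfg$poison_len), "", fixed = TRUE)[[1]]
  ex[(s + 1L):(s + 3L)] <- c("T", "A", "A")
  lin$introns[[k]]$exon <- list(group = group,
                                seq = paste(ex, collapse = ""), stop_off = s)
  lin$introns[[k]]$seq3 <- make_intron_seq(cfg)
  lin
}

remove_poison <- function(lin, k) {
  lin$introns[[k]]$exon <- NULL
  lin$introns[[k]]$seq3 <- NULL
  lin
}

eligible_hosts <- function(lin, cfg, free_only = TRUE) {
  ks <- seq_along(lin$introns)
  keep <- vapply(ks, function(k) {
    (!free_only || is.null(lin$introns[[k]]$exon)) && poison_host_ok(lin, k, cfg)
  }, TRUE)
  ks[keep]
}

## ---- branch evolution -----------------------------------------------------

sim_env_new <- function() {
  env <- new.env(parent = emptyenv())
  env$log <- list()
  env$intron_counter <- 0L
  env$poison_counter <- 0L
  env
}

log_event <- function(env, branch, copy, action, detail) {
  env$log[[length(env$log) + 1L]] <-
    data.frame(branch = branch, copy = copy, action = action,
               detail = detail, stringsAsFactors = FALSE)
}

apply_intron_gain <- function(lin, cfg, env, branch, pos = NULL) {
  cds_len <- nchar(lin$cds) + 3L
  if (is.null(pos)) {
    cand <- setdiff(seq.int(6L, cds_len - 6L, by = 3L),
                    lineage_intron_positions(lin))
    if (!length(cand)) return(lin)
    pos <- sample(cand, 1L)
  }
  env$intron_counter <- env$intron_counter + 1L
  id <- paste0("n", env$intron_counter)
  intr <- list(id = id, cds_pos = as.integer(pos),
               seq5 = make_intron_seq(cfg), exon = NULL, seq3 = NULL)
  lin$introns <- append(lin$introns, list(intr),
                        after = sum(lineage_intron_positions(lin) < pos))
  log_event(env, branch, lin$copy, "intron_gain", id)
  lin
}

apply_intron_loss <- function(lin, cfg, env, branch, id) {
  k <- match(id, vapply(lin$introns, function(i) i$id, ""))
  if (is.na(k)) return(lin)
  if (length(lin$introns) <= 3L) {
    warning("intron loss skipped: would leave too few introns")
    return(lin)
  }
  if (!is.null(lin$introns[[k]]$exon))
    log_event(env, branch, lin$copy, "poison_death", lin$introns[[k]]$exon$group)
  log_event(env, branch, lin$copy, "intron_loss", id)
  lin$introns[[k]] <- NULL
  lin
}

apply_poison_birth <- function(lin, cfg, env, branch, group = NULL,
                               host = NULL, avoid = character(0)) {
  ids <- vapply(lin$introns, function(i) i$id, "")
  hosts <- eligible_hosts(lin, cfg)
  k <- NA_integer_
  if (!is.null(host)) {
    k <- match(host, ids)
    if (is.na(k) || !(k %in% hosts)) k <- NA_integer_   # fall back to random
  }
  if (is.na(k)) {
    hosts <- setdiff(hosts, which(ids %in% avoid))
    if (!length(hosts)) { warning("no eligible poison host; birth skipped"); return(lin) }
    k <- if (length(hosts) == 1L) hosts else sample(hosts, 1L)
  }
  if (is.null(group)) {
    env$poison_counter <- env$poison_counter + 1L
    group <- paste0("p", env$poison_counter)
  }
  lin <- add_poison(lin, k, group, cfg)
  log_event(env, branch, lin$copy, "poison_birth",
            paste0(group, "@", lin$introns[[k]]$id))
  lin
}

apply_poison_death <- function(lin, cfg, env, branch, group) {
  ks <- which(vapply(lin$introns, function(i)
    !is.null(i$exon) && i$exon$group == group, TRUE))
  if (!length(ks)) return(lin)
  lin <- remove_poison(lin, ks[1])
  log_event(env, branch, lin$copy, "poison_death", group)
  if (runif(1) < cfg$replacement_coupling)
    lin <- apply_poison_birth(lin, cfg, env, branch)
  lin
}

# evolve all lineages along one branch; returns list(lins, derived) where
# derived maps each pre-branch copy to the copies descending from it (itself
# plus any duplicates created on this branch)
evolve_branch <- function(lins, branch, blen, cfg, env) {
  derived <- setNames(as.list(names(lins)), names(lins))
  do_duplicate <- function(copy, new_copy) {
    newlin <- lins[[copy]]
    newlin$copy <- new_copy
    lins[[new_copy]] <<- newlin
    orig <- names(derived)[vapply(derived, function(v) copy %in% v, TRUE)][1]
    derived[[orig]] <<- c(derived[[orig]], new_copy)
    log_event(env, branch, copy, "duplication", new_copy)
  }
  # duplications declared outside the script sit at the top of the branch
  for (d in cfg$duplications) {
    if (!identical(d$branch, branch) || !d$copy %in% names(lins)) next
    do_duplicate(d$copy, d$new_copy)
  }
  # scripted events in order (may include mid-branch duplications)
  for (a in cfg$script) {
    if (!identical(a$branch, branch) || !a$copy %in% names(lins)) next
    if (identical(a$action, "duplicate")) {
      do_duplicate(a$copy, a$new_copy)
      next
    }
    lins[[a$copy]] <- switch(a$action,
      poison_birth = apply_poison_birth(lins[[a$copy]], cfg, env, branch,
                                        group = a$group, host = a$host %||% NULL,
                                        avoid = a$avoid %||% character(0)),
      poison_death = apply_poison_death(lins[[a$copy]], cfg, env, branch, a$group),
      intron_gain = apply_intron_gain(lins[[a$copy]], cfg, env, branch,
                                      pos = a$pos %||% NULL),
      intron_loss = apply_intron_loss(lins[[a$copy]], cfg, env, branch, a$intron),
      sv_stop(paste("unknown scripted action:", a$action), "config_error"))
  }
  # stochastic processes per lineage
  for (nm in names(lins)) {
    lin <- lins[[nm]]
    # intron loss
    ploss <- 1 - exp(-cfg$intron_loss_rate * blen)
    for (id in vapply(lin$introns, function(i) i$id, "")) {
      if (runif(1) < ploss) lin <- apply_intron_loss(lin, cfg, env, branch, id)
    }
    # intron gain
    ngain <- rpois(1, cfg$intron_gain_rate * blen)
    for (j in seq_len(ngain)) lin <- apply_intron_gain(lin, cfg, env, branch)
    # poison death / birth
    pdeath <- 1 - exp(-cfg$poison_death_rate * blen)
    for (i in seq_along(lin$introns)) {
      ex <- lin$introns[[i]]$exon
      if (!is.null(ex) && runif(1) < pdeath)
        lin <- apply_poison_death(lin, cfg, env, branch, ex$group)
    }
    nbirth <- rpois(1, cfg$poison_birth_rate * blen)
    for (j in seq_len(nbirth)) lin <- apply_poison_birth(lin, cfg, env, branch)
    # substitutions: CDS (stop-rejecting, start codon protected), UTRs,
    # intron interiors (splice sites, stop block, poison exon protected)
    nsub <- rpois(1, cfg$substitution_rate * nchar(lin$cds) * blen)
    lin$cds <- mutate_seq(lin$cds, nsub, protect = 1:3, coding = TRUE)
    for (u in c("utr5", "utr3")) {
      nu <- rpois(1, cfg$substitution_rate * nchar(lin[[u]]) * blen)
      lin[[u]] <- mutate_seq(lin[[u]], nu)
    }
    for (i in seq_along(lin$introns)) {
      for (part in c("seq5", "seq3")) {
        s <- lin$introns[[i]][[part]]
        if (is.null(s)) next
        L <- nchar(s)
        prot <- c(1:13, (L - 1L):L)   # GT + stop block ... AG
        np <- rpois(1, cfg$substitution_rate * L * blen)
        lin$introns[[i]][[part]] <- mutate_seq(s, np, protect = prot)
      }
    }
    lins[[nm]] <- lin
  }
  list(lins = lins, derived = derived)
}

## ---- the simulator --------------------------------------------------------

#' Simulate evolution of a gene family with ground truth
#'
#' Evolves an ancestral multi-exon gene down the configured species tree
#' (duplications, substitutions, intron gain/loss, poison-exon
#' birth/death/replacement), assembles per-species synthetic chromosomes
#' (genes alternate strands), and records complete ground truth.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `splice_sim`: `config`, `genomes` (named
#'   chromosome sequences), `models` (named list of [gene_model()]),
#'   `isoforms` (named list of [isoform()]), `catalog` (per-isoform data
#'   frame with mixture weights and truth NMD status), `proteins`, `msa`
#'   (identity alignment), `truth` (genes / introns / events tables, branch
#'   log, regime, true gene tree newick), `species_tree`.
#' @export
simulate_family <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tree <- ape::read.tree(text = cfg$species_tree)
  env <- sim_env_new()
  anc <- new_lineage("A", cfg)
  for (ap in cfg$ancestral_poisons) {
    anc <- add_poison(anc, ap$host, ap$group, cfg)
    log_event(env, "root", "A", "poison_birth",
              paste0(ap$group, "@", anc$introns[[ap$host]]$id))
  }
  env$genes <- list()       # gene_id -> list(lin, species)
  ntip <- length(tree$tip.label)
  children <- tree_children(tree)
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
  edge_len <- setNames(tree$edge.length, tree$edge[, 2])

  rec <- function(node, lins) {
    # returns per-copy newick subtree strings (copies as named at this node)
    if (node <= ntip) {
      sp <- tree$tip.label[node]
      out <- list()
      for (nm in names(lins)) {
        gid <- paste0(sp, "_", nm)
        env$genes[[gid]] <- list(lin = lins[[nm]], species = sp)
        out[[nm]] <- gid
      }
      return(out)
    }
    per_child <- list()
    for (ch in children[[node]]) {
      branch <- node_id(tree, ch)
      blen <- edge_len[[as.character(ch)]]
      ev <- evolve_branch(lins, branch, blen, cfg, env)
      subres <- rec(ch, ev$lins)
      # collapse duplicates created on this branch back onto original copies
      res <- list()
      for (orig in names(lins)) {
        grp <- ev$derived[[orig]]
        parts <- unlist(subres[grp], use.names = FALSE)
        res[[orig]] <- if (length(parts) > 1)
          paste0("(", paste(paste0(parts, ":0"), collapse = ","), ")")
        else parts
        res[[orig]] <- paste0(res[[orig]], ":", format(blen, trim = TRUE))
      }
      per_child[[length(per_child) + 1L]] <- res
    }
    out <- list()
    for (nm in names(lins)) {
      parts <- unlist(lapply(per_child, function(x) x[[nm]]), use.names = FALSE)
      out[[nm]] <- if (length(parts) > 1)
        paste0("(", paste(parts, collapse = ","), ")")
      else parts
    }
    out
  }
  top <- rec(root, list(A = anc))
  gene_tree_nwk <- paste0(if (length(top) > 1)
    paste0("(", paste(unlist(top), collapse = ","), ")")
    else unlist(top), ";")

  assemble_sim(env, tree, cfg, gene_tree_nwk)
}

# turn evolved lineages into chromosomes, gene models, isoforms, and truth
assemble_sim <- function(env, tree, cfg, gene_tree_nwk) {
  genomes <- character(0)
  models <- list(); isoforms <- list()
  catalog <- list(); truth_genes <- list(); truth_introns <- list()
  truth_events <- list()
  species_order <- tree$tip.label
  copy_subfam <- function(copy) if (copy == "A") "SRSF5like" else "SRSF46like"
  for (sp in species_order) {
    gids <- names(env$genes)[vapply(env$genes, function(g) g$species == sp, TRUE)]
    gids <- sort(gids)
    chrom <- paste0("chr_", sp)
    seq_parts <- character(0)
    offset <- 0L
    for (gi in seq_along(gids)) {
      gid <- gids[gi]
      lin <- env$genes[[gid]]$lin
      strand <- if (gi %% 2L == 1L) "+" else "-"
      spacer <- rand_dna(cfg$spacer_len)
      seq_parts <- c(seq_parts, spacer)
      offset <- offset + cfg$spacer_len
      asm <- assemble_gene(lin, gid, sp, strand, chrom, offset, cfg)
      seq_parts <- c(seq_parts, asm$chrom_seq)
      offset <- offset + nchar(asm$chrom_seq)
      models[[gid]] <- asm$model
      isoforms <- c(isoforms, asm$isoforms)
      catalog[[gid]] <- asm$catalog
      truth_genes[[gid]] <- data.frame(
        gene_id = gid, species = sp, copy = lin$copy,
        subfamily = copy_subfam(lin$copy), stringsAsFactors = FALSE)
      truth_introns[[gid]] <- asm$introns
      if (nrow(asm$events)) truth_events[[gid]] <- asm$events
    }
    genomes[[chrom]] <- paste(seq_parts, collapse = "")
  }
  proteins <- vapply(models, function(m) "", "")
  genome_vec <- unlist(genomes)
  for (gid in names(models))
    proteins[[gid]] <- gene_protein(genome_vec, models[[gid]])
  truth <- list(
    schema_version = "1",
    regime = cfg$regime,
    genes = do.call(rbind, truth_genes),
    introns = do.call(rbind, truth_introns),
    events = if (length(truth_events)) do.call(rbind, truth_events) else
      data.frame(gene_id = character(0), group = character(0),
                 kind = character(0), host_intron_id = character(0),
                 host_ordinal = integer(0), start = integer(0),
                 end = integer(0), nmd_target = logical(0)),
    branch_log = if (length(env$log)) do.call(rbind, env$log) else
      data.frame(branch = character(0), copy = character(0),
                 action = character(0), detail = character(0)),
    gene_tree = gene_tree_nwk,
    species_tree = cfg$species_tree)
  rownames(truth$genes) <- rownames(truth$introns) <- NULL
  if (nrow(truth$events)) rownames(truth$events) <- NULL
  structure(list(config = cfg, genomes = genome_vec, models = models,
                 isoforms = isoforms,
                 catalog = do.call(rbind, c(catalog, list(make.row.names = FALSE))),
                 proteins = proteins, msa = proteins, truth = truth),
            class = "splice_sim")
}

# assemble one gene: chromosome segment, gene_model, isoforms, truth rows
assemble_gene <- function(lin, gid, sp, strand, chrom, offset, cfg) {
  coding <- paste0(lin$cds, "TAA")
  cds_len <- nchar(coding)
  pos <- lineage_intron_positions(lin)
  K <- length(pos)
  bounds <- c(0L, pos, cds_len)
  coding_pieces <- substring(coding, bounds[-length(bounds)] + 1L, bounds[-1])
  exon_seqs <- coding_pieces
  exon_seqs[1] <- paste0(lin$utr5, exon_seqs[1])
  exon_seqs[K + 1L] <- paste0(exon_seqs[K + 1L], lin$utr3)
  intron_seqs <- vapply(lin$introns, intron_full_seq, "")
  # forward (transcription-orientation) coordinates
  fwd_parts <- character(2L * K + 1L)
  fwd_parts[seq(1L, 2L * K + 1L, by = 2L)] <- exon_seqs
  if (K) fwd_parts[seq(2L, 2L * K, by = 2L)] <- intron_seqs
  part_len <- nchar(fwd_parts)
  part_end <- cumsum(part_len)
  part_start <- part_end - part_len
  L <- sum(part_len)
  exon_fwd <- cbind(start = part_start[seq(1L, 2L * K + 1L, by = 2L)],
                    end = part_end[seq(1L, 2L * K + 1L, by = 2L)])
  intron_fwd <- if (K) cbind(start = part_start[seq(2L, 2L * K, by = 2L)],
                             end = part_end[seq(2L, 2L * K, by = 2L)])
                else matrix(integer(0), ncol = 2)
  cds_fwd <- c(cfg$utr_len, L - cfg$utr_len)
  gene_seq <- paste(fwd_parts, collapse = "")
  tr <- function(iv) {   # forward interval -> chromosome interval
    if (strand == "+") cbind(start = offset + iv[, 1], end = offset + iv[, 2])
    else cbind(start = offset + L - iv[, 2], end = offset + L - iv[, 1])
  }
  exg <- tr(exon_fwd)
  chrom_seq <- if (strand == "+") gene_seq else revcomp(gene_seq)
  cdsg <- tr(matrix(cds_fwd, ncol = 2))
  model <- gene_model(gid, sp, chrom, strand,
                      exons = to_transcription_order(exg, strand),
                      cds_start = cdsg[1, "start"], cds_end = cdsg[1, "end"])
  introns_df <- if (K) data.frame(
    gene_id = gid,
    intron_id = vapply(lin$introns, function(i) i$id, ""),
    ordinal = seq_len(K) - 1L,
    codon_index = pos %/% 3L, phase = pos %% 3L,
    length = nchar(intron_seqs), stringsAsFactors = FALSE)
  else data.frame(gene_id = character(0), intron_id = character(0),
                  ordinal = integer(0), codon_index = integer(0),
                  phase = integer(0), length = integer(0))
  # isoforms + events
  isoforms <- list(); cat_rows <- list(); ev_rows <- list()
  prod_iso <- build_isoform(model, NULL)
  prod_iso$isoform_id <- paste0(gid, ":productive")
  isoforms[[prod_iso$isoform_id]] <- prod_iso
  cat_rows[[1]] <- data.frame(gene_id = gid, isoform_id = prod_iso$isoform_id,
                              kind = "PRODUCTIVE", group = NA_character_,
                              host_ordinal = NA_integer_, nmd_target = FALSE,
                              weight = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    ex <- lin$introns[[k]]$exon
    if (is.null(ex)) next
    exon_fwd_iv <- matrix(c(intron_fwd[k, "start"] + nchar(lin$introns[[k]]$seq5),
                            intron_fwd[k, "start"] + nchar(lin$introns[[k]]$seq5) +
                              nchar(ex$seq)), ncol = 2)
    exon_g <- tr(exon_fwd_iv)
    intron_g <- tr(intron_fwd[k, , drop = FALSE])
    cas_ev <- data.frame(kind = "CASSETTE_EXON", gene_id = gid,
                         host_intron = k - 1L,
                         start = exon_g[1, "start"], end = exon_g[1, "end"],
                         stringsAsFactors = FALSE)
    ret_ev <- data.frame(kind = "INTRON_RETENTION", gene_id = gid,
                         host_intron = k - 1L,
                         start = intron_g[1, "start"], end = intron_g[1, "end"],
                         stringsAsFactors = FALSE)
    # polyA terminus: 30 nt past the in-exon stop codon
    t_fwd <- exon_fwd_iv[1, 1] + ex$stop_off + 3L + 30L - 1L
    t_g <- if (strand == "+") offset + t_fwd else offset + L - 1L - t_fwd
    pa_ev <- data.frame(kind = "ALT_POLYA", gene_id = gid,
                        host_intron = k - 1L, start = t_g, end = t_g + 1L,
                        stringsAsFactors = FALSE)
    specs <- list(list(ev = cas_ev, kind = "CASSETTE", w = cfg$inclusion_rate,
                       nmd = TRUE, cassette = NULL),
                  list(ev = ret_ev, kind = "RETENTION", w = cfg$retention_rate,
                       nmd = TRUE, cassette = NULL),
                  list(ev = pa_ev, kind = "POLYA", w = cfg$polyA_rate,
                       nmd = FALSE, cassette = cas_ev))
    for (spc in specs) {
      iso <- build_isoform(model, spc$ev, cassette = spc$cassette)
      iso$isoform_id <- paste0(gid, ":", tolower(spc$kind), "_", ex$group)
      isoforms[[iso$isoform_id]] <- iso
      cat_rows[[length(cat_rows) + 1L]] <- data.frame(
        gene_id = gid, isoform_id = iso$isoform_id, kind = spc$kind,
        group = ex$group, host_ordinal = k - 1L, nmd_target = spc$nmd,
        weight = spc$w, stringsAsFactors = FALSE)
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        spc$ev, group = ex$group,
        host_intron_id = lin$introns[[k]]$id, nmd_target = spc$nmd,
        stringsAsFactors = FALSE)
    }
  }
  cat_df <- do.call(rbind, cat_rows)
  # the configured rates define the per-gene isoform mixture: genes carrying
  # several poison exons share the unproductive flux equally, so the total
  # event weight (and hence the stabilization fold change) does not scale
  # with poison count
  n_poisons <- length(unique(stats::na.omit(cat_df$group)))
  if (n_poisons > 1)
    cat_df$weight <- cat_df$weight / n_poisons
  wsum <- sum(cat_df$weight, na.rm = TRUE)
  cat_df$weight[is.na(cat_df$weight)] <- 1 - wsum
  ev_df <- if (length(ev_rows)) {
    d <- do.call(rbind, ev_rows)
    data.frame(gene_id = d$gene_id, group = d$group, kind = d$kind,
               host_intron_id = d$host_intron_id, host_ordinal = d$host_intron,
               start = d$start, end = d$end, nmd_target = d$nmd_target,
               stringsAsFactors = FALSE)
  } else data.frame(gene_id = character(0), group = character(0),
                    kind = character(0), host_intron_id = character(0),
                    host_ordinal = integer(0), start = integer(0),
                    end = integer(0), nmd_target = logical(0))
  list(chrom_seq = chrom_seq, model = model, isoforms = isoforms,
       catalog = cat_df, introns = introns_df, events = ev_df)
}

#' @export
print.splice_sim <- function(x, ...) {
  cat(sprintf("<splice_sim> %d genes in %d species; %d truth events; regime %s\n",
              length(x$models), length(unique(x$truth$genes$species)),
              nrow(x$truth$events), x$truth$regime))
  invisible(x)
}
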