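# End-to-end orchestration: simulate -> map introns -> call events ->
# classify NMD -> infer history -> scan conservation -> report.
#
# All randomness is driven by the simulation config seed; outputs are
# deterministic plain-text files, so a rerun with the same config is
# byte-identical (the timestamped log file is the only exception).

#' Pipeline analysis options
#'
#' Single source of truth for every analysis threshold.
#'
#' @param outgroup Gene id used to root the family tree.
#' @param nmd_threshold_nt Junction-rule threshold (nt).
#' @param window Column tolerance for intron-character merging.
#' @param max_gap_fraction Gap-fraction flagging threshold for characters.
#' @param min_overhang Minimum exonic anchor for retention calls (nt).
#' @param min_fold Stabilization fold-change threshold.
#' @param min_len Minimum perfect-identity run length (columns).
#' @param bootstrap_reps Bootstrap replicates for the family tree (0 = skip).
#' @param min_support Minimum EST support for an event to enter history
#'   inference.
#' @param reference_genes Named vector mapping subfamily label to the
#'   reference gene whose character profile defines it.
#' @param conservation_pair Two gene ids whose event-isoform mRNAs are
#'   scanned for perfect-identity runs.
#' @param relaxed_linkage Use the relaxed replacement-linkage rule.
#' @return List of class `pipeline_options`.
#' @export
pipeline_options <- function(outgroup = "fungus_A",
                             nmd_threshold_nt = 50L,
                             window = 0L, max_gap_fraction = 0.5,
                             min_overhang = 10L, min_fold = 2.0,
                             min_len = 200L, bootstrap_reps = 0L,
                             min_support = 1L,
                             reference_genes = c(SRSF5like = "human_A",
                                                 SRSF46like = "human_C"),
                             conservation_pair = c("human_A", "mouse_A"),
                             relaxed_linkage = FALSE) {
  structure(as.list(environment()), class = "pipeline_options")
}

#' Load a pipeline configuration from YAML
#'
#' The document has two blocks: `simulation` (fields of [sim_config()], plus
#' `scenario: srsf` or `scenario: <regime>` to start from a bundled
#' scenario) and `pipeline` (fields of [pipeline_options()]). Unknown keys
#' are a validation error.
#'
#' @param path YAML file.
#' @return List with `config` ([sim_config()]) and `opts`
#'   ([pipeline_options()]).
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), c("simulation", "pipeline"))
  if (length(bad))
    sv_stop(paste("unknown config block(s):", paste(bad, collapse = ", ")),
            "config_error")
  simy <- y$simulation %||% list()
  scen <- simy$scenario %||% NULL
  simy$scenario <- NULL
  allowed <- names(formals(sim_config))
  bad <- setdiff(names(simy), allowed)
  if (length(bad))
    sv_stop(paste("unknown simulation key(s):", paste(bad, collapse = ", ")),
            "config_error")
  config <- if (is.null(scen) || identical(scen, "srsf")) {
    do.call(srsf_scenario, c(list(seed = simy$seed %||% 1L),
                             simy[setdiff(names(simy), "seed")]))
  } else if (scen %in% c("SINGLE_ORIGIN", "INDEPENDENT", "REPLACEMENT")) {
    do.call(regime_config, c(list(regime = scen, seed = simy$seed %||% 1L),
                             simy[setdiff(names(simy), "seed")]))
  } else sv_stop(paste("unknown scenario:", scen), "config_error")
  py <- y$pipeline %||% list()
  bad <- setdiff(names(py), names(formals(pipeline_options)))
  if (length(bad))
    sv_stop(paste("unknown pipeline key(s):", paste(bad, collapse = ", ")),
            "config_error")
  list(config = config, opts = do.call(pipeline_options, py))
}

pipeline_log <- function(con, level, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, msg)
  writeLines(line, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Simulates the configured family (or reuses a supplied simulation), maps
#' intron characters, calls splice events from the emitted ESTs, classifies
#' event isoforms as NMD targets, runs the stabilization comparison, infers
#' the family's origin-model verdict on an outgroup-rooted NJ tree, scans a
#' gene pair for perfect-identity runs, scores everything against simulated
#' truth, and writes a machine-readable report.
#'
#' A rerun into a directory holding a report for the identical configuration
#' skips recomputation and returns the existing report (`force = TRUE`
#' overrides).
#'
#' @param config A [sim_config()] (e.g. [srsf_scenario()]) or a YAML path
#'   for [load_pipeline_config()].
#' @param out_dir Output directory.
#' @param opts A [pipeline_options()].
#' @param force Recompute even when a matching report exists.
#' @return List of class `pipeline_result`: the report plus in-memory tables
#'   (`icm`, `events`, `nmd_calls`, `stabilization`, `origin`, `tree`,
#'   `sim`).
#' @export
run_pipeline <- function(config, out_dir, opts = pipeline_options(),
                         force = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    loaded <- load_pipeline_config(config)
    config <- loaded$config
    opts <- loaded$opts
  }
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config_to_list(config, opts), cfg_path)
  cfg_md5 <- unname(tools::md5sum(cfg_path))
  report_path <- file.path(out_dir, "report.json")
  if (!force && file.exists(report_path)) {
    old <- jsonlite::read_json(report_path, simplifyVector = TRUE)
    if (identical(old$config_md5, cfg_md5) &&
        all(file.exists(file.path(out_dir, names(old$manifest))))) {
      res <- structure(list(report = old, skipped = TRUE), class = "pipeline_result")
      return(res)
    }
  }
  logcon <- file(file.path(out_dir, "pipeline.log"), "w")
  on.exit(close(logcon))
  pipeline_log(logcon, "INFO", sprintf("seed=%d regime=%s outgroup=%s",
                                       config$seed, config$regime, opts$outgroup))

  ## stage 1: simulate ------------------------------------------------------
  pipeline_log(logcon, "INFO", "stage simulate")
  sim <- simulate_family(config)
  sim_dir <- file.path(out_dir, "sim")
  write_sim(sim, sim_dir)

  ## stage 2: intron characters --------------------------------------------
  pipeline_log(logcon, "INFO", "stage map-introns")
  sites <- do.call(rbind, lapply(sim$models, intron_sites))
  anchored <- anchor_sites(sites, sim$msa, proteins = sim$proteins)
  icm <- build_character_matrix(anchored, window = opts$window,
                                max_gap_fraction = opts$max_gap_fraction,
                                msa = sim$msa)
  write.table(anchored, file.path(out_dir, "anchored_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_character_matrix(icm, file.path(out_dir, "character_matrix.tsv"))
  profiles <- apply(icm$matrix, 1, function(r) colnames(icm$matrix)[r == 1],
                    simplify = FALSE)
  refs <- lapply(opts$reference_genes, function(g) profiles[[g]] %||% character(0))
  subfam <- do.call(rbind, lapply(names(profiles), function(g) {
    cl <- classify_subfamily(profiles[[g]], refs)
    data.frame(gene_id = g, label = cl$label, score = cl$score)
  }))
  write.table(subfam, file.path(out_dir, "subfamily.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 3: splice events -------------------------------------------------
  pipeline_log(logcon, "INFO", "stage call-events")
  ests <- c(read_ests(file.path(sim_dir, "ests_wt.bed")),
            read_ests(file.path(sim_dir, "ests_nmd_deficient.bed")))
  est_chrom <- vapply(ests, function(e) e$chrom, "")
  events <- do.call(rbind, lapply(sim$models, function(g) {
    call_events(ests[est_chrom == g$chrom], g, min_overhang = opts$min_overhang)
  }))
  rownames(events) <- NULL
  write.table(events, file.path(out_dir, "events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 4: NMD classification + stabilization ----------------------------
  pipeline_log(logcon, "INFO", "stage classify-nmd")
  nmd_calls <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, , drop = FALSE]
    g <- sim$models[[ev$gene_id]]
    cas <- events[events$gene_id == ev$gene_id &
                  events$kind == "CASSETTE_EXON" &
                  events$host_intron == ev$host_intron, , drop = FALSE]
    iso <- build_isoform(g, ev, cassette = if (ev$kind == "ALT_POLYA" &&
                                               nrow(cas)) cas[1, ] else NULL)
    call <- classify_nmd(iso, sim$genomes, threshold_nt = opts$nmd_threshold_nt)
    data.frame(ev, verdict = call$verdict, stop_mrna_pos = call$stop_mrna_pos,
               last_junction = call$last_junction, distance = call$distance)
  }))
  if (!is.null(nmd_calls)) rownames(nmd_calls) <- NULL
  write.table(nmd_calls, file.path(out_dir, "nmd_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ab <- read.table(file.path(sim_dir, "abundances.tsv"), sep = "\t",
                   header = TRUE, stringsAsFactors = FALSE)
  stab <- stabilization_report(ab, min_fold = opts$min_fold)
  write.table(stab, file.path(out_dir, "stabilization.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 5: history inference ---------------------------------------------
  pipeline_log(logcon, "INFO", "stage infer-history")
  tree <- nj_tree(p_distance_matrix(sim$msa))
  tree <- root_at_outgroup(tree, opts$outgroup)
  groups <- event_homology_groups(events, icm, min_support = opts$min_support)
  origin <- if (length(groups))
    infer_origin_model(tree, groups, relaxed = opts$relaxed_linkage)
  else NULL
  boots <- NULL
  if (opts$bootstrap_reps > 0) {
    boots <- bootstrap_support(sim$msa, n_reps = opts$bootstrap_reps,
                               seed = config$seed)
    write.table(boots$support, file.path(out_dir, "bootstrap_support.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  history <- list(
    verdict = if (is.null(origin)) "NO_EVENTS" else origin$verdict,
    groups = lapply(groups, I),
    linkages = if (!is.null(origin) && nrow(origin$linkages)) origin$linkages
               else NULL,
    histories = if (is.null(origin)) NULL else lapply(origin$histories, function(h)
      list(gain_branch = h$gain_branch, loss_branches = I(h$loss_branches),
           cost = h$cost, fitch_cost = h$fitch_cost)),
    tree = ape::write.tree(tree))
  jsonlite::write_json(history, file.path(out_dir, "history.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")

  ## stage 6: conservation ---------------------------------------------------
  pipeline_log(logcon, "INFO", "stage scan-conservation")
  cons <- conservation_stage(sim, opts)
  if (!is.null(cons$runs))
    write.table(cons$runs, file.path(out_dir, "conservation_runs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 7: report ---------------------------------------------------------
  pipeline_log(logcon, "INFO", "stage report")
  metrics <- score_against_truth(list(subfamily = subfam, sites = sites,
                                      icm = icm, events = events,
                                      origin = origin, sim = sim),
                                 sim$truth)
  out_files <- setdiff(list.files(out_dir, recursive = TRUE),
                       c("report.json", "pipeline.log"))
  manifest <- as.list(unname(tools::md5sum(file.path(out_dir, out_files))))
  names(manifest) <- out_files
  report <- list(
    config_md5 = cfg_md5, seed = config$seed,
    parameters = config_to_list(config, opts),
    verdict = history$verdict,
    n_events = nrow(events),
    n_characters = nrow(icm$characters),
    conservation = cons$summary,
    metrics = metrics,
    manifest = manifest)
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  structure(list(report = report, icm = icm, events = events,
                 nmd_calls = nmd_calls, stabilization = stab,
                 origin = origin, tree = tree, sim = sim, subfamily = subfam,
                 skipped = FALSE),
            class = "pipeline_result")
}

config_to_list <- function(config, opts) {
  cl <- unclass(config)
  cl <- cl[!vapply(cl, is.function, TRUE)]
  list(simulation = cl, pipeline = unclass(opts))
}

#' In-memory history inference for a simulated family
#'
#' The event-detection and history-inference core of [run_pipeline()] without
#' file I/O: emit ESTs for both conditions, call events per gene, anchor
#' intron characters, group events by homologous host intron, build the
#' outgroup-rooted NJ tree, and return the origin-model verdict. Used for
#' replicate studies of regime recovery.
#'
#' @param sim A [simulate_family()] result.
#' @param opts A [pipeline_options()].
#' @return List with `origin`, `groups`, `events`, `icm`, `tree`.
#' @export
infer_family_history <- function(sim, opts = pipeline_options()) {
  ests <- c(emit_ests(sim, "wt"), emit_ests(sim, "nmd_deficient"))
  est_chrom <- vapply(ests, function(e) e$chrom, "")
  events <- do.call(rbind, lapply(sim$models, function(g)
    call_events(ests[est_chrom == g$chrom], g,
                min_overhang = opts$min_overhang)))
  sites <- do.call(rbind, lapply(sim$models, intron_sites))
  anchored <- anchor_sites(sites, sim$msa, proteins = sim$proteins)
  icm <- build_character_matrix(anchored, window = opts$window,
                                max_gap_fraction = opts$max_gap_fraction,
                                msa = sim$msa)
  tree <- root_at_outgroup(nj_tree(p_distance_matrix(sim$msa)), opts$outgroup)
  groups <- event_homology_groups(events, icm, min_support = opts$min_support)
  origin <- if (length(groups)) infer_origin_model(tree, groups,
                                                   relaxed = opts$relaxed_linkage)
            else NULL
  list(origin = origin, groups = groups, events = events, icm = icm,
       tree = tree)
}

# events -> homology groups keyed by the host intron's character key
event_homology_groups <- function(events, icm, min_support = 1L) {
  if (is.null(events) || !nrow(events)) return(list())
  ev <- events[events$support >= min_support, , drop = FALSE]
  if (!nrow(ev)) return(list())
  amap <- icm$assignment
  key <- amap$key[match(paste(ev$gene_id, ev$host_intron),
                        paste(amap$gene_id, amap$intron_index))]
  ev <- ev[!is.na(key) & nzchar(key), , drop = FALSE]
  key <- key[!is.na(key) & nzchar(key)]
  split(ev$gene_id, key) |> lapply(unique)
}

conservation_stage <- function(sim, opts) {
  pair <- opts$conservation_pair
  if (!all(pair %in% names(sim$models)))
    return(list(runs = NULL, summary = NULL))
  pick_iso <- function(gid) {
    cat_g <- sim$catalog[sim$catalog$gene_id == gid, , drop = FALSE]
    id <- c(cat_g$isoform_id[cat_g$kind == "CASSETTE"],
            cat_g$isoform_id[cat_g$kind == "PRODUCTIVE"])[1]
    spliced_sequence(sim$genomes, sim$isoforms[[id]])
  }
  seqs <- setNames(vapply(pair, pick_iso, ""), pair)
  if (nchar(seqs[1]) != nchar(seqs[2]))
    return(list(runs = NULL, summary = NULL))
  runs <- perfect_identity_runs(seqs, min_len = opts$min_len)
  prof <- column_identity_profile(seqs)
  lens <- sim$truth$introns$length
  long_q <- max(lens)
  pct <- intron_length_percentile(lens, long_q)
  list(runs = runs,
       summary = list(n_runs = nrow(runs),
                      longest_run = if (nrow(runs)) max(runs$length) else 0L,
                      mean_identity = mean(prof),
                      long_intron_len = long_q,
                      long_intron_top_fraction = pct$top_fraction))
}

#' Score pipeline inferences against simulated truth
#'
#' @param run List with elements `subfamily`, `sites`, `icm`, `events`,
#'   `origin`, `sim` (as assembled by [run_pipeline()]).
#' @param truth A simulation truth bundle.
#' @return List of metrics, each a fraction with counts.
#' @export
score_against_truth <- function(run, truth) {
  m <- list()
  frac <- function(num, den) list(value = if (den > 0) num / den else NA_real_,
                                  n = den)
  # ortholog/subfamily labels
  if (!is.null(run$subfamily)) {
    lab <- merge(run$subfamily, truth$genes, by = "gene_id")
    m$subfamily_accuracy <- frac(sum(lab$label == lab$subfamily), nrow(lab))
  }
  # intron (codon, phase) recovery
  if (!is.null(run$sites)) {
    pred <- unique(paste(run$sites$gene_id, run$sites$codon_index, run$sites$phase))
    tru <- unique(paste(truth$introns$gene_id, truth$introns$codon_index,
                        truth$introns$phase))
    m$intron_site_precision <- frac(sum(pred %in% tru), length(pred))
    m$intron_site_recall <- frac(sum(tru %in% pred), length(tru))
  }
  # character grouping: co-grouped (gene, intron ordinal) pairs
  if (!is.null(run$icm)) {
    am <- run$icm$assignment
    item <- paste(am$gene_id, am$intron_index)
    tkey <- paste(truth$introns$codon_index, truth$introns$phase)[
      match(item, paste(truth$introns$gene_id, truth$introns$ordinal))]
    pairs_of <- function(keys) {
      unlist(lapply(split(item, keys), function(g) {
        if (length(g) < 2) return(character(0))
        g <- sort(g)
        combn(g, 2, FUN = paste, collapse = "~")
      }), use.names = FALSE)
    }
    pp <- pairs_of(am$key); tp <- pairs_of(tkey)
    m$grouping_precision <- frac(sum(pp %in% tp), length(pp))
    m$grouping_recall <- frac(sum(tp %in% pp), length(tp))
  }
  # event calls
  if (!is.null(run$events)) {
    pkey <- paste(run$events$gene_id, run$events$kind, run$events$host_intron,
                  run$events$start, run$events$end)
    tkey <- paste(truth$events$gene_id, truth$events$kind,
                  truth$events$host_ordinal, truth$events$start,
                  truth$events$end)
    m$event_precision <- frac(sum(pkey %in% tkey), length(pkey))
    m$event_recall <- frac(sum(tkey %in% pkey), length(tkey))
  }
  # NMD verdicts across the full isoform catalog
  if (!is.null(run$sim)) {
    sim <- run$sim
    pred <- vapply(sim$catalog$isoform_id, function(id)
      classify_nmd(sim$isoforms[[id]], sim$genomes)$verdict == "NMD_TARGET", TRUE)
    m$nmd_accuracy <- frac(sum(pred == sim$catalog$nmd_target),
                           nrow(sim$catalog))
  }
  # verdict
  if (!is.null(run$origin) && !identical(truth$regime, "NONE"))
    m$verdict_correct <- frac(as.integer(run$origin$verdict == truth$regime), 1L)
  m
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> verdict %s; %s events; %s characters%s\n",
              x$report$verdict, x$report$n_events, x$report$n_characters,
              if (isTRUE(x$skipped)) " (skipped: up-to-date)" else ""))
  invisible(x)
}
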