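# Simulator contracts: null model, event-process statistics, truth
# consistency, determinism, EST/abundance sampling.

small_tree <- "((s1:0.5,s2:0.5)n1:0.5,s3:1.0)r;"

test_that("all rates zero gives structurally identical descendants", {
  cfg <- sim_config(seed = 31, species_tree = small_tree,
                    substitution_rate = 0, intron_gain_rate = 0,
                    intron_loss_rate = 0)
  sim <- simulate_family(cfg)
  rows <- split(sim$truth$introns[, c("codon_index", "phase")],
                sim$truth$introns$gene_id)
  expect_equal(length(unique(lapply(rows, function(x) unname(as.list(x))))), 1L)
  expect_equal(length(unique(unname(sim$proteins))), 1L)
})

test_that("intron gains follow the configured Poisson event process", {
  # total branch length of the small tree is 2.5
  lam <- 0.8; Tt <- 2.5
  counts <- vapply(1:200, function(s) {
    cfg <- sim_config(seed = 4000 + s, species_tree = small_tree,
                      substitution_rate = 0, intron_gain_rate = lam,
                      intron_loss_rate = 0)
    sim <- simulate_family(cfg)
    sum(sim$truth$branch_log$action == "intron_gain")
  }, 0)
  expect_lt(abs(mean(counts) - lam * Tt), 3 * stats::sd(counts) / sqrt(200))
})

test_that("a scripted coupled death/birth is logged as replacement on one branch", {
  cfg <- sim_config(seed = 32, species_tree = small_tree,
                    ancestral_poisons = list(list(group = "anc", host = 3L)),
                    script = list(
                      list(branch = "n1", copy = "A", action = "poison_death",
                           group = "anc")),
                    replacement_coupling = 1, regime = "REPLACEMENT")
  sim <- simulate_family(cfg)
  lg <- sim$truth$branch_log
  expect_equal(sim$truth$regime, "REPLACEMENT")
  expect_true(any(lg$action == "poison_death" & lg$branch == "n1"))
  expect_true(any(lg$action == "poison_birth" & lg$branch == "n1"))
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- srsf_scenario(seed = 33)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim(simulate_family(cfg), d1)
  write_sim(simulate_family(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("truth is internally consistent and NMD labels satisfy the junction rule", {
  sim <- simulate_family(srsf_scenario(seed = 34))
  tru <- sim$truth
  # every event's host intron exists in its gene
  key <- paste(tru$introns$gene_id, tru$introns$ordinal)
  expect_true(all(paste(tru$events$gene_id, tru$events$host_ordinal) %in% key))
  # cross-module check: truth NMD flags agree with the classifier
  for (i in seq_len(nrow(sim$catalog))) {
    call <- classify_nmd(sim$isoforms[[sim$catalog$isoform_id[i]]], sim$genomes)
    expect_equal(call$verdict == "NMD_TARGET", sim$catalog$nmd_target[i],
                 info = sim$catalog$isoform_id[i])
  }
  # regime labels are from the allowed set
  expect_true(tru$regime %in% c("SINGLE_ORIGIN", "INDEPENDENT",
                                "REPLACEMENT", "NONE"))
})

test_that("truth serialization round-trips", {
  sim <- simulate_family(sim_config(seed = 35, species_tree = small_tree,
                                    ancestral_poisons = list(list(group = "anc",
                                                                  host = 3L))))
  tf <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, tf)
  back <- read_truth(tf)
  expect_equal(back$regime, sim$truth$regime)
  expect_equal(back$genes, sim$truth$genes)
  expect_equal(back$events, sim$truth$events)
  expect_equal(back$gene_tree, sim$truth$gene_tree)
})

test_that("EST sampling respects the isoform mixture and the NMD conditions", {
  cfg0 <- srsf_scenario(seed = 36, inclusion_rate = 0)
  sim0 <- simulate_family(cfg0)
  ests0 <- emit_ests(sim0, "wt")
  expect_false(any(grepl("cassette", vapply(ests0, `[[`, "", "name"))))
  # full NMD in wt, none in the deficient strain
  cfg1 <- srsf_scenario(seed = 36, nmd_efficiency = 1)
  sim1 <- simulate_family(cfg1)
  wt_names <- vapply(emit_ests(sim1, "wt"), `[[`, "", "name")
  nd_names <- vapply(emit_ests(sim1, "nmd_deficient"), `[[`, "", "name")
  expect_false(any(grepl("cassette|retention", wt_names)))
  expect_true(any(grepl("cassette", nd_names)))
  # polyA reads are 3'-anchored and flagged
  pa <- grepl(";pA=1", nd_names)
  expect_true(any(pa))
})

test_that("EST isoform fractions match the thinned mixture weight", {
  cfg <- srsf_scenario(seed = 37, n_ests = 400L)
  sim <- simulate_family(cfg)
  gid <- "human_A"
  cat_g <- sim$catalog[sim$catalog$gene_id == gid, ]
  w <- cat_g$weight
  w[cat_g$nmd_target] <- w[cat_g$nmd_target] * (1 - cfg$nmd_efficiency)
  w <- w / sum(w)
  p_cas <- w[cat_g$kind == "CASSETTE"]
  obs <- vapply(1:30, function(r) {
    ests <- emit_ests(sim, "wt", seed = 9000 + r)
    nm <- vapply(ests, `[[`, "", "name")
    mean(grepl(paste0(gid, ":cassette"), nm[grepl(paste0(gid, ":"), nm)]))
  }, 0)
  se <- stats::sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - p_cas), 3 * se + 1e-9)
})

test_that("abundance thinning produces the expected fold change", {
  cfg <- srsf_scenario(seed = 38)
  sim <- simulate_family(cfg)
  det <- emit_abundances(sim, deterministic = TRUE)
  g <- det[det$gene_id == "fungus_A", ]
  f_wt <- g$count_wt / sum(g$count_wt)
  f_nd <- g$count_nmd_deficient / sum(g$count_nmd_deficient)
  i <- which(g$kind == "RETENTION")
  # thinned multinomial algebra: fold = norm_wt / ((1-eff) * norm_nd) ... the
  # unthinned weights cancel, so verify directly from the weights
  cat_g <- sim$catalog[sim$catalog$gene_id == "fungus_A", ]
  w <- cat_g$weight
  wt_w <- w; wt_w[cat_g$nmd_target] <- wt_w[cat_g$nmd_target] * (1 - cfg$nmd_efficiency)
  expect_equal(f_nd[i] / f_wt[i],
               (w[i] / sum(w)) / (wt_w[i] / sum(wt_w)), tolerance = 1e-9)
  expect_gt(f_nd[i] / f_wt[i], 2)
  # nmd_efficiency 0: both conditions share expected fractions
  cfg0 <- srsf_scenario(seed = 38, nmd_efficiency = 0)
  det0 <- emit_abundances(simulate_family(cfg0), deterministic = TRUE)
  expect_equal(det0$count_wt, det0$count_nmd_deficient)
})

test_that("every emitted EST derives from a cataloged isoform", {
  sim <- simulate_family(srsf_scenario(seed = 39))
  ests <- emit_ests(sim, "nmd_deficient", n_ests = 20L)
  iso_of <- sub("\\|.*$", "", vapply(ests, `[[`, "", "name"))
  expect_true(all(iso_of %in% sim$catalog$isoform_id))
})
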