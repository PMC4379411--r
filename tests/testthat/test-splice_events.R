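# Event calling, isoform construction, NMD rule, stabilization, RT-PCR.

make_est <- function(blocks, chrom = "chrT", strand = "+", polyA = FALSE) {
  list(name = paste0("e", sample.int(1e6, 1), if (polyA) ";pA=1" else ""),
       chrom = chrom, strand = strand,
       blocks = cbind(start = blocks[, 1], end = blocks[, 2]), polyA = polyA)
}

test_that("cassette, retention and polyA events are called from EST block geometry", {
  g <- toy_gene("+")  # exons [0,100) [200,300) [400,500)
  ests <- list(
    make_est(cbind(c(50, 130, 200), c(100, 160, 250))),   # cassette in intron 0
    make_est(cbind(50, 300)),                              # retention of intron 0
    make_est(cbind(c(250, 330), c(300, 360)), polyA = TRUE))  # polyA in intron 1
  ev <- call_events(ests, g, min_overhang = 10L)
  expect_setequal(ev$kind, c("CASSETTE_EXON", "INTRON_RETENTION", "ALT_POLYA"))
  cas <- ev[ev$kind == "CASSETTE_EXON", ]
  expect_equal(c(cas$host_intron, cas$start, cas$end), c(0L, 130L, 160L))
  ret <- ev[ev$kind == "INTRON_RETENTION", ]
  expect_equal(c(ret$host_intron, ret$start, ret$end), c(0L, 100L, 200L))
  pa <- ev[ev$kind == "ALT_POLYA", ]
  expect_equal(c(pa$host_intron, pa$start), c(1L, 359L))
  # support accumulates over duplicate observations
  ev2 <- call_events(c(ests, ests[1]), g)
  expect_equal(ev2$support[ev2$kind == "CASSETTE_EXON"], 2L)
})

test_that("cassette calls require exact flanking junction agreement", {
  g <- toy_gene("+")
  # flank junction off by one nt: not a cassette
  ests <- list(make_est(cbind(c(50, 130, 201), c(100, 160, 250))))
  expect_equal(nrow(call_events(ests, g)), 0L)
  # retention needs the full overhang on both sides
  expect_equal(nrow(call_events(list(make_est(cbind(95, 300))), g,
                                min_overhang = 10L)), 0L)
  # ESTs off locus/strand are skipped with a count
  ev <- call_events(list(make_est(cbind(50, 300), strand = "-")), g)
  expect_equal(attr(ev, "n_skipped"), 1L)
})

test_that("isoform construction realizes each event kind", {
  g <- toy_gene("+")
  ev_cas <- data.frame(kind = "CASSETTE_EXON", gene_id = "toy",
                       host_intron = 0L, start = 130L, end = 160L)
  iso <- build_isoform(g, ev_cas)
  expect_equal(iso$blocks[, "start"], c(0L, 130L, 200L, 400L))
  expect_equal(enumerate_junctions(iso), c(100L, 130L, 230L))
  ev_ret <- data.frame(kind = "INTRON_RETENTION", gene_id = "toy",
                       host_intron = 0L, start = 100L, end = 200L)
  iso_r <- build_isoform(g, ev_ret)
  expect_equal(iso_r$blocks[, "start"], c(0L, 400L))
  expect_equal(iso_r$blocks[, "end"], c(300L, 500L))
  ev_pa <- data.frame(kind = "ALT_POLYA", gene_id = "toy",
                      host_intron = 0L, start = 149L, end = 150L)
  iso_p <- build_isoform(g, ev_pa)
  expect_equal(unname(iso_p$blocks), cbind(0L, 150L), ignore_attr = TRUE)
  expect_true(iso_p$polyA_truncated)
  expect_error(build_isoform(g, data.frame(kind = "CASSETTE_EXON",
                                           gene_id = "other", host_intron = 0L,
                                           start = 1L, end = 2L)),
               class = "splicevo_input_error")
})

test_that("retained-intron mRNA equals productive mRNA with the intron spliced in", {
  sim <- simulate_family(srsf_scenario(seed = 6))
  cat_r <- sim$catalog[sim$catalog$kind == "RETENTION", ][1:5, ]
  for (i in seq_len(nrow(cat_r))) {
    gid <- cat_r$gene_id[i]
    g <- sim$models[[gid]]
    ret <- sim$isoforms[[cat_r$isoform_id[i]]]
    prod <- build_isoform(g, NULL)
    m_ret <- spliced_sequence(sim$genomes, ret)
    m_prod <- spliced_sequence(sim$genomes, prod)
    k <- cat_r$host_ordinal[i] + 1L
    introns <- gene_introns(g)
    ilen <- unname(introns[k, "end"] - introns[k, "start"])
    j <- enumerate_junctions(prod)[k]
    expect_equal(nchar(m_ret), nchar(m_prod) + ilen)
    expect_equal(paste0(substr(m_prod, 1, j), substr(m_ret, j + 1, j + ilen),
                        substr(m_prod, j + 1, nchar(m_prod))), m_ret)
  }
})

test_that("the junction rule classifies by stop-to-last-junction distance", {
  # hand-built gene: three junctions at 200/450/700 in a 900-nt mRNA
  set.seed(99)
  seqlen <- 1200
  blocks <- cbind(start = c(0L, 250L, 550L, 850L), end = c(200L, 500L, 800L, 1050L))
  base <- strsplit(rand_seq(seqlen), "")[[1]]
  base[base == "T"] <- "C"              # wipe stops, then place one
  place_stop <- function(genome_chars, mrna_stop_pos) {
    # write TAA so that translation from 0 ends with stop at mrna_stop_pos
    p <- mrna_stop_pos - 3              # mRNA offset of stop codon start
    block_of <- function(q) { off <- 0; for (k in 1:4) { len <- blocks[k,2]-blocks[k,1]
      if (q < off + len) return(blocks[k,1] + (q - off)); off <- off + len }; NA }
    for (d in 0:2) genome_chars[block_of(p + d) + 1] <- c("T","A","A")[d + 1]
    genome_chars
  }
  mk <- function(stop_pos) {
    gch <- place_stop(base, stop_pos)
    genome <- c(chrT = paste(gch, collapse = ""))
    iso <- isoform("g", "chrT", "+", blocks, cds_offset = 0L)
    classify_nmd(iso, genome, threshold_nt = 50L)
  }
  r1 <- mk(600)   # distance 100 >= 50
  expect_equal(r1$verdict, "NMD_TARGET")
  expect_equal(r1$distance, 100L)
  r2 <- mk(681)   # stop must sit at a codon boundary: 681 = 227*3 -> dist 19
  expect_equal(r2$verdict, "PRODUCTIVE")
  r3 <- mk(900)   # stop in last exon
  expect_equal(r3$verdict, "ESCAPE_LAST_EXON")
})

test_that("polyA-truncated isoforms with upstream stop escape as truncated", {
  sim <- simulate_family(srsf_scenario(seed = 6))
  cat_p <- sim$catalog[sim$catalog$kind == "POLYA", ]
  expect_gt(nrow(cat_p), 0)
  for (i in seq_len(min(5, nrow(cat_p)))) {
    call <- classify_nmd(sim$isoforms[[cat_p$isoform_id[i]]], sim$genomes)
    expect_equal(call$verdict, "ESCAPE_TRUNCATED")
  }
})

test_that("raising the threshold never converts PRODUCTIVE to NMD_TARGET", {
  set.seed(55)
  for (i in 1:50) {
    ri <- rand_isoform()
    v1 <- classify_nmd(ri$iso, ri$genome, threshold_nt = 30L)$verdict
    v2 <- classify_nmd(ri$iso, ri$genome, threshold_nt = 80L)$verdict
    if (v1 == "PRODUCTIVE") expect_true(v2 != "NMD_TARGET")
    if (v2 == "NMD_TARGET") expect_equal(v1, "NMD_TARGET")
  }
})

test_that("stabilization uses pseudocounted fractions and the fold threshold", {
  counts <- data.frame(gene_id = "g", isoform_id = c("prod", "ptc"),
                       count_wt = c(90, 10), count_nmd_deficient = c(50, 50))
  rep <- stabilization_report(counts, min_fold = 2)
  ptc <- rep[rep$isoform_id == "ptc", ]
  expect_equal(ptc$fold_change, (50.5 / 101) / (10.5 / 101), tolerance = 1e-12)
  expect_true(ptc$stabilized)
  expect_false(rep$stabilized[rep$isoform_id == "prod"])
  # identical fractions give fold 1
  counts2 <- data.frame(gene_id = "g", isoform_id = c("a", "b"),
                        count_wt = c(30, 70), count_nmd_deficient = c(30, 70))
  expect_equal(stabilization_report(counts2)$fold_change, c(1, 1))
  # missing condition entries are treated as zero counts
  counts3 <- data.frame(gene_id = "g", isoform_id = c("a", "b"),
                        count_wt = c(10, NA), count_nmd_deficient = c(10, 30))
  expect_equal(stabilization_report(counts3)$fraction_wt,
               c(10.5 / 11, 0.5 / 11))
})

test_that("virtual RT-PCR reproduces the two-band retention assay logic", {
  sim <- simulate_family(srsf_scenario(seed = 6))
  # fungal-like gene (or fallback): productive vs retained host intron
  gid <- pick_retention_gene(sim)
  cat_f <- sim$catalog[sim$catalog$gene_id == gid, ]
  prod <- sim$isoforms[[cat_f$isoform_id[cat_f$kind == "PRODUCTIVE"]]]
  ret <- sim$isoforms[[cat_f$isoform_id[cat_f$kind == "RETENTION"][1]]]
  k <- cat_f$host_ordinal[cat_f$kind == "RETENTION"][1] + 1L
  g <- sim$models[[gid]]
  introns <- gene_introns(g)
  ilen <- unname(introns[k, "end"] - introns[k, "start"])
  m <- spliced_sequence(sim$genomes, prod)
  j <- enumerate_junctions(prod)
  # primers flanking the intron, neither spanning a junction
  fwd <- substr(m, j[k] - 60, j[k] - 41)
  rev <- oracle_revcomp(substr(m, j[k] + 41, j[k] + 60))
  res <- virtual_rt_pcr(list(prod, ret), sim$genomes, fwd, rev)
  expect_equal(res$status, c("ok", "ok"))
  expect_equal(diff(res$product_length), ilen)
  # reverse primer spanning the junction removed by retention: product lost
  jn <- j[k]
  rev_span <- oracle_revcomp(substr(m, jn - 9, jn + 10))
  res2 <- virtual_rt_pcr(list(prod, ret), sim$genomes, fwd, rev_span)
  expect_equal(res2$status, c("ok", "no_product"))
  # random primer matches nothing
  res3 <- virtual_rt_pcr(list(prod), sim$genomes, fwd, strrep("ACGT", 5))
  expect_true(all(res3$status != "ok"))
  expect_error(virtual_rt_pcr(list(prod), sim$genomes, "ACGTACGT", rev),
               class = "splicevo_input_error")
})
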