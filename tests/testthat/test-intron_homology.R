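# Intron positions as characters: (codon, phase) extraction, alignment
# anchoring, character matrix construction, subfamily calls.

test_that("intron (codon, phase) arithmetic follows the interrupted-codon convention", {
  g <- toy_gene("+")
  s <- intron_sites(g)
  # intron 0 after 90 coding nt, intron 1 after 190 coding nt
  expect_equal(s$codon_index, c(30L, 63L))
  expect_equal(s$phase, c(0L, 1L))
  expect_equal(s$intron_index, c(0L, 1L))
  # on the minus strand transcription order flips: coding runs 492 -> 10, so
  # the first intron encountered sits after 92 coding nt, the second after 192
  g2 <- toy_gene("-")
  s2 <- intron_sites(g2)
  expect_equal(s2$codon_index, c(30L, 64L))
  expect_equal(s2$phase, c(2L, 0L))
})

test_that("CDS length not divisible by 3 is a structural error", {
  g <- gene_model("x", "sp", "c", "+",
                  cbind(start = c(0L, 200L), end = c(100L, 300L)),
                  cds_start = 10L, cds_end = 291L)
  expect_error(intron_sites(g), class = "splicevo_structural_error")
})

test_that("simulator intron positions are recovered exactly (round trip)", {
  sim <- simulate_family(srsf_scenario(seed = 5))
  for (gid in names(sim$models)) {
    s <- intron_sites(sim$models[[gid]])
    tru <- sim$truth$introns[sim$truth$introns$gene_id == gid, ]
    expect_equal(s$codon_index, tru$codon_index, info = gid)
    expect_equal(s$phase, tru$phase, info = gid)
  }
})

test_that("anchoring maps codon indices through the gene's own gap pattern", {
  sites <- data.frame(gene_id = "g1", intron_index = 0L,
                      codon_index = 100L, phase = 0L,
                      genomic_start = 0L, genomic_end = 10L)
  msa <- c(g1 = paste0(strrep("A", 100), "R", strrep("A", 19)))
  expect_equal(anchor_sites(sites, msa)$column, 100L)
  # five gaps inserted before residue 100 shift the column by five
  msa2 <- c(g1 = paste0(strrep("A", 50), "-----", strrep("A", 50), "R",
                        strrep("A", 19)))
  expect_equal(anchor_sites(sites, msa2)$column, 105L)
  # row/protein mismatch is an input error
  expect_error(anchor_sites(sites, msa, proteins = c(g1 = "MKV")),
               class = "splicevo_input_error")
})

test_that("anchoring agrees with a per-residue scan oracle under random gaps", {
  set.seed(31)
  for (rep in 1:25) {
    n_res <- 60
    codons <- sort(sample(0:(n_res - 1), 4))
    aa <- rand_seq(n_res)  # letters irrelevant
    gaps <- sort(sample(1:(n_res + 20), 12))
    row <- character(0); res_to_col <- integer(n_res); r <- 0
    for (col in seq_len(n_res + 12)) {
      if (col %in% gaps && r < n_res) row <- c(row, "-")
      else { r <- r + 1; if (r > n_res) break; row <- c(row, substr(aa, r, r)); res_to_col[r] <- col - 1 }
    }
    msa <- c(gX = paste(row, collapse = ""))
    sites <- data.frame(gene_id = "gX", intron_index = seq_along(codons) - 1L,
                        codon_index = codons, phase = 0L,
                        genomic_start = 0L, genomic_end = 10L)
    anc <- anchor_sites(sites, msa)
    expect_equal(anc$column, res_to_col[codons + 1])
  }
})

test_that("characters merge by phase and column window; exact keys match hashing", {
  anchored <- data.frame(
    gene_id = c(paste0("g", 1:8), "g9"),
    column = c(rep(55L, 8), 55L),
    phase = c(rep(0L, 8), 1L),
    intron_index = 0L)
  icm <- build_character_matrix(anchored, window = 0L)
  expect_equal(nrow(icm$characters), 2L)  # phase must match
  # window 2 merges columns 55 and 57 at the same phase
  anchored2 <- data.frame(gene_id = c("a", "b"), column = c(55L, 57L),
                          phase = 0L, intron_index = 0L)
  expect_equal(nrow(build_character_matrix(anchored2, window = 2L)$characters), 1L)
  expect_equal(nrow(build_character_matrix(anchored2, window = 0L)$characters), 2L)
  # random sites at window 0 group exactly like key hashing
  set.seed(8)
  rnd <- data.frame(gene_id = paste0("g", sample(1:20, 100, replace = TRUE)),
                    column = sample(0:30, 100, replace = TRUE),
                    phase = sample(0:2, 100, replace = TRUE),
                    intron_index = seq_len(100))
  icm3 <- build_character_matrix(rnd, window = 0L)
  expect_equal(sort(icm3$characters$key),
               sort(unique(sprintf("col%d_p%d", rnd$column, rnd$phase))))
})

test_that("anchoring is gap-invariant: all-gap columns shift columns but not groupings", {
  sim <- simulate_family(sim_config(seed = 12, species_tree = "(s1:0.2,(s2:0.1,s3:0.1)n1:0.1)r;"))
  sites <- do.call(rbind, lapply(sim$models, intron_sites))
  icm1 <- build_character_matrix(anchor_sites(sites, sim$msa))
  # insert a shared all-gap column block at position 50
  msa2 <- vapply(sim$msa, function(s)
    paste0(substr(s, 1, 50), "-----", substr(s, 51, nchar(s))), "")
  icm2 <- build_character_matrix(anchor_sites(sites, msa2))
  norm <- function(icm) unname(lapply(seq_len(ncol(icm$matrix)), function(j)
    sort(rownames(icm$matrix)[icm$matrix[, j] == 1])))
  expect_setequal(norm(icm1), norm(icm2))
})

test_that("orthologs share identical character rows when no gain/loss occurred", {
  cfg <- sim_config(seed = 14, intron_gain_rate = 0, intron_loss_rate = 0)
  sim <- simulate_family(cfg)
  sites <- do.call(rbind, lapply(sim$models, intron_sites))
  icm <- build_character_matrix(anchor_sites(sites, sim$msa))
  rows <- apply(icm$matrix, 1, paste, collapse = "")
  expect_equal(length(unique(rows)), 1L)
})

test_that("subfamily classification maximizes Jaccard similarity with tie -> unclassified", {
  refs <- list(SRSF5like = c("10", "55", "120", "200"),
               SRSF46like = c("30", "90", "150"))
  cl <- classify_subfamily(c("10", "55", "120"), refs)
  expect_equal(cl$label, "SRSF5like")
  expect_equal(cl$score, 0.75)
  expect_equal(classify_subfamily(character(0), refs)$label, "unclassified")
  # equal similarity to both references
  refs2 <- list(a = c("1", "2"), b = c("1", "3"))
  expect_equal(classify_subfamily(c("1"), refs2)$label, "unclassified")
  # disjoint from everything
  expect_equal(classify_subfamily(c("99"), refs)$label, "unclassified")
})
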