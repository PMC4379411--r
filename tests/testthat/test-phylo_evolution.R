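# Distances, NJ, bootstrap, Dollo parsimony, origin-model inference.

test_that("p-distance uses pairwise deletion and matches the column-scan oracle", {
  msa <- c(a = "AAAA", b = "AAAT")
  expect_equal(p_distance_matrix(msa)["a", "b"], 0.25)
  expect_equal(p_distance_matrix(c(a = "AA-A", b = "AAAA"))["a", "b"], 0)
  expect_error(p_distance_matrix(c(a = "--", b = "AA")),
               class = "splicevo_input_error")
  set.seed(3)
  for (i in 1:5) {
    msa <- setNames(vapply(1:4, function(j) {
      s <- strsplit(rand_seq(60), "")[[1]]
      s[sample(60, 8)] <- "-"
      paste(s, collapse = "")
    }, ""), letters[1:4])
    expect_equal(p_distance_matrix(msa), oracle_pdist(msa))
  }
})

test_that("NJ recovers the additive-tree split and is deterministic under ties", {
  d <- matrix(c(0, 3, 3, 5,
                3, 0, 4, 6,
                3, 4, 0, 4,
                5, 6, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  expect_true("A|B" %in% splicevo:::tree_splits(tr) ||
              "C|D" %in% splicevo:::tree_splits(tr))
  # equal distances: stable topology across repeated runs
  de <- matrix(1, 4, 4, dimnames = dimnames(d)); diag(de) <- 0
  expect_equal(ape::write.tree(nj_tree(de)), ape::write.tree(nj_tree(de)))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)),
               class = "splicevo_input_error")
})

test_that("bootstrap support concentrates on well-supported splits", {
  set.seed(10)
  block <- function() rand_seq(150)
  x <- block(); y <- block()
  msa <- c(A = x, B = x, C = y, D = y)
  bs <- bootstrap_support(msa, n_reps = 100L, seed = 17L)
  key <- grep("^(A\\|B|C\\|D)$", bs$support$split)
  # with n_reps 1 supports are 0 or 1
  bs1 <- bootstrap_support(msa, n_reps = 1L, seed = 17L)
  expect_true(all(bs1$support$support %in% c(0, 1)))
  expect_true(all(bs$support$support[key] >= 0.8))
  expect_error(bootstrap_support(msa, n_reps = 0L),
               class = "splicevo_input_error")
})

test_that("Dollo places the gain above the MRCA and counts maximal zero subtrees", {
  tr <- ape::read.tree(text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)r;")
  h <- dollo_history(tr, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(h$gain_branch, "ab")
  expect_equal(h$cost, 0L)
  h2 <- dollo_history(tr, c(A = 1, B = 0, C = 1, D = 0))
  expect_equal(h2$gain_branch, "r")
  expect_setequal(h2$loss_branches, c("B", "D"))
  expect_equal(h2$cost, 2L)
  # all-zero character: empty history
  h0 <- dollo_history(tr, c(A = 0, B = 0, C = 0, D = 0))
  expect_true(is.na(h0$gain_branch))
  expect_equal(h0$cost, 0L)
})

test_that("Dollo cost equals exhaustive single-gain enumeration on random trees", {
  set.seed(20)
  for (rep in 1:40) {
    ts <- rand_tree_states(sample(4:10, 1))
    h <- dollo_history(ts$tree, ts$states)
    expect_equal(h$cost, oracle_dollo_cost(ts$tree, ts$states))
    # implied leaf states must match the observations
    present <- splicevo:::descendant_tips(
      ts$tree, splicevo:::node_of_id(ts$tree, h$gain_branch))
    lost <- unlist(lapply(h$loss_branches, function(b)
      splicevo:::descendant_tips(ts$tree, splicevo:::node_of_id(ts$tree, b))))
    implied <- setdiff(present, lost)
    expect_setequal(implied, names(ts$states)[ts$states == 1])
  }
})

test_that("Dollo histories are equivariant under leaf relabeling", {
  set.seed(21)
  ts <- rand_tree_states(8)
  perm <- sample(ts$tree$tip.label)
  tr2 <- ts$tree
  tr2$tip.label <- perm[match(ts$tree$tip.label, sort(ts$tree$tip.label))]
  # map states through the same relabeling
  st2 <- setNames(ts$states[sort(names(ts$states))], perm)
  h1 <- dollo_history(ts$tree, ts$states)
  h2 <- dollo_history(tr2, st2)
  expect_equal(h1$cost, h2$cost)
  expect_equal(h1$fitch_cost, h2$fitch_cost)
})

test_that("origin-model rule distinguishes single origin, independence, replacement", {
  tr <- ape::read.tree(text = "(((A:1,B:1)ab:1,(C:1,D:1)cd:1)in:1,O:2)r;")
  # one group covering every leaf
  om1 <- infer_origin_model(tr, list(g1 = c("A", "B", "C", "D", "O")))
  expect_equal(om1$verdict, "SINGLE_ORIGIN")
  # two groups confined to disjoint clades, no ancestral loss linkage
  om2 <- infer_origin_model(tr, list(g1 = c("A", "B"), g2 = c("C", "D")))
  expect_equal(om2$verdict, "INDEPENDENT")
  # ancestral group lost on the branch where a new group was gained
  om3 <- infer_origin_model(tr, list(anc = c("A", "B", "O"),
                                     new = c("C", "D")))
  expect_equal(om3$verdict, "REPLACEMENT")
  expect_equal(om3$linkages$loss_branch, "cd")
  expect_equal(om3$linkages$gain_branch, "cd")
  # gain strictly below the loss branch also links
  om4 <- infer_origin_model(tr, list(anc = c("A", "B", "O"), new = c("C")))
  expect_equal(om4$verdict, "REPLACEMENT")
  expect_error(infer_origin_model(tr, list(g = c("A", "ZZZ"))),
               class = "splicevo_input_error")
})

test_that("trees are rooted at the declared outgroup", {
  tr <- nj_tree(p_distance_matrix(c(O = "AAAATTTT", X = "CCCCTTTT",
                                    Y = "CCCCTTTA", Z = "CCCATTTA")))
  rt <- root_at_outgroup(tr, "O")
  expect_true(ape::is.rooted(rt))
  expect_error(root_at_outgroup(tr, "nope"), class = "splicevo_input_error")
})
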