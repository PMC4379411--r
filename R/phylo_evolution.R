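# Trees, Dollo parsimony, and origin-model inference.
#
# External maximum-likelihood trees (newick) are first-class inputs; the
# built-in tree path is p-distance + neighbor joining with column-resampling
# bootstrap. The inference content of the package is the character analysis:
# Dollo (single-gain) reconstruction of intron/poison-exon characters and the
# family-level verdict distinguishing a single ancestral origin of
# unproductive splicing, independent origins, and replacement (an ancestral
# event lost while a new one is gained on the same lineage).

## ---- distances and trees --------------------------------------------------

pdist_from_mat <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-"
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok))
      sv_stop(sprintf("no comparable columns between %s and %s",
                      rownames(m)[i], rownames(m)[j]), "input_error")
    d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
  }
  d
}

#' Pairwise p-distance matrix of an alignment
#'
#' Mismatch fraction over columns where neither sequence has a gap
#' (pairwise deletion).
#'
#' @param msa Named character vector of aligned sequences (>= 2).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(msa) {
  if (length(msa) < 2) sv_stop("need at least two sequences", "input_error")
  if (length(unique(nchar(msa))) != 1) sv_stop("aligned rows differ in length", "input_error")
  pdist_from_mat(do.call(rbind, strsplit(msa, "", fixed = TRUE)))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}); negative branch lengths are
#' clamped to zero with a warning.
#'
#' @param dist Square symmetric distance matrix with dimnames (>= 3 taxa).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dist) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist) ||
      !isTRUE(all.equal(dist, t(dist), tolerance = 1e-8)))
    sv_stop("distance matrix must be square and symmetric", "input_error")
  tr <- ape::nj(dist)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

# canonical bipartition keys of a tree (non-trivial splits only):
# each split is represented by the side not containing the first taxon
# (alphabetically), labels sorted and joined by "|".
tree_splits <- function(tree) {
  labs <- tree$tip.label
  anchor <- sort(labs)[1]
  pp <- ape::prop.part(tree)
  n <- length(labs)
  keys <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L || length(side) > n - 2L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for the splits of the full-data NJ tree
#'
#' Columns are resampled with replacement per replicate and the tree rebuilt
#' (p-distance + NJ); support for each non-trivial split of the full-data
#' tree is the fraction of replicate trees containing it. Replicate `r` uses
#' RNG seed `seed + r` for reproducibility.
#'
#' @param msa Named character vector of aligned sequences.
#' @param n_reps Number of replicates (default 100).
#' @param seed Base RNG seed.
#' @return List with `tree` (full-data NJ tree) and `support` (data frame
#'   `split`, `support`).
#' @export
bootstrap_support <- function(msa, n_reps = 100L, seed = 1L) {
  if (n_reps < 1) sv_stop("n_reps must be >= 1", "input_error")
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  full <- nj_tree(pdist_from_mat(m))
  target <- tree_splits(full)
  hits <- setNames(numeric(length(target)), target)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_tree <- suppressWarnings(nj_tree(pdist_from_mat(m[, cols, drop = FALSE])))
    rs <- tree_splits(rep_tree)
    hits[target %in% rs] <- hits[target %in% rs] + 1
  }
  list(tree = full,
       support = data.frame(split = target, support = unname(hits) / n_reps))
}

#' Root a tree at a declared outgroup
#' @param tree A `phylo`.
#' @param outgroup Tip label (or labels) of the outgroup.
#' @return Rooted `phylo`.
#' @export
root_at_outgroup <- function(tree, outgroup) {
  if (!all(outgroup %in% tree$tip.label))
    sv_stop("outgroup not among tip labels", "input_error")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

## ---- tree bookkeeping -----------------------------------------------------

# branch ids: a branch is named by its child node — tip label for terminal
# branches, the node label (or "node<N>") for internal ones. The root's
# "branch" is the stem above the root.
node_id <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label[node - ntip]
    if (!is.na(lab) && nzchar(lab)) return(lab)
  }
  paste0("node", node)
}

node_of_id <- function(tree, id) {
  ntip <- length(tree$tip.label)
  i <- match(id, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(id, tree$node.label)
    if (!is.na(j)) return(ntip + j)
  }
  if (grepl("^node[0-9]+$", id)) return(as.integer(sub("^node", "", id)))
  sv_stop(paste("unknown branch id:", id), "input_error")
}

tree_parents <- function(tree) {
  par <- integer(max(tree$edge))
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par  # 0 for root
}

tree_children <- function(tree) {
  ch <- vector("list", max(tree$edge))
  for (k in seq_len(nrow(tree$edge)))
    ch[[tree$edge[k, 1]]] <- c(ch[[tree$edge[k, 1]]], tree$edge[k, 2])
  ch
}

# is `node` equal to or a descendant of `anc`?
is_desc_or_equal <- function(parents, node, anc) {
  while (node != 0L) {
    if (node == anc) return(TRUE)
    node <- parents[node]
  }
  FALSE
}

descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ch <- tree_children(tree)
  acc <- character(0); stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= ntip) acc <- c(acc, tree$tip.label[v]) else stack <- c(stack, ch[[v]])
  }
  acc
}

## ---- Dollo parsimony ------------------------------------------------------

#' Dollo parsimony history of one binary character
#'
#' Under Dollo parsimony a character is gained exactly once and can only be
#' lost. The gain is placed on the branch above the most recent common
#' ancestor of all state-1 leaves; losses are the minimal set of branches
#' (maximal all-zero subtrees within the gain clade) explaining every
#' state-0 leaf. Equal-cost alternative gain placements (ancestors of the
#' MRCA reaching the same loss count) are reported rather than suppressed,
#' and the unrestricted Fitch parsimony cost is given for comparison.
#'
#' @param tree Rooted `phylo` with unique tip labels.
#' @param states Named 0/1 vector over all tip labels.
#' @return Object of class `event_history`: `gain_branch`, `loss_branches`,
#'   `cost` (number of losses), `fitch_cost`, `alternatives` (data frame of
#'   equal-cost gain placements), `present` (state-1 leaves).
#'   All-zero characters yield an empty history (`gain_branch = NA`).
#' @export
dollo_history <- function(tree, states) {
  if (is.null(names(states)) || !all(tree$tip.label %in% names(states)))
    sv_stop("states must be named over all tip labels", "input_error")
  states <- states[tree$tip.label]
  ones <- tree$tip.label[states == 1]
  hist0 <- structure(list(gain_branch = NA_character_,
                          loss_branches = character(0), cost = 0L,
                          fitch_cost = 0L,
                          alternatives = data.frame(branch = character(0),
                                                    cost = integer(0)),
                          present = character(0)),
                     class = "event_history")
  if (length(ones) == 0) return(hist0)
  ntip <- length(tree$tip.label)
  parents <- tree_parents(tree)
  children <- tree_children(tree)
  mrca <- if (length(ones) == 1) match(ones, tree$tip.label) else
    ape::getMRCA(tree, ones)
  # all-zero flag per node
  nn <- max(tree$edge)
  allzero_of <- function() {
    az <- rep(NA, nn)
    rec <- function(v) {
      if (v <= ntip) { az[v] <<- states[v] == 0; return(az[v]) }
      vals <- vapply(children[[v]], rec, TRUE)
      az[v] <<- all(vals)
      az[v]
    }
    root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
    rec(root)
    az
  }
  allzero <- allzero_of()
  losses_under <- function(g) {
    # maximal all-zero subtrees strictly below g (g itself contains a 1)
    out <- integer(0); stack <- children[[g]]
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (allzero[v]) out <- c(out, v)
      else if (v > ntip) stack <- c(stack, children[[v]])
    }
    out
  }
  loss_nodes <- losses_under(mrca)
  cost <- length(loss_nodes)
  # equal-cost alternative gain placements among ancestors of the MRCA
  alt <- data.frame(branch = character(0), cost = integer(0))
  v <- parents[mrca]
  while (v != 0L) {
    cv <- length(losses_under(v))
    alt <- rbind(alt, data.frame(branch = node_id(tree, v), cost = cv))
    v <- parents[v]
  }
  alt <- alt[alt$cost == cost, , drop = FALSE]
  structure(list(gain_branch = node_id(tree, mrca),
                 loss_branches = vapply(loss_nodes, function(v) node_id(tree, v), ""),
                 cost = cost,
                 fitch_cost = fitch_cost(tree, states),
                 alternatives = alt,
                 present = ones),
            class = "event_history")
}

# unrestricted binary Fitch parsimony change count
fitch_cost <- function(tree, states) {
  ntip <- length(tree$tip.label)
  children <- tree_children(tree)
  cost <- 0L
  rec <- function(v) {
    if (v <= ntip) return(if (states[v] == 1) 2L else 1L)  # bitmask {0}=1,{1}=2
    sets <- vapply(children[[v]], rec, 0L)
    inter <- Reduce(bitwAnd, sets)
    if (inter != 0L) inter else { cost <<- cost + length(sets) - 1L; Reduce(bitwOr, sets) }
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
  rec(root)
  cost
}

#' @export
print.event_history <- function(x, ...) {
  cat(sprintf("<event_history> gain on %s; %d loss(es)%s; Fitch cost %d\n",
              x$gain_branch, x$cost,
              if (x$cost) paste0(" [", paste(x$loss_branches, collapse = ", "), "]") else "",
              x$fitch_cost))
  invisible(x)
}

## ---- origin-model inference -----------------------------------------------

#' Classify a family's unproductive-splicing history
#'
#' Runs [dollo_history()] per event homology group and applies the decision
#' rule: one group only = `SINGLE_ORIGIN`; otherwise `REPLACEMENT` if any
#' group's gain lies on (or below) a loss branch of another group — an
#' ancestral event replaced by a new one on the same lineage; otherwise
#' `INDEPENDENT`. All replacement linkages are reported.
#'
#' @param tree Rooted `phylo` over all family genes.
#' @param groups Named list: homology group -> member leaves (genes showing
#'   the event).
#' @param relaxed If `TRUE`, a linkage also counts when the gain falls
#'   anywhere within the clade of the loss branch's parent (tolerates
#'   branch-resolution uncertainty).
#' @return Object of class `origin_model`: `verdict`, `linkages` (data frame
#'   `lost_group`, `gained_group`, `loss_branch`, `gain_branch`),
#'   `histories` (per-group [dollo_history()] results).
#' @export
infer_origin_model <- function(tree, groups, relaxed = FALSE) {
  if (length(groups) < 1) sv_stop("need at least one homology group", "input_error")
  for (g in names(groups))
    if (!all(groups[[g]] %in% tree$tip.label))
      sv_stop(sprintf("group %s references unknown leaves", g), "input_error")
  parents <- tree_parents(tree)
  histories <- lapply(groups, function(members) {
    st <- setNames(as.integer(tree$tip.label %in% members), tree$tip.label)
    dollo_history(tree, st)
  })
  if (length(groups) == 1) {
    return(structure(list(verdict = "SINGLE_ORIGIN",
                          linkages = data.frame(), histories = histories),
                     class = "origin_model"))
  }
  linkages <- list()
  for (i in names(groups)) for (j in names(groups)) {
    if (i == j) next
    hi <- histories[[i]]; hj <- histories[[j]]
    if (is.na(hj$gain_branch) || !length(hi$loss_branches)) next
    gnode <- node_of_id(tree, hj$gain_branch)
    for (lb in hi$loss_branches) {
      lnode <- node_of_id(tree, lb)
      anchor <- if (relaxed) parents[lnode] else lnode
      if (anchor == 0L) anchor <- lnode
      if (is_desc_or_equal(parents, gnode, anchor)) {
        linkages[[length(linkages) + 1L]] <- data.frame(
          lost_group = i, gained_group = j,
          loss_branch = lb, gain_branch = hj$gain_branch,
          stringsAsFactors = FALSE)
      }
    }
  }
  verdict <- if (length(linkages)) "REPLACEMENT" else "INDEPENDENT"
  structure(list(verdict = verdict,
                 linkages = if (length(linkages)) do.call(rbind, linkages)
                            else data.frame(),
                 histories = histories),
            class = "origin_model")
}

#' @export
print.origin_model <- function(x, ...) {
  cat(sprintf("<origin_model> verdict: %s (%d group(s), %d linkage(s))\n",
              x$verdict, length(x$histories),
              if (is.data.frame(x$linkages)) nrow(x$linkages) else 0L))
  invisible(x)
}
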