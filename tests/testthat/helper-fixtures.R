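# Shared fixtures, cached once per test run ------------------------------

REF <- synthetic_reference()
TREE <- toy_haplogroup_tree()
MUMMY <- aconcagua_haplotype()

SYN_POOL <- synonymous_transition_sites()
# deterministic synonymous / replacement token positions for constructions
syn_positions <- function(k, from = 10L) SYN_POOL[seq(from, by = 7L, length.out = k)]
nonsyn_positions <- function(k, from = 1L) seq(5905L + 3L * (from - 1L), by = 3L,
                                               length.out = k)  # CO1 2nd codon pos

mk_hap <- function(id, positions = integer(), range = c(1L, 16569L)) {
  v <- if (length(positions)) parse_variants(as.character(positions))
       else empty_variants()
  haplotype(id, v, range = range)
}

c1b_motif <- function(tree = TREE) {
  m <- node_motif(tree, "C1b")
  m[!m$back, , drop = FALSE]
}

# Exhaustive maximum-parsimony oracle -------------------------------------
# Minimum number of changes over all unrooted binary topologies, computed by
# Fitch on every topology. Haplotypes are given as a list of integer vectors
# (site indices of derived variants); the root (all-ancestral) is included
# as an extra leaf, so rooting is irrelevant to the score.

.tree_cache <- new.env(parent = emptyenv())

all_rooted_trees <- function(leaves) {
  key <- paste(leaves, collapse = ",")
  if (!is.null(.tree_cache[[key]])) return(.tree_cache[[key]])
  trees <- if (length(leaves) == 1) {
    list(leaves[1])
  } else {
    prev <- all_rooted_trees(leaves[-length(leaves)])
    leaf <- leaves[length(leaves)]
    out <- list()
    for (tr in prev) {
      for (ins in insert_leaf_everywhere(tr, leaf)) out[[length(out) + 1L]] <- ins
    }
    out
  }
  .tree_cache[[key]] <- trees
  trees
}

insert_leaf_everywhere <- function(tree, leaf) {
  # insert on the edge above `tree` plus recursively inside
  out <- list(list(tree, leaf))
  if (is.list(tree)) {
    for (side in 1:2) {
      for (sub in insert_leaf_everywhere(tree[[side]], leaf)) {
        copy <- tree
        copy[[side]] <- sub
        out[[length(out) + 1L]] <- copy
      }
    }
  }
  out
}

fitch_cost <- function(tree, states) {
  # states: matrix [leaf, site] with 1 = ancestral, 2 = derived
  rec <- function(node) {
    if (!is.list(node)) {
      return(list(set = states[node, ], cost = 0L))
    }
    a <- rec(node[[1]]); b <- rec(node[[2]])
    inter <- bitwAnd(a$set, b$set)
    uni <- bitwOr(a$set, b$set)
    empty <- inter == 0L
    list(set = ifelse(empty, uni, inter),
         cost = a$cost + b$cost + sum(empty))
  }
  rec(tree)$cost
}

oracle_parsimony_length <- function(hap_sets) {
  # hap_sets: list of distinct token vectors (characters as site ids)
  tokens <- unique(unlist(hap_sets))
  if (length(tokens) == 0) return(0L)
  n <- length(hap_sets)
  states <- matrix(1L, n + 1L, length(tokens))  # leaf n+1 = ancestral root
  for (i in seq_len(n)) states[i, tokens %in% hap_sets[[i]]] <- 2L
  leaves <- seq_len(n + 1L)
  if (n == 0) return(0L)
  trees <- all_rooted_trees(leaves[-1])
  best <- Inf
  for (tr in trees) {
    cost <- fitch_cost(list(1L, tr), states)
    if (cost < best) best <- cost
  }
  as.integer(best)
}

# Random near-perfect-phylogeny instance for the parsimony oracle sweep:
# a random laminar genealogy under infinite sites, optionally with one
# planted recurrent mutation on two disjoint, uniquely-tagged clades.
random_parsimony_instance <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(2:6, 1)
    next_site <- 0L
    new_site <- function() { next_site <<- next_site + 1L; next_site }
    clusters <- list()
    haps <- replicate(n, character(), simplify = FALSE)
    grow <- function(tips) {
      if (length(tips) >= 2 && stats::runif(1) < 0.8) {
        k <- sample(1:(length(tips) - 1), 1)
        parts <- list(tips[1:k], tips[(k + 1):length(tips)])
        for (p in parts) {
          if (length(p) >= 2 && stats::runif(1) < 0.9) {
            site <- as.character(new_site())
            for (t in p) haps[[t]] <<- c(haps[[t]], site)
            clusters[[length(clusters) + 1L]] <<- p
          }
          grow(p)
        }
      }
    }
    grow(seq_len(n))
    # private variants so several tips are distinct
    for (t in seq_len(n)) {
      for (k in seq_len(sample(0:2, 1))) {
        haps[[t]] <- c(haps[[t]], as.character(new_site()))
        clusters[[length(clusters) + 1L]] <- t
      }
    }
    # plant one recurrence on two terminal branches (the common detectable
    # case in near-perfect mtDNA phylogenies: the same transition arising
    # independently on two tips)
    if (stats::runif(1) < 0.4 && n >= 3) {
      pick <- sample(n, 2)
      site <- as.character(new_site())
      for (t in pick) haps[[t]] <- c(haps[[t]], site)
    }
    if (next_site > 10L) return(random_parsimony_instance(seed + 100003L))
    haps
  })
}

greedy_parsimony_length <- function(hap_sets) {
  h <- dplyr::bind_rows(lapply(seq_along(hap_sets), function(i) {
    v <- if (length(hap_sets[[i]]))
      parse_variants(hap_sets[[i]]) else empty_variants()
    haplotype(paste0("h", i), v)
  }))
  gt <- build_parsimony_tree(h, root = NULL, mask = NULL)
  sum(gt$branches$length)
}
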