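test_that("haplotypes identical to the root collapse to a zero-length tree", {
  h <- dplyr::bind_rows(mk_hap("a"), mk_hap("b"), mk_hap("c"))
  gt <- build_parsimony_tree(h)
  expect_equal(sum(gt$branches$length), 0)
  expect_equal(nrow(gt$tips), 1)
  expect_equal(gt$tips$multiplicity, 3)
  expect_equal(gt$n, 3)
})

test_that("perfect-phylogeny data give total length = distinct variants", {
  p <- nonsyn_positions(6)
  h <- dplyr::bind_rows(
    mk_hap("a", p[1:3]), mk_hap("b", p[1:2]),
    mk_hap("c", c(p[1], p[4])), mk_hap("d", p[5:6]))
  gt <- build_parsimony_tree(h)
  expect_equal(sum(gt$branches$length), 6)
  expect_equal(oracle_parsimony_length(list(
    as.character(p[1:3]), as.character(p[1:2]),
    as.character(c(p[1], p[4])), as.character(p[5:6]))), 6)
})

test_that("a planted recurrent mutation costs exactly one extra step", {
  p <- nonsyn_positions(5)
  # tips a and c acquire p5 independently inside clades {a,b} and {c,d}
  sets <- list(c(p[1], p[3], p[5]), p[1],
               c(p[2], p[4], p[5]), p[2])
  h <- dplyr::bind_rows(lapply(seq_along(sets), function(i)
    mk_hap(letters[i], sets[[i]])))
  gt <- build_parsimony_tree(h)
  expect_equal(sum(gt$branches$length), 5 + 1)
  expect_equal(oracle_parsimony_length(lapply(sets, as.character)), 6)
  # the recurrent token sits on two branches
  tok <- as.character(p[5])
  hits <- sum(vapply(gt$branches$tokens, function(x) tok %in% x, logical(1)))
  expect_equal(hits, 2)
})

test_that("greedy length equals the exhaustive Fitch minimum on random instances", {
  for (seed in 1:120) {
    sets <- random_parsimony_instance(seed)
    distinct <- unique(sets)
    got <- greedy_parsimony_length(sets)
    want <- oracle_parsimony_length(distinct)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("branch incidences are consistent: sum l_b n_b = sum d_i", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      sets <- random_parsimony_instance(sample(10000L, 1))
      h <- dplyr::bind_rows(lapply(seq_along(sets), function(i) {
        v <- if (length(sets[[i]])) parse_variants(sets[[i]]) else empty_variants()
        haplotype(paste0("h", i), v)
      }))
      gt <- build_parsimony_tree(h, mask = NULL)
      bw <- branch_weights(gt)
      d <- root_distances(gt)
      expect_equal(sum(bw$length * bw$n_desc), sum(d$d * d$multiplicity))
    }
  })
})

test_that("merged duplicate tips carry their multiplicity as branch weight", {
  p <- nonsyn_positions(2)
  h <- dplyr::bind_rows(mk_hap("a", p), mk_hap("b", p), mk_hap("c", p[1]))
  gt <- build_parsimony_tree(h)
  expect_equal(nrow(gt$tips), 2)
  merged <- gt$tips[gt$tips$multiplicity == 2, ]
  term <- gt$branches[gt$branches$id == merged$cluster, ]
  expect_equal(term$n_b, 2)
})

test_that("synonymous filtering recomputes distances from annotated events", {
  h <- dplyr::bind_rows(
    mk_hap("a", c(syn_positions(1), nonsyn_positions(1))),
    mk_hap("b"))
  gt <- build_parsimony_tree(h)
  expect_equal(sort(root_distances(gt)$d), c(0L, 2L))
  d_syn <- root_distances(gt, filter = "synonymous", reference = REF)
  expect_equal(sort(d_syn$d), c(0L, 1L))
  expect_error(root_distances(gt, filter = "synonymous"), "reference")
})

test_that("back mutations relative to the root count as events", {
  root <- parse_variants(c("16223", "16298"))
  h <- mk_hap("a", 16325)
  h$variants[[1]] <- parse_variants(c("16223", "16325"))  # lost 16298
  gt <- build_parsimony_tree(h, root = root)
  expect_equal(root_distances(gt)$d, 2L)  # gained 16325, lost 16298
})

test_that("newick export round-trips through ape", {
  p <- nonsyn_positions(4)
  h <- dplyr::bind_rows(mk_hap("a", p[1:2]), mk_hap("b", p[1]), mk_hap("c", p[3]))
  nwk <- genealogy_newick(build_parsimony_tree(h), comments = FALSE)
  phy <- ape::read.tree(text = nwk)
  expect_s3_class(phy, "phylo")
  expect_true(all(c("a", "b", "c") %in% phy$tip.label))
})

test_that("the exhaustive oracle agrees with phangorn's parsimony search", {
  for (seed in c(3, 14, 159)) {
    sets <- unique(random_parsimony_instance(seed))
    tokens <- unique(unlist(sets))
    if (length(tokens) == 0 || length(sets) < 3) next
    mat <- matrix("0", length(sets) + 1, length(tokens),
                  dimnames = list(c(paste0("h", seq_along(sets)), "root"),
                                  NULL))
    for (i in seq_along(sets)) mat[i, tokens %in% sets[[i]]] <- "1"
    dat <- phangorn::phyDat(mat, type = "USER", levels = c("0", "1"))
    tr <- phangorn::pratchet(dat, trace = 0, all = FALSE)
    expect_equal(min(phangorn::parsimony(tr, dat)),
                 oracle_parsimony_length(sets))
  }
})
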