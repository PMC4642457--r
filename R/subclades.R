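#' Propose new sub-clades from placed haplotypes
#'
#' Within each haplogroup node, maximal sets of private variants shared by
#' at least `min_members` haplotypes become proposed child clades; nested
#' sharing yields nested proposals (formally, the proposals are the closed
#' variant sets of the private-variant incidence relation with support >=
#' `min_members`). Output order is deterministic: by node, then decreasing
#' member count, then motif tokens.
#'
#' @param placed A haplotype frame with a `best_node` column (e.g. the output
#'   of [classify_haplotypes()]), or a plain haplotype frame plus `node`.
#' @param tree A `haplo_tree`.
#' @param min_members Minimum mitogenomes defining a new clade (>= 2).
#' @param mask A [hotspot_mask()].
#' @param node Node name used for all rows when `placed` has no `best_node`.
#' @return Tibble: `node`, `proposal`, `parent_proposal`, `motif`
#'   (space-separated tokens), `members` (list-column of sample ids),
#'   `n_members`.
#' @export
discover_subclades <- function(placed, tree, min_members = 2L,
                               mask = default_hotspot_mask(), node = NULL) {
  if (min_members < 2) abort("min_members must be >= 2")
  if (!"best_node" %in% names(placed)) {
    if (is.null(node)) abort("supply a `best_node` column or `node`")
    placed$best_node <- node
  }
  out <- list()
  for (nd in sort(unique(placed$best_node))) {
    sub <- placed[placed$best_node == nd, , drop = FALSE]
    priv <- lapply(seq_len(nrow(sub)), function(i)
      variant_keys(private_mutations(sub[i, ], nd, tree, mask)))
    names(priv) <- sub$sample_id
    props <- closed_shared_sets(priv, min_members)
    if (nrow(props) == 0) next
    props$node <- nd
    props$proposal <- paste0(nd, "-p", seq_len(nrow(props)))
    # nesting: parent = smallest strict superset of the member set
    props$parent_proposal <- vapply(seq_len(nrow(props)), function(i) {
      supersets <- which(vapply(seq_len(nrow(props)), function(j) {
        j != i && all(props$members[[i]] %in% props$members[[j]]) &&
          length(props$members[[j]]) > length(props$members[[i]])
      }, logical(1)))
      if (length(supersets) == 0) return(NA_character_)
      props$proposal[supersets[which.min(lengths(props$members[supersets]))]]
    }, character(1))
    out[[length(out) + 1L]] <- props
  }
  if (length(out) == 0) {
    return(tibble(node = character(), proposal = character(),
                  parent_proposal = character(), motif = character(),
                  members = list(), n_members = integer()))
  }
  res <- dplyr::bind_rows(out)
  res[, c("node", "proposal", "parent_proposal", "motif", "members", "n_members")]
}

# Closed variant sets with support >= min_members: intersect carrier sets to
# a fixpoint, then report, for each closed carrier set, all variants carried
# by every member.
closed_shared_sets <- function(priv_tokens, min_members) {
  samples <- names(priv_tokens)
  all_tokens <- unique(unlist(priv_tokens))
  if (length(all_tokens) == 0)
    return(tibble(motif = character(), members = list(), n_members = integer()))
  carriers <- lapply(all_tokens, function(tk)
    samples[vapply(priv_tokens, function(p) tk %in% p, logical(1))])
  sets <- unique(lapply(carriers, sort))
  repeat {
    extra <- list()
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      if (i < j) {
        inter <- sort(intersect(sets[[i]], sets[[j]]))
        if (length(inter) >= min_members &&
            !any(vapply(c(sets, extra), identical, logical(1), inter)))
          extra[[length(extra) + 1L]] <- inter
      }
    }
    if (length(extra) == 0) break
    sets <- c(sets, extra)
  }
  sets <- sets[lengths(sets) >= min_members]
  if (length(sets) == 0)
    return(tibble(motif = character(), members = list(), n_members = integer()))
  motifs <- lapply(sets, function(S) {
    shared <- Reduce(intersect, priv_tokens[S])
    sort(shared)
  })
  keep <- lengths(motifs) > 0
  sets <- sets[keep]; motifs <- motifs[keep]
  # closure: members = all haplotypes carrying the full motif
  members <- lapply(motifs, function(mo)
    samples[vapply(priv_tokens, function(p) all(mo %in% p), logical(1))])
  key <- vapply(members, paste, character(1), collapse = "|")
  keep <- !duplicated(key)
  sets <- members[keep]; motifs <- motifs[keep]
  ord <- order(-lengths(sets), vapply(motifs, paste, character(1), collapse = " "))
  tibble(
    motif = vapply(motifs[ord], paste, character(1), collapse = " "),
    members = sets[ord],
    n_members = lengths(sets[ord])
  )
}
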