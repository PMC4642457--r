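#' Classify haplotypes against a haplogroup motif tree
#'
#' Each haplotype is masked, then scored against every node's cumulative
#' motif: score = (matched defining variants) − (missing defining variants),
#' where only motif variants inside the haplotype's sequenced range are
#' considered (so control-region-only records are never penalised for
#' coding-region motifs). Retained back-mutation tokens in a cumulative
#' motif are ignored. The best node maximises the score; ties break to the
#' node with more matched defining variants, then to the *shallower* node
#' (a sub-clade is never assigned without in-range evidence for its own
#' defining variants), then lexicographically by name, so results are
#' deterministic.
#'
#' @param h A haplotype frame.
#' @param tree A `haplo_tree` (see [read_haplogroup_tree()]).
#' @param mask A [hotspot_mask()] applied before scoring; `NULL` for none.
#' @return The haplotype frame with columns `best_node`, `score`, `n_matched`,
#'   `n_missing`, `n_private`, `runner_up`, `runner_up_score` and list-columns
#'   `matched`, `missing`, `private` appended.
#' @examples
#' tree <- toy_haplogroup_tree()
#' classify_haplotypes(aconcagua_haplotype(), tree)$best_node
#' @export
classify_haplotypes <- function(h, tree, mask = default_hotspot_mask()) {
  if (nrow(tree$nodes) == 0) abort("empty tree")
  if (!is.null(mask)) h <- mask_hotspots(h, mask)
  motifs <- lapply(tree_node_names(tree), function(nm) {
    m <- node_motif(tree, nm)
    m[!m$back, , drop = FALSE]  # retained '@' tokens carry no expectation
  })
  names(motifs) <- tree_node_names(tree)

  res <- lapply(seq_len(nrow(h)), function(i) {
    r <- hap_range(h, i)
    toks <- hap_tokens(h, i)
    stats <- vapply(motifs, function(m) {
      m <- m[range_contains(r, m$pos), , drop = FALSE]
      k <- variant_keys(m)
      matched <- sum(k %in% toks)
      c(matched - (length(k) - matched), matched)
    }, numeric(2))
    scores <- stats[1, ]
    ord <- order(-scores, -stats[2, ], tree$nodes$depth, tree$nodes$name)
    best <- ord[1]
    best_name <- tree$nodes$name[best]
    m <- motifs[[best_name]]
    m_in <- m[range_contains(r, m$pos), , drop = FALSE]
    k <- variant_keys(m_in)
    matched <- m_in[k %in% toks, , drop = FALSE]
    missing <- m_in[!k %in% toks, , drop = FALSE]
    private <- variants_setdiff(h$variants[[i]], motifs[[best_name]])
    tibble(
      best_node = best_name, score = scores[best],
      n_matched = nrow(matched), n_missing = nrow(missing),
      n_private = nrow(private),
      runner_up = tree$nodes$name[ord[2]] %||% NA_character_,
      runner_up_score = if (length(ord) > 1) scores[ord[2]] else NA_real_,
      matched = list(matched), missing = list(missing), private = list(private)
    )
  })
  dplyr::bind_cols(h, dplyr::bind_rows(res))
}

#' Private mutations of a haplotype relative to a haplogroup node
#'
#' The masked variant set of the haplotype minus the cumulative motif of
#' `node` — the lineage-specific variation on top of the clade root.
#'
#' @param h A one-row haplotype frame.
#' @param node Node name in `tree`.
#' @param tree A `haplo_tree`.
#' @param mask A [hotspot_mask()]; `NULL` for none.
#' @return A variant tibble.
#' @export
private_mutations <- function(h, node, tree, mask = default_hotspot_mask()) {
  stopifnot(nrow(h) == 1)
  if (!is.null(mask)) h <- mask_hotspots(h, mask)
  motif <- node_motif(tree, node)
  variants_setdiff(h$variants[[1]], motif[!motif$back, , drop = FALSE])
}

#' Cross-check laboratory operators against a sample haplotype
#'
#' An authentication step for ancient-DNA work: every operator haplotype is
#' classified on the same tree as the sample, and flagged `incompatible`
#' when the two classifications cannot describe the same maternal lineage —
#' either the best nodes lie on disjoint root paths below their deepest
#' common ancestor, or one node is strictly deeper and the shallower
#' haplotype demonstrably lacks (within its sequenced range) defining
#' variants of the deeper node. An operator identical to the sample is
#' `compatible` and flagged for review.
#'
#' @param sample A one-row haplotype frame.
#' @param operators A haplotype frame of operator profiles.
#' @param tree A `haplo_tree`.
#' @param mask A [hotspot_mask()].
#' @return Tibble: one row per operator with `operator`, `operator_node`,
#'   `sample_node`, `shared_variants`, `verdict`, `note`.
#' @export
contamination_check <- function(sample, operators, tree,
                                mask = default_hotspot_mask()) {
  if (nrow(operators) == 0) abort("empty operator set")
  s_cls <- classify_haplotypes(sample, tree, mask)
  o_cls <- classify_haplotypes(operators, tree, mask)
  s_path <- tree_path(tree, s_cls$best_node[1])
  s_masked <- mask_hotspots(sample, mask %||% hotspot_mask())

  rows <- lapply(seq_len(nrow(o_cls)), function(i) {
    o_node <- o_cls$best_node[i]
    o_path <- tree_path(tree, o_node)
    shared <- length(intersect(hap_tokens(s_masked),
                               variant_keys(mask_hotspots(
                                 operators$variants[[i]],
                                 mask %||% hotspot_mask()))))
    identical_hap <- setequal(hap_tokens(s_masked),
                              variant_keys(mask_hotspots(
                                operators$variants[[i]],
                                mask %||% hotspot_mask())))
    on_s_path <- o_node %in% s_path
    on_o_path <- s_cls$best_node[1] %in% o_path
    verdict <- "compatible"; note <- ""
    if (identical_hap) {
      note <- "identical to sample; review for contamination"
    } else if (!on_s_path && !on_o_path) {
      verdict <- "incompatible"
      note <- "best nodes on disjoint root paths"
    } else {
      # ancestor/descendant relation: check the shallower haplotype against
      # the deeper node's extra defining variants
      deeper <- if (on_s_path) s_cls$best_node[1] else o_node
      shallower_hap <- if (on_s_path) operators[i, ] else sample
      extra <- node_motif(tree, deeper)
      extra <- extra[!extra$back, , drop = FALSE]
      anc <- if (on_s_path) o_node else s_cls$best_node[1]
      anc_motif <- node_motif(tree, anc)
      extra <- variants_setdiff(extra, anc_motif[!anc_motif$back, , drop = FALSE])
      r <- hap_range(shallower_hap)
      extra <- extra[range_contains(r, extra$pos), , drop = FALSE]
      lacks <- variants_setdiff(extra, shallower_hap$variants[[1]])
      if (nrow(lacks) > 0 && !identical_hap) {
        verdict <- "incompatible"
        note <- sprintf("lineage lacks %d defining variant(s) of %s",
                        nrow(lacks), deeper)
      }
    }
    tibble(operator = operators$sample_id[i], operator_node = o_node,
           sample_node = s_cls$best_node[1], shared_variants = shared,
           verdict = verdict, note = note)
  })
  dplyr::bind_rows(rows)
}
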