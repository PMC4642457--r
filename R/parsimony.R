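#' Build a within-clade maximum-parsimony genealogy
#'
#' Builds a rooted genealogy for a set of haplotypes around a clade root
#' (ancestral motif). Events are the symmetric differences from the root:
#' derived variants plus back mutations for root-motif variants a haplotype
#' lacks. Identical haplotypes merge into one tip with multiplicity. The
#' search is greedy shared-derived-variant agglomeration: characters whose
#' carrier sets are pairwise compatible (nested or disjoint) form the tree
#' backbone; characters in conflict (recurrent mutations) are laid on the
#' minimal set of branches covering their carriers. For the near-perfect
#' phylogenies typical of mtDNA clades this attains the parsimony minimum.
#'
#' @param h A haplotype frame of clade members.
#' @param root The clade root: a one-row haplotype frame, a variant tibble,
#'   or `NULL` for an empty (reference-equal) root.
#' @param mask A [hotspot_mask()]; by default hotspots *and* indels are
#'   excluded, matching the dating convention.
#' @param count_indels Keep insertion/deletion events? Overrides the mask's
#'   blanket indel switch when `TRUE`.
#' @return An object of class `genealogy`.
#' @export
build_parsimony_tree <- function(h, root = NULL,
                                 mask = default_hotspot_mask(mask_indels = TRUE),
                                 count_indels = FALSE) {
  if (nrow(h) == 0) abort("empty haplotype set")
  root_v <- if (is.null(root)) empty_variants() else as_variant_tbl(root)
  if (!is.null(mask)) {
    if (count_indels) mask$mask_indels <- FALSE
    root_v <- mask_hotspots(root_v, mask)
  }
  root_keys <- variant_keys(root_v)

  ev_sets <- lapply(seq_len(nrow(h)), function(i) {
    v <- h$variants[[i]]
    if (!is.null(mask)) v <- mask_hotspots(v, mask)
    if (!count_indels) v <- v[!v$kind %in% c("insertion", "deletion"), , drop = FALSE]
    k <- variant_keys(v)
    derived <- setdiff(k, root_keys)
    r <- hap_range(h, i)
    in_range <- root_v[range_contains(r, root_v$pos), , drop = FALSE]
    lost <- setdiff(variant_keys(in_range), k)
    sort(c(derived, if (length(lost)) paste0("@", lost)))
  })

  key <- vapply(ev_sets, paste, character(1), collapse = " ")
  tip_of <- match(key, unique(key))
  n_tips <- max(tip_of)
  tip_sets <- ev_sets[!duplicated(key)]
  mult <- as.integer(table(factor(tip_of, levels = seq_len(n_tips))))
  samples <- split(h$sample_id, tip_of)

  tokens <- unique(unlist(tip_sets))
  carriers <- lapply(tokens, function(tk)
    which(vapply(tip_sets, function(s) tk %in% s, logical(1))))
  names(carriers) <- tokens

  # greedy agglomeration: accept characters most-shared first (ties by
  # position) while their carrier sets stay laminar with what is accepted;
  # rejected characters are recurrent and get covered by several branches
  tok_pos <- suppressWarnings(
    as.integer(gsub("[^0-9].*$", "", sub("^@", "", tokens))))
  tok_pos[is.na(tok_pos)] <- 0L
  csize <- vapply(carriers, function(cl) sum(mult[cl]), numeric(1))
  token_order <- order(-csize, tok_pos)
  accepted <- list()
  conflict <- rep(FALSE, length(tokens))
  for (t in token_order) {
    S <- sort(carriers[[t]])
    ok <- TRUE
    for (cl in accepted) {
      inter <- length(intersect(S, cl))
      if (inter > 0 && inter < length(S) && inter < length(cl)) { ok <- FALSE; break }
    }
    if (ok) accepted[[length(accepted) + 1L]] <- S else conflict[t] <- TRUE
  }

  # laminar cluster family: accepted carrier sets + one singleton per tip
  clusters <- unique(c(accepted, lapply(seq_len(n_tips), function(t) t)))
  ckey <- vapply(clusters, paste, character(1), collapse = ",")
  clusters <- clusters[!duplicated(ckey)]
  sizes <- vapply(clusters, function(cl) sum(mult[cl]), numeric(1))
  ord <- order(-sizes, vapply(clusters, paste, character(1), collapse = ","))
  clusters <- clusters[ord]

  parent <- vapply(seq_along(clusters), function(i) {
    sup <- which(vapply(seq_along(clusters), function(j) {
      j != i && length(clusters[[j]]) > length(clusters[[i]]) &&
        all(clusters[[i]] %in% clusters[[j]])
    }, logical(1)))
    if (length(sup) == 0) return(0L)
    sup[which.min(lengths(clusters[sup]))]
  }, integer(1))

  branch_tokens <- vector("list", length(clusters))
  cover_cluster <- function(S) {
    taken <- integer()
    walk <- function(children_of) {
      for (ci in children_of) {
        cl <- clusters[[ci]]
        if (all(cl %in% S)) taken <<- c(taken, ci)
        else if (length(intersect(cl, S)) > 0) walk(which(parent == ci))
      }
    }
    walk(which(parent == 0L))
    taken
  }
  for (t in seq_along(tokens)) {
    S <- carriers[[t]]
    where <- if (!conflict[t]) {
      which(vapply(clusters, function(cl) identical(sort(cl), sort(S)),
                   logical(1)))[1]
    } else NULL
    ids <- if (!is.null(where) && !is.na(where)) where else cover_cluster(S)
    for (ci in ids)
      branch_tokens[[ci]] <- c(branch_tokens[[ci]], tokens[t])
  }

  branches <- tibble(
    id = seq_along(clusters),
    parent = parent,
    tokens = lapply(branch_tokens, function(x) sort(x %||% character())),
    length = vapply(branch_tokens, length, integer(1)),
    n_b = vapply(clusters, function(cl) sum(mult[cl]), integer(1)),
    tips = clusters
  )
  tip_cluster <- vapply(seq_len(n_tips), function(t) {
    cand <- which(vapply(clusters, function(cl) identical(cl, t), logical(1)))
    cand[1]
  }, integer(1))
  d <- vapply(seq_len(n_tips), function(t) {
    ci <- tip_cluster[t]; total <- 0L
    while (ci != 0L) { total <- total + branches$length[ci]; ci <- branches$parent[ci] }
    total
  }, integer(1))
  tips <- tibble(
    tip = seq_len(n_tips),
    cluster = tip_cluster,
    samples = unname(samples),
    label = vapply(samples, `[[`, character(1), 1),
    multiplicity = mult,
    d = d
  )
  structure(list(branches = branches, tips = tips,
                 n = sum(mult), tokens = tokens),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat("<genealogy> ", x$n, " sampled mtDNAs, ", nrow(x$tips),
      " distinct haplotypes, total length ", sum(x$branches$length),
      " mutations\n", sep = "")
  invisible(x)
}

#' Per-tip root distances
#'
#' Number of mutational events between each tip and the clade root,
#' optionally restricted to synonymous changes (which requires a gene map
#' and reference for annotation).
#'
#' @param gt A `genealogy`.
#' @param filter `"all"` or `"synonymous"`.
#' @param genes,reference Needed for the synonymous filter.
#' @return Tibble `(tip, label, multiplicity, d)`.
#' @export
root_distances <- function(gt, filter = c("all", "synonymous"),
                           genes = rcrs_gene_map(), reference = NULL) {
  filter <- match.arg(filter)
  if (filter == "synonymous") gt <- filter_genealogy_synonymous(gt, genes, reference)
  gt$tips[, c("tip", "label", "multiplicity", "d")]
}

#' Branch lengths and descendant-tip weights
#'
#' The per-branch quantities behind the heuristic standard error of rho:
#' branch length (mutation count) and number of descendant sampled mtDNAs.
#'
#' @param gt A `genealogy`.
#' @return Tibble `(branch, length, n_desc)`.
#' @export
branch_weights <- function(gt) {
  tibble(branch = gt$branches$id, length = gt$branches$length,
         n_desc = gt$branches$n_b)
}

# Restrict a genealogy's events to synonymous substitutions; topology kept,
# branch lengths and root distances recomputed.
filter_genealogy_synonymous <- function(gt, genes = rcrs_gene_map(),
                                        reference = NULL) {
  if (is.null(reference))
    abort("synonymous filtering requires a reference for annotation")
  all_tokens <- unique(unlist(gt$branches$tokens))
  keep <- if (length(all_tokens)) {
    ann <- annotate_variants(parse_variants(sub("^@", "", all_tokens)),
                             genes, reference)
    stats::setNames(ann$effect == "synonymous", all_tokens)
  } else logical()
  gt$branches$tokens <- lapply(gt$branches$tokens, function(tk) tk[keep[tk]])
  gt$branches$length <- vapply(gt$branches$tokens, length, integer(1))
  gt$tips$d <- vapply(gt$tips$tip, function(t) {
    ci <- gt$tips$cluster[t]; total <- 0L
    while (ci != 0L) { total <- total + gt$branches$length[ci]
                       ci <- gt$branches$parent[ci] }
    total
  }, integer(1))
  gt
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.genealogy <- function(x, ...) {
  out <- x$branches
  out$tokens <- vapply(out$tokens, paste, character(1), collapse = " ")
  out$tips <- vapply(out$tips, paste, character(1), collapse = ",")
  out
}

#' @export
glance.genealogy <- function(x, ...) {
  d <- rep(x$tips$d, x$tips$multiplicity)
  rho <- compute_rho(d)
  sigma <- compute_sigma(x)
  tibble(n = x$n, n_haplotypes = nrow(x$tips),
         total_length = sum(x$branches$length),
         rho = rho, sigma = sigma,
         star_index = if (sigma > 0) star_index(rho, sigma, x$n) else NA_real_)
}

#' Newick export of a genealogy
#'
#' Branch lengths are mutation counts; mutation lists are attached as
#' bracketed comments.
#'
#' @param gt A `genealogy`.
#' @param comments Attach `[&mutations=...]` comments?
#' @return Newick string.
#' @export
genealogy_newick <- function(gt, comments = TRUE) {
  br <- gt$branches
  lab <- function(ci) {
    t <- which(gt$tips$cluster == ci)
    if (length(t) == 1) gsub("[ ():,;]", "_", gt$tips$label[t]) else ""
  }
  build <- function(ci) {
    kids <- br$id[br$parent == ci]
    com <- if (comments && length(br$tokens[[ci]]) > 0)
      paste0("[&mutations=", paste(br$tokens[[ci]], collapse = "|"), "]") else ""
    body <- if (length(kids) == 0) lab(ci)
    else paste0("(", paste(vapply(kids, build, character(1)), collapse = ","),
                ")", lab(ci))
    paste0(body, ":", br$length[ci], com)
  }
  top <- br$id[br$parent == 0L]
  paste0("(", paste(vapply(top, build, character(1)), collapse = ","), ")root;")
}
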