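#' Phylogeny-aware nomenclature resolution
#'
#' Length variation (especially in the control region) often admits several
#' variant spellings of the same sample sequence. Following standard
#' forensic practice, the spelling that best fits the known phylogeny is
#' preferred over the most parsimonious one: among all alignment-equivalent
#' representations of each indel-containing window (allowing up to
#' `extra_events` events beyond the minimum), the one whose tokens match the
#' most motifs in `tree` is chosen; ties break to fewer events, then fewer
#' indel events (substitutions are preferred to insert/delete rewrites),
#' then the leftmost placement.
#'
#' @param h A one-row haplotype frame.
#' @param tree A `haplo_tree` supplying the motif vocabulary.
#' @param reference Reference sequence string.
#' @param extra_events How far beyond the minimal event count to search
#'   (default 1).
#' @param window_pad Context bases added around each indel window (default 6,
#'   wide enough to span short homopolymer runs).
#' @return The haplotype frame with possibly re-spelled variants.
#' @export
resolve_nomenclature <- function(h, tree, reference, extra_events = 1L,
                                 window_pad = 6L) {
  stopifnot(nrow(h) == 1)
  v <- h$variants[[1]]
  if (nrow(v) == 0 || !any(v$kind %in% c("insertion", "deletion"))) return(h)
  universe <- tree_token_universe(tree)

  v <- v[order(v$pos), , drop = FALSE]
  gap <- 5L
  grp <- cumsum(c(1L, diff(v$pos) > gap))
  parts <- list()
  for (g in unique(grp)) {
    w <- v[grp == g, , drop = FALSE]
    parts[[length(parts) + 1L]] <-
      if (any(w$kind %in% c("insertion", "deletion")))
        resolve_window(w, reference, universe, extra_events, window_pad)
      else w
  }
  out <- dplyr::bind_rows(parts)
  out <- out[order(out$pos, out$kind), , drop = FALSE]
  h$variants[[1]] <- out
  h
}

tree_token_universe <- function(tree) {
  toks <- unlist(lapply(tree$nodes$motif, function(m) {
    m <- m[!m$back, , drop = FALSE]
    variant_keys(m)
  }))
  unique(toks)
}

resolve_window <- function(w, reference, universe, extra_events, pad) {
  wstart <- max(1L, min(w$pos) - pad)
  wend <- min(nchar(reference), max(w$end_pos) + pad)
  ref_win <- substring(reference, wstart, wend)
  sample_win <- apply_variants(local_shift(w, wstart), ref_win)

  cands <- enumerate_representations(ref_win, sample_win, extra_events)
  if (length(cands) == 0) return(w)
  # token strings in absolute coordinates, for scoring
  tok_sets <- lapply(cands, function(ev) {
    vapply(ev, function(e) event_token(e, wstart), character(1))
  })
  score <- vapply(tok_sets, function(tk) sum(tk %in% universe), numeric(1))
  events <- lengths(cands)
  indels <- vapply(cands, function(ev)
    sum(vapply(ev, function(e) e$kind %in% c("insertion", "deletion"),
               logical(1))), numeric(1))
  leftpos <- vapply(cands, function(ev)
    paste(sprintf("%06d", sort(vapply(ev, `[[`, numeric(1), "pos") + wstart - 1L)),
          collapse = ","), character(1))
  best <- order(-score, events, indels, leftpos)[1]
  out <- dplyr::bind_rows(lapply(cands[[best]], function(e) {
    new_variant_tbl(e$pos + wstart - 1L, e$end + wstart - 1L, e$kind,
                    allele = e$allele)
  }))
  if (nrow(out) > 0) {
    is_ins <- out$kind == "insertion"
    out$ins_index[is_ins] <- stats::ave(seq_len(sum(is_ins)), out$pos[is_ins],
                                        FUN = seq_along)
  }
  out
}

event_token <- function(e, wstart) {
  p <- e$pos + wstart - 1L
  switch(e$kind,
         transition = as.character(p),
         transversion = paste0(p, e$allele),
         insertion = paste0(p, "+", e$allele),
         deletion = if (e$end > e$pos) paste0(p, "-", e$end + wstart - 1L, "d")
                    else paste0(p, "d"))
}

# shift variant coordinates into window-local 1-based coordinates
local_shift <- function(v, wstart) {
  v$pos <- v$pos - (wstart - 1L)
  v$end_pos <- v$end_pos - (wstart - 1L)
  v
}

# All event lists transforming `ref` into `sample` with at most
# (minimal cost + extra) events; an indel run of any length is one event.
# Events are plain lists (pos, end, kind, allele) in window coordinates.
# The search is pruned by a suffix-cost lower bound, so only near-optimal
# alignments are visited.
enumerate_representations <- function(ref, sample, extra = 1L) {
  r <- strsplit(ref, "")[[1]]
  s <- strsplit(sample, "")[[1]]
  m <- length(r); n <- length(s)
  S <- suffix_costs(r, s)          # (m+1) x (n+1): min events for suffixes
  budget <- S[1, 1] + extra
  out <- list()
  rec <- function(i, j, used, acc) {
    if (used + S[i, j] > budget) return()
    if (i > m && j > n) {
      out[[length(out) + 1L]] <<- acc
      return()
    }
    if (i <= m && j <= n) {
      if (r[i] == s[j]) {
        rec(i + 1L, j + 1L, used, acc)
      } else {
        kind <- if (is_transition_pair(r[i], s[j])) "transition" else "transversion"
        ev <- list(pos = i, end = i, kind = kind,
                   allele = if (kind == "transversion") s[j] else NA_character_)
        rec(i + 1L, j + 1L, used + 1L, c(acc, list(ev)))
      }
    }
    if (i <= m) {
      for (k in i:m) {  # delete run r[i..k]
        ev <- list(pos = i, end = k, kind = "deletion", allele = NA_character_)
        rec(k + 1L, j, used + 1L, c(acc, list(ev)))
      }
    }
    if (j <= n && i >= 2L) {  # insert run s[j..k] after ref position i-1
      for (k in j:n) {
        ev <- list(pos = i - 1L, end = i - 1L, kind = "insertion",
                   allele = paste(s[j:k], collapse = ""))
        rec(i, k + 1L, used + 1L, c(acc, list(ev)))
      }
    }
  }
  rec(1L, 1L, 0L, list())
  out
}

suffix_costs <- function(r, s) {
  m <- length(r); n <- length(s)
  S <- matrix(0L, m + 1L, n + 1L)
  S[m + 1L, 1:n] <- 1L             # one insertion event clears any suffix
  S[1:m, n + 1L] <- 1L
  for (i in m:1) for (j in n:1) {
    best <- S[i + 1L, j + 1L] + (r[i] != s[j])
    best <- min(best, 1L + min(S[(i + 1L):(m + 1L), j]))   # delete a run
    best <- min(best, 1L + min(S[i, (j + 1L):(n + 1L)]))   # insert a run
    S[i, j] <- best
  }
  S
}
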