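#' Index a haplotype database for motif search
#'
#' Builds an inverted token -> record index over a haplotype frame. Optional:
#' [search_motif()] accepts a plain frame and scans linearly, but the index
#' makes repeated searches over large databases cheap.
#'
#' @param db A haplotype frame.
#' @return A `haplotype_db` object wrapping the frame and its index.
#' @export
haplotype_db <- function(db) {
  idx <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(db))) {
    for (tk in hap_tokens(db, i)) {
      idx[[tk]] <- c(idx[[tk]], i)
    }
  }
  structure(list(records = db, index = idx), class = "haplotype_db")
}

#' Search a haplotype database for a variant motif
#'
#' Returns the records that carry every `required` and every `backbone`
#' variant, with two standard allowances: masked (hotspot) variants are
#' ignored on the query side, and a query variant outside a record's
#' sequenced range neither matches nor excludes that record (partial
#' control-region records are judged only on what they cover). Matches are
#' returned in `sample_id` order.
#'
#' @param db A haplotype frame or a [haplotype_db()].
#' @param required Variant tibble or character tokens that define the motif
#'   of interest (e.g. `"16124"`).
#' @param backbone Optional haplogroup backbone tokens records must also
#'   carry (e.g. the C1b control-region motif).
#' @param mask A [hotspot_mask()] applied to the query sets.
#' @return The matching records (haplotype frame rows).
#' @export
search_motif <- function(db, required, backbone = NULL,
                         mask = default_hotspot_mask()) {
  hdb <- if (inherits(db, "haplotype_db")) db else NULL
  records <- if (is.null(hdb)) db else hdb$records
  if (nrow(records) == 0) return(records)
  as_tokens <- function(x) {
    if (is.null(x)) return(character())
    if (is.character(x)) x <- parse_variants(x)
    if (!is.null(mask)) x <- mask_hotspots(x, mask)
    variant_keys(x)
  }
  req <- as_tokens(required)
  bb <- as_tokens(backbone)
  query <- unique(c(req, bb))
  if (length(query) == 0) {
    out <- records[order(records$sample_id), , drop = FALSE]
    return(out)
  }
  qpos <- parse_variants(sub("^@", "", query))$pos

  if (!is.null(hdb)) {
    # a record is excluded once any in-range query token is absent from it
    violators <- integer()
    for (k in seq_along(query)) {
      p <- qpos[k]
      in_range <- ifelse(records$range_start <= records$range_end,
                         p >= records$range_start & p <= records$range_end,
                         p >= records$range_start | p <= records$range_end)
      carrying <- hdb$index[[query[k]]] %||% integer()
      violators <- union(violators, setdiff(which(in_range), carrying))
    }
    out <- records[setdiff(seq_len(nrow(records)), violators), , drop = FALSE]
  } else {
    hit <- vapply(seq_len(nrow(records)), function(i) {
      r <- hap_range(records, i)
      in_range <- range_contains(r, qpos)
      toks <- hap_tokens(records, i)
      all(query[in_range] %in% toks)
    }, logical(1))
    out <- records[hit, , drop = FALSE]
  }
  out[order(out$sample_id), , drop = FALSE]
}
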