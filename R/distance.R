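#' Mutational distance between two haplotypes
#'
#' Counts the mutational events separating two haplotypes over the
#' intersection of their sequenced ranges: the size of the symmetric
#' difference of their (optionally masked) variant sets, each multi-position
#' deletion counting as one event. With `count_indels = FALSE` insertions and
#' deletions are excluded, as is common practice in mtDNA dating.
#'
#' @param a,b One-row haplotype frames (see [haplotype()]).
#' @param count_indels Count insertion/deletion events? Default `TRUE`.
#' @param mask Optional [hotspot_mask()] applied to both sides first.
#' @return A non-negative integer; symmetric in its arguments.
#' @export
mutational_distance <- function(a, b, count_indels = TRUE, mask = NULL) {
  ra <- hap_range(a); rb <- hap_range(b)
  common <- range_intersect_positions(ra, rb)
  if (length(common) == 0) abort("disjoint sequenced ranges")
  va <- a$variants[[1]]; vb <- b$variants[[1]]
  if (!is.null(mask)) {
    va <- mask_hotspots(va, mask)
    vb <- mask_hotspots(vb, mask)
  }
  restrict <- function(v) {
    v <- v[v$pos %in% common, , drop = FALSE]
    if (!count_indels) v <- v[!v$kind %in% c("insertion", "deletion"), , drop = FALSE]
    v
  }
  ka <- variant_keys(restrict(va))
  kb <- variant_keys(restrict(vb))
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}
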