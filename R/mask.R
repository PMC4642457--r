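#' Hotspot masks
#'
#' Mutational hotspots — positions that mutate so fast they carry no
#' phylogenetic signal — are excluded from classification, tree building and
#' dating. A mask holds (i) point positions masked for any change, (ii)
#' (position, derived allele) pairs, (iii) regions in which a class of events
#' is masked, (iv) specific indel events, and (v) an optional blanket
#' `mask_indels` switch used for dating.
#'
#' The default mask follows standard mtDNA practice: 16519, the 16182C/16183C
#' poly-C companions, insertions around position 310 (the 303–315 C-stretch)
#' and the 523–524 AC deletion.
#'
#' @param points Integer positions masked outright.
#' @param pairs Tibble with columns `pos`, `allele` (derived) masked as a pair.
#' @param regions Tibble with columns `start`, `end`, `kinds` (comma-separated
#'   variant kinds masked inside the region; `"any"` for all).
#' @param variants Variant tibble of specific events to mask.
#' @param mask_indels If `TRUE`, all insertions and deletions are masked.
#' @return An object of class `hotspot_mask`.
#' @export
hotspot_mask <- function(points = integer(),
                         pairs = tibble(pos = integer(), allele = character()),
                         regions = tibble(start = integer(), end = integer(),
                                          kinds = character()),
                         variants = empty_variants(),
                         mask_indels = FALSE) {
  structure(list(points = as.integer(points), pairs = pairs, regions = regions,
                 variants = variants, mask_indels = mask_indels),
            class = "hotspot_mask")
}

#' @rdname hotspot_mask
#' @export
default_hotspot_mask <- function(mask_indels = FALSE) {
  hotspot_mask(
    points = 16519L,
    pairs = tibble(pos = c(16182L, 16183L), allele = c("C", "C")),
    regions = tibble(start = 303L, end = 315L, kinds = "insertion"),
    variants = parse_variants("523-524d"),
    mask_indels = mask_indels
  )
}

#' Which variants does a mask remove?
#'
#' @param v A variant tibble.
#' @param mask A [hotspot_mask()].
#' @return Logical vector, `TRUE` where the variant is masked.
#' @export
is_masked <- function(v, mask) {
  if (nrow(v) == 0) return(logical())
  hit <- v$pos %in% mask$points
  if (nrow(mask$pairs) > 0) {
    derived <- ifelse(v$kind == "transversion", v$allele, NA_character_)
    # a masked (pos, allele) pair matches transversions to that allele and,
    # for completeness, transitions whose derived allele is known to match
    pk <- paste(mask$pairs$pos, mask$pairs$allele)
    hit <- hit | paste(v$pos, derived) %in% pk
  }
  for (i in seq_len(nrow(mask$regions))) {
    r <- mask$regions[i, ]
    kinds <- strsplit(r$kinds, ",")[[1]]
    in_reg <- v$pos >= r$start & v$pos <= r$end
    if (!identical(kinds, "any")) in_reg <- in_reg & v$kind %in% kinds
    hit <- hit | in_reg
  }
  if (nrow(mask$variants) > 0)
    hit <- hit | variant_keys(v) %in% variant_keys(mask$variants)
  if (isTRUE(mask$mask_indels))
    hit <- hit | v$kind %in% c("insertion", "deletion")
  hit
}

#' Remove hotspot variants from haplotypes
#'
#' Returns the haplotype frame with masked variants dropped from every
#' record; the input is not modified. Masking is idempotent.
#'
#' @param h A haplotype frame (or a bare variant tibble).
#' @param mask A [hotspot_mask()]; defaults to [default_hotspot_mask()].
#' @return Same shape as the input.
#' @export
mask_hotspots <- function(h, mask = default_hotspot_mask()) {
  if (is.data.frame(h) && "pos" %in% names(h)) {
    return(h[!is_masked(h, mask), , drop = FALSE])
  }
  h$variants <- lapply(h$variants, function(v) v[!is_masked(v, mask), , drop = FALSE])
  h
}
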