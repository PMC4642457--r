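#' Construct a haplotype frame
#'
#' A haplotype frame is the package's tabular container for mtDNA samples:
#' one row per sample with columns `sample_id`, `population`, `country`,
#' `period`, `range_start`, `range_end` and a `variants` list-column of
#' variant tibbles (see [parse_variants()]). All user-facing operations take
#' and return this shape so analyses chain with the pipe.
#'
#' @param sample_id Sample identifier.
#' @param variants A variant tibble, or a character vector of compact tokens.
#' @param range A [seq_range()] or length-2 integer vector (start, end).
#' @param population,country,period Optional metadata.
#' @return A one-row tibble.
#' @examples
#' haplotype("S1", c("16223", "16298"), range = c(16024, 16569))
#' @export
haplotype <- function(sample_id, variants = empty_variants(),
                      range = c(1L, RCRS_LENGTH),
                      population = NA_character_, country = NA_character_,
                      period = NA_character_) {
  if (is.character(variants)) variants <- parse_variants(variants)
  if (is.numeric(range)) range <- seq_range(range[1], range[2])
  check_variants(variants)
  out_of_range <- !range_contains(range, variants$pos)
  if (any(out_of_range)) {
    abort(sprintf("variant %s lies outside the sequenced range %s",
                  format_variants(variants[which(out_of_range)[1], ]),
                  format_range(range)))
  }
  keys <- paste(variants$pos, variants$kind, variants$ins_index)
  if (anyDuplicated(keys))
    abort("duplicate variant (position, kind, insertion index) in haplotype")
  tibble(
    sample_id = sample_id,
    population = population, country = country, period = period,
    range_start = range$start, range_end = range$end,
    variants = list(variants)
  )
}

hap_range <- function(h, i = 1L) seq_range(h$range_start[i], h$range_end[i])

hap_tokens <- function(h, i = 1L) variant_keys(h$variants[[i]])

#' Read a haplotype table (tab-delimited, EMPOP-style)
#'
#' Expected columns: `sample_id`, `population`, `country`, `range`
#' (e.g. `"16024-16569"`; hyphen or en-dash) and `variants` (space-separated
#' compact tokens; empty, `"."` or `"rCRS"` denote no variants). Extra
#' columns are carried through; `#` starts a comment line.
#'
#' @param path File path.
#' @return A haplotype frame (one row per sample).
#' @export
read_haplotypes <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    .default = readr::col_character()))
  need <- c("sample_id", "range", "variants")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0)
    abort(paste0("haplotype table missing columns: ",
                 paste(missing, collapse = ", ")))
  ranges <- parse_range_string(raw$range)
  vars <- lapply(raw$variants, function(s) {
    s <- trimws(s %||% "")
    if (is.na(s) || s %in% c("", ".", "rCRS")) return(empty_variants())
    parse_variants(strsplit(s, "[[:space:]]+")[[1]])
  })
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    haplotype(raw$sample_id[i], vars[[i]], ranges[[i]],
              population = raw$population[i] %||% NA_character_,
              country = if ("country" %in% names(raw)) raw$country[i] else NA_character_,
              period = if ("period" %in% names(raw)) raw$period[i] else NA_character_)
  })
  dplyr::bind_rows(rows)
}

#' @rdname read_haplotypes
#' @param h A haplotype frame.
#' @export
write_haplotypes <- function(h, path) {
  out <- tibble(
    sample_id = h$sample_id,
    population = h$population,
    country = h$country,
    range = paste0(h$range_start, "-", h$range_end),
    variants = vapply(h$variants, function(v) {
      if (nrow(v) == 0) "." else paste(format_variants(v), collapse = " ")
    }, character(1))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Rebase root-relative haplotypes onto absolute (rCRS-relative) notation
#'
#' Control-region tables are often published relative to a clade root motif
#' rather than to the rCRS. `rebase_haplotypes()` adds the root motif (within
#' each record's sequenced range) to every record, yielding rCRS-relative
#' variant sets; tokens already present are not duplicated.
#'
#' @param h A haplotype frame with root-relative `variants`.
#' @param root_motif Variant tibble of the clade root motif (rCRS-relative).
#' @return The haplotype frame with absolute variant sets.
#' @export
rebase_haplotypes <- function(h, root_motif) {
  check_variants(root_motif)
  h$variants <- lapply(seq_len(nrow(h)), function(i) {
    r <- hap_range(h, i)
    motif <- root_motif[range_contains(r, root_motif$pos), , drop = FALSE]
    variants_union(h$variants[[i]], motif)
  })
  h
}
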