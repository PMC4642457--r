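#' Sequence-range helpers (1-based, inclusive, circular)
#'
#' mtDNA coordinates are 1-based rCRS positions on a circular molecule of
#' 16,569 bases. A range with `start > end` wraps through the origin (the
#' control region, 16024..576, is the canonical example).
#'
#' @param start,end 1-based inclusive endpoints.
#' @param L Molecule length (defaults to the rCRS length, 16569).
#' @return `seq_range()` returns a named list; `range_positions()` an integer
#'   vector of member positions in molecule order; `range_contains()` a
#'   logical vector.
#' @export
seq_range <- function(start, end, L = RCRS_LENGTH) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1 || end < 1 || start > L || end > L)
    abort(sprintf("range %d-%d outside 1..%d", start, end, L))
  list(start = start, end = end, L = L)
}

#' Length of the rCRS molecule
#' @export
RCRS_LENGTH <- 16569L

#' @rdname seq_range
#' @param r A range from [seq_range()].
#' @export
range_positions <- function(r) {
  if (r$start <= r$end) r$start:r$end else c(r$start:r$L, 1:r$end)
}

#' @rdname seq_range
#' @param pos Integer vector of positions to test.
#' @export
range_contains <- function(r, pos) {
  if (r$start <= r$end) pos >= r$start & pos <= r$end
  else pos >= r$start | pos <= r$end
}

range_intersect_positions <- function(a, b) {
  pa <- range_positions(a)
  pa[range_contains(b, pa)]
}

parse_range_string <- function(x, L = RCRS_LENGTH) {
  x <- gsub("–|—", "-", trimws(x))
  parts <- strsplit(x, "-", fixed = TRUE)
  lapply(parts, function(p) {
    if (length(p) != 2) abort(sprintf("malformed range '%s'", x[1]))
    seq_range(as.integer(p[1]), as.integer(p[2]), L = L)
  })
}

format_range <- function(r) paste0(r$start, "-", r$end)
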