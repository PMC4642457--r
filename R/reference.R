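#' Read / write reference and sample sequences (FASTA)
#'
#' Thin wrappers over Biostrings. `read_reference()` returns a plain upper-case
#' character string (the package's working representation of a circular
#' reference molecule) plus its id as an attribute.
#'
#' @param path FASTA file path.
#' @return `read_reference()`: a character string with attribute `id`.
#' @export
read_reference <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < 1) abort("empty FASTA file")
  seq <- toupper(as.character(set[[1]]))
  if (grepl("[^ACGTN]", seq)) abort("reference alphabet outside {A,C,G,T,N}")
  structure(seq, id = names(set)[1])
}

#' @rdname read_reference
#' @param seq Character string sequence.
#' @param id Sequence id for the FASTA header.
#' @export
write_reference <- function(seq, path, id = attr(seq, "id") %||% "reference") {
  set <- Biostrings::DNAStringSet(as.character(seq))
  names(set) <- id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Apply a variant set to a reference sequence
#'
#' Reconstructs the sample sequence a haplotype denotes: transitions flip the
#' reference base, transversions substitute the stored allele, deletions drop
#' their range, insertions add bases after their anchor position (ordered by
#' `ins_index`). Back-mutation (`@`) records revert to the reference state and
#' therefore leave the sequence unchanged when applied from the reference
#' itself.
#'
#' @param variants A variant tibble (or one-row haplotype frame, in which case
#'   its `variants` list-column is used).
#' @param reference Reference sequence as a character string.
#' @param alignment If `TRUE`, also return the implied pairwise alignment
#'   (`ref_aln`, `sample_aln` with `-` gaps) for use with [call_variants()].
#' @return The derived sequence (character string), or a list with elements
#'   `sample`, `ref_aln`, `sample_aln` when `alignment = TRUE`.
#' @export
apply_variants <- function(variants, reference, alignment = FALSE) {
  v <- as_variant_tbl(variants)
  check_variants(v)
  L <- nchar(reference)
  if (nrow(v) > 0 && any(v$end_pos > L)) abort("variant position outside reference")
  ref_bases <- strsplit(reference, "")[[1]]
  bases <- ref_bases
  ins <- rep("", L + 1L)  # ins[p + 1] = bases inserted after position p
  deleted <- rep(FALSE, L)

  act <- v[!v$back, , drop = FALSE]
  subs <- act[act$kind %in% c("transition", "transversion"), , drop = FALSE]
  dels <- act[act$kind == "deletion", , drop = FALSE]
  inss <- act[act$kind == "insertion", , drop = FALSE]

  if (nrow(subs) > 0) {
    newb <- ifelse(subs$kind == "transition",
                   transition_partner(bases[subs$pos]), subs$allele)
    bases[subs$pos] <- newb
  }
  for (i in seq_len(nrow(dels))) deleted[dels$pos[i]:dels$end_pos[i]] <- TRUE
  if (nrow(subs) > 0 && any(deleted[subs$pos]))
    abort("substitution inside a deleted range")
  if (nrow(inss) > 0) {
    inss <- inss[order(inss$pos, inss$ins_index), , drop = FALSE]
    if (any(deleted[inss$pos]))
      abort("insertion and deletion overlapping the same position")
    for (i in seq_len(nrow(inss)))
      ins[inss$pos[i] + 1L] <- paste0(ins[inss$pos[i] + 1L], inss$allele[i])
  }

  sample_cols <- ifelse(deleted, "", bases)
  pieces <- paste0(sample_cols, ins[-1L])
  out <- paste0(ins[1L], paste(pieces, collapse = ""))
  if (!alignment) return(out)

  ref_cols <- paste0(ref_bases, strrep("-", nchar(ins[-1L])))
  samp_cols <- paste0(ifelse(deleted, "-", bases), ins[-1L])
  ref_aln <- paste0(strrep("-", nchar(ins[1L])), paste(ref_cols, collapse = ""))
  samp_aln <- paste0(ins[1L], paste(samp_cols, collapse = ""))
  list(sample = out, ref_aln = ref_aln, sample_aln = samp_aln)
}

as_variant_tbl <- function(x) {
  if (is.data.frame(x) && "variants" %in% names(x) && !"pos" %in% names(x)) {
    stopifnot(nrow(x) == 1)
    return(x$variants[[1]])
  }
  x
}

#' Call variants from an aligned sample sequence
#'
#' Compares a sample to the reference over a range and returns the variant
#' set transforming one into the other. Input is either an ungapped sample of
#' the same length as the range (columnwise comparison) or an explicit
#' pairwise alignment (`sample_aln` / `ref_aln`, `-` gaps). Indels are
#' left-aligned: an insertion or deletion inside a homopolymer run is reported
#' at the leftmost equivalent position.
#'
#' @param sample Ungapped sample sequence covering `range` (ignored when an
#'   alignment is given).
#' @param reference Reference sequence (character string).
#' @param range A [seq_range()]; defaults to the whole molecule.
#' @param sample_aln,ref_aln Optional aligned sequences of equal length.
#' @param sample_id,population,country Metadata for the returned haplotype.
#' @return A one-row haplotype frame (see [haplotype()]).
#' @export
call_variants <- function(sample = NULL, reference, range = NULL,
                          sample_aln = NULL, ref_aln = NULL,
                          sample_id = "sample", population = NA_character_,
                          country = NA_character_) {
  L <- nchar(reference)
  if (is.null(range)) range <- seq_range(1L, L, L = L)
  pos_map <- range_positions(range)

  if (is.null(sample_aln)) {
    sample <- toupper(sample)
    if (grepl("[^ACGTN-]", sample)) abort("non-nucleotide characters in sample")
    if (grepl("-", sample, fixed = TRUE))
      abort("gapped sample requires `ref_aln`")
    if (nchar(sample) != length(pos_map))
      abort("alignment length mismatch: sample does not cover the range")
    ref_sub <- paste(strsplit(reference, "")[[1]][pos_map], collapse = "")
    sample_aln <- sample
    ref_aln <- ref_sub
  } else {
    sample_aln <- toupper(sample_aln); ref_aln <- toupper(ref_aln)
    if (nchar(sample_aln) != nchar(ref_aln)) abort("alignment length mismatch")
    if (grepl("[^ACGTN-]", paste0(sample_aln, ref_aln)))
      abort("non-nucleotide characters in alignment")
  }

  rc <- strsplit(ref_aln, "")[[1]]
  sc <- strsplit(sample_aln, "")[[1]]
  # reference position of each column (NA on insertion columns)
  idx <- cumsum(rc != "-")
  col_pos <- ifelse(rc == "-", NA_integer_, pos_map[idx])
  if (sum(rc != "-") != length(pos_map))
    abort("alignment length mismatch: reference side does not cover the range")

  vars <- list()
  i <- 1L
  n <- length(rc)
  while (i <= n) {
    if (rc[i] == "-") {                       # insertion run
      j <- i
      while (j < n && rc[j + 1L] == "-") j <- j + 1L
      anchor <- if (i == 1L) pos_map[1L] - 1L else col_pos[i - 1L]
      seqins <- paste(sc[i:j], collapse = "")
      vars[[length(vars) + 1L]] <-
        left_align_insertion(anchor, seqins, reference)
      i <- j + 1L
    } else if (sc[i] == "-") {                # deletion run
      j <- i
      while (j < n && sc[j + 1L] == "-" && rc[j + 1L] != "-") j <- j + 1L
      d <- left_align_deletion(col_pos[i], col_pos[j], reference)
      vars[[length(vars) + 1L]] <- d
      i <- j + 1L
    } else {
      if (sc[i] != rc[i] && sc[i] != "N" && rc[i] != "N") {
        kind <- if (is_transition_pair(rc[i], sc[i])) "transition" else "transversion"
        vars[[length(vars) + 1L]] <-
          new_variant_tbl(col_pos[i], col_pos[i], kind,
                          allele = if (kind == "transversion") sc[i] else NA_character_,
                          ref = rc[i])
      }
      i <- i + 1L
    }
  }
  v <- if (length(vars)) dplyr::bind_rows(vars) else empty_variants()
  # number multiple insertions at one anchor
  if (nrow(v) > 0) {
    is_ins <- v$kind == "insertion"
    if (any(is_ins)) {
      v$ins_index[is_ins] <- stats::ave(seq_len(sum(is_ins)), v$pos[is_ins],
                                        FUN = seq_along)
    }
    v <- v[order(v$pos, v$kind, v$ins_index), , drop = FALSE]
  }
  haplotype(sample_id, v, range, population = population, country = country)
}

left_align_insertion <- function(pos, bases, reference) {
  # shift an insertion leftwards while the preceding reference base equals the
  # last inserted base (rotating the inserted string)
  b <- strsplit(bases, "")[[1]]
  while (pos >= 1L && substring(reference, pos, pos) == b[length(b)]) {
    b <- c(b[length(b)], b[-length(b)])
    pos <- pos - 1L
  }
  new_variant_tbl(max(pos, 0L), max(pos, 0L), "insertion",
                  allele = paste(b, collapse = ""))
}

left_align_deletion <- function(start, end, reference) {
  while (start > 1L &&
         substring(reference, start - 1L, start - 1L) ==
         substring(reference, end, end)) {
    start <- start - 1L
    end <- end - 1L
  }
  new_variant_tbl(start, end, "deletion")
}
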