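#' @importFrom rlang .data abort %||%
#' @importFrom tibble tibble as_tibble
NULL

# Canonical column set of a variant tibble. `ref` is optional knowledge of the
# reference allele (carried by the table dialect), not part of variant identity.
VARIANT_COLS <- c("pos", "end_pos", "kind", "allele", "back", "ins_index")

new_variant_tbl <- function(pos = integer(), end_pos = pos,
                            kind = character(), allele = NA_character_,
                            back = FALSE, ins_index = NA_integer_,
                            ref = NA_character_) {
  tibble(
    pos = as.integer(pos), end_pos = as.integer(end_pos),
    kind = as.character(kind), allele = as.character(allele),
    back = as.logical(back), ins_index = as.integer(ins_index),
    ref = as.character(ref)
  )
}

#' An empty variant table
#'
#' @return A zero-row tibble with the canonical variant columns
#'   (`pos`, `end_pos`, `kind`, `allele`, `back`, `ins_index`, `ref`).
#' @export
empty_variants <- function() new_variant_tbl()

variant_error <- function(token, why) {
  abort(sprintf("malformed variant token '%s': %s", token, why),
        class = "mitorho_notation_error")
}

check_variants <- function(v) {
  stopifnot(is.data.frame(v))
  missing <- setdiff(VARIANT_COLS, names(v))
  if (length(missing) > 0) {
    abort(paste0("not a variant table; missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  bad <- v$end_pos < v$pos
  if (any(bad)) variant_error(format_variants(v[which(bad)[1], ]),
                              "deletion range reversed")
  invisible(v)
}

#' Parse mtDNA variant tokens
#'
#' Parses rCRS-relative variant nomenclature into a variant tibble. Two
#' dialects are understood:
#' \describe{
#'   \item{compact}{forensic shorthand, e.g. `"16223"` (transition),
#'     `"3552A"` (transversion to A), `"249d"` / `"290-291d"` (deletions;
#'     en-dash accepted), `"309+C"` (insertion; a second insertion event at
#'     the same site is written `"309.2+C"`), `"@16223"` (back mutation).}
#'   \item{table}{position-plus-substitution layout, e.g. token `"8584"`
#'     with `substitution = "G-A"`; indel tokens keep the compact shape and
#'     a substitution of `"-"`.}
#' }
#'
#' @param tokens Character vector of variant tokens.
#' @param dialect `"compact"` or `"table"`.
#' @param substitution For the table dialect, a character vector parallel to
#'   `tokens` holding `"REF-DERIVED"` pairs (or `"-"` for indels).
#' @return A variant tibble with one row per token, in input order.
#' @examples
#' parse_variants(c("16327", "@16223", "290-291d", "309+C", "3552A"))
#' parse_variants("8584", dialect = "table", substitution = "G-A")
#' @export
parse_variants <- function(tokens, dialect = c("compact", "table"),
                           substitution = NULL) {
  dialect <- match.arg(dialect)
  if (length(tokens) == 0) return(empty_variants())
  if (dialect == "table") {
    if (is.null(substitution)) abort("table dialect requires `substitution`")
    stopifnot(length(substitution) == length(tokens))
  }
  if (dialect == "compact") {
    # fast path: plain (possibly back-mutation) transitions, vectorised
    tidy <- gsub("[[:space:]]", "", tokens)
    back <- startsWith(tidy, "@")
    bare <- sub("^@", "", tidy)
    if (all(grepl("^[0-9]+$", bare))) {
      p <- as.integer(bare)
      if (any(is.na(p) | p < 1)) variant_error(tokens[which(is.na(p) | p < 1)[1]],
                                               "malformed position")
      return(new_variant_tbl(p, p, rep("transition", length(p)),
                             back = back))
    }
  }
  rows <- lapply(seq_along(tokens), function(i) {
    parse_one_variant(tokens[i],
                      if (dialect == "table") substitution[i] else NULL)
  })
  dplyr::bind_rows(rows)
}

parse_one_variant <- function(token, substitution = NULL) {
  raw <- token
  tok <- gsub("–|—", "-", trimws(token))  # en/em dash -> hyphen
  tok <- gsub("[[:space:]]", "", tok)
  if (!nzchar(tok)) variant_error(raw, "empty token")
  back <- startsWith(tok, "@")
  if (back) tok <- substring(tok, 2)

  ref <- NA_character_
  derived <- NA_character_
  if (!is.null(substitution)) {
    sub <- gsub("–|−|[[:space:]]", "-", substitution)
    if (grepl("^[ACGT]-[ACGT]$", sub)) {
      ref <- substring(sub, 1, 1)
      derived <- substring(sub, 3, 3)
    } else if (!sub %in% c("-", "", "--")) {
      variant_error(raw, sprintf("unrecognised substitution '%s'", substitution))
    }
  }

  if (grepl("^\\d+-\\d+d$", tok)) {            # range deletion
    ends <- as.integer(strsplit(sub("d$", "", tok), "-")[[1]])
    if (ends[2] < ends[1]) variant_error(raw, "deletion range reversed")
    return(new_variant_tbl(ends[1], ends[2], "deletion", back = back, ref = ref))
  }
  if (grepl("^\\d+d$", tok)) {                 # point deletion
    p <- as.integer(sub("d$", "", tok))
    return(new_variant_tbl(p, p, "deletion", back = back, ref = ref))
  }
  m <- regmatches(tok, regexec("^(\\d+)(?:\\.(\\d+))?\\+([A-Za-z]+)$", tok))[[1]]
  if (length(m) > 0) {                         # insertion
    bases <- toupper(m[4])
    if (grepl("[^ACGT]", bases)) variant_error(raw, "inserted bases outside {A,C,G,T}")
    idx <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    if (idx < 1) variant_error(raw, "insertion index must be >= 1")
    p <- as.integer(m[2])
    return(new_variant_tbl(p, p, "insertion", allele = bases, back = back,
                           ins_index = idx, ref = ref))
  }
  m <- regmatches(tok, regexec("^(\\d+)([A-Za-z]?)$", tok))[[1]]
  if (length(m) == 0) variant_error(raw, "unrecognised shape")
  p <- suppressWarnings(as.integer(m[2]))
  if (is.na(p) || p < 1) variant_error(raw, "malformed position")
  suffix <- toupper(m[3])
  if (nzchar(suffix)) {                        # explicit derived allele
    if (!suffix %in% c("A", "C", "G", "T"))
      variant_error(raw, "allele outside {A,C,G,T}")
    kind <- if (!is.na(ref) && is_transition_pair(ref, suffix))
      "transition" else "transversion"
    allele <- if (kind == "transversion") suffix else NA_character_
    return(new_variant_tbl(p, p, kind, allele = allele, back = back, ref = ref))
  }
  # bare position: transition; the table dialect may reveal a transversion
  if (!is.na(ref) && !is.na(derived)) {
    kind <- if (is_transition_pair(ref, derived)) "transition" else "transversion"
    allele <- if (kind == "transversion") derived else NA_character_
    return(new_variant_tbl(p, p, kind, allele = allele, back = back, ref = ref))
  }
  new_variant_tbl(p, p, "transition", back = back, ref = ref)
}

is_transition_pair <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G") && a != b) ||
    (a %in% c("C", "T") && b %in% c("C", "T") && a != b)
}

transition_partner <- function(base) {
  unname(c(A = "G", G = "A", C = "T", T = "C", N = "N")[base])
}

#' Format variants as nomenclature tokens
#'
#' Inverse of [parse_variants()]. The compact dialect returns one token per
#' variant; the table dialect returns a tibble of `(variant, substitution)`
#' columns and requires reference alleles (either stored in the `ref` column
#' or derivable from `reference`).
#'
#' @param v A variant tibble.
#' @param dialect `"compact"` or `"table"`.
#' @param reference Optional reference sequence (character string) used to
#'   fill in reference alleles for the table dialect.
#' @return Character vector of tokens (compact) or a tibble (table).
#' @export
format_variants <- function(v, dialect = c("compact", "table"),
                            reference = NULL) {
  dialect <- match.arg(dialect)
  if (nrow(v) == 0) {
    return(if (dialect == "compact") character()
           else tibble(variant = character(), substitution = character()))
  }
  check_variants(v)
  core <- vapply(seq_len(nrow(v)), function(i) {
    r <- v[i, ]
    body <- switch(r$kind,
      transition = as.character(r$pos),
      transversion = paste0(r$pos, r$allele),
      deletion = if (r$end_pos > r$pos) paste0(r$pos, "-", r$end_pos, "d")
                 else paste0(r$pos, "d"),
      insertion = if (!is.na(r$ins_index) && r$ins_index > 1L)
        paste0(r$pos, ".", r$ins_index, "+", r$allele)
      else paste0(r$pos, "+", r$allele),
      abort(sprintf("unknown variant kind '%s'", r$kind))
    )
    paste0(if (isTRUE(r$back)) "@" else "", body)
  }, character(1))
  if (dialect == "compact") return(core)

  refs <- if ("ref" %in% names(v)) v$ref else rep(NA_character_, nrow(v))
  subs <- vapply(seq_len(nrow(v)), function(i) {
    r <- v[i, ]
    if (r$kind %in% c("insertion", "deletion")) return("-")
    ref <- refs[i]
    if (is.na(ref) && !is.null(reference))
      ref <- substring(reference, r$pos, r$pos)
    if (is.na(ref)) abort(paste0("table dialect needs a reference allele for ",
                                 core[i]))
    derived <- if (r$kind == "transition") transition_partner(ref) else r$allele
    paste0(ref, "-", derived)
  }, character(1))
  tibble(variant = sub("^@", "", core),
         substitution = ifelse(grepl("^@", core), paste0("@", subs), subs))
}

# Canonical token identity used for set operations on variant tables.
variant_keys <- function(v) {
  if (nrow(v) == 0) return(character())
  format_variants(v)
}

# Set difference / intersection on variant tables by canonical token.
variants_setdiff <- function(a, b) a[!variant_keys(a) %in% variant_keys(b), , drop = FALSE]
variants_intersect <- function(a, b) a[variant_keys(a) %in% variant_keys(b), , drop = FALSE]
variants_union <- function(a, b) {
  out <- dplyr::bind_rows(a, b)
  out[!duplicated(variant_keys(out)), , drop = FALSE]
}
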