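#' Standard rCRS gene map
#'
#' Coordinates of the mitochondrial protein-coding genes, rRNAs and
#' control-region hypervariable segments in rCRS numbering (NC_012920).
#' ND6 is encoded on the light strand; several genes end in an incomplete
#' stop codon completed by polyadenylation, so protein lengths need not be
#' multiples of three. Individual tRNA genes are not itemised: positions
#' falling in no listed feature are reported as `tRNA/other`.
#'
#' @return Tibble with columns `feature`, `class` (`protein`, `rRNA`,
#'   `control`), `strand` (`+`/`-`), `start`, `end`.
#' @export
rcrs_gene_map <- function() {
  tibble::tribble(
    ~feature, ~class,    ~strand, ~start,  ~end,
    "HVS-2",  "control", "+",     1L,      576L,
    "12 S",   "rRNA",    "+",     648L,    1601L,
    "16 S",   "rRNA",    "+",     1671L,   3229L,
    "ND1",    "protein", "+",     3307L,   4262L,
    "ND2",    "protein", "+",     4470L,   5511L,
    "CO1",    "protein", "+",     5904L,   7445L,
    "CO2",    "protein", "+",     7586L,   8269L,
    "ATP8",   "protein", "+",     8366L,   8572L,
    "ATP6",   "protein", "+",     8527L,   9207L,
    "CO3",    "protein", "+",     9207L,   9990L,
    "ND3",    "protein", "+",     10059L,  10404L,
    "ND4L",   "protein", "+",     10470L,  10766L,
    "ND4",    "protein", "+",     10760L,  12137L,
    "ND5",    "protein", "+",     12337L,  14148L,
    "ND6",    "protein", "-",     14149L,  14673L,
    "CYTB",   "protein", "+",     14747L,  15887L,
    "HVS-1",  "control", "+",     16024L,  16569L
  )
}

# HVS partitions used by the control-region clocks
HVS1_PARTITION <- c(16051L, 16400L)
HVS2_PARTITION <- c(68L, 263L)

MITO_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C", N = "N")

.mito_code_env <- new.env(parent = emptyenv())

mito_translate <- function(codon) {
  if (is.null(.mito_code_env$code))
    .mito_code_env$code <- Biostrings::getGeneticCode("SGC1")  # vertebrate mito
  if (nchar(codon) != 3 || grepl("[^ACGT]", codon)) return(NA_character_)
  unname(.mito_code_env$code[codon])
}

features_at <- function(pos, genes) {
  genes[genes$start <= pos & genes$end >= pos, , drop = FALSE]
}

#' Annotate variants with gene context and codon effect
#'
#' For substitutions inside protein-coding genes the affected codon is
#' translated on the coding strand (light-strand genes are reverse
#' complemented) with the vertebrate mitochondrial genetic code, and the
#' change is classified as `synonymous` or `replacement` (with the
#' amino-acid change). Other positions yield `rRNA`, `non-coding` (control
#' region), or `tRNA` (positions outside all mapped features); indels are
#' labelled `indel`.
#'
#' @param v A variant tibble (or one-row haplotype frame).
#' @param genes A gene map, by default [rcrs_gene_map()].
#' @param reference Reference sequence string; required for codon effects.
#' @return The variant tibble with columns `feature`, `feature_class`,
#'   `effect`, `aa_change` appended.
#' @examples
#' ref <- synthetic_reference(seed = 1)
#' annotate_variants(parse_variants(c("8584", "7028")), reference = ref)
#' @export
annotate_variants <- function(v, genes = rcrs_gene_map(), reference = NULL) {
  v <- as_variant_tbl(v)
  check_variants(v)
  n <- nrow(v)
  feature <- character(n); fclass <- character(n)
  effect <- character(n); aa_change <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (v$pos[i] > RCRS_LENGTH) abort("position outside reference")
    ft <- features_at(v$pos[i], genes)
    if (nrow(ft) == 0) {
      feature[i] <- "tRNA/other"; fclass[i] <- "tRNA"; effect[i] <- "tRNA"
      next
    }
    feature[i] <- paste(ft$feature, collapse = "/")
    fclass[i] <- ft$class[1]
    if (v$kind[i] %in% c("insertion", "deletion")) {
      effect[i] <- "indel"
      next
    }
    if (ft$class[1] == "rRNA") { effect[i] <- "rRNA"; next }
    if (ft$class[1] == "control") { effect[i] <- "non-coding"; next }
    if (is.null(reference))
      abort("protein annotation requires a reference sequence")
    cd <- codon_effect(v$pos[i], v$kind[i], v$allele[i], ft[1, ], reference)
    effect[i] <- cd$effect
    aa_change[i] <- cd$aa_change
  }
  v$feature <- feature
  v$feature_class <- fclass
  v$effect <- effect
  v$aa_change <- aa_change
  v
}

codon_effect <- function(pos, kind, allele, gene, reference) {
  heavy <- function(p) substring(reference, p, p)
  ref_base <- heavy(pos)
  new_base <- if (kind == "transition") transition_partner(ref_base) else allele
  if (gene$strand == "+") {
    offset <- pos - gene$start
    codon_i <- offset %/% 3L
    cpos <- gene$start + 3L * codon_i + 0:2
    if (cpos[3] > gene$end)  # trailing incomplete stop codon
      return(list(effect = "incomplete-codon", aa_change = NA_character_))
    ref_codon <- paste(vapply(cpos, heavy, character(1)), collapse = "")
    alt <- strsplit(ref_codon, "")[[1]]
    alt[pos - cpos[1] + 1L] <- new_base
  } else {
    offset <- gene$end - pos
    codon_i <- offset %/% 3L
    cpos <- gene$end - 3L * codon_i - 0:2  # heavy positions, coding order
    if (cpos[3] < gene$start)
      return(list(effect = "incomplete-codon", aa_change = NA_character_))
    ref_codon <- paste(MITO_COMPLEMENT[vapply(cpos, heavy, character(1))],
                       collapse = "")
    alt <- strsplit(ref_codon, "")[[1]]
    alt[which(cpos == pos)] <- MITO_COMPLEMENT[[new_base]]
  }
  alt_codon <- paste(alt, collapse = "")
  aa_ref <- mito_translate(ref_codon)
  aa_alt <- mito_translate(alt_codon)
  if (is.na(aa_ref) || is.na(aa_alt))
    return(list(effect = "incomplete-codon", aa_change = NA_character_))
  if (aa_ref == aa_alt) list(effect = "synonymous", aa_change = NA_character_)
  else list(effect = "replacement", aa_change = paste0(aa_ref, "-", aa_alt))
}

#' Sites at which a transition is guaranteed synonymous
#'
#' Third codon positions of protein-coding genes: under the vertebrate
#' mitochondrial code every third-position transition is synonymous, so
#' these sites form the sampling pool for synonymous-clock simulations.
#'
#' @param genes A gene map.
#' @return Sorted integer vector of rCRS positions.
#' @export
synonymous_transition_sites <- function(genes = rcrs_gene_map()) {
  out <- integer()
  prot <- genes[genes$class == "protein", , drop = FALSE]
  covered <- integer(RCRS_LENGTH)
  for (i in seq_len(nrow(prot)))
    covered[prot$start[i]:prot$end[i]] <- covered[prot$start[i]:prot$end[i]] + 1L
  for (i in seq_len(nrow(prot))) {
    g <- prot[i, ]
    if (g$strand == "+") {
      third <- seq(g$start + 2L, g$end, by = 3L)
    } else {
      third <- seq(g$end - 2L, g$start, by = -3L)
    }
    out <- c(out, third)
  }
  out <- unique(out)
  sort(out[covered[out] == 1L])  # drop overlapping reading frames
}
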