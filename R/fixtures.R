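#' Packaged fixtures: the Aconcagua mummy haplotype, its C1b*i* relatives,
#' and the toy haplogroup tree
#'
#' `aconcagua_haplotype()` loads the complete mitogenome haplotype of the
#' 500-year-old Aconcagua child mummy (51 variants relative to the rCRS; the
#' 10 lineage-private ones are flagged in the `private` column of the
#' variant tibble). `c1bi_related_haplotypes()` loads the published
#' control-region haplotypes related to the mummy's C1b*i* clade, with
#' variants relative to the C1b root. `toy_haplogroup_tree()` loads the
#' condensed rCRS-anchored haplogroup skeleton used for classification.
#'
#' @return A haplotype frame, or a `haplo_tree`.
#' @export
aconcagua_haplotype <- function() {
  path <- system.file("extdata", "aconcagua_variants.tsv", package = "mitorho",
                      mustWork = TRUE)
  tab <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    .default = readr::col_character()))
  v <- parse_variants(tab$variant, dialect = "table",
                      substitution = tab$substitution)
  v$private <- tab$private == "yes"
  haplotype("Aconcagua", v, range = c(1L, RCRS_LENGTH),
            population = "Inca", country = "Argentina (Mendoza)",
            period = "AD 1480")
}

#' @rdname aconcagua_haplotype
#' @export
c1bi_related_haplotypes <- function() {
  path <- system.file("extdata", "c1bi_related.tsv", package = "mitorho",
                      mustWork = TRUE)
  read_haplotypes(path)
}

#' @rdname aconcagua_haplotype
#' @export
toy_haplogroup_tree <- function() {
  path <- system.file("extdata", "toy_tree.txt", package = "mitorho",
                      mustWork = TRUE)
  read_haplogroup_tree(path)
}

#' The C1b control-region backbone motif
#'
#' HVS-I part of the C1b cumulative motif on the packaged tree — the
#' backbone used for control-region database searches.
#'
#' @param tree A `haplo_tree` (defaults to the packaged toy tree).
#' @return A variant tibble.
#' @export
c1b_hvs1_backbone <- function(tree = toy_haplogroup_tree()) {
  m <- node_motif(tree, "C1b")
  m <- m[!m$back, , drop = FALSE]
  m[m$pos >= 16024L, , drop = FALSE]
}

# Base anchors of the synthetic reference: reference alleles implied by the
# published variant table, codon contexts reproducing its amino-acid
# changes (vertebrate mitochondrial code), the HVS-II poly-T / poly-C
# contexts behind indel placement, and assorted control-region sites used
# by fixtures.
reference_anchors <- function() {
  tibble::tribble(
    ~pos, ~base,
    56L, "A", 57L, "T", 58L, "T", 59L, "T", 60L, "T", 64L, "C", 73L, "A",
    146L, "T", 194L, "C",
    248L, "G", 249L, "A",
    263L, "A", 289L, "T", 290L, "A", 291L, "A",
    303L, "C", 304L, "C", 305L, "C", 306L, "C", 307L, "C", 308L, "C",
    309L, "C", 310L, "T", 311L, "C", 312L, "C", 313L, "C", 314L, "C",
    315L, "C",
    455L, "G", 489L, "T", 493L, "A",
    522L, "G", 523L, "A", 524L, "C",
    662L, "T", 750L, "A", 1438L, "A", 2563L, "T", 2706L, "A",
    3550L, "C", 3551L, "C", 3552L, "T",
    4715L, "A", 4769L, "A", 5135L, "C",
    7028L, "C", 7194L, "G", 7195L, "G", 7196L, "C",
    8584L, "G", 8585L, "C",
    8701L, "A", 8702L, "C",
    8725L, "A", 8726L, "C",
    8860L, "A", 8861L, "C",
    9540L, "T", 9541L, "T", 9542L, "A", 9545L, "A",
    10398L, "A", 10399L, "C", 10400L, "C", 10873L, "T",
    11719L, "G", 11914L, "G", 12705L, "C", 13263L, "A",
    14317L, "A", 14318L, "T", 14319L, "T",
    14765L, "A", 14766L, "C", 14767L, "T",
    14783L, "T", 14784L, "T", 14785L, "A",
    15043L, "G", 15301L, "G",
    15326L, "A", 15327L, "C",
    15485L, "C", 15486L, "T", 15487L, "A",
    16092L, "T", 16111L, "C", 16124L, "T",
    16182L, "A", 16183L, "A", 16189L, "T",
    16222L, "C", 16223L, "C", 16298L, "T", 16311L, "T",
    16316L, "A", 16325L, "T", 16327L, "C", 16362L, "T", 16519L, "T"
  )
}

#' Synthetic rCRS-like reference genome
#'
#' A random 16,569-base sequence whose bases are pinned, at the positions
#' the packaged fixtures touch, to the states the published variant table
#' implies (reference alleles, codon contexts reproducing the printed
#' amino-acid changes, homopolymer contexts around the common control-region
#' indels). It is a stand-in for the rCRS sufficient for every computation
#' in this package that needs sequence context; it is *synthetic* and must
#' not be mistaken for the true rCRS.
#'
#' @param seed RNG seed for the unconstrained positions.
#' @param length Molecule length.
#' @return Character string of length `length` with attribute
#'   `id = "synthetic-rCRS"`.
#' @export
synthetic_reference <- function(seed = 1L, length = RCRS_LENGTH) {
  bases <- withr::with_seed(seed,
    sample(c("A", "C", "G", "T"), length, replace = TRUE))
  a <- reference_anchors()
  bases[a$pos] <- a$base
  structure(paste(bases, collapse = ""), id = "synthetic-rCRS")
}

#' Laboratory-operator contamination fixtures
#'
#' Two synthetic operator control-region profiles: an H2-like haplotype
#' (rCRS-near) and a W5a1a1a-like haplotype, both over the control-region
#' range (wrapping the origin). Used to exercise the contamination
#' cross-check against a C1b sample.
#'
#' @return A haplotype frame with two rows.
#' @export
operator_haplotypes <- function() {
  dplyr::bind_rows(
    haplotype("operator_H2", c("263"), range = c(16024L, 576L),
              population = "lab staff"),
    haplotype("operator_W5", c("73", "263", "16223", "57", "60+T"),
              range = c(16024L, 576L), population = "lab staff")
  )
}

#' Seeded decoy C1b database
#'
#' Synthetic HVS-I records that carry the C1b control-region backbone but
#' never the 16124 transition, drawn from a hotspot-free position pool, for
#' embedding the published C1b*i* relatives in a realistic search database.
#'
#' @param n Number of decoys.
#' @param seed RNG seed.
#' @param tree Haplogroup tree supplying the C1b backbone.
#' @return A haplotype frame of `n` records with range 16024-16383.
#' @export
decoy_c1b_db <- function(n = 100L, seed = 1L, tree = toy_haplogroup_tree()) {
  backbone <- c1b_hvs1_backbone(tree)
  pool <- setdiff(16051:16365,
                  c(16124L, backbone$pos, 16182L, 16183L, 16189L, 16092L))
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      k <- sample(1:3, 1)
      extra <- parse_variants(as.character(sort(sample(pool, k))))
      haplotype(sprintf("decoy%03d", i), variants_union(backbone, extra),
                range = c(16024L, 16383L), population = "synthetic decoy")
    })
    dplyr::bind_rows(rows)
  })
}

#' Write all packaged and generated fixtures to a directory
#'
#' Emits the mummy variant table, the C1b*i* related-haplotype table, the
#' toy haplogroup tree, a synthetic reference FASTA, the operator
#' contamination fixtures and a decoy search database.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed for the generated (synthetic) fixtures.
#' @return Invisibly, a named character vector of file paths.
#' @export
make_fixtures <- function(dir = tempfile("fixtures"), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mummy = file.path(dir, "aconcagua_variants.tsv"),
    related = file.path(dir, "c1bi_related.tsv"),
    tree = file.path(dir, "toy_tree.txt"),
    reference = file.path(dir, "synthetic_reference.fasta"),
    operators = file.path(dir, "operators.tsv"),
    decoys = file.path(dir, "decoy_db.tsv")
  )
  file.copy(system.file("extdata", "aconcagua_variants.tsv", package = "mitorho"),
            paths[["mummy"]], overwrite = TRUE)
  file.copy(system.file("extdata", "c1bi_related.tsv", package = "mitorho"),
            paths[["related"]], overwrite = TRUE)
  file.copy(system.file("extdata", "toy_tree.txt", package = "mitorho"),
            paths[["tree"]], overwrite = TRUE)
  write_reference(synthetic_reference(seed), paths[["reference"]])
  write_haplotypes(operator_haplotypes(), paths[["operators"]])
  write_haplotypes(decoy_c1b_db(seed = seed), paths[["decoys"]])
  invisible(paths)
}
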