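test_that("compact tokens parse to the events they denote", {
  v <- parse_variants(c("16327", "@16223", "290-291d", "290–291d",
                        "3552A", "309+C", "309.2+C", "249d"))
  expect_equal(v$kind, c("transition", "transition", "deletion", "deletion",
                         "transversion", "insertion", "insertion", "deletion"))
  expect_equal(v$pos, c(16327L, 16223L, 290L, 290L, 3552L, 309L, 309L, 249L))
  expect_equal(v$end_pos[3:4], c(291L, 291L))   # en-dash accepted
  expect_true(v$back[2])
  expect_equal(v$allele[5:7], c("A", "C", "C"))
  expect_equal(v$ins_index[6:7], c(1L, 2L))
})

test_that("table dialect distinguishes transitions from transversions", {
  v <- parse_variants(c("8584", "3552", "60+T"), dialect = "table",
                      substitution = c("G-A", "T-A", "-"))
  expect_equal(v$kind, c("transition", "transversion", "insertion"))
  expect_equal(v$allele, c(NA, "A", "T"))
  expect_equal(v$ref, c("G", "T", NA))
})

test_that("malformed tokens raise notation errors naming the token", {
  expect_error(parse_variants("291-290d"), "291-290d")
  expect_error(parse_variants("16327Z"), "allele")
  expect_error(parse_variants("xyz"), "xyz")
  expect_error(parse_variants(""), "empty")
  expect_error(parse_variants("309+CX"), "309\\+CX")
})

test_that("format/parse round-trips are identities on random variants", {
  withr::with_seed(7, {
    for (rep in 1:40) {
      kind <- sample(c("transition", "transversion", "insertion", "deletion"), 1)
      pos <- sample(16569L, 1)
      v <- switch(kind,
        transition = new_variant_tbl(pos, pos, "transition",
                                     back = sample(c(TRUE, FALSE), 1)),
        transversion = new_variant_tbl(pos, pos, "transversion",
                                       allele = sample(c("A", "C", "G", "T"), 1)),
        insertion = new_variant_tbl(pos, pos, "insertion",
                                    allele = paste(sample(c("A", "C", "G", "T"),
                                                          sample(1:3, 1),
                                                          replace = TRUE),
                                                   collapse = ""),
                                    ins_index = sample(1:3, 1)),
        deletion = new_variant_tbl(pos, min(pos + sample(0:2, 1), 16569L),
                                   "deletion"))
      tok <- format_variants(v)
      v2 <- parse_variants(tok)
      expect_equal(v2[, c("pos", "end_pos", "kind", "allele", "back", "ins_index")],
                   v[, c("pos", "end_pos", "kind", "allele", "back", "ins_index")])
      expect_equal(format_variants(v2), tok)
    }
  })
})

test_that("table-dialect round trip preserves substitutions", {
  tab <- format_variants(parse_variants(c("8584", "15487T", "16124"),
                                        dialect = "table",
                                        substitution = c("G-A", "A-T", "T-C")),
                         dialect = "table")
  back <- parse_variants(tab$variant, dialect = "table",
                         substitution = tab$substitution)
  expect_equal(back$kind, c("transition", "transversion", "transition"))
  expect_equal(tab$substitution, c("G-A", "A-T", "T-C"))
})

test_that("circular ranges wrap through the origin", {
  r <- seq_range(16024, 576)
  expect_true(all(range_contains(r, c(16024, 16569, 1, 576, 73))))
  expect_false(any(range_contains(r, c(577, 16023, 8000))))
  expect_equal(length(range_positions(r)), 16569 - 16024 + 1 + 576)
})
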