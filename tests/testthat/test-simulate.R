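test_that("zero TMRCA leaves every lineage identical to the root", {
  sim <- simulate_clade(simulation_spec(8, 0, seed = 3))
  expect_true(all(vapply(sim$haplotypes$variants, nrow, integer(1)) == 0))
  expect_equal(sim$d_true, rep(0L, 8))
})

test_that("star simulations recover the Poisson mean and dispersion", {
  # pooled lineages across seeded replicates at the calibration point
  # T = 3624 yr on the whole-molecule clock (expected one mutation/lineage)
  d <- unlist(lapply(1:20, function(s)
    simulate_clade(simulation_spec(1000, 3624, clock_whole_molecule(),
                                   seed = s))$d_true))
  expect_lt(abs(mean(d) - 1), 0.03)
  expect_lt(abs(stats::var(d) / mean(d) - 1), 0.10)
})

test_that("the same seed reproduces byte-identical output", {
  s1 <- simulate_clade(simulation_spec(15, 9000, clock_synonymous(), seed = 99))
  s2 <- simulate_clade(simulation_spec(15, 9000, clock_synonymous(), seed = 99))
  expect_identical(s1$haplotypes, s2$haplotypes)
  y1 <- simulate_clade(simulation_spec(6, 9000, topology = "yule", seed = 7))
  y2 <- simulate_clade(simulation_spec(6, 9000, topology = "yule", seed = 7))
  expect_identical(y1$haplotypes, y2$haplotypes)
})

test_that("synonymous-clock simulations place only synonymous transitions", {
  sim <- simulate_clade(simulation_spec(10, 30000, clock_synonymous(), seed = 21))
  toks <- unlist(lapply(sim$haplotypes$variants, variant_keys))
  ann <- annotate_variants(parse_variants(unique(toks)), reference = REF)
  expect_true(all(ann$effect == "synonymous"))
})

test_that("yule genealogies carry consistent root distances", {
  sim <- simulate_clade(simulation_spec(6, 20000, topology = "yule", seed = 12))
  expect_equal(lengths(lapply(sim$haplotypes$variants, variant_keys)),
               as.integer(sim$d_true), ignore_attr = TRUE)
  expect_s3_class(sim$phylo, "phylo")
})

test_that("the recovery experiment is unbiased, covered and reproducible", {
  spec <- simulation_spec(20, 10000, clock_synonymous(), seed = 42)
  rec <- recovery_experiment(spec, replicates = 150)
  expect_lt(abs(rec$rel_bias), 0.05)
  expect_gt(rec$coverage, 0.55)
  expect_lt(rec$coverage, 0.80)
  rec2 <- recovery_experiment(spec, replicates = 1)
  rec3 <- recovery_experiment(spec, replicates = 1)
  expect_identical(rec2, rec3)
})

test_that("packaged fixtures parse cleanly and match their printed shape", {
  expect_equal(nrow(MUMMY$variants[[1]]), 51)
  expect_equal(sum(MUMMY$variants[[1]]$private), 10)
  rel <- c1bi_related_haplotypes()
  expect_equal(nrow(rel), 7)
  wari <- rel[rel$sample_id == "Wari1", ]
  expect_setequal(format_variants(wari$variants[[1]]),
                  c("16124", "16189", "16222", "16316"))
  expect_equal(c(wari$range_start, wari$range_end), c(16011, 16382))
  expect_equal(sum(rel$country == "Bolivia (La Paz)"), 3)
  # no warnings anywhere in fixture parsing
  expect_no_warning({aconcagua_haplotype(); c1bi_related_haplotypes()})
})

test_that("make_fixtures writes a complete, reloadable set", {
  dir <- tempfile("fx")
  paths <- make_fixtures(dir, seed = 4)
  expect_true(all(file.exists(paths)))
  ref <- read_reference(paths[["reference"]])
  expect_equal(nchar(ref), 16569)
  ops <- read_haplotypes(paths[["operators"]])
  expect_equal(nrow(ops), 2)
  db <- read_haplotypes(paths[["decoys"]])
  expect_equal(nrow(db), 100)
  expect_false(any(grepl("^16124$", unlist(lapply(db$variants, variant_keys)))))
})

test_that("excessive mutation load is reported", {
  expect_error(
    simulate_clade(simulation_spec(2000, 5e6, clock_synonymous(), seed = 1)),
    "exhausts")
})
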