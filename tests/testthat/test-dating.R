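test_that("rho is the multiplicity-weighted mean root distance", {
  expect_equal(compute_rho(c(1, 2)), 1.5)
  expect_equal(compute_rho(0), 0)
  expect_equal(compute_rho(c(3, 3, 3, 2, 2)), 2.6)
  expect_equal(compute_rho(c(3, 2), weights = c(3, 2)), 2.6)
  expect_error(compute_rho(numeric()), "empty")
})

test_that("sigma follows the genealogy-weighted formula", {
  two_tip <- build_parsimony_tree(dplyr::bind_rows(
    mk_hap("a", nonsyn_positions(1)), mk_hap("b", nonsyn_positions(2, from = 5))))
  expect_equal(compute_sigma(two_tip), sqrt(3) / 2)
  three_tip <- build_parsimony_tree(dplyr::bind_rows(
    mk_hap("a", nonsyn_positions(6, from = 10)),
    mk_hap("b", nonsyn_positions(6, from = 20)),
    mk_hap("c", nonsyn_positions(5, from = 30))))
  expect_equal(compute_sigma(three_tip), sqrt(17) / 3)
  # n identical tips one branch of length l: sigma = sqrt(l)
  ident <- build_parsimony_tree(dplyr::bind_rows(
    mk_hap("a", nonsyn_positions(4, from = 40)),
    mk_hap("b", nonsyn_positions(4, from = 40)),
    mk_hap("c", nonsyn_positions(4, from = 40))))
  expect_equal(compute_sigma(ident), 2)
})

test_that("the star index hits its printed values and bounds", {
  expect_equal(round(star_index(2/3, sqrt(2)/3, 3), 1), 1.0)
  expect_equal(round(star_index(4.29, 1.03, 7), 1), 0.6)
  # all samples one shared haplotype: sigma = sqrt(l), index = 1/n
  expect_equal(star_index(5, sqrt(5), 4), 1/4)
  expect_warning(s0 <- star_index(0, 0, 3), "undefined")
  expect_true(is.na(s0))
})

test_that("clocks convert rho to kya as printed", {
  expect_equal(round(rho_to_years(0.50, clock_synonymous()), 2), 3.94)
  expect_equal(round(rho_to_years(2.60, clock_synonymous()), 2), 20.50)
  expect_equal(rho_to_years(0, clock_synonymous()), 0)
  expect_equal(round(rho_to_years(1.50, clock_whole_molecule()), 2), 5.44)
  # per-site control-region clocks
  expect_equal(round(rho_to_years(1, clock_hvs1()) * 1000),
               round(1 / (1.64273e-7 * 350)))  # ~17.4 kyr per HVS-I transition
  expect_error(rho_to_years(1, list(a = 1)), "invalid clock")
  expect_error(rho_to_years(-1, clock_synonymous()), "non-negative")
})

test_that("intervals are rho +/- sigma through the clock, clipped at zero", {
  expect_equal(round(interval_years(0.25, 0.25, clock_synonymous()), 2),
               c(lower = 0, upper = 3.94))
  expect_equal(round(interval_years(0.50, 0.50, clock_synonymous()), 2),
               c(lower = 0, upper = 7.88))
  expect_equal(interval_years(0.5, 0, clock_synonymous()),
               c(lower = rho_to_years(0.5, clock_synonymous()),
                 upper = rho_to_years(0.5, clock_synonymous())))
})

test_that("clade reports reproduce the printed star-like rows", {
  cfgs <- table2_configs()
  for (label in names(cfgs)) check_table2_row(cfgs[[label]], label)
})

test_that("a single-haplotype clade dates to zero with a degenerate interval", {
  gt <- build_parsimony_tree(dplyr::bind_rows(mk_hap("a"), mk_hap("b")))
  rep_ <- clade_report(gt, clock_whole_molecule())
  expect_equal(rep_$rho, 0)
  expect_equal(rep_$tmrca_kya, 0)
  expect_equal(rep_$lower_kya, rep_$upper_kya)
})

test_that("perfect stars satisfy sigma = sqrt(rho/n) and star index 1", {
  withr::with_seed(41, {
    for (rep in 1:15) {
      n <- sample(3:8, 1)
      counts <- stats::rpois(n, 2) + 1  # distinct non-empty tips
      offs <- cumsum(c(1, counts))
      haps <- dplyr::bind_rows(lapply(seq_len(n), function(i)
        mk_hap(paste0("t", i), nonsyn_positions(counts[i], from = offs[i]))))
      gt <- build_parsimony_tree(haps)
      g <- glance(gt)
      expect_equal(g$sigma, sqrt(g$rho / g$n))
      expect_equal(g$star_index, 1)
    }
  })
})

test_that("the star index stays in [1/n, 1] on random genealogies", {
  withr::with_seed(43, {
    for (rep in 1:25) {
      sets <- random_parsimony_instance(sample(20000L, 1))
      if (all(lengths(sets) == 0)) next
      h <- dplyr::bind_rows(lapply(seq_along(sets), function(i) {
        v <- if (length(sets[[i]])) parse_variants(sets[[i]]) else empty_variants()
        haplotype(paste0("h", i), v)
      }))
      gt <- build_parsimony_tree(h, mask = NULL)
      g <- glance(gt)
      if (is.na(g$star_index)) next
      expect_gte(g$star_index, 1 / g$n - 1e-12)
      expect_lte(g$star_index, 1 + 1e-12)
    }
  })
})

test_that("synonymous ages scale by 7.884 kyr per synonymous substitution", {
  # the clock-consistency identity of the star-like synonymous rows
  for (rho in c(1/3, 0.25, 0.5, 4/3, 5/3, 2.6)) {
    expect_equal(rho_to_years(rho, clock_synonymous()) / rho, 7.884)
  }
})
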