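# Constructed clade configurations matching the published founder-age table
# (whole-variation and synonymous-only columns of the star-like rows).
# Each entry: haplotypes realising the genealogy shape, the clock column it
# feeds, and the printed values it must reproduce at table precision.

table2_configs <- function() {
  sp <- syn_positions(40)
  ns <- nonsyn_positions(60)
  list(
    C1b13d_whole = list(
      haps = dplyr::bind_rows(mk_hap("a", ns[1]), mk_hap("b", ns[2:3])),
      clock = clock_whole_molecule(),
      expect = list(n = 2, rho = 1.50, sigma = 0.87, star = 1.0)),
    C1b13d_syn = list(
      haps = dplyr::bind_rows(mk_hap("a"), mk_hap("b", sp[1])),
      clock = clock_synonymous(),
      expect = list(n = 2, rho = 0.50, sigma = 0.50, star = 1.0,
                    tmrca = 3.94, lower = 0.00, upper = 7.88)),
    C1b13c1_whole = list(
      haps = dplyr::bind_rows(mk_hap("a", ns[4:5]), mk_hap("b", ns[4]),
                              mk_hap("c", ns[6:7]), mk_hap("d", ns[8:9])),
      clock = clock_whole_molecule(),
      expect = list(n = 4, rho = 1.75, sigma = 0.75, star = 0.8)),
    C1b13c1_syn = list(
      haps = dplyr::bind_rows(mk_hap("a", sp[2]), mk_hap("b"),
                              mk_hap("c"), mk_hap("d")),
      clock = clock_synonymous(),
      expect = list(n = 4, rho = 0.25, sigma = 0.25, star = 1.0,
                    tmrca = 1.97, lower = 0.00, upper = 3.94)),
    C1b6_whole = list(
      haps = dplyr::bind_rows(mk_hap("a", ns[10:11]), mk_hap("b"), mk_hap("c")),
      clock = clock_whole_molecule(),
      expect = list(n = 3, rho = 0.67, sigma = 0.47, star = 1.0)),
    C1b6_syn = list(
      haps = dplyr::bind_rows(mk_hap("a", sp[3]), mk_hap("b"), mk_hap("c")),
      clock = clock_synonymous(),
      expect = list(n = 3, rho = 0.33, sigma = 0.33, star = 1.0,
                    tmrca = 2.63, lower = 0.00, upper = 5.26)),
    C1b13a1_whole = list(
      haps = dplyr::bind_rows(mk_hap("a", ns[12:17]), mk_hap("b", ns[18:23]),
                              mk_hap("c", ns[24:28])),
      clock = clock_whole_molecule(),
      expect = list(n = 3, rho = 5.67, sigma = 1.37, star = 1.0)),
    C1b13a1_syn = list(
      haps = dplyr::bind_rows(mk_hap("a", sp[4:5]), mk_hap("b", sp[6:7]),
                              mk_hap("c", sp[8])),
      clock = clock_synonymous(),
      expect = list(n = 3, rho = 1.67, sigma = 0.75, star = 1.0,
                    tmrca = 13.14, lower = 7.26, upper = 19.02)),
    C1b7_whole = list(
      haps = {
        sh <- ns[29:39]  # 11 shared mutations on the {a,b} stem
        dplyr::bind_rows(
          mk_hap("a", c(sh, ns[40])), mk_hap("b", sh),
          mk_hap("c", ns[41:42]), mk_hap("d", ns[43:44]),
          mk_hap("e", ns[45]), mk_hap("f", ns[46]), mk_hap("g", ns[47]))
      },
      clock = clock_whole_molecule(),
      expect = list(n = 7, rho = 4.29, sigma = 1.03, star = 0.6)),
    C1b7_syn = list(
      haps = dplyr::bind_rows(
        mk_hap("a", sp[9:11]), mk_hap("b", sp[9:11]), mk_hap("c", sp[9:10]),
        mk_hap("d", sp[12]), mk_hap("e", sp[13]), mk_hap("f"), mk_hap("g")),
      clock = clock_synonymous(),
      expect = list(n = 7, rho = 1.43, sigma = 0.70, star = 0.4,
                    tmrca = 11.26, lower = 5.75, upper = 16.78)),
    C1b8_whole = list(
      haps = {
        X <- ns[48:49]; Y <- ns[50:54]
        dplyr::bind_rows(
          mk_hap("a", c(X, Y, syn_positions(3, from = 200))),
          mk_hap("b", c(X, Y, syn_positions(4, from = 230))),
          mk_hap("c", c(X, syn_positions(4, from = 260))),
          mk_hap("d", c(X, syn_positions(5, from = 290))),
          mk_hap("e", c(X, syn_positions(5, from = 330))))
      },
      clock = clock_whole_molecule(),
      expect = list(n = 5, rho = 8.20, sigma = 1.91, star = 0.4)),
    C1b8_syn = list(
      haps = dplyr::bind_rows(
        mk_hap("a", sp[14:16]), mk_hap("b", sp[14:16]), mk_hap("c", sp[14:16]),
        mk_hap("d", sp[17:18]), mk_hap("e", sp[19:20])),
      clock = clock_synonymous(),
      expect = list(n = 5, rho = 2.60, sigma = 1.11, star = 0.4,
                    tmrca = 20.5, lower = 11.72, upper = 29.28))
  )
}

check_table2_row <- function(cfg, label) {
  gt <- build_parsimony_tree(cfg$haps)
  rep_ <- format_clade_report(
    clade_report(gt, cfg$clock, clade = label, reference = REF))
  e <- cfg$expect
  expect_equal(rep_$n, e$n, info = label)
  expect_equal(rep_$rho, e$rho, info = label)
  expect_equal(rep_$sigma, e$sigma, info = label)
  expect_equal(rep_$star, e$star, info = label)
  if (!is.null(e$tmrca)) {
    expect_equal(rep_$tmrca_kya, e$tmrca, tolerance = 0.006, info = label)
    expect_equal(rep_$lower_kya, e$lower, tolerance = 0.006, info = label)
    expect_equal(rep_$upper_kya, e$upper, tolerance = 0.006, info = label)
  }
  invisible(rep_)
}
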