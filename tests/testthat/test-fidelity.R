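# Drake correction factors, per-bp conversion, repair efficiencies,
# growth grading, robustness table.

ref_counts <- spectrum_counts(B_CT = 101, B_mis = 341, I = 42)
can_locus <- target_locus("reporter", T = 1773)

test_that("correction factors reproduce the reference reporter values", {
  cf <- correction_factors(ref_counts, can_locus)
  # printed reference: C = 4.87, tau = 391 bp
  expect_equal(round(cf$C, 2), 4.87)
  expect_equal(round(cf$tau), 391)
  # direct-arithmetic oracle for the combined factor
  expect_equal(cf$C2, ((64 / 3) * 101 + 42) / 484, tolerance = 1e-12)
  expect_equal(cf$tau, 1773 / cf$C2, tolerance = 1e-12)
})

test_that("correction factors degenerate and error cases", {
  # observed stop fraction at the random expectation, no indels -> no correction
  cf1 <- correction_factors(spectrum_counts(B_CT = 3, B_mis = 61, I = 0),
                            target_locus("x", 900))
  expect_equal(cf1$C, 1, tolerance = 1e-12)
  expect_equal(cf1$C2, 1, tolerance = 1e-12)
  expect_equal(cf1$tau, 900, tolerance = 1e-12)
  expect_error(correction_factors(spectrum_counts(0, 10, 2), can_locus),
               "chain-terminating")
})

test_that("correction factors are scale-free in the counts", {
  cf1 <- correction_factors(ref_counts, can_locus)
  for (k in c(2, 5, 10)) {
    cfk <- correction_factors(
      spectrum_counts(B_CT = 101 * k, B_mis = 341 * k, I = 42 * k), can_locus)
    expect_equal(cfk$C, cf1$C, tolerance = 1e-12)
    expect_equal(cfk$C2, cf1$C2, tolerance = 1e-12)
    expect_equal(cfk$tau, cf1$tau, tolerance = 1e-12)
  }
})

test_that("per-bp conversion matches the published worked examples", {
  # diploid URA3 reporter: 3.5e-4 * 6.79 / 804 = 3.0e-6 (printed precision 0.05e-6)
  dip <- locus_presets()$diploid_yeast_ura3
  mu_b <- 3.5e-4 * dip$C2 / dip$T
  expect_lt(abs(mu_b - 3.0e-6), 0.05e-6)
  expect_equal(round(dip$T / dip$C2), 118)  # tau = 804/6.79 -> 118 bp
  # mouse ouabain target: 65e-7 / 20 = 3.3e-7 (printed precision 0.05e-7)
  expect_lt(abs(per_bp_rate(65e-7, tau = 20) - 3.3e-7), 0.051e-7)
  expect_equal(per_bp_rate(0, tau = 20), 0)
})

test_that("per-bp conversion is linear and consistent with tau", {
  cf <- correction_factors(ref_counts, can_locus)
  mu <- 2.3e-6
  expect_equal(per_bp_rate(2 * mu, cf), 2 * per_bp_rate(mu, cf), tolerance = 1e-12)
  # mu_b * tau = mu_T exactly
  expect_equal(per_bp_rate(mu, cf) * cf$tau, mu, tolerance = 1e-12)
})

test_that("allele_target_size multiplies bp per allele by allele number", {
  expect_equal(allele_target_size(5, 4), 20)
  expect_equal(allele_target_size(7.5, 1), 7.5)
  expect_equal(allele_target_size(2.5, 2), 5)
  expect_error(allele_target_size(5, 0))
})

test_that("fold effects reproduce printed table entries at 3 significant figures", {
  expect_equal(signif(fold_effect(5200e-7, 34e-7), 3), 153)
  expect_equal(signif(fold_effect(5200e-7, 23e-7), 3), 226)
  expect_equal(fold_effect(3e-7, 3e-7), 1)
  expect_error(fold_effect(1e-6, 0), "proficient")
})

test_that("repair efficiency arithmetic and properties", {
  expect_equal(repair_efficiency(1)$efficiency_pct, 0)
  expect_equal(repair_efficiency(2)$efficiency_pct, 50)
  e157 <- repair_efficiency(157)$efficiency_pct
  expect_equal(e157, 100 * (1 - 1 / 157), tolerance = 1e-12)
  expect_gt(e157, 99)
  # strictly increasing in fold, asymptote 100
  folds <- c(1, 1.5, 3, 10, 100, 1e4)
  effs <- vapply(folds, function(f) repair_efficiency(f)$efficiency_pct, numeric(1))
  expect_true(all(diff(effs) > 0))
  expect_true(all(effs < 100))
  expect_warning(neg <- repair_efficiency(0.5), "antimutator")
  expect_lt(neg$efficiency_pct, 0)
})

test_that("serial pathways multiply and double-mutant prediction is linear", {
  expect_equal(combined_fidelity(157, 163), 25591)
  expect_gt(combined_fidelity(157, 163), 1e4)
  expect_equal(combined_fidelity(1, 42), 42)
  expect_equal(combined_fidelity(2, 3), 6)
  expect_equal(signif(predict_double_mutant_rate(135e-7, 157), 1), 2e-3)
  expect_equal(predict_double_mutant_rate(4e-6, 1), 4e-6)
  expect_equal(predict_double_mutant_rate(270e-7, 157),
               2 * predict_double_mutant_rate(135e-7, 157), tolerance = 1e-12)
})

test_that("growth grading bands and monotonicity", {
  expect_equal(classify_growth(4.9e-7), "+++")
  expect_equal(classify_growth(5e-5), "+++")    # band edge inclusive
  expect_equal(classify_growth(3e-4), "++")
  expect_equal(classify_growth(1.1e-3), "+")
  expect_equal(classify_growth(2.1e-3), "-")
  rates <- sort(10^runif(200, -8, -1))
  grades <- classify_growth(rates)
  rank <- c("+++" = 3, "++" = 2, "+" = 1, "-" = 0)[grades]
  expect_true(all(diff(rank) <= 0))
})

test_that("robustness table assembles per-bp rates from presets", {
  entries <- data.frame(
    organism = c("diploid yeast", "mouse"),
    mu_T = c(3.5e-4, 65e-7),
    preset = c("diploid_yeast_ura3", "mouse_ouabain"),
    stringsAsFactors = FALSE)
  tab <- robustness_table(entries)
  expect_equal(nrow(tab), 2)
  expect_lt(abs(tab$mu_b[1] - 3.0e-6), 0.05e-6)
  expect_equal(tab$mu_b_adjusted[1], tab$mu_b[1] * 1.8, tolerance = 1e-12)
  expect_lt(abs(tab$mu_b[2] - 3.3e-7), 0.051e-7)
  expect_equal(tab$mu_b_adjusted[2], tab$mu_b[2], tolerance = 1e-12)
  # empty input -> empty table
  expect_equal(nrow(robustness_table(data.frame())), 0)
  # missing constants are reported
  bad <- data.frame(organism = "x", mu_T = 1e-6, preset = "nope")
  expect_error(robustness_table(bad), "unknown preset")
})
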