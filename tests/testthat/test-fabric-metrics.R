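test_that("AVE and pooled CV reproduce the didactic quadruples", {
  p <- quad_profiles()
  expect_equal(compute_ave(p$A), 100)
  expect_equal(compute_ave(p$B), 100)
  expect_equal(compute_ave(p$C), 100)
  expect_equal(round(100 * compute_pooled_cv(p$A), 2), 3.65)
  expect_equal(round(100 * compute_pooled_cv(p$B), 2), 17.87)
  expect_equal(round(100 * compute_pooled_cv(p$C), 2), 4.40)
  expect_equal(round(100 * compute_pooled_cv(p$D), 2), 3.46)
  two_spots <- gene_profile("G", "CO", rbind(rep(10, 4), rep(30, 4)))
  expect_equal(compute_ave(two_spots), 20)
  expect_equal(compute_pooled_cv(gene_profile("G", "CO", rep(5, 4))), 0)
})

test_that("pooled CV equals explicit-sum CV for single-spot profiles", {
  set.seed(11)
  for (i in 1:100) {
    v <- runif(4, 0.5, 50)
    expect_equal(compute_pooled_cv(gene_profile("G", "CO", v)), cv_bf(v),
                 tolerance = 1e-10)
  }
})

test_that("chi-square mid-interval factor matches table quantiles at r = 3", {
  # chi-square 2.5/97.5 percentiles for df = 3 from a statistics table
  q_hi <- 9.3484
  q_lo <- 0.21580
  expect_equal(chi2_midinterval_factor(3, "sqrt"),
               0.5 * (sqrt(3 / q_hi) + sqrt(3 / q_lo)), tolerance = 1e-4)
  expect_equal(chi2_midinterval_factor(3, "linear"),
               0.5 * (3 / q_hi + 3 / q_lo), tolerance = 1e-4)
  expect_error(chi2_midinterval_factor(0), class = "genefabric_value_error")
})

test_that("the correction factor decreases in r and tends to 1", {
  rs <- c(1, 2, 3, 5, 10, 30, 100, 1000)
  f <- chi2_midinterval_factor(rs)
  expect_true(all(diff(f) < 0))
  expect_gt(f[length(f)], 1)
  expect_lt(f[length(f)], 1.05)
})

test_that("REV applies the correction to the pooled CV and is scale free", {
  p <- quad_profiles()$A
  expect_equal(compute_rev(p),
               chi2_midinterval_factor(3) * compute_pooled_cv(p) * 100)
  expect_equal(round(compute_rev(p), 2), 7.84)
  doubled <- gene_profile("A", "CO", 2 * quad_values$A)
  expect_equal(compute_rev(doubled), compute_rev(p))
  expect_equal(compute_rev(gene_profile("G", "CO", rep(3, 4))), 0)
})

test_that("inflating deviations from the mean strictly increases REV", {
  set.seed(3)
  for (i in 1:20) {
    v <- runif(4, 10, 20)
    p1 <- gene_profile("G", "CO", v)
    p2 <- gene_profile("G", "CO", mean(v) + 1.5 * (v - mean(v)))
    expect_gt(compute_rev(p2), compute_rev(p1))
  }
})

test_that("COR reproduces the didactic pair correlations on the linear scale", {
  p <- quad_profiles()
  expect_equal(round(compute_cor(p$A, p$B, log2 = FALSE), 2), 0.95)
  expect_equal(round(compute_cor(p$A, p$C, log2 = FALSE), 3), -0.997)
  expect_equal(compute_cor(p$A, p$D, log2 = FALSE), 0)
  expect_equal(compute_cor(p$A, p$A, log2 = FALSE), 1)
})

test_that("gene-means COR equals brute-force Pearson on random profiles", {
  set.seed(23)
  for (i in 1:200) {
    a <- runif(4, 0.5, 20)
    b <- runif(4, 0.5, 20)
    got <- compute_cor(gene_profile("a", "CO", a), gene_profile("b", "CO", b),
                       log2 = TRUE)
    expect_equal(got, pearson_bf(log2(a), log2(b)), tolerance = 1e-12)
  }
})

test_that("COR is symmetric and undefined (not 0) for constant profiles", {
  p <- quad_profiles()
  expect_equal(compute_cor(p$A, p$B, log2 = FALSE),
               compute_cor(p$B, p$A, log2 = FALSE))
  flat <- gene_profile("F", "CO", rep(2, 4))
  expect_true(is.na(compute_cor(p$A, flat)))
})

test_that("pooled-spots COR agrees with gene-means for equal spot counts and clamps otherwise", {
  a <- gene_profile("a", "CO", c(96, 98, 102, 104))
  b <- gene_profile("b", "CO", c(87, 83, 110, 120))
  expect_equal(compute_cor(a, b, mode = "pooled_spots", log2 = FALSE),
               compute_cor(a, b, mode = "gene_means", log2 = FALSE),
               tolerance = 1e-12)
  # two identical spots double the sums; the quotient leaves [-1, 1]
  b2 <- gene_profile("b", "CO", rbind(c(87, 83, 110, 120), c(87, 83, 110, 120)))
  expect_warning(r <- compute_cor(a, b2, mode = "pooled_spots", log2 = FALSE),
                 "clamped")
  expect_lte(abs(r), 1)
})

test_that("pair classification applies inclusive thresholds", {
  expect_equal(classify_pair(0.95), "synergistic")
  expect_equal(classify_pair(-0.997), "antagonistic")
  expect_equal(classify_pair(0), "independent")
  expect_equal(classify_pair(0.05), "independent")
  expect_equal(classify_pair(0.5), "not_significant")
  expect_equal(classify_pair(-0.9499), "not_significant")
  expect_equal(classify_pair(NA_real_), "not_significant")
  expect_error(classify_pair(0.5, sig_threshold = 0.5, ind_threshold = 0.6),
               class = "genefabric_value_error")
})

test_that("coordination score combines the didactic pair classes", {
  tab <- quad_table()
  pairs <- cor_pairs(tab, "CO", log2 = FALSE)
  expect_equal(nrow(pairs), 6)
  # oracle: classify all six pairs from brute-force Pearson
  want <- sapply(combn(names(quad_values), 2, simplify = FALSE), function(pr) {
    r <- pearson_bf(quad_values[[pr[1]]], quad_values[[pr[2]]])
    if (r >= 0.95) "synergistic" else if (r <= -0.95) "antagonistic"
    else if (abs(r) <= 0.05) "independent" else "not_significant"
  })
  expect_equal(sort(pairs$klass), sort(want))
  cs <- coordination_score(pairs, names(quad_values), "toy")
  pct <- function(k) 100 * sum(want == k) / 6
  expect_equal(cs$syn_pct, pct("synergistic"))
  expect_equal(cs$coord,
               pct("synergistic") + pct("antagonistic") - pct("independent"))
})

test_that("coordination score arithmetic and degenerate sets", {
  pairs <- tibble::tibble(
    gene_a = c("a", "a", "a", "b", "b", "c"),
    gene_b = c("b", "c", "d", "c", "d", "d"),
    condition = "CO",
    cor = c(1, 1, 1, -1, 0, 0.5),
    klass = c("synergistic", "synergistic", "synergistic",
              "antagonistic", "independent", "not_significant")
  )
  cs <- coordination_score(pairs, c("a", "b", "c", "d"))
  expect_equal(cs$syn_pct + cs$ant_pct + cs$ind_pct, 100 * 5 / 6)
  expect_equal(cs$coord, cs$syn_pct + cs$ant_pct - cs$ind_pct)
  all_syn <- dplyr::mutate(pairs, klass = "synergistic")
  expect_equal(coordination_score(all_syn, c("a", "b", "c", "d"))$coord, 100)
  expect_error(coordination_score(pairs, "a"),
               class = "genefabric_empty_set_error")
})

test_that("fabric summary rows recompute from single-gene operations", {
  set.seed(5)
  tab <- make_toy_table(list(G1 = runif(4, 1, 9),
                             G2 = matrix(runif(8, 1, 9), 2)))
  fs <- fabric_summary(tab, "CO")
  profs <- gene_profiles(tab, "CO")
  for (g in names(profs)) {
    row <- fs[fs$gene == g, ]
    expect_equal(row$ave, compute_ave(profs[[g]]))
    expect_equal(row$rev, compute_rev(profs[[g]]))
  }
})
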