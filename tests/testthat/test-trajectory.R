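make_fabric <- function(genes, condition, ave, rev) {
  tibble::tibble(gene = genes, condition = condition, n_spots = 1,
                 ave = ave, pooled_cv = rev / 100, rev = rev)
}

test_that("a gene identical in both conditions sits at the origin", {
  genes <- c("a", "b", "c")
  fab <- make_fabric(genes, "CO", c(1, 2, 3), c(10, 20, 30))
  cm <- diag(3); cm[upper.tri(cm)] <- cm[lower.tri(cm)] <- 0.5
  dimnames(cm) <- list(genes, genes)
  rec <- compute_itt("a", fab, fab, cm, cm, universe = genes)
  expect_equal(rec$td, 0)
  expect_equal(c(rec$d_ave, rec$d_rev, rec$d_cor), c(0, 0, 0))
})

test_that("a hand-built 3-gene universe matches the spreadsheet computation", {
  genes <- c("a", "b", "c")
  fab_ref <- make_fabric(genes, "CO", c(10, 20, 30), c(5, 10, 15))
  fab_case <- make_fabric(genes, "HO", c(12, 18, 60), c(6, 9, 45))
  cr <- matrix(c(1, .8, .2, .8, 1, -.4, .2, -.4, 1), 3,
               dimnames = list(genes, genes))
  cc <- matrix(c(1, .1, .9, .1, 1, 0, .9, 0, 1), 3,
               dimnames = list(genes, genes))
  rec <- compute_itt("a", fab_ref, fab_case, cr, cc, universe = genes)
  d_ave <- (12 - 10) / mean(c(10, 20, 30))
  d_rev <- (6 - 5) / mean(c(5, 10, 15))
  d_cor <- sqrt(mean(c(.1 - .8, .9 - .2)^2)) / sqrt(mean(c(.8, .2)^2))
  expect_equal(rec$d_ave, d_ave, tolerance = 1e-12)
  expect_equal(rec$d_rev, d_rev, tolerance = 1e-12)
  expect_equal(rec$d_cor, d_cor, tolerance = 1e-12)
  expect_equal(rec$td, sqrt(d_ave^2 + d_rev^2 + d_cor^2), tolerance = 1e-12)
})

test_that("TD grows strictly with each component's magnitude", {
  genes <- c("a", "b", "c")
  fab_ref <- make_fabric(genes, "CO", c(10, 20, 30), c(5, 10, 15))
  fab1 <- make_fabric(genes, "HO", c(12, 20, 30), c(5, 10, 15))
  fab2 <- make_fabric(genes, "HO", c(14, 20, 30), c(5, 10, 15))
  cm <- diag(3); cm[cm == 0] <- 0.5; dimnames(cm) <- list(genes, genes)
  r1 <- compute_itt("a", fab_ref, fab1, cm, cm, universe = genes)
  r2 <- compute_itt("a", fab_ref, fab2, cm, cm, universe = genes)
  expect_equal(r2$d_ave, 2 * r1$d_ave)
  expect_gt(r2$td, r1$td)
})

test_that("TD equals the brute-force evaluation on random small universes", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(3:6, 1)
    genes <- paste0("g", seq_len(n))
    ave_ref <- runif(n, 1, 50); ave_case <- runif(n, 1, 50)
    rev_ref <- runif(n, 1, 80); rev_case <- runif(n, 1, 80)
    rnd_cor <- function() {
      m <- matrix(runif(n * n, -1, 1), n); m <- (m + t(m)) / 2; diag(m) <- 1
      dimnames(m) <- list(genes, genes); m
    }
    cr <- rnd_cor(); cc <- rnd_cor()
    fr <- make_fabric(genes, "CO", ave_ref, rev_ref)
    fc <- make_fabric(genes, "HO", ave_case, rev_case)
    i_g <- sample(n, 1)
    rec <- compute_itt(genes[i_g], fr, fc, cr, cc, universe = genes)
    expect_equal(rec$td,
                 td_bf(i_g, ave_ref, ave_case, rev_ref, rev_case, cr, cc),
                 tolerance = 1e-12)
  }
})

test_that("TD is invariant under a common rescaling of reference AVEs", {
  genes <- c("a", "b", "c", "d")
  fab_ref <- make_fabric(genes, "CO", c(10, 20, 30, 40), c(5, 10, 15, 20))
  fab_case <- make_fabric(genes, "HO", c(12, 18, 60, 40), c(6, 9, 45, 20))
  cm <- diag(4); cm[cm == 0] <- 0.3; dimnames(cm) <- list(genes, genes)
  base <- compute_itt("a", fab_ref, fab_case, cm, cm, universe = genes)
  scaled_ref <- dplyr::mutate(fab_ref, ave = ave * 7)
  scaled_case <- dplyr::mutate(fab_case, ave = ave * 7)
  scaled <- compute_itt("a", scaled_ref, scaled_case, cm, cm, universe = genes)
  expect_equal(scaled$td, base$td, tolerance = 1e-12)
})

test_that("trajectory table agrees with per-gene computation on synthetic data", {
  ds <- generate_dataset(synthetic_spec(n_genes = 30), seed = 3)
  tr <- trajectory_table(ds$table, "CO", "HO")
  fab <- fabric_summary(ds$table, c("CO", "HO"))
  fr <- fab[fab$condition == "CO", ]
  fc <- fab[fab$condition == "HO", ]
  uni <- tr$gene
  cr <- cor_matrix(ds$table, "CO", genes = uni)
  cc <- cor_matrix(ds$table, "HO", genes = uni)
  g <- uni[5]
  expect_equal(tr$td[tr$gene == g],
               compute_itt(g, fr, fc, cr, cc, universe = uni)$td,
               tolerance = 1e-12)
})

test_that("TD ranking can disagree with |x| and WIR rankings", {
  # gene X: 50-fold induction of a lowly expressed, stable, coordination-
  # preserving gene (big |x|, small TD). gene Y: unchanged mean but exploded
  # variability and scrambled coordination (x ~ 1, big TD).
  set.seed(21)
  jit <- function(m, cv = 0.02) m * (1 + rnorm(4, 0, cv))
  co <- list(X = jit(0.01), Y = c(20, 20.2, 19.8, 20.1),
             Z1 = jit(10), Z2 = jit(8), Z3 = jit(12), Z4 = jit(9))
  hm <- co
  hm$X <- 50 * co$X                 # same pattern: correlations preserved
  hm$Y <- c(20.1, 5, 35, 20)        # same mean, chaotic fluctuations
  vals <- lapply(names(co), function(g) c(co[[g]], hm[[g]]))
  names(vals) <- names(co)
  tab <- make_toy_table(vals, conditions = c("CO", "HM"))
  reg <- regulation_table(tab, "CO", "HM")
  tr <- trajectory_table(tab, "CO", "HM")
  q <- summarize_quantifiers(reg, tr)
  top_x <- q$gene[which.min(q$rank_x)]
  top_td <- q$gene[which.min(q$rank_td)]
  expect_equal(top_x, "X")
  expect_equal(top_td, "Y")
  expect_false(top_x == top_td)
})

test_that("pathway TD summaries average and rank member genes", {
  tr <- tibble::tibble(gene = c("a", "b", "c"), contrast = "CO->HO",
                       d_ave = 0, d_rev = 0, d_cor = 0, td = c(1, 2, 3))
  out <- pathway_td_summary(tr, c("a", "b", "c"), "toy")
  expect_equal(out$summary$mean_td, 2)
  expect_equal(out$ranking$gene, c("c", "b", "a"))
  same <- dplyr::mutate(tr, td = 5)
  expect_equal(pathway_td_summary(same, c("a", "b"))$summary$mean_td, 5)
  expect_error(pathway_td_summary(tr, "zz"),
               class = "genefabric_empty_set_error")
})
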