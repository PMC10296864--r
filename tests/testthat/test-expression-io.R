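test_that("a toy TSV parses into a probe table with the declared layout", {
  header <- paste(c("gene", paste0(rep(c("CO", "HO", "CM", "HM"), each = 4),
                                   "_", 1:4)), collapse = "\t")
  rows <- vapply(1:4, function(i) {
    paste(c(paste0("G", i), round(runif(16, 1, 10), 3)), collapse = "\t")
  }, character(1))
  path <- write_tmp_tsv(c(header, rows))
  layout <- list(CO = paste0("CO_", 1:4), HO = paste0("HO_", 1:4),
                 CM = paste0("CM_", 1:4), HM = paste0("HM_", 1:4))
  tab <- read_expression_table(path, layout)
  expect_s3_class(tab, "probe_table")
  expect_equal(nrow(tab$data), 4)
  expect_equal(tab$conditions, c("CO", "HO", "CM", "HM"))
  expect_equal(tab$n_dropped, 0L)
})

test_that("a duplicated gene symbol yields redundant probing (R_i = 2)", {
  header <- paste(c("gene", paste0("CO_", 1:4)), collapse = "\t")
  rows <- c(paste(c("G1", 1, 2, 3, 4), collapse = "\t"),
            paste(c("G1", 2, 3, 4, 5), collapse = "\t"),
            paste(c("G2", 5, 6, 7, 8), collapse = "\t"))
  path <- write_tmp_tsv(c(header, rows))
  tab <- read_expression_table(path, list(CO = paste0("CO_", 1:4)))
  profs <- gene_profiles(tab, "CO")
  expect_equal(profs[["G1"]]$n_spots, 2)
  expect_equal(profs[["G2"]]$n_spots, 1)
})

test_that("rows with missing or non-numeric cells are dropped and counted", {
  header <- paste(c("gene", paste0("CO_", 1:4)), collapse = "\t")
  rows <- c(paste(c("G1", 1, 2, 3, 4), collapse = "\t"),
            paste(c("G2", 1, "NA", 3, 4), collapse = "\t"),
            paste(c("G3", 1, 2, "x", 4), collapse = "\t"))
  path <- write_tmp_tsv(c(header, rows))
  expect_message(
    tab <- read_expression_table(path, list(CO = paste0("CO_", 1:4))),
    "dropped 2"
  )
  expect_equal(nrow(tab$data), 1)
  expect_equal(tab$n_dropped, 2L)
  # drop count + retained rows = input rows
  expect_equal(tab$n_dropped + nrow(tab$data), 3)
})

test_that("probe table invariants are enforced", {
  base <- data.frame(spot_id = c("s1", "s2"), gene = c("A", "B"),
                     CO_1 = c(1, 2), CO_2 = c(2, 3))
  layout <- data.frame(sample = c("CO_1", "CO_2"), condition = "CO")
  expect_error(probe_table(transform(base, CO_1 = c(-1, 2)), layout),
               class = "genefabric_value_error")
  expect_error(
    probe_table(base, data.frame(sample = "CO_1", condition = "CO")),
    class = "genefabric_design_error"
  )
  expect_error(
    probe_table(base[, -1], layout),
    class = "genefabric_format_error"
  )
})

test_that("GMT parsing keeps one set per line and de-duplicates members", {
  citrate <- c("Acly", "Aco2", "Fh", "Idh2", "Idh3g", "Ogdh", "Pck2", "Pdha1")
  path <- write_tmp_tsv(c(
    paste(c("citrate_cycle", "desc", citrate), collapse = "\t"),
    "S\td\tG1\tG1\tG2"
  ))
  gs <- read_gene_sets(path)
  expect_equal(nrow(gs), 2)
  expect_length(gs$genes[[1]], 8)
  expect_equal(gs$genes[[2]], c("G1", "G2"))
})

test_that("an empty GMT file gives an empty set list; short lines error", {
  empty <- write_tmp_tsv(character())
  expect_equal(nrow(read_gene_sets(empty)), 0)
  bad <- write_tmp_tsv("name_only\tdesc")
  expect_error(read_gene_sets(bad), class = "genefabric_format_error")
})

test_that("median normalization divides by the per-condition median", {
  tab <- make_toy_table(list(G1 = c(1, 2, 3, 4)))
  norm <- normalize_to_median(tab)
  expect_equal(unname(unlist(norm$data[paste0("CO_", 1:4)])),
               c(0.4, 0.8, 1.2, 1.6))
  const <- normalize_to_median(make_toy_table(list(G1 = rep(7, 4))))
  expect_true(all(unlist(const$data[paste0("CO_", 1:4)]) == 1))
})

test_that("median normalization is idempotent and scale invariant", {
  set.seed(42)
  vals <- list(G1 = runif(4, 1, 5), G2 = runif(4, 1, 5), G3 = runif(4, 1, 5))
  tab <- make_toy_table(vals)
  n1 <- normalize_to_median(tab)
  n2 <- normalize_to_median(n1)
  expect_equal(n1$data, n2$data)
  scaled <- make_toy_table(lapply(vals, `*`, 13.7))
  expect_equal(normalize_to_median(scaled)$data, n1$data)
  # per-condition median of the result is 1
  expect_equal(median(as.matrix(n1$data[paste0("CO_", 1:4)])), 1)
})

test_that("gene profiles average redundant spots into replicate values", {
  p <- quad_profiles()$A
  expect_equal(p$replicate_values, c(96, 98, 102, 104),
               ignore_attr = TRUE)
  expect_equal(unname(p$spot_means), 100)
  two <- gene_profile("G", "CO", rbind(c(1, 1, 1, 1), c(3, 3, 3, 3)))
  expect_equal(unname(two$replicate_values), c(2, 2, 2, 2))
  same <- gene_profile("G", "CO", rbind(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(unname(same$replicate_values), c(1, 2, 3, 4))
})

test_that("gene profiles are independent of row order", {
  set.seed(7)
  vals <- list(G1 = matrix(runif(8, 1, 9), 2), G2 = runif(4, 1, 9))
  tab <- make_toy_table(vals)
  perm <- tab
  perm$data <- perm$data[rev(seq_len(nrow(perm$data))), ]
  p1 <- gene_profiles(tab, "CO")
  p2 <- gene_profiles(perm, "CO")
  expect_equal(names(p1), names(p2))
  expect_equal(p1$G1$replicate_values, p2$G1$replicate_values)
  expect_equal(sort(p1$G1$spot_means), sort(p2$G1$spot_means))
})
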