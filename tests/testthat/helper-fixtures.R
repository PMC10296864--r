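# Fixtures and independent brute-force oracles used across the suite.

# Four-replicate quadruples of the didactic genes A-D (normalized units).
quad_values <- list(
  A = c(96, 98, 102, 104),
  B = c(87, 83, 110, 120),
  C = c(105, 102, 98, 95),
  D = c(103, 97, 97, 103)
)

quad_profiles <- function() {
  lapply(names(quad_values), function(g) gene_profile(g, "CO", quad_values[[g]])) |>
    setNames(names(quad_values))
}

# one-spot-per-gene probe table; `values` is a named list of per-gene
# matrices (genes x (conditions*reps)) or, for a single condition, vectors
make_toy_table <- function(values, conditions = "CO", n_reps = 4) {
  samples <- paste0(rep(conditions, each = n_reps), "_", seq_len(n_reps))
  rows <- lapply(names(values), function(g) {
    v <- values[[g]]
    if (is.null(dim(v))) v <- matrix(v, nrow = 1)
    tibble::tibble(spot_id = paste0(g, "_s", seq_len(nrow(v))), gene = g) |>
      dplyr::bind_cols(tibble::as_tibble(matrix(v, nrow(v),
                                                dimnames = list(NULL, samples))))
  })
  probe_table(dplyr::bind_rows(rows),
              tibble::tibble(sample = samples,
                             condition = rep(conditions, each = n_reps)))
}

quad_table <- function() make_toy_table(quad_values)

# --- independent oracles (explicit-sum implementations) ---

pearson_bf <- function(a, b) {
  da <- a - sum(a) / length(a)
  db <- b - sum(b) / length(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

cv_bf <- function(v) {
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / (length(v) - 1)) / m
}

welch_bf <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * stats::pt(-abs(t_stat), df)
}

# direct evaluation of the 3-component trajectory for gene i
td_bf <- function(i, ave_ref, ave_case, rev_ref, rev_case, cor_ref, cor_case) {
  d_ave <- (ave_case[i] - ave_ref[i]) / mean(ave_ref)
  d_rev <- (rev_case[i] - rev_ref[i]) / mean(rev_ref)
  j <- setdiff(seq_along(ave_ref), i)
  num <- sqrt(mean((cor_case[i, j] - cor_ref[i, j])^2))
  den <- sqrt(mean(cor_ref[i, j]^2))
  d_cor <- num / den
  sqrt(d_ave^2 + d_rev^2 + d_cor^2)
}

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
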