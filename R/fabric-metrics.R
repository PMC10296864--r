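#' Average expression level (AVE) of a gene profile
#'
#' AVE is the mean over a gene's redundant spots of the per-spot replicate
#' means, in median-normalized expression units.
#'
#' @param profile A `gene_profile` (see [gene_profiles()]).
#' @return Numeric scalar.
#' @export
compute_ave <- function(profile) {
  stopifnot(inherits(profile, "gene_profile"), profile$n_spots >= 1)
  mean(profile$spot_means)
}

#' Pooled coefficient of variation of a gene profile
#'
#' The square root of the mean over spots of `(s_k / mu_k)^2`, where `mu_k`
#' and `s_k` are the replicate mean and sample SD of spot `k`. For a single
#' spot this is the ordinary CV. Spots are technical replicates, so pooling
#' across them uses all of the redundant probing of a gene.
#'
#' @param profile A `gene_profile`.
#' @return CV as a fraction (0.05 = 5%).
#' @export
compute_pooled_cv <- function(profile) {
  stopifnot(inherits(profile, "gene_profile"))
  if (any(profile$spot_means == 0)) {
    abort(paste0("Gene ", profile$gene, ": spot mean of 0; CV undefined."),
          class = "genefabric_degenerate_error")
  }
  sqrt(mean((profile$spot_sds / profile$spot_means)^2))
}

#' Chi-square mid-interval correction factor
#'
#' Corrects a coefficient of variation estimated from few replicates by the
#' midpoint of its chi-square confidence interval. With `r` degrees of
#' freedom the sqrt variant (default) is
#' `0.5 * (sqrt(r / chisq(0.975, r)) + sqrt(r / chisq(0.025, r)))` where the
#' quantiles are the upper 97.5 and lower 2.5 percentiles; the `linear`
#' variant applies the midpoint on the variance scale without the square
#' roots. The factor is strictly decreasing in `r` and tends to 1 as the
#' replication grows.
#'
#' @param r Degrees of freedom (`n_replicates * n_spots - 1`); must be >= 1.
#' @param variant `"sqrt"` (default) or `"linear"`.
#' @return Numeric factor >= 1 for small `r`.
#' @export
chi2_midinterval_factor <- function(r, variant = c("sqrt", "linear")) {
  variant <- match.arg(variant)
  if (any(r < 1)) abort("Degrees of freedom must be >= 1.", class = "genefabric_value_error")
  hi <- qchisq(0.975, df = r)
  lo <- qchisq(0.025, df = r)
  if (variant == "sqrt") {
    0.5 * (sqrt(r / hi) + sqrt(r / lo))
  } else {
    0.5 * (r / hi + r / lo)
  }
}

#' Relative expression variability (REV) of a gene profile
#'
#' REV is the chi-square mid-interval corrected pooled CV, expressed in
#' percent. Low REV marks genes whose expression fluctuations are tightly
#' limited by homeostatic control; high REV marks loosely controlled genes.
#'
#' @param profile A `gene_profile`.
#' @param variant Correction variant, see [chi2_midinterval_factor()].
#' @return REV in percent.
#' @export
compute_rev <- function(profile, variant = c("sqrt", "linear")) {
  variant <- match.arg(variant)
  cv <- compute_pooled_cv(profile)
  r <- profile$n_replicates * profile$n_spots - 1
  chi2_midinterval_factor(r, variant) * cv * 100
}

#' Per-condition fabric summary (AVE, pooled CV, REV)
#'
#' @param table A [probe_table()].
#' @param conditions Conditions to summarize (default all).
#' @param rev_variant See [chi2_midinterval_factor()].
#' @return A tibble of class `fabric_summary`: `gene`, `condition`,
#'   `n_spots`, `ave`, `pooled_cv` (fraction), `rev` (percent).
#' @export
fabric_summary <- function(table, conditions = NULL,
                           rev_variant = c("sqrt", "linear")) {
  rev_variant <- match.arg(rev_variant)
  conditions <- conditions %||% table$conditions
  rows <- purrr::map_dfr(conditions, function(cond) {
    profs <- gene_profiles(table, cond)
    purrr::map_dfr(profs, function(p) {
      cv <- if (any(p$spot_means == 0)) NA_real_ else compute_pooled_cv(p)
      tibble(
        gene = p$gene, condition = cond, n_spots = p$n_spots,
        ave = compute_ave(p),
        pooled_cv = cv,
        rev = if (is.na(cv)) NA_real_ else
          chi2_midinterval_factor(p$n_replicates * p$n_spots - 1, rev_variant) * cv * 100
      )
    })
  })
  class(rows) <- c("fabric_summary", class(rows))
  rows
}

#' Expression correlation (COR) of two gene profiles
#'
#' Pearson product-moment correlation of two genes' expression across the
#' biological replicates of one condition. The default `gene_means` mode
#' averages a gene's spots within each replicate first and correlates the
#' two per-replicate vectors (log2-transformed when `log2 = TRUE`). The
#' `pooled_spots` mode evaluates the spot-level double sum over all spot
#' pairs; when the two genes have different spot counts that quotient is not
#' guaranteed to lie in `[-1, 1]` and is clamped (with a warning).
#'
#' @param profile_i,profile_g `gene_profile`s from the same condition with
#'   the same replicate count (>= 3).
#' @param mode `"gene_means"` (default) or `"pooled_spots"`.
#' @param log2 Correlate log2 expressions (default `TRUE`).
#' @return Correlation in `[-1, 1]`, or `NA` when either profile has zero
#'   variance (undefined correlation, distinct from 0).
#' @export
compute_cor <- function(profile_i, profile_g,
                        mode = c("gene_means", "pooled_spots"), log2 = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile_i, "gene_profile"), inherits(profile_g, "gene_profile"))
  if (profile_i$n_replicates != profile_g$n_replicates) {
    abort("Profiles must have the same replicate count.", class = "genefabric_design_error")
  }
  if (profile_i$n_replicates < 3) {
    abort("COR needs >= 3 biological replicates.", class = "genefabric_design_error")
  }
  tf <- if (log2) function(x) base::log2(x) else identity
  if (mode == "gene_means") {
    a <- tf(profile_i$replicate_values)
    b <- tf(profile_g$replicate_values)
    if (!all(is.finite(a)) || !all(is.finite(b))) return(NA_real_)
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    return(cor(a, b))
  }
  vi <- tf(profile_i$values); vg <- tf(profile_g$values)
  if (!all(is.finite(vi)) || !all(is.finite(vg))) return(NA_real_)
  di <- vi - mean(rowMeans(vi))
  dg <- vg - mean(rowMeans(vg))
  den <- sqrt(sum(di^2) * sum(dg^2))
  if (den == 0) return(NA_real_)
  # the triple sum over (k_i, k_g, j) factorizes over replicates
  r <- sum(colSums(di) * colSums(dg)) / den
  if (abs(r) > 1) {
    warn(paste0("pooled_spots COR outside [-1,1] for ", profile_i$gene, "/",
                profile_g$gene, "; clamped."))
    r <- sign(r)
  }
  r
}

#' Classify a gene-pair correlation
#'
#' Pairs with `|COR|` at or above `sig_threshold` are significantly
#' synergistic (positive) or antagonistic (negative); pairs with `|COR|` at
#' or below `ind_threshold` are independently expressed; everything in
#' between is not significant. `NA` correlations (undefined, e.g. constant
#' profiles) classify as not significant.
#'
#' @param cor Numeric vector of correlations (may contain `NA`).
#' @param sig_threshold Significance threshold, boundary inclusive
#'   (default 0.95).
#' @param ind_threshold Independence threshold (default 0.05); must be below
#'   `sig_threshold`.
#' @return Character vector with levels `synergistic`, `antagonistic`,
#'   `independent`, `not_significant`.
#' @export
classify_pair <- function(cor, sig_threshold = 0.95, ind_threshold = 0.05) {
  if (ind_threshold >= sig_threshold) {
    abort("`ind_threshold` must be below `sig_threshold`.", class = "genefabric_value_error")
  }
  dplyr::case_when(
    is.na(cor) ~ "not_significant",
    cor >= sig_threshold ~ "synergistic",
    cor <= -sig_threshold ~ "antagonistic",
    abs(cor) <= ind_threshold ~ "independent",
    TRUE ~ "not_significant"
  )
}

#' Gene-gene correlation matrix for one condition
#'
#' @inheritParams compute_cor
#' @param table A [probe_table()].
#' @param condition Condition label.
#' @param genes Optional subset of genes (case-insensitive match).
#' @return Symmetric genes x genes correlation matrix; `NA` where a gene has
#'   zero variance (or a non-finite log2 value).
#' @export
cor_matrix <- function(table, condition, genes = NULL, log2 = TRUE) {
  m <- gene_replicate_matrix(table, condition)
  if (!is.null(genes)) {
    sel <- match_members(genes, rownames(m))
    m <- m[sel, , drop = FALSE]
  }
  if (log2) m <- base::log2(m)
  ok <- apply(m, 1, function(x) all(is.finite(x)) && sd(x) > 0)
  cm <- matrix(NA_real_, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  if (any(ok)) {
    cm[ok, ok] <- suppressWarnings(cor(t(m[ok, , drop = FALSE])))
  }
  diag(cm)[ok] <- 1
  cm
}

#' All-pairs classified correlations for one condition
#'
#' @inheritParams cor_matrix
#' @inheritParams classify_pair
#' @return A tibble of class `cor_pairs`: `gene_a`, `gene_b` (a < b in the
#'   data's gene order), `condition`, `cor`, `klass`.
#' @export
cor_pairs <- function(table, condition, genes = NULL, log2 = TRUE,
                      sig_threshold = 0.95, ind_threshold = 0.05) {
  cm <- cor_matrix(table, condition, genes = genes, log2 = log2)
  out <- pairs_from_matrix(cm, condition, sig_threshold, ind_threshold)
  class(out) <- c("cor_pairs", class(out))
  out
}

pairs_from_matrix <- function(cm, condition, sig_threshold = 0.95,
                              ind_threshold = 0.05) {
  g <- rownames(cm)
  if (length(g) < 2) {
    return(tibble(gene_a = character(), gene_b = character(),
                  condition = character(), cor = numeric(), klass = character()))
  }
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  tibble(
    gene_a = g[idx[, 1]],
    gene_b = g[idx[, 2]],
    condition = condition,
    cor = cm[idx],
    klass = classify_pair(cm[idx], sig_threshold, ind_threshold)
  )
}

#' Coordination score of a gene set
#'
#' SYN, ANT and IND are the percentages of within-set gene pairs that are
#' significantly synergistically, antagonistically or independently
#' expressed; the coordination score is `SYN + ANT - IND`, so a set whose
#' pairs fluctuate mostly in concert (in either phase) scores high, and a
#' set of mutually independent genes scores negative.
#'
#' @param pairs A `cor_pairs` tibble (see [cor_pairs()]).
#' @param members Character vector of set member symbols (case-insensitive),
#'   or a one-row slice of a [read_gene_sets()] tibble.
#' @param set_name Label for the output (default deduced).
#' @return One-row tibble: `set`, `condition`, `n_genes`, `n_pairs`,
#'   `syn_pct`, `ant_pct`, `ind_pct`, `coord`.
#' @export
coordination_score <- function(pairs, members, set_name = NULL) {
  if (is.data.frame(members)) {
    set_name <- set_name %||% members$set[[1]]
    members <- members$genes[[1]]
  }
  set_name <- set_name %||% "gene_set"
  universe <- unique(c(pairs$gene_a, pairs$gene_b))
  present <- match_members(members, universe)
  if (length(present) < 2) {
    abort(paste0("Gene set ", set_name, ": fewer than 2 members present."),
          class = "genefabric_empty_set_error")
  }
  sub <- dplyr::filter(pairs, .data$gene_a %in% present & .data$gene_b %in% present)
  n_pairs <- nrow(sub)
  pct <- function(k) 100 * sum(sub$klass == k) / n_pairs
  tibble(
    set = set_name,
    condition = sub$condition[1] %||% NA_character_,
    n_genes = length(present),
    n_pairs = n_pairs,
    syn_pct = pct("synergistic"),
    ant_pct = pct("antagonistic"),
    ind_pct = pct("independent"),
    coord = pct("synergistic") + pct("antagonistic") - pct("independent")
  )
}
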