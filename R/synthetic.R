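#' Specification for a synthetic replicated expression dataset
#'
#' Describes a log-normal expression model over a multi-condition,
#' replicated, redundantly probed design, with a latent-factor correlation
#' structure so synergistic, antagonistic and independent gene pairs exist
#' by construction, and planted per-condition fold-changes. Defaults emulate
#' a 4-condition (CO/HO/CM/HM) x 4-replicate rat-lung microarray study:
#' baseline levels spanning roughly 0.2-300 median units, per-gene
#' biological CVs spanning 3%-160%, and fold-change magnitudes up to ~250.
#'
#' @param n_genes Number of genes (default 200).
#' @param conditions Ordered condition labels; the first is the reference.
#' @param n_replicates Biological replicates per condition (default 4).
#' @param spot_probs Named probabilities of a gene being probed by 1, 2, ...
#'   redundant spots.
#' @param baseline_log2_mean,baseline_log2_sd Normal distribution of gene
#'   baseline log2 expression.
#' @param cv_range Per-gene biological CV range (fractions); CVs are drawn
#'   log-uniformly.
#' @param technical_cv Technical (spot-level) CV, shared by all spots.
#' @param blocks Data frame with columns `size`, `rho` and `antagonistic`
#'   (logical: alternate loading signs inside the block) defining latent
#'   correlation blocks; remaining genes load on no factor (independent).
#' @param regulated_fraction Fraction of genes given a planted fold-change
#'   in every non-reference condition (default 0.15).
#' @param fold_range Range of planted fold-change magnitudes, drawn
#'   log-uniformly with random sign (default `c(1.2, 250)`).
#' @param regulation Optional explicit tibble (`gene` index or symbol,
#'   `condition`, `fold` signed) overriding the random plant.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 200,
                           conditions = c("CO", "HO", "CM", "HM"),
                           n_replicates = 4,
                           spot_probs = c("1" = 0.70, "2" = 0.25, "3" = 0.05),
                           baseline_log2_mean = 2,
                           baseline_log2_sd = 3,
                           cv_range = c(0.03, 1.60),
                           technical_cv = 0.05,
                           blocks = data.frame(size = c(10, 10),
                                               rho = c(0.98, 0.98),
                                               antagonistic = c(FALSE, TRUE)),
                           regulated_fraction = 0.15,
                           fold_range = c(1.2, 250),
                           regulation = NULL) {
  stopifnot(n_genes >= 2, length(conditions) >= 2, n_replicates >= 2,
            all(cv_range > 0), technical_cv >= 0,
            all(fold_range >= 1))
  if (!is.null(blocks)) {
    blocks <- as_tibble(blocks)
    if (sum(blocks$size) > n_genes) {
      abort("Correlation blocks cannot cover more genes than `n_genes`.",
            class = "genefabric_spec_error")
    }
    if (any(blocks$rho < 0 | blocks$rho > 1)) {
      abort("Block `rho` must lie in [0, 1] (loading structure must be PSD).",
            class = "genefabric_spec_error")
    }
  }
  if (!is.null(regulation)) {
    regulation <- as_tibble(regulation)
    if (any(regulation$fold == 0)) {
      abort("Planted fold-changes must be non-zero.", class = "genefabric_spec_error")
    }
  }
  structure(
    list(n_genes = n_genes, conditions = conditions,
         n_replicates = n_replicates, spot_probs = spot_probs,
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         cv_range = cv_range, technical_cv = technical_cv, blocks = blocks,
         regulated_fraction = regulated_fraction, fold_range = fold_range,
         regulation = regulation),
    class = "synthetic_spec"
  )
}

# log2-scale SD giving a log-normal variable the target linear-scale CV
log2_sd_for_cv <- function(cv) sqrt(log(1 + cv^2)) / log(2)

# signed ratio (|x| >= 1, or a positive fraction) -> log2 fold
signed_log2_fold <- function(x) {
  out <- rep(NA_real_, length(x))
  pos <- !is.na(x) & x > 0
  out[pos] <- log2(x[pos])
  out[!is.na(x) & x < 0] <- -log2(-x[!is.na(x) & x < 0])
  out
}

#' Generate a synthetic dataset with known ground truth
#'
#' Each biological replicate of a gene is generated on the log2 scale as
#' baseline + planted condition effect + factor loading x latent replicate
#' factor + biological noise; each redundant spot then adds independent
#' technical noise. Biological draws are shared across a gene's spots (spots
#' are technical replicates), which is what makes redundant probing
#' informative for the pooled CV. Values are exponentiated and
#' median-normalized per condition; ground-truth fold-changes are recorded
#' after normalization.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; generation is deterministic given (spec, seed).
#' @return A list of class `synthetic_dataset` with elements `table` (a
#'   normalized [probe_table()]), `truth` (list: `genes`, `expression`,
#'   `cor` matrix on the log2 scale, `pairs` planted pair classes,
#'   `pathways` planted gene sets) and `spec`.
#' @export
generate_dataset <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  ng <- spec$n_genes
  conds <- spec$conditions
  nr <- spec$n_replicates
  genes <- sprintf("g%04d", seq_len(ng))

  n_spots <- sample(as.integer(names(spec$spot_probs)), ng, replace = TRUE,
                    prob = spec$spot_probs)
  baseline <- stats::rnorm(ng, spec$baseline_log2_mean, spec$baseline_log2_sd)
  cv <- exp(stats::runif(ng, log(spec$cv_range[1]), log(spec$cv_range[2])))
  s_tot <- log2_sd_for_cv(cv)

  # latent-factor structure: blocks of co-loaded genes
  block <- rep(NA_integer_, ng)
  loading_sign <- rep(1, ng)
  if (!is.null(spec$blocks) && nrow(spec$blocks) > 0) {
    at <- 1L
    for (b in seq_len(nrow(spec$blocks))) {
      idx <- seq(at, length.out = spec$blocks$size[b])
      block[idx] <- b
      if (spec$blocks$antagonistic[b]) {
        loading_sign[idx] <- rep_len(c(1, -1), length(idx))
      }
      at <- at + spec$blocks$size[b]
    }
  }
  rho <- ifelse(is.na(block), 0, spec$blocks$rho[block])
  loading <- loading_sign * sqrt(rho) * s_tot
  resid_sd <- sqrt(1 - rho) * s_tot

  # planted regulation (reference condition gets fold 1)
  reg <- spec$regulation
  if (is.null(reg)) {
    n_reg <- round(spec$regulated_fraction * ng)
    reg_genes <- if (n_reg > 0) sample(genes, n_reg) else character()
    reg <- purrr::map_dfr(conds[-1], function(cc) {
      if (length(reg_genes) == 0) return(tibble())
      mag <- exp(stats::runif(length(reg_genes),
                              log(spec$fold_range[1]), log(spec$fold_range[2])))
      tibble(gene = reg_genes, condition = cc,
             fold = mag * sample(c(-1, 1), length(reg_genes), replace = TRUE))
    })
  } else if (is.numeric(reg$gene)) {
    reg$gene <- genes[reg$gene]
  }
  l2f <- matrix(0, ng, length(conds), dimnames = list(genes, conds))
  if (nrow(reg) > 0) {
    # signed fold convention: -k means 1/k on the linear scale
    l2f[cbind(match(reg$gene, genes), match(reg$condition, conds))] <-
      signed_log2_fold(reg$fold)
  }

  tech_sd <- log2_sd_for_cv(spec$technical_cv)
  n_cols <- length(conds) * nr
  cond_of_col <- rep(conds, each = nr)
  n_blocks <- if (is.null(spec$blocks)) 0 else nrow(spec$blocks)
  Z <- if (n_blocks > 0) matrix(stats::rnorm(n_blocks * n_cols), n_blocks) else NULL
  eps <- matrix(stats::rnorm(ng * n_cols), ng) * resid_sd

  gene_log2 <- baseline + l2f[, cond_of_col] + eps
  if (n_blocks > 0) {
    has_block <- !is.na(block)
    gene_log2[has_block, ] <- gene_log2[has_block, ] +
      loading[has_block] * Z[block[has_block], , drop = FALSE]
  }

  spot_gene <- rep(seq_len(ng), times = n_spots)
  tech <- if (tech_sd > 0) {
    matrix(stats::rnorm(length(spot_gene) * n_cols), length(spot_gene)) * tech_sd
  } else 0
  spot_log2 <- gene_log2[spot_gene, , drop = FALSE] + tech

  samples <- paste0(cond_of_col, "_", rep(seq_len(nr), length(conds)))
  vals <- 2^spot_log2
  colnames(vals) <- samples
  data <- bind_cols(
    tibble(spot_id = sprintf("s%05d", seq_along(spot_gene)),
           gene = genes[spot_gene]),
    as_tibble(vals)
  )
  layout <- tibble(sample = samples, condition = cond_of_col)
  raw_table <- probe_table(data, layout)
  medians <- vapply(conds, function(cc) {
    median(as.matrix(data[layout$sample[layout$condition == cc]]))
  }, numeric(1))
  table <- normalize_to_median(raw_table)

  # ground truth, post-normalization
  gm <- exp(((s_tot^2 + tech_sd^2) * log(2)^2) / 2)  # lognormal mean factor
  expression <- purrr::map_dfr(seq_along(conds), function(ci) {
    cc <- conds[ci]
    ratio <- 2^(l2f[, ci] - l2f[, 1]) * medians[1] / medians[ci]
    tibble(
      gene = genes, condition = cc,
      true_mean = 2^(baseline + l2f[, ci]) * gm / medians[ci],
      true_cv = cv,
      true_fold = ifelse(ratio >= 1, ratio, -1 / ratio)
    )
  })

  cor_truth <- diag(ng)
  dimnames(cor_truth) <- list(genes, genes)
  if (n_blocks > 0) {
    for (b in seq_len(n_blocks)) {
      idx <- which(block == b)
      cor_truth[idx, idx] <- outer(loading_sign[idx], loading_sign[idx]) *
        spec$blocks$rho[b]
      diag(cor_truth)[idx] <- 1
    }
  }
  pair_idx <- which(upper.tri(cor_truth), arr.ind = TRUE)
  pairs_truth <- tibble(
    gene_a = genes[pair_idx[, 1]],
    gene_b = genes[pair_idx[, 2]],
    true_cor = cor_truth[pair_idx],
    true_class = dplyr::case_when(
      cor_truth[pair_idx] > 0 ~ "synergistic",
      cor_truth[pair_idx] < 0 ~ "antagonistic",
      TRUE ~ "independent"
    )
  )

  pathways <- if (n_blocks > 0) {
    tibble(
      set = paste0("block_", seq_len(n_blocks)),
      description = "planted correlation block",
      genes = lapply(seq_len(n_blocks), function(b) genes[which(block == b)])
    )
  } else {
    tibble(set = character(), description = character(), genes = list())
  }

  structure(
    list(
      table = table,
      truth = list(
        genes = tibble(gene = genes, n_spots = n_spots, block = block,
                       baseline_log2 = baseline, true_cv = cv,
                       loading = loading),
        expression = expression,
        cor = cor_truth,
        pairs = pairs_truth,
        pathways = pathways,
        regulation = reg
      ),
      spec = spec,
      seed = as.integer(seed)
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> seed ", x$seed, "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Parameter-recovery report for a synthetic dataset
#'
#' Runs the estimation pipeline on a generated dataset and compares the
#' estimates against the planted ground truth: relative bias and RMSE of
#' AVE, bias/RMSE of the log2 fold estimate for regulated genes, Spearman
#' rank correlation between estimated REV and planted CV, and confusion
#' matrices of pair classification and regulation calls.
#'
#' @param dataset A [generate_dataset()] result.
#' @param case Condition compared against the reference for fold recovery
#'   (default: second condition).
#' @param sig_threshold,ind_threshold Pair-classification thresholds.
#' @return An object of class `recovery_report` with elements `metrics`
#'   (tibble), `pair_confusion` and `regulation_confusion` (tables).
#' @export
recovery_report <- function(dataset, case = NULL,
                            sig_threshold = 0.95, ind_threshold = 0.05) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  conds <- dataset$spec$conditions
  reference <- conds[1]
  case <- case %||% conds[2]
  if (!case %in% conds) {
    abort(paste0("Unknown condition: ", case), class = "genefabric_design_error")
  }
  fab <- fabric_summary(dataset$table, reference)
  truth_ref <- dplyr::filter(dataset$truth$expression, .data$condition == reference)
  j <- dplyr::inner_join(fab, truth_ref, by = "gene")
  rel_err <- (j$ave - j$true_mean) / j$true_mean
  rev_cv_spearman <- cor(j$rev, j$true_cv, method = "spearman",
                         use = "complete.obs")

  reg <- regulation_table(dataset$table, reference, case)
  truth_case <- dplyr::filter(dataset$truth$expression, .data$condition == case)
  jr <- dplyr::inner_join(reg, truth_case, by = "gene")
  fold_err <- signed_log2_fold(jr$x) - signed_log2_fold(jr$true_fold)
  planted <- abs(jr$true_fold) > 1
  regulation_confusion <- table(planted = planted, called = jr$significant)

  prs <- cor_pairs(dataset$table, reference,
                   sig_threshold = sig_threshold, ind_threshold = ind_threshold)
  jp <- dplyr::inner_join(prs, dataset$truth$pairs, by = c("gene_a", "gene_b"))
  pair_confusion <- table(truth = jp$true_class, estimated = jp$klass)

  structure(
    list(
      metrics = tibble(
        reference = reference, case = case,
        n_genes = nrow(j),
        ave_rel_bias = mean(rel_err),
        ave_rel_rmse = sqrt(mean(rel_err^2)),
        rev_cv_spearman = rev_cv_spearman,
        fold_log2_bias = mean(fold_err, na.rm = TRUE),
        fold_log2_rmse = sqrt(mean(fold_err^2, na.rm = TRUE))
      ),
      pair_confusion = pair_confusion,
      regulation_confusion = regulation_confusion
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$metrics)
  invisible(x)
}

#' @describeIn recovery_report Recovery metrics as a tibble.
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) x$metrics
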