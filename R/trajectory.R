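#' Individual transcriptomic trajectory (ITT) of one gene
#'
#' The ITT is a 3-vector of normalized changes between a reference and a
#' case condition in the three independent expression characteristics:
#' average level (AVE), variability (REV) and coordination (COR). Each
#' component is scaled by a reference-condition normalizer taken over a gene
#' universe, so the components are commensurable:
#' \itemize{
#'   \item `d_ave = (AVE_case - AVE_ref) / <AVE_ref>` (universe average),
#'   \item `d_rev = (REV_case - REV_ref) / <REV_ref>`,
#'   \item `d_cor = rms_j(COR_case(i,j) - COR_ref(i,j)) / rms_j(COR_ref(i,j))`
#'     with `j` over the universe minus the focal gene.
#' }
#' The transcriptomic distance TD is the Euclidean norm of the ITT: how far
#' the gene's whole expression behaviour moved from the reference state.
#'
#' @param gene Focal gene symbol.
#' @param fabric_ref,fabric_case [fabric_summary()] rows for the reference
#'   and case conditions (any superset of the universe).
#' @param cor_ref,cor_case Correlation matrices from [cor_matrix()] covering
#'   the universe.
#' @param universe Character vector of genes defining the normalizers and
#'   the COR partner set; defaults to all genes shared by the two fabric
#'   summaries. Pairs with an undefined COR in either condition are excluded
#'   from both mean-square sums.
#' @return One-row tibble: `gene`, `d_ave`, `d_rev`, `d_cor`, `td`.
#' @export
compute_itt <- function(gene, fabric_ref, fabric_case, cor_ref, cor_case,
                        universe = NULL) {
  universe <- universe %||% intersect(fabric_ref$gene, fabric_case$gene)
  fr <- fabric_ref[match(universe, fabric_ref$gene), ]
  fc <- fabric_case[match(universe, fabric_case$gene), ]
  if (!gene %in% universe) {
    abort(paste0("Gene ", gene, " absent from the universe."),
          class = "genefabric_design_error")
  }
  ave_norm <- mean(fr$ave, na.rm = TRUE)
  rev_norm <- mean(fr$rev, na.rm = TRUE)
  if (!is.finite(ave_norm) || ave_norm == 0 || !is.finite(rev_norm) || rev_norm == 0) {
    abort("Degenerate normalizer: universe mean AVE or REV is 0.",
          class = "genefabric_degenerate_error")
  }
  i <- match(gene, universe)
  partners <- setdiff(universe, gene)
  cr <- cor_ref[gene, partners]
  cc <- cor_case[gene, partners]
  ok <- is.finite(cr) & is.finite(cc)
  if (!any(ok) || all(cr[ok] == 0)) {
    abort(paste0("Gene ", gene, ": reference correlations all 0/undefined."),
          class = "genefabric_degenerate_error")
  }
  d_ave <- (fc$ave[i] - fr$ave[i]) / ave_norm
  d_rev <- (fc$rev[i] - fr$rev[i]) / rev_norm
  d_cor <- sqrt(mean((cc[ok] - cr[ok])^2)) / sqrt(mean(cr[ok]^2))
  tibble(gene = gene, d_ave = d_ave, d_rev = d_rev, d_cor = d_cor,
         td = sqrt(d_ave^2 + d_rev^2 + d_cor^2))
}

#' Per-gene transcriptomic trajectories for a contrast
#'
#' Computes the ITT components and TD of every gene in the universe for a
#' reference -> case contrast.
#'
#' @inheritParams regulation_table
#' @param universe Optional gene universe for the normalizers and COR
#'   partner set (default: all genes quantified in both conditions).
#' @param log2 Correlate log2 expressions (see [cor_matrix()]).
#' @return A tibble of class `trajectory_table`: `gene`, `contrast`,
#'   `d_ave`, `d_rev`, `d_cor`, `td`.
#' @export
trajectory_table <- function(table, reference, case, universe = NULL,
                             rev_variant = c("sqrt", "linear"), log2 = TRUE) {
  rev_variant <- match.arg(rev_variant)
  fab <- fabric_summary(table, c(reference, case), rev_variant = rev_variant)
  fr <- dplyr::filter(fab, .data$condition == reference)
  fc <- dplyr::filter(fab, .data$condition == case)
  universe <- universe %||% intersect(fr$gene, fc$gene)
  universe <- match_members(universe, intersect(fr$gene, fc$gene))
  cr <- cor_matrix(table, reference, genes = universe, log2 = log2)
  cc <- cor_matrix(table, case, genes = universe, log2 = log2)
  out <- purrr::map_dfr(universe, function(g) {
    tryCatch(
      compute_itt(g, fr, fc, cr, cc, universe = universe),
      genefabric_degenerate_error = function(e) {
        tibble(gene = g, d_ave = NA_real_, d_rev = NA_real_,
               d_cor = NA_real_, td = NA_real_)
      }
    )
  })
  out <- mutate(out, contrast = paste0(reference, "->", case), .after = "gene")
  class(out) <- c("trajectory_table", class(out))
  out
}

#' Pathway-level transcriptomic-distance summary
#'
#' @param trajectories A [trajectory_table()] result.
#' @param members Set member symbols (case-insensitive), or a one-row slice
#'   of a [read_gene_sets()] tibble.
#' @param set_name Label for the output.
#' @return A list with `summary` (one-row tibble: `set`, `contrast`,
#'   `n_genes`, `mean_td`) and `ranking` (member genes sorted by decreasing
#'   TD).
#' @export
pathway_td_summary <- function(trajectories, members, set_name = NULL) {
  if (is.data.frame(members)) {
    set_name <- set_name %||% members$set[[1]]
    members <- members$genes[[1]]
  }
  set_name <- set_name %||% "gene_set"
  present <- match_members(members, trajectories$gene)
  if (length(present) == 0) {
    abort(paste0("Gene set ", set_name, ": no member has a trajectory record."),
          class = "genefabric_empty_set_error")
  }
  sub <- trajectories |>
    dplyr::filter(.data$gene %in% present) |>
    arrange(dplyr::desc(.data$td))
  list(
    summary = tibble(
      set = set_name,
      contrast = sub$contrast[1],
      n_genes = nrow(sub),
      mean_td = mean(sub$td, na.rm = TRUE)
    ),
    ranking = sub
  )
}
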