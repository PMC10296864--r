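#' Run the full fabric analysis pipeline
#'
#' Orchestrates every stage for a replicated multi-condition expression
#' table: median normalization, per-condition fabric metrics (AVE/REV),
#' all-pairs correlation classification, pathway coordination scores,
#' contrast-level regulation calling (CUT, WIR), transcriptomic
#' trajectories (TD), coordination networks with remodeling reports, and
#' the four-quantifier summary per gene set. All tabular outputs are
#' written as TSV with a header comment recording the package version and
#' a configuration hash; a JSON manifest makes the run reproducible.
#'
#' @param table A [probe_table()] (raw or already normalized).
#' @param gene_sets A [read_gene_sets()] tibble (or path to a GMT file);
#'   may be `NULL` to skip set-level outputs.
#' @param out_dir Output directory, created if needed.
#' @param reference Reference condition (default first condition).
#' @param contrasts Case conditions to compare against the reference
#'   (default all others).
#' @param alpha,sig_threshold,ind_threshold,cut_pooling,rev_variant,cor_log2
#'   Stage parameters; see [call_regulation()], [classify_pair()],
#'   [compute_cut()], [chi2_midinterval_factor()], [cor_matrix()].
#' @return The run manifest (list), invisibly; written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(table, gene_sets = NULL, out_dir,
                         reference = NULL, contrasts = NULL,
                         alpha = 0.05, sig_threshold = 0.95,
                         ind_threshold = 0.05,
                         cut_pooling = "rms", rev_variant = "sqrt",
                         cor_log2 = TRUE) {
  stopifnot(inherits(table, "probe_table"))
  if (is.character(gene_sets)) gene_sets <- read_gene_sets(gene_sets)
  reference <- reference %||% table$conditions[1]
  if (!reference %in% table$conditions) {
    abort(paste0("Reference condition not in table: ", reference),
          class = "genefabric_design_error")
  }
  contrasts <- contrasts %||% setdiff(table$conditions, reference)
  unknown <- setdiff(contrasts, table$conditions)
  if (length(unknown) > 0) {
    abort(paste0("Unknown condition label(s): ", paste(unknown, collapse = ", ")),
          class = "genefabric_design_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- list(reference = reference, contrasts = contrasts, alpha = alpha,
                 sig_threshold = sig_threshold, ind_threshold = ind_threshold,
                 cut_pooling = cut_pooling, rev_variant = rev_variant,
                 cor_log2 = cor_log2)
  cfg_hash <- rlang::hash(list(config, table$data, table$layout,
                               if (is.null(gene_sets)) NULL else gene_sets))
  stamp <- paste0("# genefabric ", packageVersion("genefabric"),
                  "; config ", cfg_hash)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    writeLines(stamp, path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
    name
  }

  if (!table$normalized) table <- normalize_to_median(table)
  inform(paste0("run_pipeline: ", nrow(table$data), " spots, ",
                dplyr::n_distinct(table$data$gene), " genes, reference ",
                reference, ", contrasts ", paste(contrasts, collapse = ", ")))

  outputs <- character()
  fab <- fabric_summary(table, rev_variant = rev_variant)
  outputs <- c(outputs, emit(fab, "fabric_summary.tsv"))

  pair_tabs <- lapply(setNames(nm = table$conditions), function(cc) {
    cor_pairs(table, cc, log2 = cor_log2,
              sig_threshold = sig_threshold, ind_threshold = ind_threshold)
  })
  outputs <- c(outputs, emit(bind_rows(pair_tabs), "cor_pairs.tsv"))

  if (!is.null(gene_sets) && nrow(gene_sets) > 0) {
    coords <- purrr::map_dfr(table$conditions, function(cc) {
      purrr::map_dfr(seq_len(nrow(gene_sets)), function(i) {
        coordination_score(pair_tabs[[cc]], gene_sets[i, ])
      })
    })
    outputs <- c(outputs, emit(coords, "coord_scores.tsv"))
  }

  regs <- list(); trajs <- list()
  for (case in contrasts) {
    regs[[case]] <- regulation_table(table, reference, case, alpha = alpha,
                                     cut_pooling = cut_pooling,
                                     rev_variant = rev_variant)
    trajs[[case]] <- trajectory_table(table, reference, case,
                                      rev_variant = rev_variant,
                                      log2 = cor_log2)
    n_sig <- sum(regs[[case]]$significant, na.rm = TRUE)
    inform(paste0("  ", reference, "->", case, ": ", n_sig,
                  " significantly regulated gene(s)"))
  }
  outputs <- c(outputs, emit(bind_rows(regs), "regulation.tsv"))
  outputs <- c(outputs, emit(bind_rows(trajs), "trajectory.tsv"))

  if (!is.null(gene_sets) && nrow(gene_sets) > 0) {
    psr_tab <- purrr::map_dfr(contrasts, function(case) {
      purrr::map_dfr(seq_len(nrow(gene_sets)),
                     function(i) psr(regs[[case]], gene_sets[i, ]))
    })
    outputs <- c(outputs, emit(psr_tab, "psr.tsv"))
    td_tab <- purrr::map_dfr(contrasts, function(case) {
      purrr::map_dfr(seq_len(nrow(gene_sets)), function(i) {
        pathway_td_summary(trajs[[case]], gene_sets[i, ])$summary
      })
    })
    outputs <- c(outputs, emit(td_tab, "pathway_td.tsv"))

    edges <- list(); remodel <- list(); quant <- list()
    for (i in seq_len(nrow(gene_sets))) {
      nets <- lapply(pair_tabs, function(p) {
        tryCatch(suppressWarnings(build_network(p, gene_sets[i, ])),
                 genefabric_empty_set_error = function(e) NULL)
      })
      if (is.null(nets[[reference]])) next
      for (cc in table$conditions) {
        if (is.null(nets[[cc]])) next
        edges[[paste(i, cc)]] <- mutate(nets[[cc]]$edges,
                                        set = gene_sets$set[i], .before = 1)
      }
      for (case in contrasts) {
        if (is.null(nets[[case]])) next
        rep_ <- remodeling_report(nets[[reference]], nets[[case]])
        remodel[[paste(i, case)]] <- tidy(rep_) |>
          mutate(set = gene_sets$set[i],
                 contrast = paste0(reference, "->", case), .before = 1)
        quant[[paste(i, case)]] <-
          summarize_quantifiers(regs[[case]], trajs[[case]], gene_sets[i, ]) |>
          mutate(set = gene_sets$set[i], .before = 1)
      }
    }
    if (length(edges) > 0) outputs <- c(outputs, emit(bind_rows(edges), "network_edges.tsv"))
    if (length(remodel) > 0) outputs <- c(outputs, emit(bind_rows(remodel), "remodeling.tsv"))
    if (length(quant) > 0) outputs <- c(outputs, emit(bind_rows(quant), "quantifiers.tsv"))
  }

  manifest <- list(
    package = "genefabric",
    version = as.character(packageVersion("genefabric")),
    config = config,
    config_hash = cfg_hash,
    n_spots = nrow(table$data),
    n_genes = dplyr::n_distinct(table$data$gene),
    conditions = table$conditions,
    outputs = outputs,
    checksums = setNames(
      vapply(outputs, function(f) rlang::hash(readLines(file.path(out_dir, f))),
             character(1)), outputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Four per-gene quantifiers of transcriptomic alteration
#'
#' For each member of a gene set, the four ways of scoring its contribution
#' to a contrast's transcriptomic alteration: the uniform +1/-1/0 vote
#' (significantly up / down / not regulated), the signed expression ratio
#' `x`, the weighted individual regulation WIR, and the transcriptomic
#' distance TD — with the three non-uniform rankings, which in general
#' disagree.
#'
#' @param regulation A [regulation_table()] result for the contrast.
#' @param trajectories A [trajectory_table()] result for the same contrast.
#' @param members Set member symbols (case-insensitive), or a one-row slice
#'   of a [read_gene_sets()] tibble; default all genes shared by the two
#'   inputs.
#' @return Tibble: `gene`, `contrast`, `uniform`, `x`, `wir`, `td`,
#'   `rank_x`, `rank_wir`, `rank_td` (1 = largest magnitude).
#' @export
summarize_quantifiers <- function(regulation, trajectories, members = NULL) {
  if (is.data.frame(members)) members <- members$genes[[1]]
  genes <- intersect(regulation$gene, trajectories$gene)
  if (!is.null(members)) genes <- match_members(members, genes)
  if (length(genes) == 0) {
    abort("No gene has both regulation and trajectory records.",
          class = "genefabric_dependency_error")
  }
  reg <- dplyr::filter(regulation, .data$gene %in% genes)
  tr <- dplyr::filter(trajectories, .data$gene %in% genes)
  dplyr::inner_join(
    select(reg, "gene", "contrast", "x", "wir", "significant", "direction"),
    select(tr, "gene", "td"),
    by = "gene"
  ) |>
    mutate(
      uniform = dplyr::case_when(
        .data$direction == "up" ~ 1L,
        .data$direction == "down" ~ -1L,
        TRUE ~ 0L
      ),
      rank_x = rank(-abs(.data$x), ties.method = "min"),
      rank_wir = rank(-abs(.data$wir), ties.method = "min"),
      rank_td = rank(-.data$td, ties.method = "min")
    ) |>
    select("gene", "contrast", "uniform", "x", "wir", "td",
           "rank_x", "rank_wir", "rank_td")
}
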