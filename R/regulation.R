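#' Signed expression ratio between two conditions
#'
#' `case/ref` when the case level is at least the reference level, otherwise
#' `-ref/case`, so `|x| >= 1` always and negative values denote
#' down-regulation. Vectorized.
#'
#' @param ave_ref,ave_case Positive average expression levels.
#' @return Signed ratio with `|x| >= 1`.
#' @export
expression_ratio <- function(ave_ref, ave_case) {
  if (any(ave_ref <= 0 | ave_case <= 0, na.rm = TRUE)) {
    abort("AVE values must be > 0 to form an expression ratio.",
          class = "genefabric_degenerate_error")
  }
  ifelse(ave_case >= ave_ref, ave_case / ave_ref, -ave_ref / ave_case)
}

#' Heteroscedastic (Welch) t-test p-value for a gene
#'
#' Two-tailed Welch t-test on the gene-level per-replicate means of the two
#' conditions. Spots of one gene are technical replicates, so the test runs
#' on biological replicates by default; `on = "spots"` pools all spot-level
#' values instead.
#'
#' @param profile_ref,profile_case `gene_profile`s of the same gene in the
#'   two conditions.
#' @param on `"replicates"` (default) or `"spots"`.
#' @return p-value in `[0, 1]`. Both sides constant: 1 when the means are
#'   equal, 0 otherwise (complete separation).
#' @export
welch_p <- function(profile_ref, profile_case, on = c("replicates", "spots")) {
  on <- match.arg(on)
  a <- if (on == "replicates") profile_ref$replicate_values else as.vector(profile_ref$values)
  b <- if (on == "replicates") profile_case$replicate_values else as.vector(profile_case$values)
  if (length(a) < 2 || length(b) < 2) {
    abort("Welch test needs >= 2 values per side.", class = "genefabric_design_error")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  tryCatch(
    t.test(a, b, var.equal = FALSE)$p.value,
    error = function(e) if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
  )
}

#' Variability-calibrated fold-change cutoff (CUT)
#'
#' Replaces the arbitrary uniform fold-change cutoff with a gene- and
#' contrast-specific one derived from the gene's REV in the two conditions:
#' stably expressed, accurately probed genes get a cutoff below 1.5, noisy
#' genes a larger one. The default `rms` pooling,
#' `1 + sqrt((rev_ref^2 + rev_case^2)/2) / 100`, collapses to
#' `1 + REV/100` when the two REVs agree; `sum2` uses
#' `1 + sqrt(2 * (rev_ref^2 + rev_case^2)) / 100`.
#'
#' @param rev_ref,rev_case REVs in percent (>= 0). Vectorized.
#' @param pooling `"rms"` (default) or `"sum2"`.
#' @return Cutoff >= 1.
#' @export
compute_cut <- function(rev_ref, rev_case, pooling = c("rms", "sum2")) {
  pooling <- match.arg(pooling)
  if (any(rev_ref < 0 | rev_case < 0, na.rm = TRUE)) {
    abort("REV must be >= 0.", class = "genefabric_value_error")
  }
  s2 <- rev_ref^2 + rev_case^2
  if (pooling == "rms") 1 + sqrt(s2 / 2) / 100 else 1 + sqrt(2 * s2) / 100
}

#' Significant-regulation call
#'
#' A gene is significantly regulated when the Welch p-value is below `alpha`
#' and the absolute expression ratio strictly exceeds its cutoff.
#'
#' @param x Signed expression ratio.
#' @param p Welch p-value.
#' @param cut Cutoff from [compute_cut()].
#' @param alpha Significance level (default 0.05).
#' @return Logical vector.
#' @export
call_regulation <- function(x, p, cut, alpha = 0.05) {
  !is.na(x) & !is.na(p) & p < alpha & abs(x) > cut
}

#' Weighted individual regulation (WIR)
#'
#' `ave_ref * (|x| - 1) * sign(x) * (1 - p)`: the reference expression level
#' times the net fold departure from it, signed by the regulation direction
#' and weighted by the confidence of the regulation. Zero when `|x| = 1` or
#' `p = 1`.
#'
#' @param ave_ref Reference-condition AVE (> 0).
#' @param x Signed expression ratio, `|x| >= 1`.
#' @param p p-value in `[0, 1]`.
#' @return Signed WIR in median-normalized expression units.
#' @export
compute_wir <- function(ave_ref, x, p) {
  ave_ref * (abs(x) - 1) * sign(x) * (1 - p)
}

#' Contrast-level regulation table
#'
#' Runs the full significant-regulation analysis for one reference -> case
#' contrast: per-gene expression ratio, Welch p-value, REV-derived cutoff,
#' significance call and WIR.
#'
#' @param table A [probe_table()] (normalize first; see
#'   [normalize_to_median()]).
#' @param reference,case Condition labels.
#' @param alpha Significance level (default 0.05).
#' @param cut_pooling See [compute_cut()].
#' @param rev_variant See [chi2_midinterval_factor()].
#' @param welch_on See [welch_p()].
#' @return A tibble of class `regulation_table`: `gene`, `contrast`,
#'   `ave_ref`, `ave_case`, `x`, `p`, `cut`, `significant`, `direction`
#'   (`"up"`, `"down"`, `"none"`), `wir`.
#' @export
regulation_table <- function(table, reference, case, alpha = 0.05,
                             cut_pooling = c("rms", "sum2"),
                             rev_variant = c("sqrt", "linear"),
                             welch_on = c("replicates", "spots")) {
  cut_pooling <- match.arg(cut_pooling)
  rev_variant <- match.arg(rev_variant)
  welch_on <- match.arg(welch_on)
  prof_ref <- gene_profiles(table, reference)
  prof_case <- gene_profiles(table, case)
  genes <- intersect(names(prof_ref), names(prof_case))
  fab <- fabric_summary(table, c(reference, case), rev_variant = rev_variant)
  rev_ref <- setNames(fab$rev[fab$condition == reference], fab$gene[fab$condition == reference])
  rev_case <- setNames(fab$rev[fab$condition == case], fab$gene[fab$condition == case])
  rows <- purrr::map_dfr(genes, function(g) {
    pr <- prof_ref[[g]]; pc <- prof_case[[g]]
    a_ref <- compute_ave(pr); a_case <- compute_ave(pc)
    if (a_ref <= 0 || a_case <= 0) {
      return(tibble(gene = g, ave_ref = a_ref, ave_case = a_case,
                    x = NA_real_, p = NA_real_, cut = NA_real_))
    }
    tibble(
      gene = g, ave_ref = a_ref, ave_case = a_case,
      x = expression_ratio(a_ref, a_case),
      p = welch_p(pr, pc, on = welch_on),
      cut = compute_cut(rev_ref[[g]], rev_case[[g]], pooling = cut_pooling)
    )
  })
  out <- rows |>
    mutate(
      contrast = paste0(reference, "->", case), .after = "gene"
    ) |>
    mutate(
      significant = call_regulation(.data$x, .data$p, .data$cut, alpha),
      direction = dplyr::case_when(
        !.data$significant | is.na(.data$x) ~ "none",
        .data$x > 0 ~ "up",
        TRUE ~ "down"
      ),
      wir = ifelse(is.na(.data$x), NA_real_,
                   compute_wir(.data$ave_ref, .data$x, .data$p))
    )
  class(out) <- c("regulation_table", class(out))
  out
}

#' Percentage of significantly regulated genes (PSR) in a gene set
#'
#' @param regulation A [regulation_table()] result.
#' @param members Set member symbols (case-insensitive), or a one-row slice
#'   of a [read_gene_sets()] tibble.
#' @param set_name Label for the output.
#' @return One-row tibble: `set`, `contrast`, `n_members`, `n_quantified`,
#'   `n_significant`, `n_up`, `n_down`, `psr` (percent).
#' @export
psr <- function(regulation, members, set_name = NULL) {
  if (is.data.frame(members)) {
    set_name <- set_name %||% members$set[[1]]
    members <- members$genes[[1]]
  }
  set_name <- set_name %||% "gene_set"
  present <- match_members(members, regulation$gene)
  if (length(present) == 0) {
    abort(paste0("Gene set ", set_name, ": no member has a regulation record."),
          class = "genefabric_empty_set_error")
  }
  sub <- dplyr::filter(regulation, .data$gene %in% present)
  tibble(
    set = set_name,
    contrast = sub$contrast[1],
    n_members = length(members),
    n_quantified = nrow(sub),
    n_significant = sum(sub$significant, na.rm = TRUE),
    n_up = sum(sub$direction == "up"),
    n_down = sum(sub$direction == "down"),
    psr = 100 * sum(sub$significant, na.rm = TRUE) / nrow(sub)
  )
}
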