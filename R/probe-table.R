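#' Construct a probe table
#'
#' A probe table holds spot-level expression intensities for a replicated
#' multi-condition design in which a gene may be probed redundantly by
#' several spots (technical replicates within each biological replicate).
#' It is the input container for every downstream stage: normalization,
#' fabric metrics (AVE/REV/COR), regulation calling and trajectory analysis.
#'
#' @param data A data frame with one row per spot: a `spot_id` column
#'   (unique identifiers), a `gene` column (gene symbol of the spot; several
#'   spots may share a gene) and one numeric column per sample. All
#'   intensities must be non-negative.
#' @param layout A data frame with columns `sample` and `condition` assigning
#'   every sample column of `data` to a condition. Conditions keep the order
#'   of first appearance; every condition needs at least two samples
#'   (biological replicates).
#' @param normalized Logical; whether intensities are already median
#'   normalized (see [normalize_to_median()]).
#' @param n_dropped Number of input rows dropped during parsing (bookkeeping
#'   filled in by [read_expression_table()]).
#'
#' @return An object of class `probe_table`: a list with elements `data`
#'   (tibble), `layout` (tibble), `conditions` (character), `normalized`
#'   and `n_dropped`.
#'
#' @examples
#' tab <- probe_table(
#'   data.frame(spot_id = c("s1", "s2"), gene = c("A", "B"),
#'              CO_1 = c(1, 2), CO_2 = c(2, 3),
#'              HM_1 = c(1, 5), HM_2 = c(2, 6)),
#'   layout = data.frame(sample = c("CO_1", "CO_2", "HM_1", "HM_2"),
#'                       condition = c("CO", "CO", "HM", "HM"))
#' )
#' tab
#' @export
probe_table <- function(data, layout, normalized = FALSE, n_dropped = 0L) {
  data <- as_tibble(data)
  layout <- as_tibble(layout)
  if (!all(c("spot_id", "gene") %in% names(data))) {
    abort("`data` must contain `spot_id` and `gene` columns.", class = "genefabric_format_error")
  }
  if (!all(c("sample", "condition") %in% names(layout))) {
    abort("`layout` must contain `sample` and `condition` columns.", class = "genefabric_format_error")
  }
  missing_cols <- setdiff(layout$sample, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Sample column(s) absent from `data`: ",
                 paste(missing_cols, collapse = ", ")),
          class = "genefabric_format_error")
  }
  if (anyDuplicated(data$spot_id)) {
    abort("`spot_id` values must be unique (one gene per spot).",
          class = "genefabric_format_error")
  }
  reps <- table(layout$condition)
  if (any(reps < 2)) {
    abort(paste0("Every condition needs >= 2 replicate columns; offending: ",
                 paste(names(reps)[reps < 2], collapse = ", ")),
          class = "genefabric_design_error")
  }
  vals <- as.matrix(data[layout$sample])
  if (!is.numeric(vals)) {
    abort("Sample columns must be numeric.", class = "genefabric_format_error")
  }
  if (any(vals < 0, na.rm = TRUE)) {
    abort("Negative intensities are not allowed.", class = "genefabric_value_error")
  }
  structure(
    list(
      data = data[c("spot_id", "gene", layout$sample)],
      layout = layout,
      conditions = unique(layout$condition),
      normalized = isTRUE(normalized),
      n_dropped = as.integer(n_dropped)
    ),
    class = "probe_table"
  )
}

#' @export
print.probe_table <- function(x, ...) {
  cat("<probe_table> ", nrow(x$data), " spots / ",
      dplyr::n_distinct(x$data$gene), " genes; conditions: ",
      paste0(x$conditions, " (n=", table(x$layout$condition)[x$conditions], ")",
             collapse = ", "),
      if (x$normalized) "; median-normalized" else "",
      "\n", sep = "")
  if (x$n_dropped > 0) cat("  rows dropped at parse time:", x$n_dropped, "\n")
  invisible(x)
}

#' Replicate (sample) columns of a condition
#' @param table A [probe_table()].
#' @param condition Condition label.
#' @return Character vector of sample column names, in layout order.
#' @export
replicate_columns <- function(table, condition) {
  stopifnot(inherits(table, "probe_table"))
  if (!condition %in% table$conditions) {
    abort(paste0("Unknown condition: ", condition), class = "genefabric_design_error")
  }
  table$layout$sample[table$layout$condition == condition]
}

#' Read a tab-separated expression table
#'
#' Parses a TSV whose header row names the sample columns; `layout` assigns
#' each sample column to a condition. Rows with a missing or non-numeric
#' intensity in any assigned sample column are dropped and counted.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param layout Either a data frame with columns `sample` and `condition`,
#'   or a named list `list(CO = c("CO_1", ...), ...)` mapping each condition
#'   to its sample column names.
#' @param gene_col Name of the gene-symbol column in the file (default
#'   `"gene"`).
#' @param spot_col Optional name of a spot-identifier column; when `NULL`,
#'   spot ids are generated from row numbers.
#' @return A [probe_table()]; the number of dropped rows is reported in
#'   `n_dropped` and via a message.
#' @export
read_expression_table <- function(path, layout, gene_col = "gene",
                                  spot_col = NULL) {
  layout <- as_layout(layout)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#", progress = FALSE)
  if (!gene_col %in% names(raw)) {
    abort(paste0("Gene column `", gene_col, "` not found in ", path),
          class = "genefabric_format_error")
  }
  missing_samples <- setdiff(layout$sample, names(raw))
  if (length(missing_samples) > 0) {
    abort(paste0("Sample column(s) missing from file: ",
                 paste(missing_samples, collapse = ", ")),
          class = "genefabric_format_error")
  }
  spot_id <- if (is.null(spot_col)) {
    sprintf("spot_%05d", seq_len(nrow(raw)))
  } else {
    if (!spot_col %in% names(raw)) {
      abort(paste0("Spot column `", spot_col, "` not found."),
            class = "genefabric_format_error")
    }
    raw[[spot_col]]
  }
  vals <- suppressWarnings(
    vapply(raw[layout$sample], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, layout$sample))
  keep <- stats::complete.cases(vals) & !is.na(raw[[gene_col]]) &
    raw[[gene_col]] != ""
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(paste0("read_expression_table: dropped ", n_dropped,
                  " row(s) with missing or non-numeric values."))
  }
  out <- tibble(spot_id = spot_id[keep], gene = raw[[gene_col]][keep])
  out <- bind_cols(out, as_tibble(vals[keep, , drop = FALSE]))
  probe_table(out, layout, n_dropped = n_dropped)
}

as_layout <- function(layout) {
  if (is.data.frame(layout)) return(as_tibble(layout))
  if (is.list(layout) && !is.null(names(layout))) {
    return(tibble(
      sample = unlist(layout, use.names = FALSE),
      condition = rep(names(layout), lengths(layout))
    ))
  }
  abort("`layout` must be a data frame or a named list of sample columns.",
        class = "genefabric_format_error")
}

#' Median-normalize a probe table
#'
#' Within each condition, every intensity is divided by the median of all
#' (spot, replicate) values of that condition, so the per-condition median
#' of the result equals 1. The operation is idempotent and scale invariant.
#'
#' @param table A [probe_table()].
#' @return A normalized [probe_table()].
#' @export
normalize_to_median <- function(table) {
  stopifnot(inherits(table, "probe_table"))
  data <- table$data
  for (cond in table$conditions) {
    cols <- replicate_columns(table, cond)
    m <- median(as.matrix(data[cols]), na.rm = TRUE)
    if (!is.finite(m) || m == 0) {
      abort(paste0("Condition ", cond, " has zero/undefined median; cannot normalize."),
            class = "genefabric_degenerate_error")
    }
    data[cols] <- data[cols] / m
  }
  out <- probe_table(data, table$layout, normalized = TRUE,
                     n_dropped = table$n_dropped)
  out
}

#' Per-gene expression profiles for one condition
#'
#' Collapses a gene's redundant spots into the quantities the fabric metrics
#' are built from: per-spot replicate means and standard deviations (sample
#' SD, n-1 denominator) and the gene-level per-replicate means (average over
#' the gene's spots). Spots with a missing value in the condition are
#' excluded; a gene with no remaining spot is absent from the result.
#'
#' @param table A [probe_table()].
#' @param condition Condition label.
#' @return A named list of `gene_profile` objects (one per gene), each a list
#'   with `gene`, `values` (spots x replicates matrix), `spot_means`,
#'   `spot_sds`, `replicate_values`, `n_spots`, `n_replicates`.
#' @export
gene_profiles <- function(table, condition) {
  cols <- replicate_columns(table, condition)
  vals <- as.matrix(table$data[cols])
  rownames(vals) <- table$data$spot_id
  keep <- stats::complete.cases(vals)
  vals <- vals[keep, , drop = FALSE]
  genes <- table$data$gene[keep]
  split_idx <- split(seq_len(nrow(vals)), genes)
  out <- lapply(names(split_idx), function(g) {
    m <- vals[split_idx[[g]], , drop = FALSE]
    gene_profile(g, condition, m)
  })
  setNames(out, names(split_idx))
}

#' Build a single gene profile from a spot-by-replicate matrix
#'
#' @param gene Gene symbol.
#' @param condition Condition label.
#' @param values Numeric matrix, spots in rows, biological replicates in
#'   columns (a plain vector is taken as one spot).
#' @return A `gene_profile` object; see [gene_profiles()].
#' @export
gene_profile <- function(gene, condition, values) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  n_rep <- ncol(values)
  spot_means <- rowMeans(values)
  spot_sds <- if (n_rep > 1) {
    sqrt(rowSums((values - spot_means)^2) / (n_rep - 1))
  } else {
    rep(NA_real_, nrow(values))
  }
  structure(
    list(
      gene = gene,
      condition = condition,
      values = values,
      spot_means = spot_means,
      spot_sds = spot_sds,
      replicate_values = colMeans(values),
      n_spots = nrow(values),
      n_replicates = n_rep
    ),
    class = "gene_profile"
  )
}

#' @export
print.gene_profile <- function(x, ...) {
  cat("<gene_profile> ", x$gene, " [", x$condition, "]: ",
      x$n_spots, " spot(s) x ", x$n_replicates, " replicates\n", sep = "")
  invisible(x)
}

# gene-level replicate matrix (genes x replicates) for a condition;
# used by COR, Welch tests and the synthetic recovery checks.
gene_replicate_matrix <- function(table, condition) {
  profs <- gene_profiles(table, condition)
  do.call(rbind, lapply(profs, `[[`, "replicate_values")) |>
    (\(m) {rownames(m) <- names(profs); m})()
}
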