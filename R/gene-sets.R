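#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab separated — set name, description,
#' then member gene symbols. Duplicate members within a set are dropped.
#'
#' @param path Path to a GMT file.
#' @return A tibble with one row per set: `set`, `description`, and a
#'   `genes` list-column of unique member symbols.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(set = character(), description = character(),
                  genes = list()))
  }
  parsed <- lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  bad <- vapply(parsed, length, integer(1)) < 3
  if (any(bad)) {
    abort(paste0("GMT line(s) with fewer than 3 fields: ",
                 paste(which(bad), collapse = ", ")),
          class = "genefabric_format_error")
  }
  tibble(
    set = vapply(parsed, `[[`, character(1), 1),
    description = vapply(parsed, `[[`, character(1), 2),
    genes = lapply(parsed, function(p) unique(p[-(1:2)]))
  )
}

#' Write gene sets to a GMT file
#' @param gene_sets A tibble as returned by [read_gene_sets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gene_sets, path) {
  lines <- purrr::pmap_chr(gene_sets, function(set, description, genes, ...) {
    paste(c(set, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

# Case-insensitive match of set members against measured genes; returns the
# measured symbols. Rat symbols mix cases (Pmm1 vs LOC500959), so symbol
# matching is case-insensitive throughout.
match_members <- function(members, universe) {
  hit <- match(toupper(members), toupper(universe))
  unique(universe[hit[!is.na(hit)]])
}
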