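#' Build a coordination network over a gene set
#'
#' Nodes are the set members present in the classified pairs; edges are the
#' pairs classified synergistic, antagonistic or independent (not-significant
#' pairs carry no edge, like the blank squares of an adjacency display).
#'
#' @param pairs A [cor_pairs()] tibble.
#' @param members Node gene symbols (case-insensitive), or a one-row slice
#'   of a [read_gene_sets()] tibble; default: all genes in `pairs`.
#' @param condition Condition label (default taken from `pairs`).
#' @return An object of class `coordination_network`: list with `condition`,
#'   `nodes`, `edges` (classified pairs minus not-significant) and `pairs`
#'   (all classified pairs among the nodes, for remodeling reports).
#' @export
build_network <- function(pairs, members = NULL, condition = NULL) {
  universe <- unique(c(pairs$gene_a, pairs$gene_b))
  nodes <- if (is.null(members)) universe else {
    if (is.data.frame(members)) members <- members$genes[[1]]
    present <- match_members(members, universe)
    dropped <- setdiff(toupper(members), toupper(present))
    if (length(dropped) > 0) {
      warn(paste0("Dropping unmeasured set member(s): ",
                  paste(dropped, collapse = ", ")))
    }
    present
  }
  if (length(nodes) < 2) {
    abort("A coordination network needs >= 2 measured nodes.",
          class = "genefabric_empty_set_error")
  }
  sub <- dplyr::filter(pairs, .data$gene_a %in% nodes & .data$gene_b %in% nodes)
  structure(
    list(
      condition = condition %||% (sub$condition[1] %||% NA_character_),
      nodes = nodes,
      edges = dplyr::filter(sub, .data$klass != "not_significant"),
      pairs = sub
    ),
    class = "coordination_network"
  )
}

#' @export
print.coordination_network <- function(x, ...) {
  k <- table(factor(x$edges$klass,
                    levels = c("synergistic", "antagonistic", "independent")))
  cat("<coordination_network> ", x$condition, ": ", length(x$nodes),
      " nodes, ", nrow(x$edges), " edges (",
      paste0(names(k), "=", k, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @describeIn build_network Edge list as a tibble.
#' @param x A `coordination_network`.
#' @param ... Unused.
#' @method tidy coordination_network
#' @export
tidy.coordination_network <- function(x, ...) x$edges

#' @describeIn build_network One-row summary (node/edge/class counts).
#' @method glance coordination_network
#' @export
glance.coordination_network <- function(x, ...) {
  tibble(
    condition = x$condition,
    n_nodes = length(x$nodes),
    n_pairs = choose(length(x$nodes), 2),
    n_synergistic = sum(x$edges$klass == "synergistic"),
    n_antagonistic = sum(x$edges$klass == "antagonistic"),
    n_independent = sum(x$edges$klass == "independent")
  )
}

#' Partner counts of network nodes
#'
#' For each node, the number of synergistic, antagonistic and independent
#' partners and the percentage of possible partners (`n_nodes - 1`) each
#' class represents.
#'
#' @param network A [build_network()] result.
#' @param gene Optional single node; default all nodes.
#' @return Tibble: `gene`, `n_possible`, `synergistic`, `antagonistic`,
#'   `independent` counts and `syn_pct`, `ant_pct`, `ind_pct`.
#' @export
partner_counts <- function(network, gene = NULL) {
  stopifnot(inherits(network, "coordination_network"))
  nodes <- if (is.null(gene)) network$nodes else {
    if (!toupper(gene) %in% toupper(network$nodes)) {
      abort(paste0("Gene ", gene, " is not a network node."),
            class = "genefabric_lookup_error")
    }
    match_members(gene, network$nodes)
  }
  e <- network$edges
  long <- bind_rows(
    select(e, gene = "gene_a", klass = "klass"),
    select(e, gene = "gene_b", klass = "klass")
  )
  n_possible <- length(network$nodes) - 1
  purrr::map_dfr(nodes, function(g) {
    k <- table(factor(long$klass[long$gene == g],
                      levels = c("synergistic", "antagonistic", "independent")))
    tibble(
      gene = g, n_possible = n_possible,
      synergistic = as.integer(k[["synergistic"]]),
      antagonistic = as.integer(k[["antagonistic"]]),
      independent = as.integer(k[["independent"]]),
      syn_pct = 100 * k[["synergistic"]] / n_possible,
      ant_pct = 100 * k[["antagonistic"]] / n_possible,
      ind_pct = 100 * k[["independent"]] / n_possible
    )
  })
}

#' Network remodeling between two conditions
#'
#' Quantifies how a gene set's coordination network is rewired from a
#' reference to a case condition: per-condition class counts and
#' percentages over all `C(n, 2)` node pairs, and the full 4x4 transition
#' table of pair classes (including not-significant).
#'
#' @param network_ref,network_case [build_network()] results over the same
#'   node set.
#' @return An object of class `remodeling_report`: list with `conditions`,
#'   `n_pairs`, `counts` (tibble per condition x class) and `transitions`
#'   (4x4 matrix, reference classes in rows).
#' @export
remodeling_report <- function(network_ref, network_case) {
  if (!setequal(network_ref$nodes, network_case$nodes)) {
    abort("The two networks must share the same node set.",
          class = "genefabric_design_error")
  }
  lv <- c("synergistic", "antagonistic", "independent", "not_significant")
  pair_classes <- function(net) {
    nodes <- sort(net$nodes)
    cmb <- t(combn(nodes, 2))
    key <- paste(pmin(cmb[, 1], cmb[, 2]), pmax(cmb[, 1], cmb[, 2]))
    ek <- paste(pmin(net$pairs$gene_a, net$pairs$gene_b),
                pmax(net$pairs$gene_a, net$pairs$gene_b))
    kl <- setNames(net$pairs$klass, ek)[key]
    kl[is.na(kl)] <- "not_significant"   # pair absent = undefined/unclassified
    factor(kl, levels = lv)
  }
  ref_k <- pair_classes(network_ref)
  case_k <- pair_classes(network_case)
  n_pairs <- length(ref_k)
  counts <- bind_rows(
    tibble(condition = network_ref$condition, klass = lv,
           n = as.integer(table(ref_k)[lv])),
    tibble(condition = network_case$condition, klass = lv,
           n = as.integer(table(case_k)[lv]))
  ) |> mutate(pct = 100 * .data$n / n_pairs)
  structure(
    list(
      conditions = c(network_ref$condition, network_case$condition),
      n_pairs = n_pairs,
      counts = counts,
      transitions = table(reference = ref_k, case = case_k) |>
        unclass() |> matrix(4, 4, dimnames = list(reference = lv, case = lv))
    ),
    class = "remodeling_report"
  )
}

#' @export
print.remodeling_report <- function(x, ...) {
  cat("<remodeling_report> ", x$conditions[1], " -> ", x$conditions[2],
      " over ", x$n_pairs, " gene pairs\n", sep = "")
  print(x$transitions)
  invisible(x)
}

#' @describeIn remodeling_report Transition table in long form.
#' @param x A `remodeling_report`.
#' @param ... Unused.
#' @method tidy remodeling_report
#' @export
tidy.remodeling_report <- function(x, ...) {
  as_tibble(as.data.frame.table(x$transitions, responseName = "n")) |>
    mutate(across(c("reference", "case"), as.character),
           n = as.integer(.data$n))
}

#' @describeIn remodeling_report One-row remodeling summary.
#' @method glance remodeling_report
#' @export
glance.remodeling_report <- function(x, ...) {
  w <- function(cond, kl) {
    x$counts$n[x$counts$condition == cond & x$counts$klass == kl]
  }
  tibble(
    reference = x$conditions[1], case = x$conditions[2], n_pairs = x$n_pairs,
    syn_ref = w(x$conditions[1], "synergistic"),
    syn_case = w(x$conditions[2], "synergistic"),
    ant_ref = w(x$conditions[1], "antagonistic"),
    ant_case = w(x$conditions[2], "antagonistic"),
    preserved = sum(diag(x$transitions)),
    rewired = x$n_pairs - sum(diag(x$transitions))
  )
}
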