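#' Build a taxonomic tree from a ranked lineage table
#'
#' Each row of `taxonomy` gives the full lineage of one leaf taxon, with rank
#' columns ordered coarse to fine (e.g. Kingdom ... Genus). Internal nodes
#' are keyed by their full lineage prefix, so identical labels under
#' different parents stay distinct, and blank/missing labels become explicit
#' per-parent placeholder nodes rather than merging across parents.
#'
#' @param taxonomy Data frame of lineages, one row per leaf taxon.
#' @param taxa Character vector of leaf taxon identifiers in count-table
#'   order. Defaults to `taxonomy`'s row names (or its `taxon` column).
#' @param rank_columns Names of the lineage columns, coarse to fine.
#'   Defaults to all columns except an identifier column named `taxon`.
#' @return A `taxonomic_tree`: leaves in count-table order plus a tibble of
#'   internal nodes with their member leaf index sets (a laminar family).
#' @export
taxonomy_tree <- function(taxonomy, taxa = NULL, rank_columns = NULL) {
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  if ("taxon" %in% names(taxonomy)) {
    ids <- as.character(taxonomy[["taxon"]])
  } else if (!is.null(rownames(taxonomy)) &&
             !identical(rownames(taxonomy), as.character(seq_len(nrow(taxonomy))))) {
    ids <- rownames(taxonomy)
  } else {
    abort("taxonomy needs a 'taxon' column or row names identifying leaves")
  }
  if (anyDuplicated(ids)) abort("duplicate leaf identifiers in taxonomy")
  if (is.null(rank_columns)) rank_columns <- setdiff(names(taxonomy), "taxon")
  if (is.null(taxa)) taxa <- ids
  missing <- setdiff(taxa, ids)
  if (length(missing) > 0) {
    abort(sprintf("taxa absent from taxonomy: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  lin <- as.matrix(taxonomy[match(taxa, ids), rank_columns, drop = FALSE])
  lin[is.na(lin) | lin == ""] <- "<unclassified>"
  p <- length(taxa)

  nodes <- list(list(id = "(root)", rank = "root", label = "(root)",
                     members = seq_len(p)))
  for (r in seq_along(rank_columns)) {
    keys <- apply(lin[, seq_len(r), drop = FALSE], 1, paste, collapse = ";")
    for (k in unique(keys)) {
      nodes[[length(nodes) + 1]] <- list(
        id = k, rank = rank_columns[r],
        label = lin[match(k, keys), r],
        members = which(keys == k))
    }
  }
  new_taxonomic_tree(taxa, nodes)
}

#' Read a taxonomy table from file
#'
#' @inheritParams taxonomy_tree
#' @param path TSV/CSV file; first column (or a `taxon` column) identifies
#'   the leaf, remaining columns are ranks ordered coarse to fine.
#' @return A `taxonomic_tree`.
#' @export
read_taxonomy <- function(path, taxa = NULL, rank_columns = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!("taxon" %in% names(df))) names(df)[1] <- "taxon"
  taxonomy_tree(df, taxa = taxa, rank_columns = rank_columns)
}

#' Read a Newick tree as a taxonomic tree
#'
#' Internal clades of the Newick topology become internal nodes; branch
#' lengths are ignored. Leaf labels must match the count-table taxa.
#'
#' @param path Path to a Newick file, or a Newick string.
#' @param taxa Optional leaf order (count-table order); defaults to the tip
#'   order in the file.
#' @return A `taxonomic_tree`.
#' @export
read_newick <- function(path, taxa = NULL) {
  phy <- if (grepl("[(;]", path)) ape::read.tree(text = path)
         else ape::read.tree(path)
  if (is.null(phy)) abort("could not parse Newick input")
  if (is.null(taxa)) taxa <- phy$tip.label
  if (!setequal(taxa, phy$tip.label) || length(taxa) != length(phy$tip.label)) {
    abort("Newick tip labels do not match the supplied taxa")
  }
  clades <- ape::prop.part(phy)
  nodes <- lapply(seq_along(clades), function(i) {
    members <- sort(match(phy$tip.label[clades[[i]]], taxa))
    list(id = paste0("clade", i), rank = "clade",
         label = attr(clades, "labels")[i] %||% paste0("clade", i),
         members = members)
  })
  new_taxonomic_tree(taxa, nodes)
}

new_taxonomic_tree <- function(taxa, nodes) {
  node_tbl <- tibble::tibble(
    id = vapply(nodes, `[[`, character(1), "id"),
    rank = vapply(nodes, `[[`, character(1), "rank"),
    label = vapply(nodes, `[[`, character(1), "label"),
    members = lapply(nodes, function(n) as.integer(sort(n$members))),
    size = vapply(nodes, function(n) length(n$members), integer(1)))
  tree <- structure(list(leaves = taxa, nodes = node_tbl),
                    class = "taxonomic_tree")
  check_laminar(node_tbl$members, length(taxa))
  tree
}

# Leaf sets of a tree must form a laminar family: any two nested or disjoint.
check_laminar <- function(sets, p) {
  for (a in seq_along(sets)) {
    for (b in seq_len(a - 1L)) {
      ov <- length(intersect(sets[[a]], sets[[b]]))
      if (ov > 0 && ov < min(length(sets[[a]]), length(sets[[b]]))) {
        abort("leaf sets are not laminar (overlapping, non-nested groups)")
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.taxonomic_tree <- function(x, ...) {
  cat(sprintf("taxonomic tree: %d leaves, %d internal nodes\n",
              length(x$leaves), nrow(x$nodes)))
  invisible(x)
}
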