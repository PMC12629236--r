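#' Convert a taxonomic tree into penalty group structure
#'
#' Each retained internal node `v` contributes a group over its leaf set
#' `L_v`, with weight `|L_v|` (the group-norm divisor). Internal nodes with
#' identical leaf sets — unary taxonomic chains such as a family with a
#' single genus — are collapsed to one group attributed to the deepest rank,
#' since duplicated groups would silently multiply the penalty weight.
#'
#' @param tree A `taxonomic_tree`.
#' @param include_root Keep the root group spanning all leaves (default
#'   `TRUE`); it acts as a global shrinkage term.
#' @param group_weight Norm divisor convention: `"size"` (the method's
#'   definition, `|L_v|`) or `"sqrt_size"` (the common group-lasso
#'   convention, `sqrt(|L_v|)`).
#' @return A `tcvs_groups` object: member index sets, weights, and the leaf
#'   count `p`.
#' @export
build_groups <- function(tree, include_root = TRUE,
                         group_weight = c("size", "sqrt_size")) {
  group_weight <- match.arg(group_weight)
  stopifnot(inherits(tree, "taxonomic_tree"))
  p <- length(tree$leaves)
  nodes <- tree$nodes
  if (!include_root) nodes <- nodes[nodes$size < p, , drop = FALSE]
  if (nrow(nodes) == 0) {
    abort(paste("no internal groups remain; the penalty degenerates to a",
                "plain lasso - use the constrained-lasso variant instead"))
  }
  # collapse duplicate leaf sets, keeping the deepest (last listed) rank
  keys <- vapply(nodes$members, paste, character(1), collapse = ",")
  keep <- !duplicated(keys, fromLast = TRUE)
  nodes <- nodes[keep, , drop = FALSE]
  ord <- order(nodes$size)
  nodes <- nodes[ord, , drop = FALSE]
  structure(list(p = p,
                 ids = nodes$id,
                 ranks = nodes$rank,
                 members = nodes$members,
                 weights = if (group_weight == "size") as.numeric(nodes$size)
                           else sqrt(as.numeric(nodes$size)),
                 weight_type = group_weight,
                 augmented = FALSE),
            class = "tcvs_groups")
}

#' Augment groups for the knockoff design
#'
#' Duplicates each membership vector over the knockoff coordinates: group
#' `v` over leaves `L_v` becomes a group over `L_v` and `L_v + p`, with
#' weight `2|L_v|`. The number of groups is unchanged; each group norm then
#' couples original and knockoff coefficients of the same subtree.
#'
#' @param gs A `tcvs_groups` object (not yet augmented).
#' @return An augmented `tcvs_groups` over `2p` coordinates.
#' @export
augment_groups <- function(gs) {
  stopifnot(inherits(gs, "tcvs_groups"))
  if (gs$augmented) abort("groups are already augmented")
  p <- gs$p
  gs$members <- lapply(gs$members, function(m) c(m, m + p))
  gs$weights <- if (identical(gs$weight_type, "sqrt_size")) {
    sqrt(2) * gs$weights   # ||M_v||_1 doubles, so sqrt(|M_v|) gains sqrt(2)
  } else {
    2 * gs$weights
  }
  gs$augmented <- TRUE
  gs
}

#' Tree-guided group penalty value
#'
#' Computes `sum_v ||beta[g_v]||_2 / w_v`, the group part of the tree-guided
#' penalty (weights are group sizes, which offsets unbalanced topologies).
#'
#' @param beta Coefficient vector whose length matches the group dimension
#'   (`p`, or `2p` for augmented groups).
#' @param gs A `tcvs_groups` object.
#' @return The penalty value (a scalar).
#' @export
group_penalty_value <- function(beta, gs) {
  stopifnot(inherits(gs, "tcvs_groups"))
  d <- gs$p * (1L + gs$augmented)
  if (length(beta) != d) {
    abort(sprintf("beta has length %d but groups expect %d", length(beta), d))
  }
  sum(vapply(seq_along(gs$members), function(i) {
    sqrt(sum(beta[gs$members[[i]]]^2)) / gs$weights[i]
  }, numeric(1)))
}

#' @export
print.tcvs_groups <- function(x, ...) {
  cat(sprintf("%s group structure: %d groups over %d coordinates\n",
              if (x$augmented) "augmented" else "tree", length(x$members),
              x$p * (1L + x$augmented)))
  invisible(x)
}

#' Tidy a group structure
#'
#' @param x A `tcvs_groups` object.
#' @param ... Unused.
#' @return A tibble with one row per group: id, rank, weight and member
#'   indices (list column).
#' @method tidy tcvs_groups
#' @export
tidy.tcvs_groups <- function(x, ...) {
  tibble::tibble(id = x$ids, rank = x$ranks, weight = x$weights,
                 members = x$members)
}

#' Serialize a group structure to JSON
#'
#' @param gs A `tcvs_groups` object.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @export
groups_to_json <- function(gs, path = NULL) {
  obj <- lapply(seq_along(gs$members), function(i) {
    list(id = gs$ids[i], rank = gs$ranks[i], weight = gs$weights[i],
         members = gs$members[[i]])
  })
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
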