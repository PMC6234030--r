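## Class-level aggregation of the contact matrix, synaptic flow percentages,
## ratio-based cell classification, and network file export.

## Resolve per-body labels at the requested level for a contact matrix whose
## dimnames are body ids. Bodies absent from the cell table are orphans;
## bodies present but unlabelled are an error.
body_labels <- function(body_ids, cells, level = c("major", "subtype")) {
  level <- match.arg(level)
  lab <- if (level == "major") {
    major_class(class_of_body(body_ids, cells))
  } else {
    class_of_body(body_ids, cells, level = "subtype")
  }
  bad <- is.na(lab) | !nzchar(lab)
  if (any(bad)) {
    stop("unlabelled bodies at level '", level, "': ",
         paste(body_ids[bad], collapse = ", "))
  }
  lab
}

#' Aggregate a contact matrix by cell class
#'
#' Sums the cell-by-cell matrix over class members at the requested level
#' (`"major"`: ORN/PN/LN/other/orphan; `"subtype"`: the controlled subtype
#' vocabulary, with `unknown` and `orphan` forming their own nodes) and
#' expresses every class-pair flow as a percentage of all contacts in the
#' matrix. Those percentages sum to 100 over all class pairs, so e.g. the
#' share of contacts flowing ORN -> PN is directly comparable with the
#' published flow diagrams.
#'
#' @param mat Contact matrix whose dimnames are body ids.
#' @param cells Cell table resolving body ids to classes.
#' @param level `"major"` (default) or `"subtype"`.
#' @return List with `class_matrix` (square integer matrix over class
#'   labels, diagonal = within-class/recurrent contacts) and `flows`
#'   (`data.frame` of `pre_class`, `post_class`, `contacts`,
#'   `percent_of_total`, nonzero flows only, decreasing).
#' @export
aggregate_by_class <- function(mat, cells, level = c("major", "subtype")) {
  level <- match.arg(level)
  ids <- suppressWarnings(as.integer(rownames(mat)))
  if (anyNA(ids)) stop("matrix dimnames must be body ids")
  lab <- body_labels(ids, cells, level)
  levels_order <- unique(lab)
  f <- factor(lab, levels = levels_order)
  ## rowsum over pre classes, then again over post classes
  pre_sum <- rowsum(mat, group = f, reorder = FALSE)
  class_mat <- t(rowsum(t(pre_sum), group = f, reorder = FALSE))
  class_mat <- matrix(as.integer(class_mat), nrow = length(levels_order),
                      dimnames = list(levels_order, levels_order))
  total <- sum(class_mat)
  nz <- which(class_mat > 0, arr.ind = TRUE)
  cnt <- class_mat[nz]
  flows <- data.frame(
    pre_class = rownames(class_mat)[nz[, 1]],
    post_class = colnames(class_mat)[nz[, 2]],
    contacts = cnt,
    percent_of_total = if (total > 0) 100 * cnt / total else rep(NA_real_,
                                                                 length(cnt))
  )
  flows <- flows[order(-flows$contacts, flows$pre_class, flows$post_class), ]
  rownames(flows) <- NULL
  list(class_matrix = class_mat, flows = flows)
}

#' Aggregate pre:post contact ratio per class
#'
#' Ratio of contacts driven to contacts received by all members of each
#' class, computed from the matrix margins (row sums over column sums).
#'
#' @param mat Contact matrix whose dimnames are body ids.
#' @param cells Cell table.
#' @param level `"major"` or the laterality-preserving `"class"` grouping.
#' @return `data.frame` with `group`, `pre_contacts`, `post_contacts`,
#'   `ratio` (`NA` when the class receives no contacts).
#' @export
class_pre_post_ratio <- function(mat, cells, level = c("class", "major")) {
  level <- match.arg(level)
  ids <- suppressWarnings(as.integer(rownames(mat)))
  if (anyNA(ids)) stop("matrix dimnames must be body ids")
  lab <- class_of_body(ids, cells)
  if (level == "major") lab <- major_class(lab)
  pre <- tapply(rowSums(mat), lab, sum)
  post <- tapply(colSums(mat), lab, sum)
  data.frame(
    group = names(pre),
    pre_contacts = as.integer(pre),
    post_contacts = as.integer(post),
    ratio = ifelse(post > 0, pre / post, NA_real_),
    row.names = NULL
  )
}

#' Default classification rules on the pre:post ratio
#'
#' Ordered rule list for [classify_by_ratio()]: ratio at or above 2.5 is an
#' ORN (sensory inputs are strongly presynaptic, class ratios near 4-5),
#' ratio at or below 0.6 is a PN (outputs are predominantly postsynaptic,
#' class ratios 0.06-0.4), anything between is an LN (local interneurons
#' have near-equal pre and post counts). Boundaries are closed on the ORN
#' and PN side, open for LN.
#'
#' @return `data.frame` with columns `class`, `min_ratio`, `max_ratio`;
#'   rules are applied in order, first match wins.
#' @export
default_ratio_rules <- function() {
  data.frame(
    class = c("ORN", "PN", "LN"),
    min_ratio = c(2.5, 0, 0.6),
    max_ratio = c(Inf, 0.6, 2.5),
    stringsAsFactors = FALSE
  )
}

#' Classify cells from their pre:post synapse ratio
#'
#' Assigns a predicted major class to every body from its `pre_post_ratio`
#' using an ordered threshold rule list (first matching rule wins; the ORN
#' and PN rules are closed at their thresholds, the LN band is open). Bodies
#' with an undefined ratio (no postsynaptic contacts) are labelled
#' `unclassifiable`. A `near_boundary` flag marks ratios within 20% of a
#' rule threshold, where assignment is least certain.
#'
#' @param stats Output of [per_cell_stats()].
#' @param rules Rule table as from [default_ratio_rules()].
#' @return `data.frame` with `body_id`, `pre_post_ratio`,
#'   `predicted_class`, `near_boundary`.
#' @export
classify_by_ratio <- function(stats, rules = default_ratio_rules()) {
  ratio <- stats$pre_post_ratio
  pred <- rep("unclassifiable", length(ratio))
  for (k in rev(seq_len(nrow(rules)))) {
    hit <- !is.na(ratio) & ratio >= rules$min_ratio[k] &
      ratio <= rules$max_ratio[k]
    pred[hit] <- rules$class[k]
  }
  ## LN band is open: its bounds belong to the closed ORN/PN rules, which,
  ## applied first, win at the boundary (the loop above runs in reverse so
  ## earlier rules overwrite later ones).
  thresholds <- sort(unique(c(rules$min_ratio, rules$max_ratio)))
  thresholds <- thresholds[is.finite(thresholds) & thresholds > 0]
  near <- rep(FALSE, length(ratio))
  for (th in thresholds) {
    near <- near | (!is.na(ratio) & abs(ratio - th) <= 0.2 * th)
  }
  data.frame(
    body_id = stats$body_id,
    pre_post_ratio = ratio,
    predicted_class = pred,
    near_boundary = near
  )
}

#' Export a contact or class matrix as a network file
#'
#' Nodes are the matrix labels (carrying a `class` attribute and, for
#' class-level matrices, the member cell count when supplied); directed
#' edges carry the contact count as `weight`. Node order follows the matrix,
#' so output is deterministic. Formats: GraphML, Graphviz DOT, or a
#' `pre,post,count` edge-list CSV re-readable by
#' [read_matrix()]`(layout = "edgelist")`.
#'
#' @param mat Square labelled matrix.
#' @param path Output file.
#' @param format `"graphml"`, `"dot"`, or `"edgelist"`.
#' @param classes Optional named vector of node class labels.
#' @param n_cells Optional named vector of member cell counts per node.
#' @return `path`, invisibly.
#' @export
export_network <- function(mat, path, format = c("graphml", "dot", "edgelist"),
                           classes = NULL, n_cells = NULL) {
  format <- match.arg(format)
  if (format == "edgelist") {
    return(write_matrix(mat, path, format = "edgelist"))
  }
  g <- igraph::graph_from_adjacency_matrix(mat, mode = "directed",
                                           weighted = TRUE, diag = TRUE)
  if (!is.null(classes)) {
    igraph::V(g)$class <- unname(classes[igraph::V(g)$name])
  }
  if (!is.null(n_cells)) {
    igraph::V(g)$n_cells <- unname(n_cells[igraph::V(g)$name])
  }
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
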