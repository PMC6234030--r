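## From polyadic synapse annotations to the cell-level contact matrix and
## per-cell synaptic statistics. The counting unit throughout is one directed
## contact = one PSD: a T-bar with k PSDs contributes k contacts, because the
## postsynaptic partners of a polyad are coordinately linked to one release
## site.

#' Expand polyadic synapses into directed contacts
#'
#' Produces exactly one directed contact per PSD: the T-bar's host cell is
#' the presynaptic body, the PSD's host the postsynaptic body. Autapses
#' (pre equals post) are flagged and retained. T-bars without any PSD do not
#' appear (annotation practice removes the small minority of T-bars lacking
#' clear PSDs before counting). PSDs whose parent T-bar is missing from the
#' dataset are an error; bodies absent from the cell table are kept and
#' resolve to the `orphan` class downstream.
#'
#' @param dataset A [glomerulus_dataset()].
#' @return `data.frame` with columns `pre_body`, `post_body`, `tbar_id`,
#'   `psd_id`, `is_autapse`; one row per PSD.
#' @export
expand_contacts <- function(dataset) {
  stopifnot(inherits(dataset, "glomerulus_dataset"))
  psds <- dataset$psds
  tbars <- dataset$tbars
  idx <- match(psds$tbar_id, tbars$tbar_id)
  if (anyNA(idx)) {
    stop("PSD(s) reference missing T-bars: psd_id ",
         paste(utils::head(psds$psd_id[is.na(idx)], 5), collapse = ", "))
  }
  pre <- tbars$pre_body[idx]
  data.frame(
    pre_body = pre,
    post_body = psds$post_body,
    tbar_id = psds$tbar_id,
    psd_id = psds$psd_id,
    is_autapse = pre == psds$post_body
  )
}

#' Per-body contact totals
#'
#' Tallies, for every body appearing in the contact list, the number of
#' contacts it drives (`pre_contacts`, PSDs opposite its T-bars), the number
#' it receives (`post_contacts`, PSDs on its own membrane), and their sum.
#' Totals conserve: the column sums of `pre_contacts` and of `post_contacts`
#' both equal the number of contacts (autapses count once on each side).
#'
#' @param contacts Output of [expand_contacts()].
#' @return `data.frame` with columns `body_id`, `pre_contacts`,
#'   `post_contacts`, `total`, sorted by `body_id`.
#' @export
cell_contact_totals <- function(contacts) {
  bodies <- sort(unique(c(contacts$pre_body, contacts$post_body)))
  pre <- table(factor(contacts$pre_body, levels = bodies))
  post <- table(factor(contacts$post_body, levels = bodies))
  data.frame(
    body_id = bodies,
    pre_contacts = as.integer(pre),
    post_contacts = as.integer(post),
    total = as.integer(pre) + as.integer(post)
  )
}

#' Select the bodies included in the contact matrix
#'
#' The inclusion rule for the connectivity matrix: a body qualifies when it
#' has more than 50 contacts in the glomerulus. Under the default
#' `count_mode = "total"` this is `pre_contacts + post_contacts >= min_total`
#' (51, i.e. strictly more than 50); `count_mode = "either"` instead requires
#' one of the two directions alone to reach `min_total`.
#'
#' @param totals Output of [cell_contact_totals()].
#' @param min_total Inclusion threshold, default 51.
#' @param count_mode `"total"` (default) or `"either"`.
#' @return Integer vector of included `body_id`s, sorted.
#' @export
filter_included_bodies <- function(totals, min_total = 51,
                                   count_mode = c("total", "either")) {
  count_mode <- match.arg(count_mode)
  keep <- if (count_mode == "total") {
    totals$total >= min_total
  } else {
    totals$pre_contacts >= min_total | totals$post_contacts >= min_total
  }
  sort(totals$body_id[keep])
}

## Default row/column ordering of the matrix: outputs (PNs) first, then
## interneurons (LNs), finally inputs (ORNs), then minor classes and orphans;
## within a class, by cell name then body id.
matrix_class_order <- c("PN", "LN", "ORN_ipsi", "ORN_contra", "other", "orphan")

order_bodies <- function(body_ids, cells = NULL) {
  if (is.null(cells)) return(sort(body_ids))
  cls <- class_of_body(body_ids, cells)
  nm <- cells$name[match(body_ids, cells$body_id)]
  nm[is.na(nm)] <- ""
  rank <- match(cls, matrix_class_order)
  rank[is.na(rank)] <- length(matrix_class_order) + 1L
  body_ids[order(rank, nm, body_ids)]
}

#' Build the cell-by-cell contact matrix
#'
#' Entry (i, j) is the number of directed contacts from body i to body j,
#' over the included bodies only; the diagonal holds autapse counts. The sum
#' of all entries equals the number of contacts whose two endpoints are both
#' included. When a cell table is supplied, rows/columns are ordered PN, LN,
#' ORN (then minor classes and orphans) and by name within class — the
#' conventional display order for glomerular matrices; otherwise by body id.
#'
#' @param contacts Output of [expand_contacts()].
#' @param included Integer vector of included body ids (see
#'   [filter_included_bodies()]).
#' @param cells Optional cell table used for ordering.
#' @return Integer matrix with body ids (as character) for dimnames.
#' @export
build_contact_matrix <- function(contacts, included, cells = NULL) {
  if (length(included) == 0) stop("no included bodies")
  bodies <- order_bodies(included, cells)
  keep <- contacts$pre_body %in% bodies & contacts$post_body %in% bodies
  f_pre <- factor(contacts$pre_body[keep], levels = bodies)
  f_post <- factor(contacts$post_body[keep], levels = bodies)
  m <- table(f_pre, f_post)
  out <- matrix(as.integer(m), nrow = length(bodies),
                dimnames = list(as.character(bodies), as.character(bodies)))
  out
}

#' Per-cell synaptic statistics
#'
#' Mirrors the per-cell summary deposited alongside glomerular connectomes:
#' T-bar count, contacts driven and received, mean PSDs per T-bar
#' (`pre_contacts / n_tbars`), pre:post contact ratio, and T-bar density per
#' cubic micrometre of the cell's intraglomerular neurite volume. Ratios
#' with a zero denominator are `NA` (flagged missing), never infinite, so
#' the table serializes cleanly; densities are `NA` when the volume is
#' missing or zero. Only T-bars with at least one PSD are counted.
#'
#' @param dataset A [glomerulus_dataset()].
#' @param contacts Output of [expand_contacts()] on the same dataset
#'   (recomputed when omitted).
#' @return `data.frame` with one row per body appearing in the cell table or
#'   the contact list: `body_id`, `name`, `cell_class`, `subtype`,
#'   `n_tbars`, `pre_contacts`, `post_contacts`, `psds_per_tbar`,
#'   `pre_post_ratio`, `tbar_density`.
#' @export
per_cell_stats <- function(dataset, contacts = NULL) {
  if (is.null(contacts)) contacts <- expand_contacts(dataset)
  cells <- dataset$cells
  bodies <- sort(unique(c(cells$body_id, contacts$pre_body, contacts$post_body)))

  active_tbars <- unique(contacts$tbar_id)
  tb <- dataset$tbars[dataset$tbars$tbar_id %in% active_tbars, ]
  n_tbars <- table(factor(tb$pre_body, levels = bodies))
  pre <- table(factor(contacts$pre_body, levels = bodies))
  post <- table(factor(contacts$post_body, levels = bodies))

  idx <- match(bodies, cells$body_id)
  vol <- cells$volume_um3[idx]
  nt <- as.integer(n_tbars)
  pc <- as.integer(pre)
  qc <- as.integer(post)
  data.frame(
    body_id = bodies,
    name = ifelse(is.na(idx), paste0("orphan_", bodies), cells$name[idx]),
    cell_class = class_of_body(bodies, cells),
    subtype = ifelse(is.na(idx), "unknown", cells$subtype[idx]),
    n_tbars = nt,
    pre_contacts = pc,
    post_contacts = qc,
    psds_per_tbar = ifelse(nt > 0, pc / nt, NA_real_),
    pre_post_ratio = ifelse(qc > 0, pc / qc, NA_real_),
    tbar_density = ifelse(!is.na(vol) & vol > 0, nt / vol, NA_real_)
  )
}

#' Distribution of connection strengths
#'
#' Histogram of contact counts over the nonzero ordered pairs of the matrix
#' (the "connected pairs"; autapse diagonal entries included). Use
#' [strength_tail()] for cumulative queries such as the share of connected
#' pairs with at least three contacts.
#'
#' @param mat Contact matrix (integer, from [build_contact_matrix()] or
#'   [read_matrix()]).
#' @return `data.frame` with columns `strength` and `n_pairs`, ascending in
#'   `strength`; total `n_pairs` equals the number of nonzero entries.
#' @export
strength_distribution <- function(mat) {
  v <- as.vector(mat)
  v <- v[v > 0]
  if (length(v) == 0) {
    return(data.frame(strength = integer(), n_pairs = integer()))
  }
  tab <- table(v)
  data.frame(
    strength = as.integer(names(tab)),
    n_pairs = as.integer(tab)
  )
}

#' Tail of the strength distribution
#'
#' Number of connected ordered pairs with strength at least `k`.
#'
#' @param dist Output of [strength_distribution()].
#' @param k Minimum strength.
#' @return Integer count.
#' @export
strength_tail <- function(dist, k) {
  sum(dist$n_pairs[dist$strength >= k])
}

#' Connectivity selectivity summary of a contact matrix
#'
#' Summarizes how selectively the possible pairings are realized: the number
#' of possible ordered pairs among the n included bodies (n^2, self-pairs
#' counted since autapses occur), how many are actually connected, and the
#' connected pairs at or above the pathway criterion of 3 contacts and above
#' 10 contacts.
#'
#' @param mat Contact matrix.
#' @return List with `n_bodies`, `possible_pairs`, `connected_pairs`,
#'   `pct_connected`, `pairs_ge3`, `pct_ge3_of_connected`, `pairs_gt10`.
#' @export
connectivity_summary <- function(mat) {
  dist <- strength_distribution(mat)
  n <- nrow(mat)
  connected <- sum(dist$n_pairs)
  ge3 <- strength_tail(dist, 3)
  list(
    n_bodies = n,
    possible_pairs = n^2,
    connected_pairs = connected,
    pct_connected = 100 * connected / n^2,
    pairs_ge3 = ge3,
    pct_ge3_of_connected = if (connected > 0) 100 * ge3 / connected else NA_real_,
    pairs_gt10 = strength_tail(dist, 11)
  )
}

#' Volumetric synapse density
#'
#' Presynaptic sites (T-bars carrying at least one PSD) per cubic micrometre
#' of glomerular neuropile.
#'
#' @param dataset A [glomerulus_dataset()].
#' @return Density in synapses per um^3.
#' @export
synapse_density <- function(dataset) {
  stopifnot(inherits(dataset, "glomerulus_dataset"))
  if (dataset$neuropile_volume_um3 <= 0) stop("neuropile volume must be positive")
  active <- unique(dataset$psds$tbar_id)
  n <- sum(dataset$tbars$tbar_id %in% active)
  n / dataset$neuropile_volume_um3
}

#' Class-level mean of a per-cell statistic
#'
#' Mean and standard deviation of one column of [per_cell_stats()] within
#' each cell class (or subtype), `NA` entries dropped.
#'
#' @param stats Output of [per_cell_stats()].
#' @param column Statistic column name, e.g. `"psds_per_tbar"`.
#' @param by `"cell_class"` (default) or `"subtype"`.
#' @return `data.frame` with `group`, `n`, `mean`, `sd`.
#' @export
class_stat_summary <- function(stats, column, by = c("cell_class", "subtype")) {
  by <- match.arg(by)
  groups <- split(stats[[column]], stats[[by]])
  out <- data.frame(
    group = names(groups),
    n = vapply(groups, function(v) sum(!is.na(v)), integer(1)),
    mean = vapply(groups, function(v) mean(v, na.rm = TRUE), numeric(1)),
    sd = vapply(groups, function(v) stats::sd(v, na.rm = TRUE), numeric(1))
  )
  rownames(out) <- NULL
  out
}
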