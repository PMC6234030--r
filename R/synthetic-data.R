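## Synthetic glomerulus generator. Emits cell censuses, polyadic synapses and
## T-bar point clouds with the statistical structure the pipeline assumes --
## class-dependent contact propensities calibrated to published synaptic flow
## shares, a polyad-size law with mean 3.4 PSDs per T-bar, heavy-tailed
## per-pair connection strengths, and spatially clustered T-bar positions --
## together with ground truth for scoring every downstream stage.

## Run expr under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Polyad-size law: mean of 1 + Poisson(lambda) truncated to 1..max_psds
#'
#' The number of postsynaptic densities sharing one T-bar ("polyad size") is
#' modelled as one obligatory partner plus a Poisson count, truncated at the
#' largest observed polyad.
#'
#' @param lambda Poisson rate.
#' @param max_psds Largest admissible polyad size, default 9.
#' @return Expected polyad size (exact, by enumeration).
#' @export
truncated_polyad_mean <- function(lambda, max_psds = 9) {
  k <- 0:(max_psds - 1)
  p <- stats::dpois(k, lambda)
  1 + sum(k * p) / sum(p)
}

#' Solve for the Poisson rate whose truncated polyad mean hits a target
#'
#' @param target_mean Desired mean PSDs per T-bar, default 3.4.
#' @param max_psds Largest admissible polyad size, default 9.
#' @return The calibrated rate.
#' @export
calibrate_polyad_lambda <- function(target_mean = 3.4, max_psds = 9) {
  stats::uniroot(function(l) truncated_polyad_mean(l, max_psds) - target_mean,
                 interval = c(1e-6, 4 * max_psds), tol = 1e-10)$root
}

#' Draw polyad sizes (PSDs per T-bar) from the truncated law
#'
#' @param n Number of draws.
#' @param lambda Poisson rate (see [calibrate_polyad_lambda()]).
#' @param max_psds Largest admissible polyad size, default 9.
#' @return Integer vector in 1..max_psds.
#' @export
draw_polyad_sizes <- function(n, lambda, max_psds = 9) {
  u <- stats::runif(n) * stats::ppois(max_psds - 1, lambda)
  1L + stats::qpois(u, lambda)
}

#' Default class-level flow shares used to calibrate the generator
#'
#' Percent of all contacts carried by each directed major-class pathway in a
#' densely reconstructed glomerulus: ORN output dominates with 59.9% of all
#' contacts (39.5 to PNs, 14.5 to LNs, 5.9 to other ORNs), LNs contribute
#' 27.8% and PNs 12.3%.
#'
#' @return `data.frame` with `pre_class`, `post_class`, `percent`.
#' @export
default_flow_targets <- function() {
  data.frame(
    pre_class = c("ORN", "ORN", "ORN", "LN", "LN", "LN", "PN", "PN", "PN"),
    post_class = c("PN", "LN", "ORN", "PN", "ORN", "LN", "LN", "PN", "ORN"),
    percent = c(39.5, 14.5, 5.9, 10.4, 7.8, 9.6, 6.4, 4.1, 1.8),
    stringsAsFactors = FALSE
  )
}

## Fixed subtype census used to label the default cells.
default_subtype_census <- function() {
  list(
    PN = c(mPN1 = 3, mPN1_external = 1, mlPN1 = 2, mlPN2 = 3, mlPN3 = 2,
           lPN2 = 3, lPN2_comm = 1, lPN4 = 3),
    LN = c(LN1 = 17, LN2L = 24, LN2V = 1, LN3 = 1, LN4 = 1, LN6 = 2,
           LNV = 3, LN_LV = 3, LN_comm = 4)
  )
}

#' Configuration for the synthetic glomerulus generator
#'
#' Defaults emulate a densely reconstructed pheromone glomerulus: a census of
#' 51 ipsilateral and 56 contralateral ORNs, 18 PNs, 56 LNs (plus two minor
#' cells), roughly 11,000 T-bars carrying polyadic synapses whose PSDs per
#' T-bar average `psd_mean` over the range 1..`psd_max`, class-pair contact
#' propensities matching published flow shares, Dirichlet-multinomial
#' (preferential-attachment) partner choice giving heavy-tailed connection
#' strengths, rare PN autapses, a small orphan contact fraction, and
#' spatially clustered T-bar positions.
#'
#' @param census Named counts per class
#'   (`ORN_ipsi`, `ORN_contra`, `PN`, `LN`, `other`).
#' @param total_tbars Expected total T-bar count, default 11144.
#' @param psd_mean Target mean PSDs per T-bar, default 3.4; the underlying
#'   truncated-Poisson rate is solved numerically at configuration time.
#' @param psd_max Maximum PSDs per T-bar, default 9.
#' @param flow_targets Class-pair flow percentages (see
#'   [default_flow_targets()]); must cover every pre class with nonzero
#'   T-bars.
#' @param orn_ipsi_output_share Share of ORN output contributed by
#'   ipsilateral ORNs, default 0.7.
#' @param receptivity Named within-class per-cell weights controlling how
#'   contacts distribute inside a target class; the default triples
#'   ipsilateral ORN receptivity so per-cell pre:post ratios land in the
#'   observed clusters.
#' @param tail_alpha Dirichlet concentration per unit receptivity; smaller
#'   values concentrate a cell's output on fewer partners (heavier tail).
#'   The default 0.15 reproduces the observed connectance (roughly 23% of
#'   possible ordered pairs connected) and tail share (roughly 37% of
#'   connected pairs with 3+ contacts) at the default census.
#' @param tbar_nb_size Negative-binomial size (dispersion) of per-cell
#'   T-bar counts, default 40 — tight enough that the per-class ratio
#'   clusters stay separated, as they are in measured per-cell statistics.
#' @param autapse_rate Probability that a PN PSD targets its own cell,
#'   default 0.01.
#' @param orphan_rate Fraction of PSDs rewired to orphan fragments, default
#'   0.03; `n_orphans` fragments share them.
#' @param n_orphans Number of orphan bodies, default 6.
#' @param neuropile_volume_um3 Glomerular neuropile volume, default 4858.
#' @param centres_um K x 3 matrix of glomerulus centres (um) for point
#'   clouds; the first row centres the dataset's own T-bar cloud.
#' @param sigma_um Per-glomerulus Gaussian spread (um), default 3 for point
#'   clouds; the dataset's T-bar cloud uses `tbar_sigma_um` (default 5).
#' @param tbar_sigma_um Spread of the dataset's T-bar positions, default 5.
#' @param cloud_n Points in [generate_point_cloud()], default 50000.
#' @param seed Integer seed; identical config and seed reproduce the dataset
#'   exactly.
#' @return Object of class `synth_config` (a validated list, with the solved
#'   `psd_lambda` attached).
#' @export
synth_config <- function(census = c(ORN_ipsi = 51, ORN_contra = 56,
                                    PN = 18, LN = 56, other = 2),
                         total_tbars = 11144,
                         psd_mean = 3.4,
                         psd_max = 9,
                         flow_targets = default_flow_targets(),
                         orn_ipsi_output_share = 0.7,
                         receptivity = c(ORN_ipsi = 3, ORN_contra = 1,
                                         PN = 1, LN = 1, other = 0),
                         tail_alpha = 0.15,
                         tbar_nb_size = 40,
                         autapse_rate = 0.01,
                         orphan_rate = 0.03,
                         n_orphans = 6,
                         neuropile_volume_um3 = 4858,
                         centres_um = rbind(c(25, 25, 25),
                                            c(50, 30, 25),
                                            c(30, 52, 30)),
                         sigma_um = 3,
                         tbar_sigma_um = 5,
                         cloud_n = 50000,
                         seed = 1) {
  stopifnot(all(census >= 0), total_tbars > 0, psd_max >= 1,
            psd_mean > 1, psd_mean < psd_max + 1,
            tail_alpha > 0, tbar_nb_size > 0,
            autapse_rate >= 0, autapse_rate < 1,
            orphan_rate >= 0, orphan_rate < 1,
            neuropile_volume_um3 > 0, sigma_um > 0, tbar_sigma_um > 0)
  if (is.null(dim(centres_um))) centres_um <- matrix(centres_um, nrow = 1)
  ## propensity rows: P(post major class | pre major class)
  pre_tot <- tapply(flow_targets$percent, flow_targets$pre_class, sum)
  if (any(pre_tot <= 0)) stop("infeasible propensity: all-zero pre-class row")
  cfg <- list(
    census = census, total_tbars = total_tbars, psd_mean = psd_mean,
    psd_max = psd_max, flow_targets = flow_targets,
    orn_ipsi_output_share = orn_ipsi_output_share,
    receptivity = receptivity, tail_alpha = tail_alpha,
    tbar_nb_size = tbar_nb_size, autapse_rate = autapse_rate,
    orphan_rate = orphan_rate, n_orphans = n_orphans,
    neuropile_volume_um3 = neuropile_volume_um3,
    centres_um = centres_um, sigma_um = sigma_um,
    tbar_sigma_um = tbar_sigma_um, cloud_n = cloud_n, seed = seed,
    psd_lambda = calibrate_polyad_lambda(psd_mean, psd_max)
  )
  class(cfg) <- "synth_config"
  cfg
}

## Build the default cell table for a config (deterministic, no RNG).
synth_cells <- function(config) {
  census <- config$census
  st <- default_subtype_census()
  rows <- list()
  add_class <- function(cls, n, subtypes = NULL) {
    if (n == 0) return()
    sub <- if (is.null(subtypes)) rep("unknown", n) else {
      s <- rep(names(subtypes), subtypes)
      if (length(s) >= n) s[seq_len(n)] else c(s, rep("unknown", n - length(s)))
    }
    rows[[length(rows) + 1]] <<- data.frame(
      cell_class = cls, subtype = sub,
      stringsAsFactors = FALSE
    )
  }
  add_class("ORN_ipsi", census[["ORN_ipsi"]])
  add_class("ORN_contra", census[["ORN_contra"]])
  add_class("PN", census[["PN"]], st$PN)
  add_class("LN", census[["LN"]], st$LN)
  if ("other" %in% names(census) && census[["other"]] > 0) {
    n_other <- census[["other"]]
    oth <- c(AST3 = 1, `5HT` = 1)
    add_class("other", n_other, oth[seq_len(min(n_other, 2))])
  }
  df <- do.call(rbind, rows)
  df$body_id <- seq_len(nrow(df)) + 100L
  idx <- stats::ave(seq_len(nrow(df)), df$cell_class, df$subtype,
                    FUN = seq_along)
  tag <- ifelse(df$subtype == "unknown", df$cell_class, df$subtype)
  df$name <- sprintf("%s_%02d", tag, idx)
  soma <- c(ORN_ipsi = "antennal_nerve", ORN_contra = "commissure",
            PN = "lateral", LN = "lateral", other = "unknown")
  cell_table(
    body_id = df$body_id, name = df$name, cell_class = df$cell_class,
    subtype = df$subtype, soma_location = unname(soma[df$cell_class]),
    volume_um3 = NA_real_
  )
}

## Expected per-cell T-bar means per class from the flow calibration.
tbar_means <- function(config, cells) {
  ft <- config$flow_targets
  pre_pct <- tapply(ft$percent, ft$pre_class, sum) / 100
  share <- c(
    ORN_ipsi = unname(pre_pct["ORN"]) * config$orn_ipsi_output_share,
    ORN_contra = unname(pre_pct["ORN"]) * (1 - config$orn_ipsi_output_share),
    PN = unname(pre_pct["PN"]),
    LN = unname(pre_pct["LN"]),
    other = 0
  )
  share <- share / sum(share)
  n_class <- table(factor(cells$cell_class, levels = names(share)))
  mu <- config$total_tbars * share / pmax(as.integer(n_class), 1)
  mu[as.integer(n_class) == 0] <- 0
  mu
}

#' Generate a synthetic glomerulus dataset with ground truth
#'
#' Simulation order (fixed, so a seed fully determines the output): per-cell
#' T-bar counts (negative binomial within class), T-bar positions (Gaussian
#' around the first configured centre), polyad sizes (truncated Poisson law),
#' then for each presynaptic cell its PSD targets: PN PSDs become autapses
#' with probability `autapse_rate`; a fraction `orphan_rate` is rewired to
#' orphan fragments; the rest draw a postsynaptic major class from the
#' flow-calibrated propensity row and a partner cell within that class from a
#' Dirichlet-multinomial urn (concentration `tail_alpha` times the cell
#' receptivity), which yields heavy-tailed per-pair strengths. PSD positions
#' scatter around their T-bar. Cell volumes are drawn last, scaled so cells
#' occupy 87% of the neuropile volume.
#'
#' @param config A [synth_config()].
#' @return List with `dataset` (a valid [glomerulus_dataset()]) and `truth`:
#'   `classes` (named vector body id -> true class), `subtypes`,
#'   `flow_targets` (the calibrated percentages), `orphan_ids`, and the
#'   `config`.
#' @export
generate_glomerulus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(config$seed, {
    cells <- synth_cells(config)
    n_cells <- nrow(cells)
    mu <- tbar_means(config, cells)
    mu_cell <- unname(mu[cells$cell_class])
    n_tbars <- ifelse(
      mu_cell > 0,
      stats::rnbinom(n_cells, size = config$tbar_nb_size, mu = mu_cell),
      0L
    )

    total_tb <- sum(n_tbars)
    if (total_tb == 0) stop("configuration generated zero T-bars")
    centre_nm <- config$centres_um[1, ] * 1000
    sd_nm <- config$tbar_sigma_um * 1000
    tb_pos <- matrix(stats::rnorm(3 * total_tb, mean = rep(centre_nm,
                                                           each = total_tb),
                                  sd = sd_nm), ncol = 3)
    tb_pos <- pmax(tb_pos, 0)
    tbars <- data.frame(
      tbar_id = seq_len(total_tb),
      pre_body = rep(cells$body_id, n_tbars),
      x = tb_pos[, 1], y = tb_pos[, 2], z = tb_pos[, 3]
    )

    sizes <- draw_polyad_sizes(total_tb, config$psd_lambda, config$psd_max)
    n_psds <- sum(sizes)
    psd_tbar <- rep(tbars$tbar_id, sizes)
    psd_pre <- rep(tbars$pre_body, sizes)
    psd_pre_class <- class_of_body(psd_pre, cells)

    ## propensity rows over post major classes
    ft <- config$flow_targets
    post_levels <- c("PN", "LN", "ORN")
    prop <- matrix(0, 3, 3, dimnames = list(c("ORN", "LN", "PN"), post_levels))
    for (r in seq_len(nrow(ft))) {
      prop[ft$pre_class[r], ft$post_class[r]] <- ft$percent[r]
    }
    prop <- prop / rowSums(prop)

    ## class membership and receptivity weights
    members <- list(
      PN = cells$body_id[cells$cell_class == "PN"],
      LN = cells$body_id[cells$cell_class == "LN"],
      ORN = cells$body_id[cells$cell_class %in% c("ORN_ipsi", "ORN_contra")]
    )
    rec_w <- lapply(members, function(ids) {
      unname(config$receptivity[class_of_body(ids, cells)])
    })

    orphan_ids <- if (config$n_orphans > 0) {
      max(cells$body_id) + seq_len(config$n_orphans)
    } else integer(0)

    u <- stats::runif(n_psds)
    is_autapse <- psd_pre_class == "PN" & u < config$autapse_rate
    is_orphan <- !is_autapse &
      u >= config$autapse_rate &
      u < config$autapse_rate + config$orphan_rate &
      length(orphan_ids) > 0

    post <- integer(n_psds)
    post[is_autapse] <- psd_pre[is_autapse]
    if (any(is_orphan)) {
      post[is_orphan] <- sample(orphan_ids, sum(is_orphan), replace = TRUE)
    }

    ## remaining PSDs: class draw then Dirichlet-multinomial partner choice,
    ## grouped by (pre cell, post class) so each group shares one urn
    rest <- which(!is_autapse & !is_orphan)
    pre_major <- major_class(psd_pre_class[rest])
    cls_draw <- character(length(rest))
    for (pc in c("ORN", "LN", "PN")) {
      sel <- pre_major == pc
      if (any(sel)) {
        cls_draw[sel] <- sample(post_levels, sum(sel), replace = TRUE,
                                prob = prop[pc, ])
      }
    }
    grp <- interaction(psd_pre[rest], cls_draw, drop = TRUE)
    for (sel in split(seq_along(grp), grp)) {
      pc <- cls_draw[sel[1]]
      pre_id <- psd_pre[rest[sel[1]]]
      ids <- members[[pc]]
      a <- config$tail_alpha * rec_w[[pc]]
      a[ids == pre_id] <- 0  # self-contacts only via the autapse channel
      if (all(a == 0)) a <- rep(1, length(ids))
      w <- stats::rgamma(length(ids), shape = a)
      if (sum(w) == 0) w <- a
      post[rest[sel]] <- sample(ids, length(sel), replace = TRUE,
                                prob = w / sum(w))
    }

    psd_pos <- tb_pos[rep(seq_len(total_tb), sizes), , drop = FALSE] +
      matrix(stats::rnorm(3 * n_psds, sd = 150), ncol = 3)
    psd_pos <- pmax(psd_pos, 0)
    psds <- data.frame(
      psd_id = seq_len(n_psds),
      tbar_id = psd_tbar,
      post_body = post,
      x = psd_pos[, 1], y = psd_pos[, 2], z = psd_pos[, 3]
    )

    ## volumes: cells fill 87% of the neuropile, roughly tracking activity
    u_vol <- stats::rgamma(n_cells, shape = 6) * (n_tbars + 20)
    cells$volume_um3 <- 0.87 * config$neuropile_volume_um3 * u_vol / sum(u_vol)

    dataset <- glomerulus_dataset(cells, tbars, psds,
                                  config$neuropile_volume_um3)
    truth <- list(
      classes = stats::setNames(cells$cell_class, cells$body_id),
      subtypes = stats::setNames(cells$subtype, cells$body_id),
      flow_targets = config$flow_targets,
      orphan_ids = orphan_ids,
      config = config
    )
    list(dataset = dataset, truth = truth)
  })
}

#' Generate a multi-glomerulus synapse point cloud with true assignments
#'
#' Samples `cloud_n` points from a mixture of isotropic Gaussians, one per
#' configured glomerulus centre (equal weights), and returns the generating
#' component of every point for oracle scoring of [segment_regions()].
#'
#' @param config A [synth_config()]; `centres_um`, `sigma_um`, `cloud_n` and
#'   `seed` are used.
#' @return List with `points` (`n x 3` matrix, nm, clamped to non-negative
#'   coordinates) and `assignment` (integer vector of generating centres).
#' @export
generate_point_cloud <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  k <- nrow(config$centres_um)
  if (k < 1) stop("at least one glomerulus centre is required")
  sigma <- rep_len(config$sigma_um, k)
  if (any(sigma <= 0)) stop("sigma_um must be positive")
  with_local_seed(config$seed, {
    n <- config$cloud_n
    assignment <- sample.int(k, n, replace = TRUE)
    centres_nm <- config$centres_um * 1000
    pts <- centres_nm[assignment, , drop = FALSE] +
      matrix(stats::rnorm(3 * n, sd = rep(sigma[assignment] * 1000, 3)),
             ncol = 3)
    pts <- pmax(pts, 0)
    colnames(pts) <- c("x", "y", "z")
    list(points = pts, assignment = assignment)
  })
}
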