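#' @keywords internal
"_PACKAGE"

## Cell-class taxonomy -------------------------------------------------------

#' Cell classes recognised by the pipeline
#'
#' Major classes of antennal-lobe neurons as used throughout the package:
#' olfactory receptor neurons arriving ipsilaterally (`ORN_ipsi`) or through
#' the commissure (`ORN_contra`), projection neurons (`PN`), local
#' interneurons (`LN`), a catch-all `other` for identified cells outside the
#' three main classes (e.g. serotonergic or astrocyte-like cells), and
#' `orphan` for neurite fragments not traceable to an identified cell body.
#'
#' @return Character vector of valid `cell_class` values.
#' @export
cell_classes <- function() {
  c("ORN_ipsi", "ORN_contra", "PN", "LN", "other", "orphan")
}

#' Subtype vocabulary and its mapping to major classes
#'
#' The controlled subtype vocabulary is an open enumeration: `unknown` is
#' always admissible so datasets from other glomeruli can be loaded. Every
#' other subtype implies a major class and [validate_dataset()] flags
#' subtype/class contradictions (e.g. an `mPN1` labelled `LN`).
#'
#' @return Named character vector mapping subtype to its implied major class
#'   (`NA` for `unknown`, which is compatible with any class).
#' @export
subtype_classes <- function() {
  c(
    mPN1 = "PN", mPN1_external = "PN", mlPN1 = "PN", mlPN2 = "PN",
    mlPN3 = "PN", lPN2 = "PN", lPN2_comm = "PN", lPN4 = "PN",
    LN1 = "LN", LN2L = "LN", LN2V = "LN", LN3 = "LN", LN4 = "LN",
    LN6 = "LN", LNV = "LN", LN_LV = "LN", LN_comm = "LN",
    AST3 = "other", `5HT` = "other",
    unknown = NA_character_
  )
}

#' Collapse a cell class to its major group
#'
#' Maps `ORN_ipsi` and `ORN_contra` onto `ORN`; all other classes are
#' returned unchanged. Used for flow aggregation at `level = "major"` and for
#' scoring the ratio classifier, which cannot distinguish laterality.
#'
#' @param cell_class Character vector of classes (see [cell_classes()]).
#' @return Character vector of major classes (`ORN`, `PN`, `LN`, `other`,
#'   `orphan`).
#' @export
major_class <- function(cell_class) {
  ifelse(cell_class %in% c("ORN_ipsi", "ORN_contra"), "ORN", cell_class)
}

## Constructors ---------------------------------------------------------------

#' Construct a table of identified neuron bodies
#'
#' @param body_id Integer vector, unique body identifiers.
#' @param name Character vector of cell names.
#' @param cell_class Character vector, each in [cell_classes()].
#' @param subtype Character vector from [subtype_classes()] (default
#'   `"unknown"`).
#' @param soma_location Free-text soma tag (default `""`).
#' @param volume_um3 Non-negative intraglomerular neurite volume in cubic
#'   micrometres; `NA` when not measured.
#' @return A `data.frame` with one row per cell body.
#' @export
cell_table <- function(body_id, name, cell_class,
                       subtype = "unknown",
                       soma_location = "",
                       volume_um3 = NA_real_) {
  data.frame(
    body_id = as.integer(body_id),
    name = as.character(name),
    cell_class = as.character(cell_class),
    subtype = rep_len(as.character(subtype), length(body_id)),
    soma_location = rep_len(as.character(soma_location), length(body_id)),
    volume_um3 = rep_len(as.numeric(volume_um3), length(body_id)),
    stringsAsFactors = FALSE
  )
}

#' Assemble a glomerulus dataset
#'
#' Bundles the three annotation tables of a densely reconstructed glomerulus:
#' identified cells, presynaptic T-bars, and postsynaptic densities (PSDs).
#' One T-bar with its set of PSDs is one polyadic synapse; one PSD is one
#' directed contact once expanded by [expand_contacts()].
#'
#' Pre/post body identifiers that do not resolve to a row of `cells` are
#' retained and treated as orphan fragments downstream, mirroring how dense
#' EM reconstructions keep untraceable neurites in the count.
#'
#' @param cells `data.frame` as returned by [cell_table()].
#' @param tbars `data.frame` with columns `tbar_id`, `pre_body`, `x`, `y`,
#'   `z` (positions in nanometres).
#' @param psds `data.frame` with columns `psd_id`, `tbar_id`, `post_body`,
#'   `x`, `y`, `z` (nanometres).
#' @param neuropile_volume_um3 Positive scalar, glomerular neuropile volume
#'   in cubic micrometres.
#' @return An object of class `glomerulus_dataset`.
#' @seealso [validate_dataset()], [expand_contacts()]
#' @export
glomerulus_dataset <- function(cells, tbars, psds, neuropile_volume_um3) {
  stopifnot(is.data.frame(cells), is.data.frame(tbars), is.data.frame(psds))
  if (!is.numeric(neuropile_volume_um3) || length(neuropile_volume_um3) != 1 ||
      is.na(neuropile_volume_um3) || neuropile_volume_um3 <= 0) {
    stop("neuropile_volume_um3 must be a single positive number")
  }
  structure(
    list(
      cells = cells,
      tbars = tbars,
      psds = psds,
      neuropile_volume_um3 = as.numeric(neuropile_volume_um3)
    ),
    class = "glomerulus_dataset"
  )
}

#' @export
print.glomerulus_dataset <- function(x, ...) {
  cat("<glomerulus_dataset>\n")
  cat(sprintf("  cells: %d   T-bars: %d   PSDs: %d\n",
              nrow(x$cells), nrow(x$tbars), nrow(x$psds)))
  cat(sprintf("  neuropile volume: %.1f um^3\n", x$neuropile_volume_um3))
  invisible(x)
}

## Validation -----------------------------------------------------------------

#' Validate a glomerulus dataset against the model invariants
#'
#' Checks referential integrity and the type invariants without mutating the
#' input. Violations are reported, never raised, so a partially corrupt
#' dataset can be triaged in one pass. Contacts to bodies absent from the
#' cell table are *not* violations: they are orphan fragments and are
#' attributed to the reserved `orphan` class by the pipeline.
#'
#' Checked: uniqueness of `body_id`, `tbar_id`, `psd_id`; `cell_class` and
#' `subtype` drawn from the taxonomy and mutually consistent;
#' `volume_um3 >= 0`; finite non-negative T-bar/PSD coordinates; every PSD
#' referencing an existing T-bar; positive neuropile volume.
#'
#' @param dataset A [glomerulus_dataset()].
#' @return A `data.frame` with columns `component`, `id`, `problem`; zero
#'   rows when the dataset is valid.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "glomerulus_dataset"))
  v <- list()
  add <- function(component, id, problem) {
    v[[length(v) + 1]] <<- data.frame(
      component = component, id = as.character(id), problem = problem,
      stringsAsFactors = FALSE
    )
  }

  cells <- dataset$cells
  dup <- unique(cells$body_id[duplicated(cells$body_id)])
  for (id in dup) add("cells", id, "duplicate body_id")
  bad_class <- !(cells$cell_class %in% cell_classes())
  for (i in which(bad_class)) {
    add("cells", cells$body_id[i],
        sprintf("unknown cell_class '%s'", cells$cell_class[i]))
  }
  st <- subtype_classes()
  known_st <- cells$subtype %in% names(st)
  for (i in which(!known_st)) {
    add("cells", cells$body_id[i],
        sprintf("unknown subtype '%s'", cells$subtype[i]))
  }
  implied <- unname(st[cells$subtype])
  clash <- known_st & !is.na(implied) & !bad_class &
    implied != cells$cell_class
  for (i in which(clash)) {
    add("cells", cells$body_id[i],
        sprintf("subtype '%s' implies class %s, not %s",
                cells$subtype[i], implied[i], cells$cell_class[i]))
  }
  bad_vol <- !is.na(cells$volume_um3) & cells$volume_um3 < 0
  for (i in which(bad_vol)) add("cells", cells$body_id[i], "negative volume_um3")

  tbars <- dataset$tbars
  dup <- unique(tbars$tbar_id[duplicated(tbars$tbar_id)])
  for (id in dup) add("tbars", id, "duplicate tbar_id")
  pos <- as.matrix(tbars[, c("x", "y", "z"), drop = FALSE])
  bad_pos <- !is.finite(pos) | pos < 0
  for (i in which(rowSums(bad_pos) > 0)) {
    add("tbars", tbars$tbar_id[i], "non-finite or negative coordinate")
  }

  psds <- dataset$psds
  dup <- unique(psds$psd_id[duplicated(psds$psd_id)])
  for (id in dup) add("psds", id, "duplicate psd_id")
  missing_tbar <- !(psds$tbar_id %in% tbars$tbar_id)
  for (i in which(missing_tbar)) {
    add("psds", psds$psd_id[i],
        sprintf("references missing tbar_id %s", psds$tbar_id[i]))
  }
  pos <- as.matrix(psds[, c("x", "y", "z"), drop = FALSE])
  bad_pos <- !is.finite(pos) | pos < 0
  for (i in which(rowSums(bad_pos) > 0)) {
    add("psds", psds$psd_id[i], "non-finite or negative coordinate")
  }

  if (length(v) == 0) {
    data.frame(component = character(), id = character(),
               problem = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, v)
  }
}

#' Resolve the class (or subtype) of arbitrary body ids
#'
#' Bodies absent from the cell table are untraceable neurite fragments by
#' convention and resolve to `"orphan"`.
#'
#' @param body_id Integer vector of body ids.
#' @param cells Cell table (see [cell_table()]).
#' @param level `"class"` (default) or `"subtype"`.
#' @return Character vector of labels.
#' @export
class_of_body <- function(body_id, cells, level = c("class", "subtype")) {
  level <- match.arg(level)
  col <- if (level == "class") "cell_class" else "subtype"
  idx <- match(body_id, cells$body_id)
  out <- cells[[col]][idx]
  out[is.na(idx)] <- "orphan"
  out
}
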