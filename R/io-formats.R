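## Readers and writers for every external representation the pipeline touches.
## All readers reject malformed input (naming the offending line/cell) rather
## than silently coercing; delimiter sniffing is deliberately absent so reads
## are deterministic.

synapse_columns <- c("psd_id", "tbar_id", "pre_body", "post_body",
                     "tbar_x", "tbar_y", "tbar_z",
                     "psd_x", "psd_y", "psd_z")

#' Read a synapse annotation table
#'
#' One record per postsynaptic density (PSD), each linked to its presynaptic
#' T-bar. Required columns/fields: `psd_id`, `tbar_id`, `pre_body`,
#' `post_body`, `tbar_x/y/z`, `psd_x/y/z` (positions in nanometres); an
#' optional `confidence` column is carried through. T-bars are deduplicated
#' by `tbar_id`, so row order does not affect the result.
#'
#' @param path File to read.
#' @param dialect `"tsv"` (tab-separated, header row) or `"json"` (array of
#'   one object per PSD).
#' @return A list with data.frames `tbars` (`tbar_id`, `pre_body`, `x`, `y`,
#'   `z`) and `psds` (`psd_id`, `tbar_id`, `post_body`, `x`, `y`, `z`),
#'   ready for [glomerulus_dataset()].
#' @export
read_synapse_table <- function(path, dialect = c("tsv", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    nf <- utils::count.fields(path, sep = "\t", quote = "\"")
    if (length(unique(nf)) > 1) {
      bad <- which(nf != nf[1])[1]
      stop(sprintf("ragged synapse table: line %d has %d fields, expected %d",
                   bad, nf[bad], nf[1]))
    }
    raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                             check.names = FALSE, quote = "\"")
  } else {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (!is.data.frame(raw)) stop("JSON synapse table must be an array of objects")
    raw[] <- lapply(raw, as.character)
  }
  missing <- setdiff(synapse_columns, names(raw))
  if (length(missing) > 0) {
    stop("synapse table missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  num_cols <- setdiff(synapse_columns, character())
  for (cn in num_cols) {
    val <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(val) & !is.na(raw[[cn]]) & nzchar(raw[[cn]]))
    bad <- c(bad, which(is.na(raw[[cn]]) | !nzchar(raw[[cn]])))
    if (length(bad) > 0) {
      where <- if (dialect == "tsv") sprintf("line %d", min(bad) + 1L)
               else sprintf("element %d", min(bad))
      stop(sprintf("malformed value in column '%s' (%s)", cn, where))
    }
    raw[[cn]] <- val
  }
  dup <- unique(raw$psd_id[duplicated(raw$psd_id)])
  if (length(dup) > 0) {
    stop("duplicate psd_id: ", paste(dup, collapse = ", "))
  }
  tb <- raw[!duplicated(raw$tbar_id),
            c("tbar_id", "pre_body", "tbar_x", "tbar_y", "tbar_z")]
  tbars <- data.frame(
    tbar_id = as.integer(tb$tbar_id),
    pre_body = as.integer(tb$pre_body),
    x = tb$tbar_x, y = tb$tbar_y, z = tb$tbar_z
  )
  psds <- data.frame(
    psd_id = as.integer(raw$psd_id),
    tbar_id = as.integer(raw$tbar_id),
    post_body = as.integer(raw$post_body),
    x = raw$psd_x, y = raw$psd_y, z = raw$psd_z
  )
  list(tbars = tbars, psds = psds)
}

#' Write a synapse annotation table
#'
#' Inverse of [read_synapse_table()]: emits one record per PSD with its
#' parent T-bar columns repeated. Output ordering follows `psds` row order,
#' so writing is deterministic for a fixed dataset.
#'
#' @param dataset A [glomerulus_dataset()] or a list with `tbars`/`psds`.
#' @param path Output file.
#' @param dialect `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_synapse_table <- function(dataset, path, dialect = c("tsv", "json")) {
  dialect <- match.arg(dialect)
  tbars <- dataset$tbars
  psds <- dataset$psds
  idx <- match(psds$tbar_id, tbars$tbar_id)
  if (anyNA(idx)) stop("psds reference tbar_ids absent from tbars")
  rec <- data.frame(
    psd_id = psds$psd_id,
    tbar_id = psds$tbar_id,
    pre_body = tbars$pre_body[idx],
    post_body = psds$post_body,
    tbar_x = tbars$x[idx], tbar_y = tbars$y[idx], tbar_z = tbars$z[idx],
    psd_x = psds$x, psd_y = psds$y, psd_z = psds$z
  )
  if (dialect == "tsv") {
    utils::write.table(rec, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, eol = "\n")
  } else {
    jsonlite::write_json(rec, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}

#' Read a cell metadata table
#'
#' Delimited text with header columns `body_id`, `name`, `class`, `subtype`,
#' `soma`, `volume_um3`. Class and subtype strings are validated against the
#' taxonomy ([cell_classes()], [subtype_classes()]); unknown values are an
#' error, not a silent coercion.
#'
#' @param path File to read.
#' @param delim Field delimiter, default `","`.
#' @return A cell `data.frame` as from [cell_table()].
#' @export
read_cell_table <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", strip.white = TRUE)
  required <- c("body_id", "name", "class", "subtype", "soma", "volume_um3")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("cell table missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- which(!(raw$class %in% cell_classes()))
  if (length(bad) > 0) {
    stop(sprintf("unknown cell class '%s' (line %d)",
                 raw$class[bad[1]], bad[1] + 1L))
  }
  bad <- which(!(raw$subtype %in% names(subtype_classes())))
  if (length(bad) > 0) {
    stop(sprintf("unknown subtype '%s' (line %d)",
                 raw$subtype[bad[1]], bad[1] + 1L))
  }
  vol <- suppressWarnings(as.numeric(raw$volume_um3))
  bad <- which(is.na(vol) & nzchar(raw$volume_um3) & raw$volume_um3 != "NA")
  if (length(bad) > 0) {
    stop(sprintf("non-numeric volume_um3 (line %d)", bad[1] + 1L))
  }
  cell_table(
    body_id = as.integer(raw$body_id),
    name = raw$name,
    cell_class = raw$class,
    subtype = raw$subtype,
    soma_location = raw$soma,
    volume_um3 = vol
  )
}

#' Write a cell metadata table
#'
#' @param cells Cell `data.frame` (see [cell_table()]).
#' @param path Output file.
#' @param delim Field delimiter, default `","`.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path, delim = ",") {
  out <- data.frame(
    body_id = cells$body_id, name = cells$name, class = cells$cell_class,
    subtype = cells$subtype, soma = cells$soma_location,
    volume_um3 = cells$volume_um3
  )
  utils::write.table(out, path, sep = delim, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

## Dense-grid parsing shared between CSV and XLSX matrix readers.
parse_dense_matrix <- function(df, what) {
  if (ncol(df) < 2) stop(what, ": dense matrix needs a label column and counts")
  col_labels <- as.character(names(df)[-1])
  row_labels <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  ## tolerate an optional class row: a first data row that is entirely
  ## non-numeric in the count positions (deposited spreadsheets carry one)
  is_num_row <- function(i) {
    v <- suppressWarnings(as.numeric(as.character(unlist(body[i, ]))))
    !all(is.na(v))
  }
  if (nrow(body) >= 1 && !is_num_row(1)) {
    body <- body[-1, , drop = FALSE]
    row_labels <- row_labels[-1]
  }
  n <- nrow(body)
  counts <- matrix(0L, n, length(col_labels),
                   dimnames = list(row_labels, col_labels))
  for (j in seq_along(col_labels)) {
    v <- as.character(body[[j]])
    v[is.na(v) | !nzchar(v)] <- "0"
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num))
    if (length(bad) > 0) {
      stop(sprintf("%s: non-numeric cell at row '%s', column '%s'",
                   what, row_labels[bad[1]], col_labels[j]))
    }
    nonint <- which(num != round(num))
    if (length(nonint) > 0) {
      stop(sprintf("%s: non-integer count at row '%s', column '%s'",
                   what, row_labels[nonint[1]], col_labels[j]))
    }
    counts[, j] <- as.integer(num)
  }
  if (any(counts < 0)) stop(what, ": negative counts are not allowed")
  counts
}

#' Read a contact matrix
#'
#' Two layouts are accepted. `"dense"`: a labelled grid whose first column
#' holds presynaptic cell names and whose header holds postsynaptic cell
#' names (the layout of deposited connectivity spreadsheets; an optional
#' class row under the header is tolerated; blank cells read as 0).
#' `"edgelist"`: three columns `pre`, `post`, `count`.
#'
#' @param path File to read.
#' @param format `"csv"` or `"xlsx"` (first sheet only).
#' @param layout `"dense"` (default) or `"edgelist"`.
#' @return Integer matrix, rows = presynaptic cells, columns = postsynaptic
#'   cells, with label dimnames.
#' @export
read_matrix <- function(path, format = c("csv", "xlsx"),
                        layout = c("dense", "edgelist")) {
  format <- match.arg(format)
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    nf <- utils::count.fields(path, sep = ",", quote = "\"")
    if (length(unique(nf)) > 1) {
      bad <- which(nf != nf[1])[1]
      stop(sprintf("ragged matrix file: line %d has %d fields, expected %d",
                   bad, nf[bad], nf[1]))
    }
    df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
  } else {
    df <- as.data.frame(readxl::read_excel(path, sheet = 1, col_types = "text",
                                           .name_repair = "minimal"))
  }
  if (layout == "edgelist") {
    if (ncol(df) < 3) stop("edge list needs columns pre, post, count")
    pre <- as.character(df[[1]])
    post <- as.character(df[[2]])
    cnt <- suppressWarnings(as.numeric(df[[3]]))
    bad <- which(is.na(cnt))
    if (length(bad) > 0) {
      stop(sprintf("edge list: non-numeric count at line %d", bad[1] + 1L))
    }
    if (any(cnt != round(cnt))) stop("edge list: non-integer count")
    labels <- sort(unique(c(pre, post)))
    m <- matrix(0L, length(labels), length(labels),
                dimnames = list(labels, labels))
    for (k in seq_along(pre)) {
      m[pre[k], post[k]] <- m[pre[k], post[k]] + as.integer(cnt[k])
    }
    m
  } else {
    parse_dense_matrix(df, basename(path))
  }
}

#' Write a contact matrix
#'
#' Dense CSV output is deterministic (fixed column order, `\n` line ends),
#' so write/read/write produces a byte-identical second file. `"edgelist"`
#' emits the nonzero entries as `pre,post,count` rows in row-major order.
#'
#' @param mat Integer matrix with dimnames (e.g. from
#'   [build_contact_matrix()] or [read_matrix()]).
#' @param path Output file.
#' @param format `"csv"` (dense grid) or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, format = c("csv", "edgelist")) {
  format <- match.arg(format)
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("matrix must carry row and column labels")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "csv") {
    header <- paste(c("", colnames(mat)), collapse = ",")
    writeLines(header, con, sep = "\n")
    for (i in seq_len(nrow(mat))) {
      writeLines(paste(c(rownames(mat)[i], mat[i, ]), collapse = ","),
                 con, sep = "\n")
    }
  } else {
    writeLines("pre,post,count", con, sep = "\n")
    nz <- which(t(mat) != 0)  # row-major order
    for (k in nz) {
      j <- (k - 1L) %% ncol(mat) + 1L
      i <- (k - 1L) %/% ncol(mat) + 1L
      writeLines(sprintf("%s,%s,%d", rownames(mat)[i], colnames(mat)[j],
                         mat[i, j]), con, sep = "\n")
    }
  }
  invisible(path)
}

#' Read a 3D synapse point cloud
#'
#' CSV with header columns `x`, `y`, `z` (or `x_vox`, `y_vox`, `z_vox`).
#' Units are taken from the header by default: plain or `_nm` suffixed
#' columns are nanometres; `_vox` columns are voxel indices converted at
#' `voxel_size_nm` nanometres per voxel (8 nm for the isotropic FIB-SEM
#' grid this pipeline assumes).
#'
#' @param path File to read.
#' @param units `"auto"` (default, from header), `"nm"`, or `"voxel"`.
#' @param voxel_size_nm Nanometres per voxel when converting, default 8.
#' @return Numeric matrix `n x 3` in nanometres, columns `x`, `y`, `z`;
#'   input row order preserved.
#' @export
read_point_cloud <- function(path, units = c("auto", "nm", "voxel"),
                             voxel_size_nm = 8) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        check.names = FALSE)
  nm_cols <- c("x", "y", "z")
  nm_suffix <- c("x_nm", "y_nm", "z_nm")
  vox_cols <- c("x_vox", "y_vox", "z_vox")
  if (all(vox_cols %in% names(df))) {
    cols <- vox_cols
    header_units <- "voxel"
  } else if (all(nm_suffix %in% names(df))) {
    cols <- nm_suffix
    header_units <- "nm"
  } else if (all(nm_cols %in% names(df))) {
    cols <- nm_cols
    header_units <- "nm"
  } else {
    stop("point cloud needs columns x,y,z (or x_vox,y_vox,z_vox)")
  }
  if (units == "auto") units <- header_units
  out <- matrix(NA_real_, nrow(df), 3, dimnames = list(NULL, c("x", "y", "z")))
  for (j in 1:3) {
    v <- suppressWarnings(as.numeric(df[[cols[j]]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric coordinate in column '%s' at line %d",
                   cols[j], bad[1] + 1L))
    }
    out[, j] <- v
  }
  if (units == "voxel") out <- out * voxel_size_nm
  out
}

#' Write a 3D point cloud as CSV (nanometre columns `x,y,z`)
#'
#' @param points Numeric matrix `n x 3` (nm).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(points, path) {
  df <- data.frame(x = points[, 1], y = points[, 2], z = points[, 3])
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
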