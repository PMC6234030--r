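# Independent brute-force references and small fixture builders shared by the
# test files. The oracles are deliberately written as plain loops, not via the
# package's own code paths.

# A tiny hand-built glomerulus: bodies 1 (ORN), 2 (PN), 3 (LN); 3 T-bars.
tiny_dataset <- function() {
  cells <- cell_table(
    body_id = 1:3,
    name = c("orn_a", "pn_a", "ln_a"),
    cell_class = c("ORN_ipsi", "PN", "LN"),
    subtype = c("unknown", "mPN1", "LN1"),
    volume_um3 = c(10, 20, 30)
  )
  tbars <- data.frame(
    tbar_id = 1:3,
    pre_body = c(1L, 1L, 2L),
    x = c(100, 200, 300), y = c(100, 200, 300), z = c(100, 200, 300)
  )
  psds <- data.frame(
    psd_id = 1:6,
    tbar_id = c(1L, 1L, 1L, 2L, 2L, 3L),
    post_body = c(2L, 3L, 2L, 3L, 2L, 2L),
    x = c(110, 120, 130, 210, 220, 310),
    y = c(110, 120, 130, 210, 220, 310),
    z = c(110, 120, 130, 210, 220, 310)
  )
  psds$post_body[6] <- 1L  # keep the fixture autapse-free
  glomerulus_dataset(cells, tbars, psds, neuropile_volume_um3 = 100)
}

# Scaled-down generator configuration for fast property tests.
small_config <- function(seed, ...) {
  synth_config(
    census = c(ORN_ipsi = 10, ORN_contra = 12, PN = 5, LN = 12, other = 1),
    total_tbars = 600,
    seed = seed,
    ...
  )
}

random_count_matrix <- function(n, max_count = 12, p_zero = 0.5) {
  m <- matrix(0L, n, n, dimnames = list(as.character(seq_len(n) + 100L),
                                        as.character(seq_len(n) + 100L)))
  k <- sample.int(max_count, n * n, replace = TRUE) *
    (stats::runif(n * n) > p_zero)
  m[] <- as.integer(k)
  m
}

# Brute-force per-body tallies from a contact list.
oracle_totals <- function(contacts) {
  bodies <- sort(unique(c(contacts$pre_body, contacts$post_body)))
  out <- data.frame(body_id = bodies, pre_contacts = 0L, post_contacts = 0L)
  for (i in seq_len(nrow(contacts))) {
    r <- which(out$body_id == contacts$pre_body[i])
    out$pre_contacts[r] <- out$pre_contacts[r] + 1L
    r <- which(out$body_id == contacts$post_body[i])
    out$post_contacts[r] <- out$post_contacts[r] + 1L
  }
  out$total <- out$pre_contacts + out$post_contacts
  out
}

# Brute-force contact matrix over given bodies (sorted ascending).
oracle_matrix <- function(contacts, included) {
  bodies <- sort(included)
  m <- matrix(0L, length(bodies), length(bodies),
              dimnames = list(as.character(bodies), as.character(bodies)))
  for (i in seq_len(nrow(contacts))) {
    a <- as.character(contacts$pre_body[i])
    b <- as.character(contacts$post_body[i])
    if (a %in% rownames(m) && b %in% colnames(m)) m[a, b] <- m[a, b] + 1L
  }
  m
}

# Brute-force strength histogram (named vector strength -> count).
oracle_strengths <- function(mat) {
  counts <- integer(0)
  for (i in seq_len(nrow(mat))) {
    for (j in seq_len(ncol(mat))) {
      s <- mat[i, j]
      if (s > 0) {
        key <- as.character(s)
        counts[key] <- if (key %in% names(counts)) counts[key] + 1L else 1L
      }
    }
  }
  counts[order(as.integer(names(counts)))]
}

# Brute-force unordered pair table with reciprocity flags (plain double
# loop accumulating vectors).
oracle_pairs <- function(mat, min_each = 3, band = c(0.25, 4),
                         band_mode = "within") {
  labs <- rownames(mat)
  a <- character(0); b <- character(0)
  fw <- integer(0); bw <- integer(0); rt <- numeric(0)
  iu <- logical(0); rc <- logical(0); st <- logical(0)
  for (i in seq_len(nrow(mat))) {
    for (j in seq_len(ncol(mat))) {
      if (i < j && (mat[i, j] + mat[j, i]) >= 1) {
        fwd <- mat[i, j]; bwd <- mat[j, i]
        ratio <- if (bwd > 0) fwd / bwd else NA_real_
        rec <- fwd >= min_each && bwd >= min_each
        inb <- !is.na(ratio) &&
          (if (band_mode == "within") ratio >= band[1] && ratio <= band[2]
           else ratio <= band[1] || ratio >= band[2])
        a <- c(a, labs[i]); b <- c(b, labs[j])
        fw <- c(fw, as.integer(fwd)); bw <- c(bw, as.integer(bwd))
        rt <- c(rt, ratio)
        iu <- c(iu, max(fwd, bwd) >= min_each)
        rc <- c(rc, rec); st <- c(st, rec && inb)
      }
    }
  }
  if (length(a) == 0) return(NULL)
  data.frame(body_a = a, body_b = b, forward = fw, backward = bw,
             ratio = rt, in_universe = iu, reciprocal = rc, strong = st,
             stringsAsFactors = FALSE)
}

# Brute-force class aggregation.
oracle_class_agg <- function(mat, labels) {
  lev <- unique(labels)
  out <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_len(nrow(mat))) {
    for (j in seq_len(ncol(mat))) {
      out[labels[i], labels[j]] <- out[labels[i], labels[j]] + mat[i, j]
    }
  }
  out
}
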