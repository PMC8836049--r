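# ---- residue contact detection ----------------------------------------------

# cell-list neighbour search: returns m x 2 matrix of atom-index pairs with
# distance <= cutoff (exact; the grid only prunes candidate pairs)
.grid_atom_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  # encode 3 cell integers into one key
  span <- apply(cell, 2, max) + 2L
  key <- cell[, 1] + span[1] * (cell[, 2] + span[2] * cell[, 3])
  groups <- split(seq_len(n), key)
  cell1 <- vapply(groups, function(g) cell[g[1], 1], numeric(1))
  cell2 <- vapply(groups, function(g) cell[g[1], 2], numeric(1))
  cell3 <- vapply(groups, function(g) cell[g[1], 3], numeric(1))
  keys <- as.numeric(names(groups))
  key_pos <- stats::setNames(seq_along(keys), names(groups))
  cut2 <- cutoff^2
  out <- vector("list", 14L * length(groups))
  ct <- 0L
  # half-space of neighbour offsets so every cell pair is visited once
  offsets <- rbind(
    matrix(c(0, 0, 0), 1, 3),
    as.matrix(expand.grid(-1:1, -1:1, 1)),
    as.matrix(expand.grid(-1:1, 1, 0)),
    matrix(c(1, 0, 0), 1, 3))
  dimnames(offsets) <- NULL
  for (gi in seq_along(groups)) {
    a_idx <- groups[[gi]]
    for (oi in seq_len(nrow(offsets))) {
      off <- offsets[oi, ]
      same <- all(off == 0)
      if (same) {
        b_idx <- a_idx
      } else {
        nk <- (cell1[gi] + off[1]) +
          span[1] * ((cell2[gi] + off[2]) + span[2] * (cell3[gi] + off[3]))
        pos <- key_pos[as.character(nk)]
        if (is.na(pos)) next
        b_idx <- groups[[pos]]
      }
      A <- xyz[a_idx, , drop = FALSE]
      B <- xyz[b_idx, , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
      hit <- which(d2 <= cut2 + 1e-12, arr.ind = TRUE)
      if (same) hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      if (nrow(hit)) {
        ct <- ct + 1L
        out[[ct]] <- cbind(a_idx[hit[, 1]], b_idx[hit[, 2]])
      }
    }
  }
  if (ct == 0L) return(matrix(integer(), 0, 2))
  do.call(rbind, out[seq_len(ct)])
}

#' Residue contacts in a single frame
#'
#' A contact between residues i and j is counted when any heavy atom of
#' residue i lies within `cutoff` Angstrom (closed bound, `<=`) of any heavy
#' atom of residue j. Detection uses a cell-list spatial grid that prunes
#' candidate pairs without changing the all-pairs result. The default
#' `min_separation = 1` counts every i != j pair; raise it (e.g. 3) to focus
#' on tertiary contacts.
#'
#' @param frame n_atoms x 3 coordinate matrix.
#' @param topology the `mdu_structure` topology.
#' @param cutoff contact cutoff in Angstrom (default 6.5).
#' @param min_separation minimum sequence separation `|i - j|` (default 1).
#' @return A list of class `mdu_contactset`: `pairs` (m x 2 integer matrix of
#'   sequential residue indices, i < j), `cutoff`, `min_separation`, `n_res`.
#' @export
contact_set <- function(frame, topology, cutoff = 6.5, min_separation = 1L) {
  stopifnot(cutoff > 0, min_separation >= 1L)
  heavy <- select_atoms(topology, "heavy")
  if (!length(heavy)) stop("structure has no heavy atoms")
  xyz <- frame[heavy, , drop = FALSE]
  resid <- topology$atoms$resid[heavy]
  ap <- .grid_atom_pairs(xyz, cutoff)
  ri <- resid[ap[, 1]]; rj <- resid[ap[, 2]]
  keep <- abs(ri - rj) >= min_separation
  i <- pmin(ri[keep], rj[keep]); j <- pmax(ri[keep], rj[keep])
  pr <- unique(cbind(i, j))
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  structure(list(pairs = pr, cutoff = cutoff, min_separation = min_separation,
                 n_res = n_residues(topology)),
            class = "mdu_contactset")
}

#' @export
print.mdu_contactset <- function(x, ...) {
  cat(sprintf("<mdu_contactset> %d contacts (cutoff %.2f A, |i-j| >= %d)\n",
              nrow(x$pairs), x$cutoff, x$min_separation))
  invisible(x)
}

.pair_keys <- function(pairs, n_res) (pairs[, 1] - 1) * n_res + pairs[, 2]

# pairs with at least one member residue inside the region (sequential resids)
.region_pair_filter <- function(pairs, resids) {
  pairs[pairs[, 1] %in% resids | pairs[, 2] %in% resids, , drop = FALSE]
}

#' Native contact fraction Q over a trajectory
#'
#' Q(t) is the number of residue contacts counted at frame t divided by the
#' number of contacts in the reference structure at time zero (frame 1), so
#' Q(t0) = 1. Following the literal definition the numerator counts all
#' contacts present at time t (non-native contacts included), so Q can exceed
#' 1; `mode = "native"` restricts the numerator to the reference pairs.
#' A region restricts both counts to pairs with at least one member residue
#' inside the region (the region's contacts with its neighbouring residues).
#'
#' @param traj an `mdu_trajectory`.
#' @param stride sample every `stride`-th frame (default 1).
#' @param region optional region name.
#' @param regions an `mdu_regions` map (needed when `region` is given).
#' @param cutoff contact cutoff in Angstrom (default 6.5).
#' @param min_separation minimum sequence separation (default 1).
#' @param mode `"all"` (literal definition) or `"native"` (numerator
#'   intersected with the reference contact set).
#' @return An `mdu_timeseries` data frame (`time_ns`, `value` = Q); attributes
#'   `reference` (the frame-1 `mdu_contactset`) and `region`.
#' @export
contact_fraction_series <- function(traj, stride = 1L, region = NULL,
                                    regions = NULL, cutoff = 6.5,
                                    min_separation = 1L,
                                    mode = c("all", "native")) {
  mode <- match.arg(mode)
  idx <- seq(1L, n_frames(traj), by = stride)
  topo <- traj$topology
  resids <- NULL
  if (!is.null(region)) {
    if (is.null(regions)) stop("a region map must be supplied with `region`")
    resids <- region_resids(topo, regions, region)
  }
  sets <- lapply(idx, function(i)
    contact_set(traj$coords[[i]], topo, cutoff, min_separation))
  ref_pairs <- sets[[1]]$pairs
  if (!is.null(resids)) ref_pairs <- .region_pair_filter(ref_pairs, resids)
  denom <- nrow(ref_pairs)
  if (denom == 0L) stop("reference contact set is empty: Q is undefined")
  nres <- sets[[1]]$n_res
  ref_keys <- .pair_keys(ref_pairs, nres)
  q <- vapply(sets, function(s) {
    pr <- s$pairs
    if (!is.null(resids)) pr <- .region_pair_filter(pr, resids)
    if (mode == "native") {
      sum(.pair_keys(pr, nres) %in% ref_keys) / denom
    } else {
      nrow(pr) / denom
    }
  }, numeric(1))
  out <- new_timeseries(traj$times[idx], q, unit = "Q")
  attr(out, "reference") <- sets[[1]]
  attr(out, "region") <- region
  out
}

#' Detect a sustained drop in a contact-fraction series
#'
#' The baseline is the median of the first `baseline_frames` values; the
#' onset is the first sampled frame whose value falls below
#' `drop_factor * baseline` and stays below for at least `persistence`
#' consecutive sampled frames.
#'
#' @param series an `mdu_timeseries` (e.g. from [contact_fraction_series()]).
#' @param drop_factor fraction of baseline below which a drop is called
#'   (default 0.8).
#' @param baseline_frames frames used for the baseline (default 5).
#' @param persistence required consecutive below-threshold frames (default 3).
#' @return A one-row data frame (`onset_ns`, `onset_index`, `baseline`,
#'   `threshold`) or `NULL` when no sustained drop occurs.
#' @export
detect_q_drop <- function(series, drop_factor = 0.8, baseline_frames = 5L,
                          persistence = 3L) {
  v <- series$value
  base <- stats::median(v[seq_len(min(baseline_frames, length(v)))])
  thr <- drop_factor * base
  below <- v < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= persistence)
  if (!length(hit)) return(NULL)
  i <- starts[hit[1]]
  data.frame(onset_ns = series$time_ns[i], onset_index = i,
             baseline = base, threshold = thr)
}

# ---- ensemble and subtractive maps ------------------------------------------

#' Ensemble contact-frequency map
#'
#' Entry (i, j) is the fraction of sampled frames in which residues i and j
#' are in contact. The matrix is symmetric with zero diagonal.
#'
#' @inheritParams contact_fraction_series
#' @return An n_res x n_res matrix of class `mdu_contactmap` with attributes
#'   `n_frames`, `cutoff`, `reference` (the frame-1 indicator map).
#' @export
ensemble_contact_map <- function(traj, stride = 1L, cutoff = 6.5,
                                 min_separation = 1L) {
  idx <- seq(1L, n_frames(traj), by = stride)
  topo <- traj$topology
  nres <- n_residues(topo)
  acc <- matrix(0, nres, nres)
  ref <- NULL
  for (k in seq_along(idx)) {
    cs <- contact_set(traj$coords[[idx[k]]], topo, cutoff, min_separation)
    m <- matrix(0, nres, nres)
    m[cs$pairs] <- 1
    m <- m + t(m)
    if (k == 1L) ref <- m
    acc <- acc + m
  }
  acc <- acc / length(idx)
  structure(acc, class = c("mdu_contactmap", class(acc)),
            n_frames = length(idx), cutoff = cutoff, reference = ref)
}

#' Subtractive contact map
#'
#' `mode = "raw"` returns the elementwise difference A - B of two ensemble
#' contact maps. `mode = "loss"` first converts each map to a change map
#' relative to its own reference structure (frame-1 indicator map), i.e.
#' (A - ref_A) - (B - ref_B), which compares contact loss between ensembles
#' started from different reference structures. In either mode negative
#' entries mark contacts whose loss is greater in A; the result negates under
#' operand swap.
#'
#' @param map_a,map_b `mdu_contactmap` matrices of equal dimension.
#' @param mode `"raw"` or `"loss"`.
#' @return A signed n_res x n_res matrix.
#' @export
subtractive_map <- function(map_a, map_b, mode = c("raw", "loss")) {
  mode <- match.arg(mode)
  if (!all(dim(map_a) == dim(map_b)))
    stop("contact maps have mismatched dimensions")
  bare <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))
  if (mode == "raw") return(bare(map_a) - bare(map_b))
  ra <- attr(map_a, "reference"); rb <- attr(map_b, "reference")
  if (is.null(ra) || is.null(rb))
    stop("loss mode needs maps with a stored reference (frame-1) indicator map")
  (bare(map_a) - bare(ra)) - (bare(map_b) - bare(rb))
}

#' Mean contact frequency between two regions
#'
#' Mean of the contact-map entries over the region_a x region_b block,
#' excluding diagonal entries. Symmetric in the region arguments.
#'
#' @param map an `mdu_contactmap` (or any residue x residue matrix).
#' @param topology the `mdu_structure` the map indices refer to.
#' @param region_a,region_b region names.
#' @param regions an `mdu_regions` map.
#' @return The mean contact frequency (scalar).
#' @export
region_pair_contact_summary <- function(map, topology, region_a, region_b,
                                        regions) {
  ra <- region_resids(topology, regions, region_a)
  rb <- region_resids(topology, regions, region_b)
  if (!length(ra) || !length(rb)) stop("empty region block")
  block <- unclass(map)[ra, rb, drop = FALSE]
  diag_mask <- outer(ra, rb, `==`)
  vals <- block[!diag_mask]
  if (!length(vals)) stop("empty region block after diagonal removal")
  mean(vals)
}
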