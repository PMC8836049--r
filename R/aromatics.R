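# ---- aromatic ring geometry ---------------------------------------------------

AROMATIC_RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

AROMATIC_BAND <- c(4.5, 7.0)  # Angstrom, centroid-centroid interaction band

#' Aromatic residues of a structure
#'
#' @param struct an `mdu_structure`.
#' @param include_his treat histidine as aromatic (default FALSE; the band
#'   criterion was derived for Tyr/Trp/Phe clusters).
#' @return Data frame with `resid` (sequential), `resno` (author), `resname`.
#' @export
aromatic_residues <- function(struct, include_his = FALSE) {
  types <- c("PHE", "TYR", "TRP", if (include_his) "HIS")
  a <- struct$atoms
  first <- !duplicated(a$resid)
  sel <- first & a$resname %in% types
  data.frame(resid = a$resid[sel], resno = a$resno[sel],
             resname = a$resname[sel], stringsAsFactors = FALSE)
}

#' Aromatic ring centroid
#'
#' Unweighted mean of the ring heavy-atom coordinates (6-membered ring for
#' Phe/Tyr, the full 9-atom bicycle for Trp, 5-membered imidazole for His).
#'
#' @param struct the `mdu_structure` topology.
#' @param frame n_atoms x 3 coordinate matrix.
#' @param resid sequential residue index of an aromatic residue.
#' @return Length-3 centroid coordinates.
#' @export
ring_centroid <- function(struct, frame, resid) {
  a <- struct$atoms
  sel <- a$resid == resid
  rn <- a$resname[sel][1]
  ring <- AROMATIC_RING_ATOMS[[rn]]
  if (is.null(ring)) stop("residue ", resid, " (", rn, ") is not aromatic")
  idx <- which(sel)[match(ring, a$name[sel])]
  if (anyNA(idx)) {
    missing <- ring[is.na(match(ring, a$name[sel]))]
    stop("missing ring atom(s) ", paste(missing, collapse = ", "),
         " in residue ", resid, " (", rn, ")")
  }
  colMeans(frame[idx, , drop = FALSE])
}

# centroids of all aromatic residues in one frame: k x 3 matrix
.aromatic_centroids <- function(struct, frame, aro) {
  t(vapply(aro$resid, function(r) ring_centroid(struct, frame, r), numeric(3)))
}

# minimum ring-atom-pair distance between two aromatic residues
.ring_min_distance <- function(struct, frame, resid_a, resid_b) {
  a <- struct$atoms
  get_ring <- function(resid) {
    sel <- a$resid == resid
    ring <- AROMATIC_RING_ATOMS[[a$resname[sel][1]]]
    idx <- which(sel)[match(ring, a$name[sel])]
    frame[idx, , drop = FALSE]
  }
  A <- get_ring(resid_a); B <- get_ring(resid_b)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sqrt(max(0, min(d2)))
}

#' Aromatic pair distance over a trajectory
#'
#' Distance between two aromatic residues per sampled frame. The default
#' metric is the ring-centroid distance (the native metric of the
#' 4.5~7.0 A interaction criterion); `metric = "min_atom"` switches to the
#' minimum ring-atom-pair distance for minimal-distance-style traces.
#' Symmetric in the residue arguments.
#'
#' @param traj an `mdu_trajectory`.
#' @param res_a,res_b author residue numbers of two aromatic residues.
#' @param stride sample every `stride`-th frame (default 1).
#' @param metric `"centroid"` (default) or `"min_atom"`.
#' @return An `mdu_timeseries` (`time_ns`, `value` in Angstrom).
#' @export
pair_distance_series <- function(traj, res_a, res_b, stride = 1L,
                                 metric = c("centroid", "min_atom")) {
  metric <- match.arg(metric)
  topo <- traj$topology
  a <- topo$atoms
  to_resid <- function(rn) {
    r <- unique(a$resid[a$resno == rn])
    if (!length(r)) stop("no residue with author number ", rn)
    r[1]
  }
  ra <- to_resid(res_a); rb <- to_resid(res_b)
  idx <- seq(1L, n_frames(traj), by = stride)
  vals <- vapply(idx, function(i) {
    fr <- traj$coords[[i]]
    if (metric == "centroid") {
      sqrt(sum((ring_centroid(topo, fr, ra) - ring_centroid(topo, fr, rb))^2))
    } else {
      .ring_min_distance(topo, fr, ra, rb)
    }
  }, numeric(1))
  new_timeseries(traj$times[idx], vals, unit = "A")
}

#' Persistence of an aromatic-aromatic interaction
#'
#' Percentage of sampled frames in which the pair distance lies within the
#' aromatic interaction band (closed bounds, default 4.5 to 7.0 A).
#'
#' @inheritParams pair_distance_series
#' @param band length-2 numeric interaction band in Angstrom.
#' @return Percentage in `[0, 100]`.
#' @export
persistence_percentage <- function(traj, res_a, res_b, stride = 1L,
                                   band = AROMATIC_BAND,
                                   metric = c("centroid", "min_atom")) {
  s <- pair_distance_series(traj, res_a, res_b, stride, metric)
  if (!nrow(s)) stop("no sampled frames")
  100 * mean(s$value >= band[1] & s$value <= band[2])
}

# union-find connected components over k nodes given an edge matrix (m x 2)
.components <- function(k, edges) {
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(k), find, integer(1))
}

#' Detect aromatic clusters in one frame
#'
#' Builds the graph whose edges are aromatic pairs with centroid distance
#' inside the interaction band and reports connected components of at least
#' `min_size` members, sorted by decreasing size then lowest residue number.
#' Connectivity is transitive: two rings of a cluster need not themselves be
#' within the band.
#'
#' @param struct the `mdu_structure` topology.
#' @param frame n_atoms x 3 coordinate matrix.
#' @param min_size minimum component size reported (default 3).
#' @param band interaction band in Angstrom (default 4.5 to 7.0).
#' @param include_his treat histidine as aromatic (default FALSE).
#' @return List of integer vectors of author residue numbers, one per cluster.
#' @export
detect_aromatic_clusters <- function(struct, frame, min_size = 3L,
                                     band = AROMATIC_BAND,
                                     include_his = FALSE) {
  aro <- aromatic_residues(struct, include_his)
  k <- nrow(aro)
  if (k < 2) return(list())
  cen <- .aromatic_centroids(struct, frame, aro)
  d <- as.matrix(stats::dist(cen))
  adj <- d >= band[1] & d <= band[2]
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  comp <- .components(k, edges)
  out <- list()
  for (cid in unique(comp)) {
    members <- sort(aro$resno[comp == cid])
    if (length(members) >= min_size) out[[length(out) + 1L]] <- members
  }
  if (!length(out)) return(list())
  ord <- order(-vapply(out, length, integer(1)),
               vapply(out, min, numeric(1)))
  out[ord]
}

#' Detect formation of new aromatic clusters over a trajectory
#'
#' A cluster whose member set is absent at the reference frame and intact
#' (same member set detected) for at least `persistence` consecutive sampled
#' frames is reported, with onset at the first frame of the qualifying run.
#'
#' @param traj an `mdu_trajectory`.
#' @param reference_frame index of the reference frame (default 1).
#' @param stride sample every `stride`-th frame (default 1).
#' @param persistence required consecutive sampled frames (default 5).
#' @param min_size,band,include_his as in [detect_aromatic_clusters()].
#' @return Data frame with `onset_ns`, `onset_index` and `members`
#'   (comma-separated author residue numbers); empty when nothing forms.
#' @export
cluster_formation_events <- function(traj, reference_frame = 1L, stride = 1L,
                                     persistence = 5L, min_size = 3L,
                                     band = AROMATIC_BAND, include_his = FALSE) {
  topo <- traj$topology
  idx <- seq(1L, n_frames(traj), by = stride)
  key <- function(members) paste(members, collapse = ",")
  ref <- detect_aromatic_clusters(topo, traj$coords[[reference_frame]],
                                  min_size, band, include_his)
  ref_keys <- vapply(ref, key, character(1))
  per_frame <- lapply(idx, function(i)
    vapply(detect_aromatic_clusters(topo, traj$coords[[i]], min_size, band,
                                    include_his), key, character(1)))
  all_keys <- setdiff(unique(unlist(per_frame)), ref_keys)
  out <- list()
  for (kk in all_keys) {
    present <- vapply(per_frame, function(v) kk %in% v, logical(1))
    rl <- rle(present)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
    hit <- which(rl$values & rl$lengths >= persistence)
    if (!length(hit)) next
    onset <- starts[hit[1]]
    out[[length(out) + 1L]] <- data.frame(
      onset_ns = traj$times[idx[onset]], onset_index = onset,
      members = kk, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(onset_ns = numeric(), onset_index = integer(),
                      members = character(), stringsAsFactors = FALSE))
  ev <- do.call(rbind, out)
  ev[order(ev$onset_index), , drop = FALSE]
}
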