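# ---- rigid-body superposition ----------------------------------------------

#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation (det = +1) and translation minimizing the RMSD
#' between `mobile` and `reference` coordinates over a selection, via SVD of
#' the cross-covariance matrix.
#'
#' @param mobile n x 3 coordinate matrix to be moved.
#' @param reference n x 3 coordinate matrix held fixed.
#' @param selection optional integer indices of rows used for the fit
#'   (default: all rows). At least 3 non-collinear points are required.
#' @return A list of class `mdu_superposition`: `rotation` (3x3, det +1),
#'   `translation` (length-3), `rmsd` (Angstrom, over the selection after
#'   transform). The fitted transform maps mobile coordinates as
#'   `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3L, ncol(reference) == 3L)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3L) stop("need at least 3 atoms for superposition")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  if (nrow(A) != nrow(B)) stop("selection must have equal atom counts")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinearity check: rank of centered coordinates
  sv_a <- svd(A0, nu = 0, nv = 0)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1))
    stop("degenerate (collinear) selection: superposition is ill-conditioned")
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cb - as.numeric(R %*% ca)
  moved <- A %*% t(R) + matrix(t_vec, nrow(A), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "mdu_superposition")
}

apply_transform <- function(coords, fit) {
  coords %*% t(fit$rotation) + matrix(fit$translation, nrow(coords), 3, byrow = TRUE)
}

#' @export
print.mdu_superposition <- function(x, ...) {
  ax <- rotation_axis_angle(x$rotation)
  cat(sprintf("<mdu_superposition> rmsd %.4f A, rotation %.2f deg\n",
              x$rmsd, ax$angle))
  invisible(x)
}

# ---- RMSD / RMSF ------------------------------------------------------------

new_timeseries <- function(times, values, unit = "") {
  stopifnot(length(times) == length(values))
  structure(data.frame(time_ns = times, value = values),
            unit = unit, class = c("mdu_timeseries", "data.frame"))
}

#' Backbone RMSD time series
#'
#' Each frame is superposed to the reference frame on the selection before
#' the RMSD is computed over the same selection, so rigid-body motion does
#' not contribute.
#'
#' @param traj an `mdu_trajectory`.
#' @param reference_frame index of the reference frame (default 1, time zero).
#' @param selection integer atom indices (default: mainchain atoms).
#' @return An `mdu_timeseries` data frame (`time_ns`, `value` in Angstrom).
#' @export
rmsd_series <- function(traj, reference_frame = 1L, selection = NULL) {
  if (is.null(selection)) selection <- select_atoms(traj$topology, "mainchain")
  if (!length(selection)) stop("empty selection")
  ref <- traj$coords[[reference_frame]]
  vals <- vapply(traj$coords, function(fr)
    kabsch_superpose(fr, ref, selection)$rmsd, numeric(1))
  new_timeseries(traj$times, vals, unit = "A")
}

#' Per-residue RMSF
#'
#' Root-mean-square fluctuation about the time-averaged structure. Frames are
#' first aligned to frame 1 on the selection, averaged, then re-aligned to
#' that average (two-pass). The per-residue value is the mean RMSF of the
#' residue's mainchain atoms within the selection.
#'
#' @param traj an `mdu_trajectory` with at least 2 frames.
#' @param selection integer atom indices (default: mainchain atoms).
#' @return Data frame with `resid` (sequential), `resno` (author) and
#'   `rmsf` (Angstrom); attribute `atom_rmsf` carries the per-atom values.
#' @export
rmsf_per_residue <- function(traj, selection = NULL) {
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  if (is.null(selection)) selection <- select_atoms(traj$topology, "mainchain")
  ref <- traj$coords[[1]]
  aligned <- lapply(traj$coords, function(fr)
    apply_transform(fr, kabsch_superpose(fr, ref, selection))[selection, , drop = FALSE])
  avg <- Reduce(`+`, aligned) / length(aligned)
  # second pass: align each frame's selection onto the average selection coords
  aligned2 <- lapply(traj$coords, function(fr) {
    sub <- fr[selection, , drop = FALSE]
    fit <- kabsch_superpose(sub, avg)
    apply_transform(sub, fit)
  })
  mean2 <- Reduce(`+`, aligned2) / length(aligned2)
  ssq <- Reduce(`+`, lapply(aligned2, function(m) (m - mean2)^2)) / length(aligned2)
  atom_rmsf <- sqrt(rowSums(ssq))
  a <- traj$topology$atoms[selection, , drop = FALSE]
  agg <- stats::aggregate(atom_rmsf, by = list(resid = a$resid), FUN = mean)
  resno <- a$resno[!duplicated(a$resid)][order(unique(a$resid))]
  out <- data.frame(resid = agg$resid,
                    resno = a$resno[match(agg$resid, a$resid)],
                    rmsf = agg$x)
  attr(out, "atom_rmsf") <- atom_rmsf
  out
}

# ---- essential-dynamics PCA -------------------------------------------------

#' Essential-dynamics PCA of a trajectory
#'
#' Frames are superposed to frame 1 on the selection (removing rigid-body
#' modes), then the covariance matrix of the selected atomic coordinates is
#' diagonalized via SVD of the centered frame matrix. Eigenvalues (Angstrom^2)
#' are sorted descending; each eigenvector's sign is fixed so its first
#' nonzero component is positive.
#'
#' @param traj an `mdu_trajectory` with at least 2 frames.
#' @param selection integer atom indices (default: mainchain atoms, the
#'   main chain heavy atoms).
#' @return A list of class `mdu_eigenmodel`: `mean` (3m vector), `values`
#'   (eigenvalues, descending), `vectors` (3m x k orthonormal columns),
#'   `selection`, `trace` (total coordinate variance).
#' @export
pca_essential <- function(traj, selection = NULL) {
  if (n_frames(traj) < 2L) stop("PCA needs at least 2 frames")
  if (is.null(selection)) selection <- select_atoms(traj$topology, "mainchain")
  X <- .aligned_frame_matrix(traj, selection)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  nf <- nrow(X)
  values <- sv$d^2 / (nf - 1)
  vectors <- sv$v
  keep <- seq_len(min(nf - 1L, ncol(vectors)))
  values <- values[keep]
  vectors <- vectors[, keep, drop = FALSE]
  # sign convention: first component exceeding tolerance is positive
  for (j in seq_len(ncol(vectors))) {
    nz <- which(abs(vectors[, j]) > 1e-10)
    if (length(nz) && vectors[nz[1], j] < 0) vectors[, j] <- -vectors[, j]
  }
  structure(list(mean = mu, values = values, vectors = vectors,
                 selection = selection, trace = sum(Xc^2) / (nf - 1)),
            class = "mdu_eigenmodel")
}

.aligned_frame_matrix <- function(traj, selection) {
  ref <- traj$coords[[1]]
  rows <- lapply(traj$coords, function(fr) {
    fit <- kabsch_superpose(fr, ref, selection)
    as.numeric(t(apply_transform(fr, fit)[selection, , drop = FALSE]))
  })
  do.call(rbind, rows)
}

#' @export
print.mdu_eigenmodel <- function(x, ...) {
  cat(sprintf("<mdu_eigenmodel> %d modes over %d coordinates; lambda1 = %.4g A^2 (%.1f%% of trace)\n",
              length(x$values), length(x$mean), x$values[1],
              100 * x$values[1] / max(x$trace, .Machine$double.eps)))
  invisible(x)
}

#' Project trajectory frames onto essential modes
#'
#' @param traj an `mdu_trajectory`.
#' @param model an `mdu_eigenmodel` built from a compatible selection.
#' @param k number of modes to project onto (default 2).
#' @return Data frame with `time_ns` and columns `pc1..pck`.
#' @export
project_frames <- function(traj, model, k = 2L) {
  stopifnot(inherits(model, "mdu_eigenmodel"))
  if (k > ncol(model$vectors)) stop("k exceeds the number of available modes")
  X <- .aligned_frame_matrix(traj, model$selection)
  if (ncol(X) != length(model$mean)) stop("eigenmodel selection is incompatible with trajectory")
  P <- sweep(X, 2, model$mean) %*% model$vectors[, seq_len(k), drop = FALSE]
  out <- data.frame(time_ns = traj$times)
  for (j in seq_len(k)) out[[paste0("pc", j)]] <- P[, j]
  out
}

# ---- interdomain rotation: closure vs twist ---------------------------------

rotation_axis_angle <- function(R) {
  tr <- sum(diag(R))
  cosang <- max(-1, min(1, (tr - 1) / 2))
  angle <- acos(cosang) * 180 / pi
  if (angle < 1e-9) return(list(axis = c(1, 0, 0), angle = 0))
  if (angle > 179.999) {
    # axis from eigenvector of R with eigenvalue +1
    ev <- eigen(R)
    i <- which.min(abs(ev$values - 1))
    axis <- Re(ev$vectors[, i])
  } else {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  }
  axis <- axis / sqrt(sum(axis^2))
  list(axis = axis, angle = angle)
}

#' Interdomain rotation decomposed into closure and twist
#'
#' The frame is superposed to the reference on the fixed domain's mainchain;
#' the residual Kabsch rotation of the moving domain gives the rotation axis
#' and angle. With `d` the unit vector between the two domains' mainchain
#' centroids in the reference, the squared projection of the axis on `d`
#' splits the motion: `percent_twist = 100 (axis . d)^2` (rotation about the
#' interdomain axis) and `percent_closure = 100 - percent_twist` (hinge-like
#' closure). The hinge point reported is the moving-domain centroid projected
#' onto the screw axis.
#'
#' @param frame n x 3 coordinates of the frame to analyse.
#' @param reference_frame n x 3 reference coordinates (same topology).
#' @param topology the `mdu_structure` topology.
#' @param fixed_domain,moving_domain region names of the two domains
#'   (must be disjoint, each with at least 3 residues).
#' @param regions an `mdu_regions` map resolving the domain names.
#' @return A list of class `mdu_rotation`: `axis` (unit vector), `angle`
#'   (degrees, 0..180), `hinge_point` (Angstrom), `percent_closure`,
#'   `percent_twist` (summing to 100), `label` ("closure" or "twist").
#' @export
domain_rotation <- function(frame, reference_frame, topology,
                            fixed_domain, moving_domain, regions) {
  rf <- region_range(regions, fixed_domain)
  rm_ <- region_range(regions, moving_domain)
  if (rf[1] <= rm_[2] && rm_[1] <= rf[2])
    stop("fixed and moving domains must be disjoint")
  sel_fix <- select_atoms(topology, "mainchain", region = fixed_domain, regions = regions)
  sel_mov <- select_atoms(topology, "mainchain", region = moving_domain, regions = regions)
  if (length(unique(topology$atoms$resid[sel_fix])) < 3L ||
      length(unique(topology$atoms$resid[sel_mov])) < 3L)
    stop("each domain needs at least 3 residues")
  fit_fix <- kabsch_superpose(frame, reference_frame, sel_fix)
  moved <- apply_transform(frame, fit_fix)
  fit_mov <- kabsch_superpose(reference_frame[sel_mov, , drop = FALSE],
                              moved[sel_mov, , drop = FALSE])
  aa <- rotation_axis_angle(fit_mov$rotation)
  c_fix <- colMeans(reference_frame[sel_fix, , drop = FALSE])
  c_mov <- colMeans(reference_frame[sel_mov, , drop = FALSE])
  d <- c_mov - c_fix
  d <- d / sqrt(sum(d^2))
  pct_twist <- 100 * sum(aa$axis * d)^2
  pct_closure <- 100 - pct_twist
  hinge <- .screw_axis_point(fit_mov$rotation, fit_mov$translation, aa$axis, c_mov)
  structure(list(axis = aa$axis, angle = aa$angle, hinge_point = hinge,
                 percent_closure = pct_closure, percent_twist = pct_twist,
                 label = if (pct_closure >= 50) "closure" else "twist"),
            class = "mdu_rotation")
}

# point on the screw axis of x -> Rx + t closest to the centroid c0
.screw_axis_point <- function(R, t_vec, axis, c0) {
  if (sum(abs(R - diag(3))) < 1e-12) return(c0)
  t_perp <- t_vec - sum(t_vec * axis) * axis
  M <- diag(3) - R
  sv <- svd(M)
  dinv <- ifelse(sv$d > 1e-9, 1 / sv$d, 0)
  p0 <- as.numeric(sv$v %*% (dinv * crossprod(sv$u, t_perp)))
  p0 + sum((c0 - p0) * axis) * axis
}

#' @export
print.mdu_rotation <- function(x, ...) {
  cat(sprintf("<mdu_rotation> %.3f deg about [%.3f %.3f %.3f]; %.1f%% closure / %.1f%% twist (%s)\n",
              x$angle, x$axis[1], x$axis[2], x$axis[3],
              x$percent_closure, x$percent_twist, x$label))
  invisible(x)
}

#' Fraction of simulation time in closure vs twist motion
#'
#' Every `stride`-th frame is compared with frame 1; frames rotating by less
#' than `angle_floor` degrees carry no net interdomain rotation and are
#' excluded (reported separately), the rest are labelled closure or twist by
#' the dominant component.
#'
#' @param traj an `mdu_trajectory`.
#' @param fixed_domain,moving_domain,regions as in [domain_rotation()].
#' @param stride sample every `stride`-th frame (>= 1).
#' @param angle_floor rotation angle (degrees) below which a frame is "no net
#'   rotation" (default 1.0).
#' @return A list: `fraction_closure` and `fraction_twist` (percent of
#'   classified frames, summing to 100, `NA` with a warning when no frame
#'   exceeds the floor), `n_below_floor`, and `frames` (per-sampled-frame
#'   data frame: time_ns, angle_deg, pct_closure, label).
#' @export
motion_fraction <- function(traj, fixed_domain, moving_domain, regions,
                            stride = 1L, angle_floor = 1.0) {
  if (stride < 1L) stop("stride must be >= 1")
  idx <- seq(1L, n_frames(traj), by = stride)
  idx <- idx[idx != 1L]
  ref <- traj$coords[[1]]
  rows <- lapply(idx, function(i) {
    rot <- domain_rotation(traj$coords[[i]], ref, traj$topology,
                           fixed_domain, moving_domain, regions)
    data.frame(time_ns = traj$times[i], angle_deg = rot$angle,
               pct_closure = rot$percent_closure,
               label = if (rot$angle < angle_floor) "none" else rot$label,
               stringsAsFactors = FALSE)
  })
  frames <- do.call(rbind, rows)
  classified <- frames$label != "none"
  n_below <- sum(!classified)
  if (!any(classified)) {
    warning("no frame exceeds the rotation angle floor; motion fractions undefined")
    return(list(fraction_closure = NA_real_, fraction_twist = NA_real_,
                n_below_floor = n_below, frames = frames))
  }
  fc <- 100 * mean(frames$label[classified] == "closure")
  list(fraction_closure = fc, fraction_twist = 100 - fc,
       n_below_floor = n_below, frames = frames)
}
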