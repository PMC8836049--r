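# ---- idealized builders -------------------------------------------------------

# internal-coordinate (NeRF) placement of atom D given A-B-C and
# bond |CD|, angle B-C-D (deg), dihedral A-B-C-D (deg)
.place_atom <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal mainchain from backbone dihedrals
#'
#' Constructs N, CA, C, O coordinates for a chain of `n` residues at standard
#' bond lengths and angles with the given phi/psi (omega fixed at 180). The
#' alpha-helix defaults (phi -57, psi -47) give a geometry whose i -> i+4
#' backbone hydrogen bonds satisfy the Kabsch-Sander criterion.
#'
#' @param n number of residues (>= 3).
#' @param phi,psi backbone dihedrals in degrees (recycled along the chain).
#' @param resname residue name used for all residues (default "GLY").
#' @return An `mdu_structure` with 4 atoms per residue.
#' @export
build_ideal_helix <- function(n, phi = -57, psi = -47, resname = "GLY") {
  stopifnot(n >= 3)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7; a_CACO <- 120.8
  N <- matrix(0, n, 3); CA <- matrix(0, n, 3); C <- matrix(0, n, 3); O <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_NCA, 0, 0)
  ang <- a_NCAC * pi / 180
  C[1, ] <- CA[1, ] + b_CAC * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], b_CN, a_CACN, psi[i - 1])
      CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], b_NCA, a_CNCA, 180)
      C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ], b_CAC, a_NCAC, phi[i])
    }
    # carbonyl O anti to the next amide N (dihedral psi - 180 about N-CA-C)
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], b_CO, a_CACO, psi[i] - 180)
  }
  atoms <- data.frame(
    serial = seq_len(4L * n),
    name = rep(c("N", "CA", "C", "O"), n),
    element = rep(c("N", "C", "C", "O"), n),
    resname = resname, chain = "A",
    resno = rep(seq_len(n), each = 4L),
    resid = rep(seq_len(n), each = 4L),
    stringsAsFactors = FALSE)
  xyz <- matrix(0, 4L * n, 3)
  xyz[seq(1, 4 * n, 4), ] <- N
  xyz[seq(2, 4 * n, 4), ] <- CA
  xyz[seq(3, 4 * n, 4), ] <- C
  xyz[seq(4, 4 * n, 4), ] <- O
  new_structure(atoms, list(xyz))
}

# one residue's mainchain in the analytic flat-sheet geometry
# xc: CA x; y0: strand baseline y; dx: chain direction (+-1); sgn: carbonyl side
.sheet_residue <- function(xc, y0, dx, sgn) {
  rbind(N = c(xc - 1.2 * dx, y0 + 0.32 * sgn, 0),
        CA = c(xc, y0, 0),
        C = c(xc + 1.2 * dx, y0 + 0.40 * sgn, 0),
        O = c(xc + 1.2 * dx, y0 + 1.63 * sgn, 0))
}

.ring_template <- function(resname) {
  nm <- AROMATIC_RING_ATOMS[[resname]]
  k <- length(nm)
  radius <- c(PHE = 1.39, TYR = 1.39, TRP = 1.60, HIS = 1.35)[[resname]]
  th <- 2 * pi * (seq_len(k) - 1) / k
  xyz <- cbind(radius * cos(th), 0, radius * sin(th))
  elem <- ifelse(substr(nm, 1, 1) == "N", "N", "C")
  list(names = nm, xyz = xyz, element = elem)
}

#' Build an idealized two-domain antiparallel beta-sandwich
#'
#' Emulates the topology of a two-domain Greek-key beta-sandwich protein
#' (such as gammaD-crystallin) at desk scale: each domain is a flat
#' antiparallel sheet of `n_strands_per_domain` strands of `strand_length`
#' residues, built analytically so that the inter-strand ladder spacing is
#' 4.85 A (CA-CA) and the backbone N-H...O=C geometry of partnered rungs is
#' exactly linear with r_ON = 2.9 A, i.e. the strands satisfy the
#' Kabsch-Sander hydrogen-bond criterion by construction. Strands are not
#' joined by loop residues; the CA-CA jump between consecutive strands acts
#' as a chain break for the hydrogen-bond pattern search. Designated residues
#' carry idealized aromatic ring atoms (ring centroid 2.8 A above the CA in
#' z). Domain 2 is offset in z by `domain_gap`.
#'
#' A region map naming every strand (`d1_s1` ...) and both domains (`N_td`,
#' `C_td`) is returned alongside the structure.
#'
#' @param n_strands_per_domain strands per domain (default 4).
#' @param strand_length residues per strand (>= 4; default 7). Odd lengths
#'   place both strand termini on non-hydrogen-bonded rungs of the
#'   antiparallel ladder, so every interior residue is strand-assigned; even
#'   lengths lose the terminal rung (the partner strand's chain-start residue
#'   has no amide H).
#' @param aromatic_positions integer vector of residue positions (sequential,
#'   over the whole chain) to decorate with aromatic rings.
#' @param aromatic_types residue types for those positions (recycled;
#'   default "TYR").
#' @param domain_gap z offset of the second domain in Angstrom (default 16).
#' @return List with `structure` (`mdu_structure`) and `regions`
#'   (`mdu_regions`).
#' @export
build_toy_two_domain <- function(n_strands_per_domain = 4L, strand_length = 7L,
                                 aromatic_positions = integer(),
                                 aromatic_types = "TYR", domain_gap = 16) {
  if (strand_length < 4L) stop("infeasible geometry: strand_length must be >= 4")
  if (n_strands_per_domain < 2L) stop("infeasible geometry: need >= 2 strands per domain")
  S <- n_strands_per_domain; L <- strand_length
  n_res <- 2L * S * L
  if (length(aromatic_positions)) {
    if (any(aromatic_positions < 1 | aromatic_positions > n_res))
      stop("aromatic position(s) outside the chain")
    aromatic_types <- rep_len(aromatic_types, length(aromatic_positions))
    if (!all(aromatic_types %in% names(AROMATIC_RING_ATOMS)))
      stop("aromatic types must be PHE, TYR, TRP or HIS")
  }
  aro_of <- stats::setNames(aromatic_types, aromatic_positions)

  rows <- list(); coords <- list()
  res <- 0L
  region_rows <- list()
  for (d in 1:2) {
    z0 <- (d - 1) * domain_gap
    dom_start <- res + 1L
    for (s in seq_len(S)) {
      strand_start <- res + 1L
      dx <- if (s %% 2 == 1) 1 else -1
      y0 <- (s - 1) * 4.85
      for (r in seq_len(L)) {
        res <- res + 1L
        xi <- if (dx > 0) r else L + 1L - r   # x column index
        xc <- 3.5 * xi
        sgn <- (if (xi %% 2 == 0) 1 else -1) * (if (s %% 2 == 1) 1 else -1)
        mc <- .sheet_residue(xc, y0, dx, sgn)
        mc[, 3] <- mc[, 3] + z0
        rname <- "GLY"; extra <- NULL
        key <- as.character(res)
        if (key %in% names(aro_of)) {
          rname <- aro_of[[key]]
          tmpl <- .ring_template(rname)
          ring <- sweep(tmpl$xyz, 2, c(xc, y0, z0 + 2.8), `+`)
          extra <- list(names = tmpl$names, xyz = ring, element = tmpl$element)
        }
        nms <- c(rownames(mc), extra$names)
        elems <- c("N", "C", "C", "O", extra$element)
        xyz <- rbind(mc, extra$xyz)
        rows[[res]] <- data.frame(
          serial = 0L, name = nms, element = elems, resname = rname,
          chain = "A", resno = res, resid = res, stringsAsFactors = FALSE)
        coords[[res]] <- xyz
      }
      region_rows[[length(region_rows) + 1L]] <- data.frame(
        name = sprintf("d%d_s%d", d, s), start = strand_start, end = res,
        label = sprintf("domain %d strand %d", d, s), stringsAsFactors = FALSE)
    }
    region_rows[[length(region_rows) + 1L]] <- data.frame(
      name = if (d == 1) "N_td" else "C_td", start = dom_start, end = res,
      label = sprintf("domain %d", d), stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  xyz <- do.call(rbind, coords)
  rownames(xyz) <- NULL
  list(structure = new_structure(atoms, list(xyz)),
       regions = new_regions(do.call(rbind, region_rows)))
}

# ---- unfolding scripts ---------------------------------------------------------

#' Define a scripted synthetic-trajectory protocol
#'
#' The script fixes everything about a synthetic trajectory: frame count and
#' spacing, isotropic Gaussian coordinate noise, ramped rigid detachments of
#' named regions, a rigid interdomain rotation with a chosen twist/closure
#' mix, and aromatic cluster-formation events. Given the same seed the
#' resulting trajectory is bit-identical.
#'
#' @param seed integer RNG seed.
#' @param n_frames number of frames.
#' @param dt_ns frame spacing in ns (default 0.25).
#' @param sigma isotropic Gaussian noise s.d. per coordinate, Angstrom
#'   (default 0).
#' @param detachments list of `list(region =, onset =, displacement = c(x,y,z),
#'   ramp =)`; `onset` is a frame index, displacement in Angstrom is reached
#'   linearly over `ramp` frames starting at the onset frame.
#' @param rotations list of `list(moving_domain =, fixed_domain =,
#'   angle_deg =, twist_fraction =, axis = NULL)`; the rotation ramps linearly
#'   from 0 at frame 1 to `angle_deg` at the last frame, about an axis through
#'   the moving domain's centroid. When `axis` is `NULL` it is built from
#'   `twist_fraction` in `[0, 1]`: the squared projection of the axis onto the
#'   interdomain unit vector equals `twist_fraction`.
#' @param cluster_events list of `list(residues = c(...), onset =, distance =)`;
#'   from the onset frame the named residues (author numbers, at most 4) are
#'   rigidly moved so their ring centroids sit at the vertices of a regular
#'   simplex with edge `distance` Angstrom.
#' @return A list of class `mdu_script`.
#' @export
unfolding_script <- function(seed = 1L, n_frames = 100L, dt_ns = 0.25,
                             sigma = 0, detachments = list(),
                             rotations = list(), cluster_events = list()) {
  stopifnot(n_frames >= 1, sigma >= 0, dt_ns > 0)
  chk_onset <- function(o) if (o < 1 || o > n_frames)
    stop("script error: onset frame ", o, " outside 1..", n_frames)
  for (d in detachments) {
    chk_onset(d$onset)
    if (length(d$displacement) != 3) stop("script error: displacement must be length 3")
    if (is.null(d$ramp) || d$ramp < 1) stop("script error: ramp must be >= 1 frame")
  }
  for (r in rotations) {
    if (!is.null(r$twist_fraction) &&
        (r$twist_fraction < 0 || r$twist_fraction > 1))
      stop("script error: twist_fraction must lie in [0, 1]")
  }
  for (cl in cluster_events) {
    chk_onset(cl$onset)
    if (length(cl$residues) < 2 || length(cl$residues) > 4)
      stop("script error: cluster events support 2..4 residues")
    if (cl$distance <= 0) stop("script error: cluster distance must be positive")
  }
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 dt_ns = dt_ns, sigma = sigma, detachments = detachments,
                 rotations = rotations, cluster_events = cluster_events),
            class = "mdu_script")
}

#' Serialize / restore an unfolding script as JSON
#'
#' @param script an `mdu_script`.
#' @param path file path.
#' @return `write_script` returns `path` invisibly; `read_script` the script.
#' @export
write_script <- function(script, path) {
  jsonlite::write_json(unclass(script), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_script
#' @export
read_script <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  fix_list <- function(l) lapply(l, function(e) {
    e <- as.list(e)
    for (f in c("displacement", "residues", "axis"))
      if (!is.null(e[[f]])) e[[f]] <- unlist(e[[f]])
    e
  })
  unfolding_script(seed = x$seed, n_frames = x$n_frames, dt_ns = x$dt_ns,
                   sigma = x$sigma, detachments = fix_list(x$detachments),
                   rotations = fix_list(x$rotations),
                   cluster_events = fix_list(x$cluster_events))
}

.rotation_matrix <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# regular simplex vertex coordinates (k points, unit edge), centered at origin
.simplex_vertices <- function(k) {
  v <- switch(as.character(k),
    "2" = rbind(c(0, 0, 0), c(1, 0, 0)),
    "3" = rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
    "4" = rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                c(0.5, sqrt(3) / 6, sqrt(6) / 3)),
    stop("script error: cluster events support 2..4 residues"))
  sweep(v, 2, colMeans(v))
}

#' Simulate a scripted trajectory with known ground truth
#'
#' Builds frames as base coordinates + scripted rigid rotation + ramped
#' detachments + cluster placements + isotropic Gaussian noise, and returns
#' the true event onsets, rotation decomposition and cluster memberships the
#' analysis modules should recover.
#'
#' @param struct the base `mdu_structure` (single model).
#' @param script an `mdu_script`.
#' @param regions an `mdu_regions` map resolving the script's region names.
#' @return List with `trajectory` (`mdu_trajectory`) and `ground_truth`
#'   (list: `detachments`, `rotations` with per-frame angles, `clusters`).
#' @export
simulate_trajectory <- function(struct, script, regions) {
  stopifnot(inherits(struct, "mdu_structure"), inherits(script, "mdu_script"))
  base <- struct$models[[1]]
  nf <- script$n_frames
  a <- struct$atoms

  atoms_of_region <- function(name) {
    rng <- region_range(regions, name)
    which(a$resno >= rng[1] & a$resno <= rng[2])
  }

  # reject scripts that detach and rotate the same atoms
  rot_atoms <- unique(unlist(lapply(script$rotations,
                                    function(r) atoms_of_region(r$moving_domain))))
  for (d in script$detachments) {
    if (length(intersect(atoms_of_region(d$region), rot_atoms)))
      stop("script error: region '", d$region,
           "' is both detached and part of a rotating domain")
  }

  rot_info <- lapply(script$rotations, function(r) {
    mov <- atoms_of_region(r$moving_domain)
    mc_mov <- intersect(mov, select_atoms(struct, "mainchain"))
    fix <- atoms_of_region(r$fixed_domain)
    mc_fix <- intersect(fix, select_atoms(struct, "mainchain"))
    c_mov <- colMeans(base[mc_mov, , drop = FALSE])
    c_fix <- colMeans(base[mc_fix, , drop = FALSE])
    d_vec <- c_mov - c_fix; d_vec <- d_vec / sqrt(sum(d_vec^2))
    if (!is.null(r$axis)) {
      axis <- r$axis / sqrt(sum(r$axis^2))
      tf <- sum(axis * d_vec)^2
    } else {
      tf <- r$twist_fraction
      e <- c(0, 0, 1)
      if (abs(sum(e * d_vec)) > 0.9) e <- c(0, 1, 0)
      perp <- e - sum(e * d_vec) * d_vec
      perp <- perp / sqrt(sum(perp^2))
      axis <- sqrt(tf) * d_vec + sqrt(1 - tf) * perp
      axis <- axis / sqrt(sum(axis^2))
    }
    list(atoms = mov, center = c_mov, axis = axis, angle = r$angle_deg,
         twist_fraction = tf, moving = r$moving_domain, fixed = r$fixed_domain,
         d_vec = d_vec)
  })

  clus_info <- lapply(script$cluster_events, function(cl) {
    res_atoms <- lapply(cl$residues, function(rn) which(a$resno == rn))
    cents <- t(vapply(cl$residues, function(rn)
      ring_centroid(struct, base, unique(a$resid[a$resno == rn])[1]), numeric(3)))
    mid <- colMeans(cents)
    targets <- sweep(.simplex_vertices(length(cl$residues)) * cl$distance, 2, mid, `+`)
    shifts <- targets - cents
    list(atoms = res_atoms, shifts = shifts, onset = cl$onset,
         residues = cl$residues, distance = cl$distance)
  })

  set.seed(script$seed)
  frames <- vector("list", nf)
  rot_angles <- matrix(0, nf, max(1L, length(rot_info)))
  for (f in seq_len(nf)) {
    X <- base
    for (ri in seq_along(rot_info)) {
      info <- rot_info[[ri]]
      ang <- if (nf == 1) 0 else info$angle * (f - 1) / (nf - 1)
      rot_angles[f, ri] <- ang
      if (ang != 0) {
        R <- .rotation_matrix(info$axis, ang)
        sub <- sweep(X[info$atoms, , drop = FALSE], 2, info$center)
        X[info$atoms, ] <- sweep(sub %*% t(R), 2, info$center, `+`)
      }
    }
    for (d in script$detachments) {
      if (f >= d$onset) {
        scale <- min(1, (f - d$onset + 1) / d$ramp)
        idx <- atoms_of_region(d$region)
        X[idx, ] <- sweep(X[idx, , drop = FALSE], 2, d$displacement * scale, `+`)
      }
    }
    for (cl in clus_info) {
      if (f >= cl$onset) {
        # absolute placement (base + shift), overriding any rotation of the
        # same residues so the scripted cluster geometry is exact
        for (m in seq_along(cl$atoms))
          X[cl$atoms[[m]], ] <- sweep(base[cl$atoms[[m]], , drop = FALSE], 2,
                                      cl$shifts[m, ], `+`)
      }
    }
    if (script$sigma > 0)
      X <- X + matrix(stats::rnorm(length(X), sd = script$sigma), nrow(X), 3)
    frames[[f]] <- X
  }
  traj <- structure(list(topology = new_structure(a, list(base)),
                         times = (seq_len(nf) - 1) * script$dt_ns,
                         coords = frames),
                    class = "mdu_trajectory")
  gt <- list(
    detachments = if (length(script$detachments)) data.frame(
      region = vapply(script$detachments, `[[`, character(1), "region"),
      onset_frame = vapply(script$detachments, `[[`, numeric(1), "onset"),
      onset_ns = (vapply(script$detachments, `[[`, numeric(1), "onset") - 1) * script$dt_ns,
      stringsAsFactors = FALSE) else NULL,
    rotations = if (length(rot_info)) list(
      axis = lapply(rot_info, `[[`, "axis"),
      twist_fraction = vapply(rot_info, `[[`, numeric(1), "twist_fraction"),
      pct_twist = 100 * vapply(rot_info, `[[`, numeric(1), "twist_fraction"),
      total_angle = vapply(rot_info, `[[`, numeric(1), "angle"),
      per_frame_angle = rot_angles[, seq_along(rot_info), drop = FALSE]) else NULL,
    clusters = if (length(clus_info)) data.frame(
      members = vapply(clus_info, function(cl) paste(sort(cl$residues), collapse = ","),
                       character(1)),
      onset_frame = vapply(clus_info, function(cl) as.numeric(cl$onset), numeric(1)),
      distance = vapply(clus_info, function(cl) cl$distance, numeric(1)),
      stringsAsFactors = FALSE) else NULL,
    seed = script$seed, sigma = script$sigma)
  list(trajectory = traj, ground_truth = gt)
}

# ---- ion arithmetic ------------------------------------------------------------

AVOGADRO <- 6.02214076e23

#' Ion count for a salt concentration in a cubic box
#'
#' Number of ions of one species needed to realize a salt concentration in a
#' cubic simulation box: `round(c * N_A * V)` with the concentration converted
#' to mol/L and the box volume to liters. At 136.7 mM in a 7.0 nm box this
#' gives the 28 sodium + 28 chloride ions of a physiological-saline setup.
#'
#' @param concentration_mM salt concentration in mmol/L (>= 0).
#' @param box_edge_nm cubic box edge in nm (> 0).
#' @return Integer ion count per species.
#' @export
ion_pair_count <- function(concentration_mM, box_edge_nm) {
  if (concentration_mM < 0) stop("concentration must be non-negative")
  if (box_edge_nm <= 0) stop("box edge must be positive")
  vol_L <- (box_edge_nm * 1e-8)^3  # nm -> dm, dm^3 = L
  as.integer(round(concentration_mM * 1e-3 * AVOGADRO * vol_L))
}

# ---- presets -------------------------------------------------------------------

#' Preset synthetic systems emulating the study's unfolding phenomenology
#'
#' `"gdnhcl_like"` scripts three sequential edge-strand detachments at 15, 35
#' and 50 ns (aliased to the motif vocabulary: motif2_beta3, then
#' motif1_beta3, then motif2_beta2), mirroring a strong-denaturant unfolding
#' order. `"urea_like"` scripts one detachment plus the formation of a new
#' 4-member aromatic cluster at 55 ns and a twist-dominant interdomain
#' rotation. `"static"` leaves the structure untouched (noise-free).
#'
#' @param name preset name.
#' @param n_frames number of frames (default 100).
#' @param dt_ns frame spacing in ns (default 1).
#' @param seed RNG seed (default 1).
#' @param sigma coordinate noise s.d. in Angstrom (default 0.1, which under
#'   independent per-atom noise reproduces realistic relative backbone
#'   geometry fluctuations; 0 for `"static"`).
#' @return List with `structure`, `regions` (strand regions plus motif
#'   aliases), `script` and `name`.
#' @export
preset_unfolding <- function(name = c("gdnhcl_like", "urea_like", "static"),
                             n_frames = 100L, dt_ns = 1, seed = 1L,
                             sigma = 0.1) {
  name <- match.arg(name)
  # mid-strand positions chosen so no 3+ cluster exists at the reference:
  # in-band native pairs are 18-25 (d1_s3/s4) and 32-39 (d2_s1/s2) only
  aro_pos <- c(4, 18, 25, 32, 39, 53)
  toy <- build_toy_two_domain(4L, 7L, aromatic_positions = aro_pos,
                              aromatic_types = c("TYR", "TYR", "TRP", "TYR",
                                                 "TYR", "TYR"))
  regions <- toy$regions
  alias <- function(nm, target, label) {
    rng <- region_range(regions, target)
    data.frame(name = nm, start = rng[1], end = rng[2], label = label,
               stringsAsFactors = FALSE)
  }
  regions <- new_regions(rbind(as.data.frame(regions),
    alias("motif2_beta3", "d1_s1", "first strand lost"),
    alias("motif1_beta3", "d1_s4", "second strand lost"),
    alias("motif2_beta2", "d2_s1", "third strand lost")))
  at_ns <- function(t) as.integer(round(t / dt_ns)) + 1L
  script <- switch(name,
    static = unfolding_script(seed = seed, n_frames = n_frames, dt_ns = dt_ns,
                              sigma = 0),
    gdnhcl_like = unfolding_script(
      seed = seed, n_frames = n_frames, dt_ns = dt_ns, sigma = sigma,
      detachments = list(
        list(region = "motif2_beta3", onset = at_ns(15),
             displacement = c(0, -15, 0), ramp = 5L),
        list(region = "motif1_beta3", onset = at_ns(35),
             displacement = c(0, 15, 0), ramp = 5L),
        list(region = "motif2_beta2", onset = at_ns(50),
             displacement = c(0, -15, 0), ramp = 5L))),
    urea_like = unfolding_script(
      seed = seed, n_frames = n_frames, dt_ns = dt_ns, sigma = sigma,
      detachments = list(
        list(region = "motif2_beta3", onset = at_ns(15),
             displacement = c(0, -15, 0), ramp = 5L)),
      rotations = list(
        list(moving_domain = "C_td", fixed_domain = "N_td",
             angle_deg = 12, twist_fraction = 0.8)),
      cluster_events = list(
        list(residues = c(18, 25, 32, 39), onset = at_ns(55), distance = 5.5))))
  list(structure = toy$structure, regions = regions, script = script,
       name = name)
}
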