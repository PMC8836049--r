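# ---- Kabsch-Sander hydrogen-bond energy --------------------------------------

KS_COUPLING <- 0.084 * 332  # kcal/mol * Angstrom, partial charges 0.42 * 0.20

#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic model of an N-H...O=C hydrogen bond:
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol, with all
#' distances in Angstrom. A hydrogen bond is called when `E < -0.5` kcal/mol.
#'
#' @param n,h donor backbone N and amide H coordinates (length-3).
#' @param c,o acceptor backbone C and carbonyl O coordinates (length-3).
#' @return Energy in kcal/mol.
#' @seealso [reconstruct_amide_h()] for files without hydrogens.
#' @export
ks_hbond_energy <- function(n, h, c, o) {
  r_on <- sqrt(sum((o - n)^2))
  r_ch <- sqrt(sum((c - h)^2))
  r_oh <- sqrt(sum((o - h)^2))
  r_cn <- sqrt(sum((c - n)^2))
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5)
    stop("atomic clash: interatomic distance below 0.5 A")
  KS_COUPLING * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

#' Reconstruct the backbone amide hydrogen
#'
#' For structures without hydrogens the amide H of residue i is placed 1.0 A
#' from its N, anti-parallel to the preceding residue's C=O bond vector
#' (the DSSP convention).
#'
#' @param n backbone N of the residue (length-3).
#' @param c_prev,o_prev backbone C and O of the preceding residue.
#' @return Length-3 coordinates of the reconstructed H.
#' @export
reconstruct_amide_h <- function(n, c_prev, o_prev) {
  v <- c_prev - o_prev
  n + v / sqrt(sum(v^2))
}

# ---- per-frame assignment ----------------------------------------------------

KS_HBOND_CUTOFF <- -0.5    # kcal/mol
CHAIN_BREAK_CA <- 4.5      # Angstrom
CA_PREFILTER <- 9.0        # Angstrom, donor/acceptor CA distance prefilter

# per-residue mainchain coordinate bookkeeping for one frame
.mainchain_table <- function(frame, topology) {
  a <- topology$atoms
  resids <- sort(unique(a$resid))
  nr <- length(resids)
  get_idx <- function(nm) {
    idx <- rep(NA_integer_, nr)
    sel <- which(a$name == nm & !(a$element %in% c("H", "D")))
    idx[match(a$resid[sel], resids)] <- sel
    idx
  }
  iN <- get_idx("N"); iCA <- get_idx("CA"); iC <- get_idx("C"); iO <- get_idx("O")
  coord <- function(idx) {
    out <- matrix(NA_real_, nr, 3)
    ok <- !is.na(idx)
    out[ok, ] <- frame[idx[ok], , drop = FALSE]
    out
  }
  list(resids = resids, nr = nr,
       chain = a$chain[match(resids, a$resid)],
       resname = a$resname[match(resids, a$resid)],
       N = coord(iN), CA = coord(iCA), C = coord(iC), O = coord(iO))
}

# logical: residue i+1 follows residue i without a chain break
.connected <- function(mc) {
  nr <- mc$nr
  if (nr < 2) return(logical(0))
  dca <- sqrt(rowSums((mc$CA[-1, , drop = FALSE] - mc$CA[-nr, , drop = FALSE])^2))
  same_chain <- mc$chain[-1] == mc$chain[-nr]
  ok <- same_chain & !is.na(dca) & dca <= CHAIN_BREAK_CA
  ok & !is.na(ok)
}

# donor->acceptor hydrogen-bond matrix for one frame
.ks_hbond_matrix <- function(mc) {
  nr <- mc$nr
  conn <- .connected(mc)
  # amide H for residues 2..nr with a connected predecessor; PRO has none
  H <- matrix(NA_real_, nr, 3)
  for (i in seq_len(nr)[-1]) {
    if (!conn[i - 1]) next
    if (mc$resname[i] == "PRO") next
    if (anyNA(mc$N[i, ]) || anyNA(mc$C[i - 1, ]) || anyNA(mc$O[i - 1, ])) next
    H[i, ] <- reconstruct_amide_h(mc$N[i, ], mc$C[i - 1, ], mc$O[i - 1, ])
  }
  donor_ok <- !is.na(H[, 1]) & !is.na(mc$N[, 1])
  acc_ok <- !is.na(mc$C[, 1]) & !is.na(mc$O[, 1])
  hb <- matrix(FALSE, nr, nr)
  if (!any(donor_ok) || !any(acc_ok)) return(hb)
  ca_ok <- !is.na(mc$CA[, 1])
  di <- which(donor_ok & ca_ok)
  aj <- which(acc_ok & ca_ok)
  # CA-CA prefilter (the 1/r terms are far above -0.5 beyond 9 A)
  d2 <- outer(rowSums(mc$CA[di, , drop = FALSE]^2),
              rowSums(mc$CA[aj, , drop = FALSE]^2), `+`) -
    2 * tcrossprod(mc$CA[di, , drop = FALSE], mc$CA[aj, , drop = FALSE])
  cand <- which(d2 <= CA_PREFILTER^2, arr.ind = TRUE)
  for (k in seq_len(nrow(cand))) {
    i <- di[cand[k, 1]]; j <- aj[cand[k, 2]]
    if (abs(i - j) < 2) next
    # clashing (nonphysical) geometry cannot form a hydrogen bond
    e <- tryCatch(ks_hbond_energy(mc$N[i, ], H[i, ], mc$C[j, ], mc$O[j, ]),
                  error = function(err) Inf)
    if (e < KS_HBOND_CUTOFF) hb[i, j] <- TRUE
  }
  hb
}

#' Minimal DSSP-style secondary-structure assignment for one frame
#'
#' Computes Kabsch-Sander backbone hydrogen bonds (amide hydrogens are
#' reconstructed when absent), then assigns: 3/4/5-turn helices (G/H/I) from
#' pairs of consecutive n-turns, parallel/antiparallel bridges (B) and ladders
#' (E) from the bridge hydrogen-bond patterns, turns (T), and coil (C)
#' otherwise, with label priority H > E > G > I > B > T > C. Chains shorter
#' than 3 residues are labelled C with a warning; a CA-CA step over 4.5 A is
#' treated as a chain break terminating all hydrogen-bond patterns.
#'
#' @param frame n_atoms x 3 coordinate matrix.
#' @param topology the `mdu_structure` topology.
#' @return Character vector of per-residue labels in {H,G,I,E,B,T,C}, one per
#'   sequential residue.
#' @export
assign_secondary_structure <- function(frame, topology) {
  mc <- .mainchain_table(frame, topology)
  nr <- mc$nr
  if (nr < 3) {
    warning("chain of fewer than 3 residues: all coil")
    return(rep("C", nr))
  }
  hb <- .ks_hbond_matrix(mc)
  conn <- .connected(mc)
  # run of connectivity: i..i+n contiguous?
  contig <- function(i, n) all(conn[i:(i + n - 1)])

  turn <- list()
  for (n in c(3, 4, 5)) {
    tn <- rep(FALSE, nr)
    for (i in seq_len(nr - n)) if (contig(i, n) && hb[i + n, i]) tn[i] <- TRUE
    turn[[as.character(n)]] <- tn
  }

  lab <- rep("C", nr)
  set_min <- function(lab, idx, new) {
    # priority H > E > G > I > B > T > C
    prio <- c(H = 1, E = 2, G = 3, I = 4, B = 5, T = 6, C = 7)
    for (i in idx) if (prio[new] < prio[lab[i]]) lab[i] <- new
    lab
  }

  # turns as T first (lowest priority above C)
  for (n in c(3, 4, 5)) {
    tn <- turn[[as.character(n)]]
    for (i in which(tn)) lab <- set_min(lab, (i + 1):(i + n - 1), "T")
  }

  # bridges and ladders
  bridges <- list(); bt <- character(0)
  for (i in seq_len(nr)) {
    jmin <- i + 3
    if (jmin > nr) break
    for (j in jmin:nr) {
      # neighbour relations (i-1, i+1, j-1, j+1) must not span a chain break
      i_ok <- i > 1 && i < nr && conn[i - 1] && conn[i]
      j_ok <- j > 1 && j < nr && conn[j - 1] && conn[j]
      par1 <- i_ok && hb[j, i - 1] && hb[i + 1, j]
      par2 <- j_ok && hb[i, j - 1] && hb[j + 1, i]
      anti1 <- hb[j, i] && hb[i, j]
      anti2 <- i_ok && j_ok && hb[j + 1, i - 1] && hb[i + 1, j - 1]
      if (par1 || par2) { bridges[[length(bridges) + 1L]] <- c(i, j); bt <- c(bt, "P") }
      else if (anti1 || anti2) { bridges[[length(bridges) + 1L]] <- c(i, j); bt <- c(bt, "A") }
    }
  }
  if (length(bridges)) {
    bm <- do.call(rbind, bridges)
    in_ladder <- rep(FALSE, nrow(bm))
    key <- paste(bm[, 1], bm[, 2], bt)
    has <- function(i, j, t) paste(i, j, t) %in% key
    for (k in seq_len(nrow(bm))) {
      i <- bm[k, 1]; j <- bm[k, 2]
      if (bt[k] == "A") {
        if (has(i + 1, j - 1, "A") || has(i - 1, j + 1, "A")) in_ladder[k] <- TRUE
      } else {
        if (has(i + 1, j + 1, "P") || has(i - 1, j - 1, "P")) in_ladder[k] <- TRUE
      }
    }
    for (k in seq_len(nrow(bm))) {
      l <- if (in_ladder[k]) "E" else "B"
      lab <- set_min(lab, bm[k, ], l)
    }
  }

  # helices: two consecutive n-turns
  helix_def <- list(c("4", "H", 4L), c("3", "G", 3L), c("5", "I", 5L))
  for (hd in helix_def) {
    tn <- turn[[hd[[1]]]]
    n <- as.integer(hd[[3]])
    for (i in seq_len(nr)[-1]) {
      if (i + n - 1 > nr) break
      if (tn[i - 1] && tn[i]) lab <- set_min(lab, i:(i + n - 1), hd[[2]])
    }
  }
  lab
}

#' Secondary-structure labels over a trajectory
#'
#' @param traj an `mdu_trajectory`.
#' @param stride sample every `stride`-th frame (default 1).
#' @return A residue x frame character matrix of class `mdu_ssmatrix`;
#'   attributes `times` (ns of sampled frames) and `resno` (author numbers).
#' @export
ss_timeseries <- function(traj, stride = 1L) {
  idx <- seq(1L, n_frames(traj), by = stride)
  topo <- traj$topology
  cols <- lapply(idx, function(i) assign_secondary_structure(traj$coords[[i]], topo))
  m <- do.call(cbind, cols)
  a <- topo$atoms
  structure(m, class = c("mdu_ssmatrix", class(m)),
            times = traj$times[idx],
            resno = a$resno[!duplicated(a$resid)])
}

#' Percentage of beta structure in a region over a time window
#'
#' 100 x (count of E or B labels in the region x window block) / block size.
#'
#' @param ssmat an `mdu_ssmatrix` from [ss_timeseries()].
#' @param region region name.
#' @param regions an `mdu_regions` map.
#' @param time_window integer indices of sampled frames (default: all).
#' @return Percentage in `[0, 100]`.
#' @export
region_beta_percentage <- function(ssmat, region, regions, time_window = NULL) {
  resno <- attr(ssmat, "resno")
  rng <- region_range(regions, region)
  rows <- which(resno >= rng[1] & resno <= rng[2])
  if (!length(rows)) stop("region outside the matrix")
  if (is.null(time_window)) time_window <- seq_len(ncol(ssmat))
  if (!length(time_window)) stop("empty time window")
  block <- unclass(ssmat)[rows, time_window, drop = FALSE]
  100 * mean(block %in% c("E", "B"))
}

.rolling_mean <- function(x, window) {
  half <- window %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - half):min(n, i + half)]), numeric(1))
}

#' Detect ordered beta-loss (unfolding) events per region
#'
#' For each region, the per-frame beta content (% of E/B labels among the
#' region's residues) is smoothed with a centred rolling window. An event is
#' emitted at the first sampled frame where the smoothed content falls below
#' `threshold` and stays below for at least `persistence` consecutive frames,
#' provided the region had been at or above the threshold before. A region
#' whose content ends below 10% while at least one other region also lost
#' beta structure is flagged `melt` instead of `beta_loss`. Events are sorted
#' by onset, giving the temporal sequence of strand detachments.
#'
#' @param ssmat an `mdu_ssmatrix`.
#' @param regions an `mdu_regions` map; every region in it is monitored.
#' @param threshold beta-content threshold in percent (default 50).
#' @param persistence consecutive sampled frames required below threshold
#'   (default 5).
#' @param window rolling-mean window in sampled frames (default 5, centred).
#' @return Data frame (possibly empty) with columns `region`, `onset_ns`,
#'   `onset_index`, `kind`, `beta_before_pct`, `beta_after_pct`, sorted by
#'   onset.
#' @export
detect_unfolding_events <- function(ssmat, regions, threshold = 50,
                                    persistence = 5L, window = 5L) {
  stopifnot(threshold > 0, threshold < 100)
  times <- attr(ssmat, "times")
  resno <- attr(ssmat, "resno")
  out <- list()
  for (r in seq_len(nrow(regions))) {
    rng <- c(regions$start[r], regions$end[r])
    rows <- which(resno >= rng[1] & resno <= rng[2])
    if (!length(rows)) next
    beta <- 100 * colMeans(matrix(unclass(ssmat)[rows, , drop = FALSE] %in%
                                    c("E", "B"), nrow = length(rows)))
    roll <- .rolling_mean(beta, window)
    below <- roll < threshold
    if (!any(!below)) next  # never at/above threshold: nothing to lose
    first_above <- which(!below)[1]
    rl <- rle(below)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
    hit <- which(rl$values & rl$lengths >= persistence & starts > first_above)
    if (!length(hit)) next
    onset <- starts[hit[1]]
    # the centred rolling mean crosses up to window/2 frames before the raw
    # series; report the raw threshold crossing as the onset
    half <- window %/% 2
    cand <- seq(max(1L, onset - half), length(beta))
    raw_cross <- cand[which(beta[cand] < threshold)[1]]
    if (!is.na(raw_cross)) onset <- raw_cross
    final_beta <- roll[length(roll)]
    out[[length(out) + 1L]] <- data.frame(
      region = regions$name[r],
      onset_ns = times[onset], onset_index = onset,
      kind = "beta_loss",
      beta_before_pct = mean(beta[seq_len(onset - 1)]),
      beta_after_pct = mean(beta[onset:length(beta)]),
      final_beta_pct = final_beta,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(region = character(), onset_ns = numeric(),
                      onset_index = integer(), kind = character(),
                      beta_before_pct = numeric(), beta_after_pct = numeric(),
                      stringsAsFactors = FALSE))
  ev <- do.call(rbind, out)
  if (nrow(ev) > 1)
    ev$kind[ev$final_beta_pct < 10] <- "melt"
  ev$final_beta_pct <- NULL
  ev[order(ev$onset_index), , drop = FALSE]
}
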