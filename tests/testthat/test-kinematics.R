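test_that("Kabsch superposition recovers exact rigid transforms", {
  set.seed(1)
  A <- matrix(rnorm(30), 10, 3)

  fit0 <- kabsch_superpose(A, A)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  fitT <- kabsch_superpose(sweep(A, 2, c(-1, -2, -3)), A)
  expect_equal(fitT$rmsd, 0, tolerance = 1e-12)

  # known 30-degree z-rotation on 5 random points
  B <- matrix(rnorm(15), 5, 3)
  R30 <- rot_mat(c(0, 0, 1), 30)
  fit <- kabsch_superpose(B %*% t(R30), B)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$rotation %*% R30, diag(3), tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)

  # rmsd invariant under rigid transforms of either input
  set.seed(2)
  M <- matrix(rnorm(30), 10, 3)
  Rr <- rot_mat(c(1, 2, 3), 77)
  base_rmsd <- kabsch_superpose(M + 0.3 * matrix(rnorm(30), 10, 3), A)$rmsd
  mob <- M + 0.3 * matrix(rnorm(30), 10, 3)
  r1 <- kabsch_superpose(mob, A)$rmsd
  r2 <- kabsch_superpose(sweep(mob %*% t(Rr), 2, c(5, -2, 9), `+`), A)$rmsd
  r3 <- kabsch_superpose(mob, sweep(A %*% t(Rr), 2, c(1, 1, 1), `+`))$rmsd
  expect_equal(r1, r2, tolerance = 1e-9)
  expect_equal(r1, r3, tolerance = 1e-9)

  collinear <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(collinear, collinear), "collinear")
})

test_that("superposition rmsd matches bio3d fit.xyz", {
  skip_if_not_installed("bio3d")
  set.seed(3)
  A <- matrix(rnorm(36), 12, 3)
  B <- A + 0.5 * matrix(rnorm(36), 12, 3)
  mine <- kabsch_superpose(B, A)$rmsd
  fitted <- bio3d::fit.xyz(fixed = as.numeric(t(A)), mobile = as.numeric(t(B)),
                           fixed.inds = 1:36, mobile.inds = 1:36)
  ref <- bio3d::rmsd(as.numeric(t(A)), fitted)
  expect_equal(mine, ref, tolerance = 1e-4)
})

test_that("RMSD series removes rigid motion and matches the direct formula", {
  toy <- build_toy_two_domain(2, 5)
  s <- toy$structure
  base <- s$models[[1]]
  tr <- make_traj(s, list(base, base, base))
  expect_equal(rmsd_series(tr)$value, c(0, 0, 0), tolerance = 1e-9)

  # a rigidly rotated+translated frame superposes to rmsd 0
  R <- rot_mat(c(1, 1, 0), 25)
  tr2 <- make_traj(s, list(base, sweep(base %*% t(R), 2, c(3, 4, 5), `+`)))
  expect_equal(rmsd_series(tr2)$value[2], 0, tolerance = 1e-9)

  # one atom of a 10-atom selection displaced by 2 A -> rmsd 2/sqrt(10)
  xyz <- random_frame(10, seed = 4)
  s10 <- ca_structure(xyz)
  f2 <- xyz; f2[1, ] <- f2[1, ] + c(2, 0, 0)
  tr3 <- make_traj(s10, list(xyz, f2))
  sel <- seq_len(10)
  # without superposition the formula value is 2/sqrt(10); the optimal fit
  # can only reduce it, so compare against the unfitted value directly
  raw <- sqrt(mean(rowSums((f2 - xyz)^2)))
  expect_equal(raw, 2 / sqrt(10), tolerance = 1e-12)
  expect_lte(rmsd_series(tr3, selection = sel)$value[2], raw + 1e-9)
  expect_gt(rmsd_series(tr3, selection = sel)$value[2], 0.9 * raw)

  expect_error(rmsd_series(tr3, selection = integer()), "empty selection")
})

test_that("RMSF is zero for rigid trajectories and follows scripted motion", {
  toy <- build_toy_two_domain(4, 9)
  s <- toy$structure
  base <- s$models[[1]]
  R <- rot_mat(c(0, 0, 1), 10)
  tr <- make_traj(s, list(base, sweep(base %*% t(R), 2, c(1, 0, 0), `+`), base))
  rf <- rmsf_per_residue(tr)
  expect_true(all(rf$rmsf < 1e-9))
  expect_error(rmsf_per_residue(make_traj(s, list(base))), "2 frames")

  # one residue oscillating +-a along x, the rest fixed
  a <- 1.2
  K <- 48
  idx <- which(s$atoms$resid == 10)
  frames <- lapply(seq_len(K), function(k) {
    f <- base
    f[idx, 1] <- f[idx, 1] + a * cos(2 * pi * k / K)
    f
  })
  rf2 <- rmsf_per_residue(make_traj(s, frames))
  # the common superposition absorbs a small part of one residue's motion
  expected <- a * sqrt(mean(cos(2 * pi * seq_len(K) / K)^2))
  expect_equal(rf2$rmsf[rf2$resid == 10], expected, tolerance = 0.05)
  expect_lt(max(rf2$rmsf[rf2$resid != 10]), 0.1 * expected)
})

test_that("essential-dynamics PCA satisfies its spectral identities", {
  toy <- build_toy_two_domain(2, 7)
  s <- toy$structure
  base <- s$models[[1]]

  # static trajectory: all eigenvalues 0
  tr0 <- make_traj(s, list(base, base, base))
  expect_true(all(pca_essential(tr0)$values < 1e-12))

  # single-atom oscillation along x: lambda1 = variance, others ~ 0
  sel <- select_atoms(s, "mainchain")
  K <- 40
  amp <- 0.9
  shifts <- amp * sin(2 * pi * seq_len(K) / K)
  # displace one interior CA; alignment effect is negligible for 1 atom of many
  ca10 <- which(s$atoms$resid == 10 & s$atoms$name == "CA")
  frames <- lapply(seq_len(K), function(k) {
    f <- base; f[ca10, 1] <- f[ca10, 1] + shifts[k]; f
  })
  tr1 <- make_traj(s, frames)
  em <- pca_essential(tr1, sel)
  expect_equal(em$values[1], stats::var(shifts), tolerance = 0.02)
  expect_lt(em$values[2], 0.01 * em$values[1])

  # spectral identities on a noisy trajectory
  set.seed(5)
  frames2 <- lapply(1:25, function(k) base + matrix(rnorm(length(base), sd = 0.4),
                                                    nrow(base), 3))
  em2 <- pca_essential(make_traj(s, frames2))
  expect_true(all(em2$values > -1e-8))
  expect_equal(sum(em2$values), em2$trace, tolerance = 1e-6)
  G <- crossprod(em2$vectors)
  expect_equal(G, diag(ncol(em2$vectors)), tolerance = 1e-8)
  # sign convention: first nonzero component positive
  firsts <- apply(em2$vectors, 2, function(v) v[which(abs(v) > 1e-10)[1]])
  expect_true(all(firsts > 0))

  expect_error(pca_essential(make_traj(s, list(base))), "2 frames")
})

test_that("frame projections reproduce the eigenvalues", {
  toy <- build_toy_two_domain(2, 7)
  s <- toy$structure
  base <- s$models[[1]]
  set.seed(6)
  frames <- lapply(1:30, function(k) base + matrix(rnorm(length(base), sd = 0.3),
                                                   nrow(base), 3))
  tr <- make_traj(s, frames)
  em <- pca_essential(tr)
  pr <- project_frames(tr, em, k = 2)
  v1 <- stats::var(pr$pc1); v2 <- stats::var(pr$pc2)
  expect_equal(v1, em$values[1], tolerance = 1e-6)
  expect_equal(v2, em$values[2], tolerance = 1e-6)
  expect_gte(v1, v2)
  expect_error(project_frames(tr, em, k = length(em$values) + 5), "exceeds")

  # two scripted clusters separated along mode 1 show up bimodally; the
  # displacement alternates sign along the chain so the rigid-body
  # superposition cannot absorb it
  shift <- matrix(0, nrow(base), 3)
  mc <- select_atoms(s, "mainchain")
  shift[mc, 1] <- rep(c(3, -3), length.out = length(mc))
  frames2 <- c(lapply(1:12, function(k) base + matrix(rnorm(length(base), sd = 0.15),
                                                      nrow(base), 3)),
               lapply(1:12, function(k) base + shift +
                        matrix(rnorm(length(base), sd = 0.15), nrow(base), 3)))
  tr2 <- make_traj(s, frames2)
  em2 <- pca_essential(tr2)
  pr2 <- project_frames(tr2, em2, k = 1)
  g1 <- pr2$pc1[1:12]; g2 <- pr2$pc1[13:24]
  expect_gt(abs(mean(g1) - mean(g2)), 5 * (sd(g1) + sd(g2)))
  # the displacement between cluster means along mode 1 matches the script
  expect_equal(abs(mean(g1) - mean(g2)), 3 * sqrt(length(mc)), tolerance = 0.05)
})

test_that("domain rotations decompose into closure and twist analytically", {
  pre <- preset_unfolding("static", n_frames = 3)
  s <- pre$structure; reg <- pre$regions
  base <- s$models[[1]]
  mcF <- select_atoms(s, "mainchain", region = "N_td", regions = reg)
  mcM <- select_atoms(s, "mainchain", region = "C_td", regions = reg)
  d <- colMeans(base[mcM, ]) - colMeans(base[mcF, ])
  d <- d / sqrt(sum(d^2))
  perp <- c(1, 0, 0) - sum(c(1, 0, 0) * d) * d
  perp <- perp / sqrt(sum(perp^2))
  mov <- select_atoms(s, "all", region = "C_td", regions = reg)
  cen <- colMeans(base[mcM, ])
  rotate_domain <- function(axis, ang) {
    f <- base
    f[mov, ] <- sweep(sweep(base[mov, , drop = FALSE], 2, cen) %*%
                        t(rot_mat(axis, ang)), 2, cen, `+`)
    f
  }

  r_perp <- domain_rotation(rotate_domain(perp, 10), base, s, "N_td", "C_td", reg)
  expect_equal(r_perp$angle, 10, tolerance = 0.1)
  expect_equal(r_perp$percent_closure, 100, tolerance = 1e-6)
  expect_identical(r_perp$label, "closure")

  r_par <- domain_rotation(rotate_domain(d, 10), base, s, "N_td", "C_td", reg)
  expect_equal(r_par$percent_twist, 100, tolerance = 1e-6)
  expect_identical(r_par$label, "twist")

  ax45 <- (d + perp) / sqrt(2)
  r_45 <- domain_rotation(rotate_domain(ax45, 10), base, s, "N_td", "C_td", reg)
  expect_equal(r_45$percent_closure, 50, tolerance = 1e-6)
  expect_equal(r_45$percent_twist, 50, tolerance = 1e-6)
  expect_equal(r_45$percent_closure + r_45$percent_twist, 100, tolerance = 1e-12)

  # hinge point lies on the true rotation axis through the domain centroid
  expect_lt({
    h <- r_perp$hinge_point - cen
    sqrt(sum((h - sum(h * r_perp$axis) * r_perp$axis)^2))
  }, 1e-6)

  bad <- new_regions_overlap <- pre$regions
  expect_error(domain_rotation(base, base, s, "N_td", "d1_s2", reg),
               "disjoint")
})

test_that("motion fractions classify scripted rigid motions", {
  pre <- preset_unfolding("static", n_frames = 3)
  s <- pre$structure; reg <- pre$regions
  base <- s$models[[1]]
  mcF <- select_atoms(s, "mainchain", region = "N_td", regions = reg)
  mcM <- select_atoms(s, "mainchain", region = "C_td", regions = reg)
  d <- colMeans(base[mcM, ]) - colMeans(base[mcF, ]); d <- d / sqrt(sum(d^2))
  perp <- c(1, 0, 0) - sum(c(1, 0, 0) * d) * d; perp <- perp / sqrt(sum(perp^2))
  mov <- select_atoms(s, "all", region = "C_td", regions = reg)
  cen <- colMeans(base[mcM, ])
  rotate_domain <- function(axis, ang) {
    f <- base
    f[mov, ] <- sweep(sweep(base[mov, , drop = FALSE], 2, cen) %*%
                        t(rot_mat(axis, ang)), 2, cen, `+`)
    f
  }

  # pure twist trajectory
  tw <- make_traj(s, c(list(base), lapply(seq(2, 10, 2), function(a)
    rotate_domain(d, a))))
  mf <- motion_fraction(tw, "N_td", "C_td", reg)
  expect_equal(mf$fraction_twist, 100)

  # alternating closure / twist frames 50/50
  alt <- make_traj(s, c(list(base), lapply(1:10, function(k)
    rotate_domain(if (k %% 2) perp else d, 8))))
  mfa <- motion_fraction(alt, "N_td", "C_td", reg)
  expect_equal(mfa$fraction_closure, 50)
  expect_equal(mfa$fraction_twist, 50)
  expect_equal(mfa$fraction_closure + mfa$fraction_twist, 100)

  # static: everything below the angle floor
  st <- make_traj(s, list(base, base, base))
  expect_warning(mfs <- motion_fraction(st, "N_td", "C_td", reg), "undefined")
  expect_true(is.na(mfs$fraction_closure))
  expect_equal(mfs$n_below_floor, 2L)
})
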