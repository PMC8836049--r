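test_that("contact definition is heavy-atom, closed at the cutoff, residue-level", {
  # 3 CA-only residues at z = 0, 5, 12: only (1,2) within 6.5
  s <- ca_structure(cbind(0, 0, c(0, 5, 12)))
  cs <- contact_set(s$models[[1]], s)
  expect_equal(unname(cs$pairs), rbind(c(1L, 2L)))

  # exactly 6.5 apart -> contact (closed boundary)
  s2 <- ca_structure(cbind(0, 0, c(0, 6.5)))
  expect_equal(nrow(contact_set(s2$models[[1]], s2)$pairs), 1L)
  s3 <- ca_structure(cbind(0, 0, c(0, 6.5001)))
  expect_equal(nrow(contact_set(s3$models[[1]], s3)$pairs), 0L)

  # hydrogens do not count
  atoms <- data.frame(serial = 1:2, name = c("CA", "H"), element = c("C", "H"),
                      resname = "GLY", chain = "A", resno = 1:2, resid = 1:2,
                      stringsAsFactors = FALSE)
  s4 <- mdunfold:::new_structure(atoms, list(cbind(0, 0, c(0, 3))))
  expect_equal(nrow(contact_set(s4$models[[1]], s4)$pairs), 0L)

  # min_separation excludes near-diagonal pairs
  s5 <- ca_structure(cbind(0, 0, c(0, 3, 6)))
  expect_equal(nrow(contact_set(s5$models[[1]], s5, min_separation = 2)$pairs), 1L)
})

test_that("grid-accelerated detection equals the all-pairs oracle", {
  topo <- mainchain_topology(80)
  set.seed(11)
  for (k in 1:25) {
    fr <- random_frame(n_atoms(topo))
    cs <- contact_set(fr, topo)
    expect_identical(unname(cs$pairs), unname(brute_contact_pairs(fr, topo)))
  }
  # and on a structured (sheet) frame
  toy <- build_toy_two_domain(4, 7)
  fr <- toy$structure$models[[1]]
  expect_identical(unname(contact_set(fr, toy$structure)$pairs),
                   unname(brute_contact_pairs(fr, toy$structure)))
})

test_that("Q is 1 at the reference and follows contact counting exactly", {
  # static trajectory: Q constantly 1
  toy <- build_toy_two_domain(2, 7)
  st <- make_traj(toy$structure, rep(toy$structure$models, 4))
  q <- contact_fraction_series(st)
  expect_equal(q$value, rep(1, 4), tolerance = 1e-12)

  # reference {(1,2),(2,3)}; later frame retains only (1,2) -> Q = 0.5
  xyz0 <- cbind(0, 0, c(0, 5, 10))
  s <- ca_structure(xyz0)
  xyz1 <- cbind(0, 0, c(0, 5, 40))
  tr <- make_traj(s, list(xyz0, xyz1))
  q2 <- contact_fraction_series(tr)
  expect_equal(q2$value, c(1, 0.5), tolerance = 1e-12)

  # literal definition counts non-native contacts: Q can exceed 1
  xyz2 <- cbind(0, 0, c(0, 5, 9))   # reference has only (1,2); frame adds (2,3)
  tr2 <- make_traj(s, list(xyz1, xyz2))
  q3 <- contact_fraction_series(tr2)
  expect_equal(q3$value[2], 2 / 1, tolerance = 1e-12)
  q3n <- contact_fraction_series(tr2, mode = "native")
  expect_equal(q3n$value[2], 1, tolerance = 1e-12)

  # empty reference set is an error
  far <- ca_structure(cbind(0, 0, c(0, 50, 100)))
  expect_error(contact_fraction_series(make_traj(far, far$models)),
               "undefined")
})

test_that("scripted regional detachment produces a prompt regional Q drop", {
  pre <- preset_unfolding("static", n_frames = 60, dt_ns = 1)
  script <- unfolding_script(seed = 3, n_frames = 60, dt_ns = 1, sigma = 0.1,
                             detachments = list(list(region = "d1_s1",
                                                     onset = 40,
                                                     displacement = c(0, -15, 0),
                                                     ramp = 5)))
  sim <- simulate_trajectory(pre$structure, script, pre$regions)
  q <- contact_fraction_series(sim$trajectory, region = "d1_s1",
                               regions = pre$regions)
  pre_drop <- mean(q$value[1:39])
  expect_true(all(q$value[1:38] > 0.8 * pre_drop))
  # drops below 0.8 * baseline within 2 sampled frames of the onset
  expect_true(any(q$value[39:42] < 0.8 * pre_drop))
  # and below 0.5 before the ramp completes + 2 frames
  expect_true(any(q$value[39:47] < 0.5))
  d <- detect_q_drop(q)
  expect_false(is.null(d))
  expect_lte(abs(d$onset_index - 40), 2)
})

test_that("ensemble contact maps count frame fractions symmetrically", {
  xyz_in <- cbind(0, 0, c(0, 5))
  xyz_out <- cbind(0, 0, c(0, 50))
  s <- ca_structure(xyz_in)
  frames <- c(rep(list(xyz_in), 5), rep(list(xyz_out), 5))
  tr <- make_traj(s, frames)
  m <- ensemble_contact_map(tr)
  expect_equal(m[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(unclass(m), t(unclass(m)))
  expect_true(all(diag(unclass(m)) == 0))

  # static trajectory: indicator of the frame-0 contact set
  toy <- build_toy_two_domain(2, 5)
  st <- make_traj(toy$structure, rep(toy$structure$models, 3))
  ms <- ensemble_contact_map(st)
  expect_true(all(unclass(ms) %in% c(0, 1)))
  cs <- contact_set(toy$structure$models[[1]], toy$structure)
  ind <- matrix(0, n_residues(toy$structure), n_residues(toy$structure))
  ind[cs$pairs] <- 1; ind <- ind + t(ind)
  expect_equal(unclass(ms), ind, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("subtractive maps obey their exact algebra", {
  toy <- build_toy_two_domain(2, 5)
  set.seed(12)
  mk_traj <- function(seed) {
    sc <- unfolding_script(seed = seed, n_frames = 6, sigma = 0.4)
    simulate_trajectory(toy$structure, sc, toy$regions)$trajectory
  }
  A <- ensemble_contact_map(mk_traj(1))
  B <- ensemble_contact_map(mk_traj(2))
  expect_true(all(subtractive_map(A, A) == 0))
  expect_equal(subtractive_map(A, B), -subtractive_map(B, A), tolerance = 1e-12)
  expect_equal(subtractive_map(A, B, "loss"), -subtractive_map(B, A, "loss"),
               tolerance = 1e-12)
  expect_true(all(subtractive_map(A, A, "loss") == 0))

  # toy 3x3 maps differing in one entry: difference 0.5 there only
  m1 <- matrix(0, 3, 3); m1[1, 2] <- m1[2, 1] <- 0.8
  m2 <- matrix(0, 3, 3); m2[1, 2] <- m2[2, 1] <- 0.3
  d <- subtractive_map(m1, m2)
  expect_equal(d[1, 2], 0.5)
  expect_equal(sum(d != 0), 2L)

  expect_error(subtractive_map(m1, matrix(0, 2, 2)), "mismatch")
})

test_that("region-pair summaries average the block excluding the diagonal", {
  toy <- build_toy_two_domain(2, 5)
  reg <- toy$regions
  nres <- n_residues(toy$structure)
  m_all1 <- matrix(1, nres, nres); diag(m_all1) <- 0
  expect_equal(region_pair_contact_summary(m_all1, toy$structure,
                                           "d1_s1", "d1_s2", reg), 1)
  # 10 of the 25 block entries set to 1 -> mean 0.4, symmetric in arguments
  m <- matrix(0, nres, nres)
  ra <- 1:5; rb <- 6:10
  ones <- as.matrix(expand.grid(ra, rb))[1:10, ]
  m[ones] <- 1; m[ones[, 2:1]] <- 1
  expect_equal(region_pair_contact_summary(m, toy$structure, "d1_s1", "d1_s2", reg),
               10 / 25)
  expect_equal(region_pair_contact_summary(m, toy$structure, "d1_s1", "d1_s2", reg),
               region_pair_contact_summary(m, toy$structure, "d1_s2", "d1_s1", reg))
})
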