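test_that("ring centroids are unweighted means of the ring atoms", {
  toy <- build_toy_two_domain(2, 7, aromatic_positions = c(4, 18, 25),
                              aromatic_types = c("TYR", "TRP", "PHE"))
  s <- toy$structure
  fr <- s$models[[1]]
  a <- s$atoms

  # hand-computed mean over the 9 listed TRP ring atoms
  ring <- mdunfold:::AROMATIC_RING_ATOMS$TRP
  idx <- which(a$resid == 18 & a$name %in% ring)
  expect_length(idx, 9L)
  expect_equal(ring_centroid(s, fr, 18), colMeans(fr[idx, ]), tolerance = 1e-12)

  # hexagonal PHE/TYR ring: centroid at the template center, translation-covariant
  cen <- ring_centroid(s, fr, 4)
  fr2 <- fr + matrix(rep(c(1, 2, 3), each = nrow(fr)), nrow(fr), 3)
  expect_equal(ring_centroid(s, fr2, 4), cen + c(1, 2, 3), tolerance = 1e-12)

  # missing ring atom -> geometry error naming the atom
  drop <- which(a$resid == 4 & a$name == "CZ")
  s_bad <- mdunfold:::new_structure(a[-drop, ], list(fr[-drop, ]))
  expect_error(ring_centroid(s_bad, fr[-drop, ], 4), "CZ")
  expect_error(ring_centroid(s, fr, 5), "not aromatic")
})

test_that("pair distances are symmetric, rigid-invariant and scripted ramps cross on time", {
  toy <- build_toy_two_domain(2, 7, aromatic_positions = c(4, 18))
  s <- toy$structure
  base <- s$models[[1]]
  tr <- make_traj(s, list(base, base))
  d_ab <- pair_distance_series(tr, 4, 18)$value
  d_ba <- pair_distance_series(tr, 18, 4)$value
  expect_equal(d_ab, d_ba, tolerance = 1e-12)

  R <- rot_mat(c(0, 1, 1), 40)
  moved <- sweep(base %*% t(R), 2, c(7, -1, 2), `+`)
  tr2 <- make_traj(s, list(base, moved))
  dd <- pair_distance_series(tr2, 4, 18)$value
  expect_equal(dd[1], dd[2], tolerance = 1e-9)

  # min-atom metric is never larger than the centroid metric
  expect_lte(pair_distance_series(tr, 4, 18, metric = "min_atom")$value[1],
             d_ab[1])

  # scripted separation ramp 5 -> 12 A over frames 40..60 crosses 7.0 at the
  # scripted frame +-1
  idx18 <- which(s$atoms$resid == 18)
  cen4 <- ring_centroid(s, base, 4)
  cen18 <- ring_centroid(s, base, 18)
  u <- (cen18 - cen4) / sqrt(sum((cen18 - cen4)^2))
  sep0 <- sqrt(sum((cen18 - cen4)^2))
  frames <- lapply(1:70, function(f) {
    want <- if (f < 40) 5 else if (f > 60) 12 else 5 + 7 * (f - 40) / 20
    x <- base
    x[idx18, ] <- sweep(x[idx18, , drop = FALSE], 2, (want - sep0) * u, `+`)
    x
  })
  ser <- pair_distance_series(make_traj(s, frames), 4, 18)
  cross_expect <- 40 + 20 * (7 - 5) / 7            # ~ frame 45.7
  cross_seen <- which(ser$value > 7)[1]
  expect_lte(abs(cross_seen - ceiling(cross_expect)), 1)
})

test_that("persistence counts in-band frames exactly", {
  toy <- build_toy_two_domain(2, 7, aromatic_positions = c(4, 18))
  s <- toy$structure
  base <- s$models[[1]]
  idx18 <- which(s$atoms$resid == 18)
  set_sep <- function(want) {
    cen4 <- ring_centroid(s, base, 4); cen18 <- ring_centroid(s, base, 18)
    u <- (cen18 - cen4) / sqrt(sum((cen18 - cen4)^2))
    sep0 <- sqrt(sum((cen18 - cen4)^2))
    x <- base
    x[idx18, ] <- sweep(x[idx18, , drop = FALSE], 2, (want - sep0) * u, `+`)
    x
  }
  expect_equal(persistence_percentage(make_traj(s, rep(list(set_sep(5.5)), 4)),
                                      4, 18), 100)
  expect_equal(persistence_percentage(make_traj(s, rep(list(set_sep(10)), 4)),
                                      4, 18), 0)
  frames <- c(rep(list(set_sep(6.0)), 30), rep(list(set_sep(9)), 70))
  expect_equal(persistence_percentage(make_traj(s, frames), 4, 18), 30)
  # narrowing the band can only lower persistence
  p_wide <- persistence_percentage(make_traj(s, frames), 4, 18, band = c(4.5, 7))
  p_narrow <- persistence_percentage(make_traj(s, frames), 4, 18, band = c(5.5, 6.5))
  expect_lte(p_narrow, p_wide)
})

test_that("cluster detection equals brute-force connected components", {
  skip_if_not_installed("igraph")
  toy <- build_toy_two_domain(2, 10,
                              aromatic_positions = c(2, 5, 8, 12, 15, 18, 25, 30),
                              aromatic_types = "TYR")
  s <- toy$structure
  a <- s$atoms
  aro <- aromatic_residues(s)
  set.seed(21)
  for (k in 1:20) {
    # scatter the aromatic residues randomly in a 20 A box
    fr <- s$models[[1]]
    for (r in aro$resid) {
      idx <- which(a$resid == r)
      fr[idx, ] <- sweep(fr[idx, , drop = FALSE], 2,
                         runif(3, 0, 20) - colMeans(fr[idx, , drop = FALSE]), `+`)
    }
    mine <- detect_aromatic_clusters(s, fr, min_size = 2)
    cen <- t(vapply(aro$resid, function(r) ring_centroid(s, fr, r), numeric(3)))
    d <- as.matrix(dist(cen))
    adj <- d >= 4.5 & d <= 7.0
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    ref <- unname(lapply(split(aro$resno, comp), sort))
    ref <- ref[vapply(ref, length, 1L) >= 2]
    expect_setequal(lapply(mine, as.integer), lapply(ref, as.integer))
  }
})

test_that("cluster membership is transitive through in-band edges", {
  toy <- build_toy_two_domain(2, 10, aromatic_positions = c(2, 5, 8))
  s <- toy$structure
  a <- s$atoms
  fr <- s$models[[1]]
  place <- function(r, where) {
    idx <- which(a$resid == r)
    fr[idx, ] <<- sweep(fr[idx, , drop = FALSE], 2,
                        where - ring_centroid(s, fr, r), `+`)
  }
  # A-B 5, B-C 5, A-C 10: one component {A,B,C}
  place(2, c(0, 0, 40)); place(5, c(5, 0, 40)); place(8, c(10, 0, 40))
  cl <- detect_aromatic_clusters(s, fr)
  expect_length(cl, 1L)
  expect_equal(cl[[1]], c(2L, 5L, 8L))
  # all pairs out of band: nothing
  place(2, c(0, 0, 40)); place(5, c(20, 0, 40)); place(8, c(40, 0, 40))
  expect_length(detect_aromatic_clusters(s, fr), 0L)
})

test_that("cluster formation events honour onset, membership and persistence", {
  # static native trajectory: no events
  pre <- preset_unfolding("static", n_frames = 20)
  sim <- simulate_trajectory(pre$structure, pre$script, pre$regions)
  expect_equal(nrow(cluster_formation_events(sim$trajectory)), 0L)

  # scripted 4-ring cluster at a known onset
  pre2 <- preset_unfolding("urea_like", n_frames = 100, dt_ns = 1, seed = 5)
  sim2 <- simulate_trajectory(pre2$structure, pre2$script, pre2$regions)
  ev <- cluster_formation_events(sim2$trajectory)
  gt <- sim2$ground_truth$clusters
  hit <- ev[ev$members == gt$members, ]
  expect_equal(nrow(hit), 1L)
  expect_lte(abs(hit$onset_index - gt$onset_frame), 2)

  # a transient 2-frame contact is filtered out by persistence = 5
  toy <- build_toy_two_domain(2, 10, aromatic_positions = c(2, 5, 8))
  s <- toy$structure; a <- s$atoms
  base <- s$models[[1]]
  tight <- base
  targets <- list(`2` = c(0, 0, 40), `5` = c(5, 0, 40),
                  `8` = c(2.5, 4.33, 40))  # equilateral, all pairs ~5 A
  for (r in c(2, 5, 8)) {
    idx <- which(a$resid == r)
    tight[idx, ] <- sweep(tight[idx, , drop = FALSE], 2,
                          targets[[as.character(r)]] -
                            ring_centroid(s, base, r), `+`)
  }
  frames <- c(rep(list(base), 6), list(tight, tight), rep(list(base), 6))
  expect_equal(nrow(cluster_formation_events(make_traj(s, frames))), 0L)
})
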