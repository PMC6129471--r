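# Pose RMSD, clustering, and ranking of the recorded set.

# build a recorded set directly from an event stream
rs_from_events <- function(ev, capacity = 500) {
  rs <- new_recorded_set(fx_lh(), bd_config(capacity = capacity))
  for (e in ev) rs <- update_recorded_set(rs, e)
  rs
}

test_that("pose RMSD matrix matches direct coordinate computation", {
  lh <- fx_lh()
  ev <- synthetic_event_stream(12, seed = 2, planted_clusters = 3,
                               spread = 4, center_sep = 25)
  rs <- rs_from_events(ev)
  m <- pose_rmsd_matrix(rs)
  expect_equal(diag(m), rep(0, rs$n))
  expect_equal(m, t(m))
  # direct recomputation over the C-alpha beads
  rows <- lh$solute$atoms$atom_name == "CA"
  Y <- sweep(as.matrix(lh$solute$atoms[rows, c("x", "y", "z")]), 2,
             geometric_center(lh$solute))
  df <- as.data.frame(rs)
  coords <- lapply(seq_len(nrow(df)), function(i) {
    sweep(Y %*% t(quat_to_matrix(as.numeric(df[i, c("qw", "qx", "qy", "qz")]))),
          2, as.numeric(df[i, c("tx", "ty", "tz")]), `+`)
  })
  for (i in 1:3) for (j in 4:6) {
    expect_equal(m[i, j], sqrt(mean(rowSums((coords[[i]] - coords[[j]])^2))),
                 tolerance = 1e-9)
  }
  # a pure 3 A translation gives RMSD 3
  p0 <- pose(c(1, 0, 0, 0), c(10, 0, 0))
  p3 <- pose(c(1, 0, 0, 0), c(13, 0, 0))
  rs2 <- rs_from_events(list(list(pose = p0, energy = -2),
                             list(pose = p3, energy = -1)))
  expect_equal(pose_rmsd_matrix(rs2)[1, 2], 3, tolerance = 1e-9)
})

test_that("planted pose bundles are recovered exactly", {
  for (k in c(2, 5)) {
    ev <- synthetic_event_stream(600, seed = 40 + k, planted_clusters = k,
                                 spread = 0.3, center_sep = 30)
    rs <- rs_from_events(ev)
    truth <- vapply(ev, `[[`, numeric(1), "cluster")
    cl <- cluster_recorded_set(rs, k = k)
    expect_equal(length(cl), k)
    # members of each cluster must come from a single planted center:
    # match records back to events by translation
    df <- as.data.frame(rs)
    ev_t <- t(vapply(ev, function(e) e$pose$t, numeric(3)))
    rec_center <- vapply(seq_len(nrow(df)), function(i) {
      d <- rowSums(sweep(ev_t, 2, as.numeric(df[i, c("tx", "ty", "tz")]))^2)
      truth[which.min(d)]
    }, numeric(1))
    for (g in cl) {
      expect_equal(length(unique(rec_center[g$members])), 1)
    }
    # weighted sizes conserve the total count
    expect_equal(sum(vapply(cl, `[[`, numeric(1), "weighted_size")),
                 sum(df$count))
    expect_equal(sum(vapply(cl, `[[`, numeric(1), "population_fraction")), 1)
  }
})

test_that("clustering is invariant to event order", {
  ev <- synthetic_event_stream(300, seed = 77, planted_clusters = 3,
                               spread = 0.4, center_sep = 25)
  rs1 <- rs_from_events(ev)
  rs2 <- rs_from_events(rev(ev))
  cl1 <- cluster_recorded_set(rs1, k = 3)
  cl2 <- cluster_recorded_set(rs2, k = 3)
  sizes1 <- sort(vapply(cl1, `[[`, numeric(1), "weighted_size"))
  sizes2 <- sort(vapply(cl2, `[[`, numeric(1), "weighted_size"))
  expect_equal(sizes1, sizes2)
  e1 <- sort(vapply(cl1, `[[`, numeric(1), "representative_energy"))
  e2 <- sort(vapply(cl2, `[[`, numeric(1), "representative_energy"))
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("ranking is by weighted size with energy tie-break, and top_clusters truncates", {
  ev <- synthetic_event_stream(200, seed = 8, planted_clusters = 4,
                               spread = 0.3, center_sep = 30)
  rs <- rs_from_events(ev)
  cl <- cluster_recorded_set(rs, k = 4)
  w <- vapply(cl, `[[`, numeric(1), "weighted_size")
  expect_true(all(diff(w) <= 0))
  fr <- vapply(cl, `[[`, numeric(1), "population_fraction")
  expect_true(all(diff(fr) <= 0))
  # ties (equal event counts per planted center) break by lower
  # representative energy
  for (i in seq_len(length(cl) - 1)) {
    if (w[i] == w[i + 1]) {
      expect_lte(cl[[i]]$representative_energy,
                 cl[[i + 1]]$representative_energy)
    }
  }
  top <- top_clusters(cl, 2)
  expect_equal(length(top), 2)
  expect_equal(top[[1]]$rank, 1)
  expect_equal(length(top_clusters(cl, 99)), length(cl))
  # representative is the lowest-energy member
  df <- as.data.frame(rs)
  for (g in cl) {
    expect_equal(g$representative_energy, min(df$energy[g$members]))
  }
})

test_that("k of set size yields singletons and small sets warn", {
  ev <- synthetic_event_stream(40, seed = 9, planted_clusters = 4,
                               spread = 0.2, center_sep = 30)
  rs <- rs_from_events(ev)
  cl <- cluster_recorded_set(rs, k = rs$n)
  expect_equal(length(cl), rs$n)
  expect_true(all(vapply(cl, function(g) length(g$members), numeric(1)) == 1))
  expect_warning(cluster_recorded_set(rs, k = rs$n + 5), "singletons")
})
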