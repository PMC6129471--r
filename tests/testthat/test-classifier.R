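# Groove sites, element contacts, the alpha3 arrow, configuration
# classification, and the match matrix.

test_that("groove sites follow the labeling convention on the fixture", {
  nuc <- fx_nucleosome()
  sites <- groove_site_coords(enumerate_groove_sites(nuc), nuc)
  idx <- vapply(sites, `[[`, numeric(1), "index")
  # closed 147 + 2x18 bp fixture: dyad groove, two dyad-adjacent grooves,
  # two grooves per arm
  expect_equal(idx, c(-3, -2, -1, 0, 1, 2, 3))
  seg <- vapply(sites, `[[`, character(1), "segment")
  expect_equal(seg[idx == 0], "N-DNA")
  expect_equal(seg[idx == -3], "L-DNA1")
  expect_equal(seg[idx == 3], "L-DNA2")
  expect_equal(sum(idx == 0), 1)
  # site centers sit within one helix radius + one phosphate spread of
  # the member phosphates
  for (s in sites) {
    d <- sqrt(rowSums(sweep(s$phos_xyz, 2, s$center)^2))
    expect_lt(min(d), 12)
  }
})

test_that("element contacts equal the brute-force all-pairs scan", {
  nuc <- fx_nucleosome()
  lh <- fx_lh()
  sites <- fx_sites()
  set.seed(55)
  poses <- c(lapply(1:20, function(i) random_near_pose(nuc, lh)),
             list(place_reference_pose(lh, nuc, "on-dyad")))
  for (p in poses) {
    impl <- element_contacts(lh, p, sites)
    orc <- contacts_oracle(lh, p, nuc, sites)
    expect_identical(impl, orc)
  }
})

test_that("contact cutoff edge behaves as a closed bound", {
  nuc <- fx_nucleosome()
  lh <- fx_lh()
  sites <- fx_sites()
  s0 <- sites[[which(vapply(sites, `[[`, numeric(1), "index") == 0)]]
  # place the whole LH far away, then slide one known alpha3 bead to
  # exactly 4.9 A from a site-0 phosphate via translation of the pose
  a <- lh$solute$atoms
  a3row <- which(a$residue_index == 100)
  target <- s0$phos_xyz[1, ] + c(4.9, 0, 0)
  shift <- target - as.numeric(a[a3row, c("x", "y", "z")])
  p <- pose(c(1, 0, 0, 0), geometric_center(lh$solute) + shift)
  got <- element_contacts(lh, p, sites)
  expect_true(0 %in% got$alpha3)
  # far away: all element lists empty
  far <- pose(c(1, 0, 0, 0), c(500, 500, 500))
  expect_identical(element_contacts(lh, far, sites),
                   list(alpha3 = integer(0), beta1 = integer(0),
                        l1 = integer(0)))
})

test_that("alpha3 symbol quantizes the in-plane azimuth and X-calls the axis", {
  nuc <- fx_nucleosome()
  lh <- fx_lh()
  p <- place_reference_pose(lh, nuc, "on-dyad")
  expect_equal(alpha3_symbol(lh, p, nuc), "\u2191")
  # rotate the whole complex about the dyad axis by 45 degrees: the arrow
  # advances by one compass step (equivariance)
  arrows <- c("\u2192", "\u2197", "\u2191", "\u2196",
              "\u2190", "\u2199", "\u2193", "\u2198")
  base_i <- match(alpha3_symbol(lh, p, nuc), arrows)
  for (k in 1:3) {
    qk <- quat_from_axis_angle(nuc$dyad_axis, k * pi / 4)
    pk <- pose(quat_multiply(qk, p$q),
               as.numeric(quat_to_matrix(qk) %*% (p$t - nuc$dyad_point)) +
                 nuc$dyad_point)
    expect_equal(alpha3_symbol(lh, pk, nuc),
                 arrows[(base_i - 1 + k) %% 8 + 1], label = paste("k =", k))
  }
  # align the helix with the dyad axis: X
  fr <- chromadock:::.viewing_frame(nuc)
  a <- lh$solute$atoms
  nterm <- as.numeric(a[match(95, a$residue_index), c("x", "y", "z")])
  cterm <- as.numeric(a[match(109, a$residue_index), c("x", "y", "z")])
  v_body <- (cterm - nterm) / sqrt(sum((cterm - nterm)^2))
  rot_axis <- c(v_body[2] * fr$n[3] - v_body[3] * fr$n[2],
                v_body[3] * fr$n[1] - v_body[1] * fr$n[3],
                v_body[1] * fr$n[2] - v_body[2] * fr$n[1])
  ang <- acos(sum(v_body * fr$n))
  q_align <- quat_from_axis_angle(rot_axis, ang)
  expect_equal(alpha3_symbol(lh, pose(q_align, c(200, 0, 0)), nuc), "X")
})

test_that("reference fixtures classify to the published worked configurations", {
  nuc <- fx_nucleosome()
  lh <- fx_lh()
  p_on <- place_reference_pose(lh, nuc, "on-dyad")
  cfg_on <- classify(lh, p_on, nuc)
  expect_equal(cfg_on$string, "(\u22123\u2191, 0, +3)")
  expect_equal(cfg_on$dyad_mode, "on-dyad")
  p_off <- place_reference_pose(lh, nuc, "off-dyad-L1")
  cfg_off <- classify(lh, p_off, nuc)
  expect_true(all(unlist(cfg_off$contacts) < 0))
  expect_equal(cfg_off$dyad_mode, "off-dyad-L-DNA1")
  expect_identical(as.integer(cfg_off$contacts$beta1), c(-2L, -1L))
  # neither reference pose overlaps the excluded volume
  expect_false(check_overlap(fx_exclusion(), lh, p_on))
  expect_false(check_overlap(fx_exclusion(), lh, p_off))
})

test_that("classification respects the dyad mirror symmetry", {
  nuc <- fx_nucleosome()
  lh <- fx_lh()
  sites <- fx_sites()
  arrows <- c("\u2192", "\u2197", "\u2191", "\u2196",
              "\u2190", "\u2199", "\u2193", "\u2198")
  # the dyad twofold is a proper rotation: in-plane azimuths advance by
  # half a turn (reflection would be an improper operation the nucleosome
  # does not possess)
  mirror_arrow <- function(s) {
    if (s == "X") return("X")
    i <- match(s, arrows)
    arrows[(i - 1 + 4) %% 8 + 1]
  }
  set.seed(123)
  n_checked <- 0
  for (i in 1:100) {
    p <- random_near_pose(nuc, lh)
    pm <- twofold_pose(p, nuc)
    c1 <- classify(lh, p, nuc, sites = sites)
    c2 <- classify(lh, pm, nuc, sites = sites)
    for (el in c("alpha3", "beta1", "l1")) {
      expect_identical(as.integer(c2$contacts[[el]]),
                       as.integer(sort(-c1$contacts[[el]])))
    }
    expect_identical(c2$alpha3_symbol, mirror_arrow(c1$alpha3_symbol))
    swap <- c("on-dyad" = "on-dyad", "off-dyad-L-DNA1" = "off-dyad-L-DNA2",
              "off-dyad-L-DNA2" = "off-dyad-L-DNA1", "mixed" = "mixed",
              "none" = "none")
    expect_identical(c2$dyad_mode, unname(swap[c1$dyad_mode]))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 100)
})

test_that("classification is invariant under global rigid transforms", {
  nuc <- fx_nucleosome()
  lh <- fx_lh()
  p <- place_reference_pose(lh, nuc, "on-dyad")
  qg <- quat_from_axis_angle(c(1, 2, -1), 0.7)
  Rg <- quat_to_matrix(qg)
  tg <- c(15, -30, 40)
  # transform the whole system: nucleosome atoms and the pose
  nuc2 <- nuc
  xyz <- as.matrix(nuc$solute$atoms[, c("x", "y", "z")])
  xyz2 <- sweep(xyz %*% t(Rg), 2, tg, `+`)
  nuc2$solute$atoms$x <- xyz2[, 1]
  nuc2$solute$atoms$y <- xyz2[, 2]
  nuc2$solute$atoms$z <- xyz2[, 3]
  nuc2$dyad_point <- as.numeric(Rg %*% nuc$dyad_point) + tg
  nuc2$dyad_axis <- as.numeric(Rg %*% nuc$dyad_axis)
  nuc2$superhelix_center <- as.numeric(Rg %*% nuc$superhelix_center) + tg
  p2 <- pose(quat_multiply(qg, p$q), as.numeric(Rg %*% p$t) + tg)
  c1 <- classify(lh, p, nuc)
  c2 <- classify(lh, p2, nuc2)
  expect_identical(c1$string, c2$string)
  expect_identical(c1$dyad_mode, c2$dyad_mode)
})

test_that("configuration comparison categories follow the match scheme", {
  mk <- function(a3, b1, l1) {
    structure(list(contacts = list(alpha3 = a3, beta1 = b1, l1 = l1),
                   alpha3_symbol = "\u2191", dyad_mode = "on-dyad"),
              class = "lh_configuration")
  }
  ref <- mk(-3L, 0L, 3L)
  expect_equal(compare_configurations(ref, ref), "identical")
  expect_equal(compare_configurations(mk(-2L, 0L, 3L), ref), "partial")
  expect_equal(compare_configurations(mk(-2L, 1L, 3L), ref), "partial")
  expect_equal(compare_configurations(mk(-2L, 1L, 2L), ref), "different")
  # empty-vs-empty element lists count as matching
  expect_equal(compare_configurations(mk(integer(0), 0L, 3L),
                                      mk(integer(0), 0L, 2L)), "partial")
})

test_that("the match matrix reports planted shift counts", {
  mk <- function(a3, b1, l1) {
    cfg <- structure(list(contacts = list(alpha3 = a3, beta1 = b1, l1 = l1),
                          alpha3_symbol = "\u2191", dyad_mode = "on-dyad"),
                     class = "lh_configuration")
    cfg$string <- format(cfg)
    cfg
  }
  wt <- list(c1 = mk(-3L, 0L, 3L), c2 = mk(-1L, c(-2L, -1L), -2L))
  runs <- list(
    WT = wt,
    mutA = list(c1 = mk(-3L, 0L, 3L), c2 = mk(-1L, c(-2L, -1L), -2L)),  # 0 shifts
    mutB = list(c1 = mk(1L, 2L, 3L), c2 = mk(-1L, c(-2L, -1L), -2L)),   # 1 shift
    mutC = list(c1 = mk(1L, 2L, 2L), c2 = mk(0L, 0L, 0L)))              # 2 shifts
  mat <- build_match_matrix(runs)
  sc <- attr(mat, "shift_counts")
  expect_equal(unname(sc[c("mutA", "mutB", "mutC")]), c(0, 1, 2))
  expect_equal(nrow(mat), 8)
  expect_true(all(mat$category[mat$variant == "WT"] == "reference"))
  # a missing reference cell is flagged
  runs_bad <- runs
  runs_bad$mutA$c3 <- mk(0L, 0L, 0L)
  expect_warning(build_match_matrix(runs_bad), "without a reference")
})
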