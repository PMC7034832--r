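make_trio <- function(dOA, angle_deg = 180) {
  # donor O, its H on the x axis, acceptor placed so the D-H-A angle at H
  # equals angle_deg with d(D, A) = dOA
  atoms <- data.frame(serial = 1:3,
                      name = c("OD1", "HD1", "OA1"),
                      elem = c("O", "H", "O"),
                      resid = c(1, 1, 2), resname = c("DNR", "DNR", "ACC"),
                      chain = "X",
                      donor = c(TRUE, FALSE, FALSE),
                      acceptor = c(FALSE, FALSE, TRUE),
                      hydrogen_of = c(NA, 1L, NA),
                      stringsAsFactors = FALSE)
  top <- new_topology(atoms, bonds = cbind(1, 2))
  h <- c(1, 0, 0)
  th <- angle_deg * pi / 180
  # solve for acceptor on the D-H line rotated by (180 - angle) at H
  dir <- c(cos(pi - th), sin(pi - th), 0)
  # choose |HA| so that |DA| = dOA
  f <- function(r) sqrt(sum((h + r * dir)^2)) - dOA
  r <- uniroot(f, c(1e-3, dOA + 2))$root
  xyz <- rbind(c(0, 0, 0), h, h + r * dir)
  list(top = top, xyz = xyz)
}

test_that("collinear close donor-acceptor geometry is one hydrogen bond", {
  s <- make_trio(2.8, 180)
  ev <- detect_hbonds_frame(s$xyz, s$top)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$atom_a, 1L)
  expect_equal(ev$atom_b, 3L)
  expect_equal(ev$hydrogen, 2L)
  expect_equal(ev$distance, 2.8, tolerance = 1e-9)
  expect_equal(ev$angle, 180, tolerance = 1e-6)
})

test_that("the 4 Angstrom distance cutoff excludes a collinear pair", {
  s <- make_trio(4.5, 180)
  expect_equal(nrow(detect_hbonds_frame(s$xyz, s$top)), 0)
})

test_that("the 120 degree angle cutoff is honoured at the boundary", {
  just_in <- make_trio(3.0, 121)
  just_out <- make_trio(3.0, 119)
  expect_equal(nrow(detect_hbonds_frame(just_in$xyz, just_in$top)), 1)
  expect_equal(nrow(detect_hbonds_frame(just_out$xyz, just_out$top)), 0)
})

test_that("salt bridges count per heavy-atom pair with opposite signs only", {
  atoms <- data.frame(serial = 1:6,
                      name = c("NZ", "OE1", "OE2", "NH1", "NH2", "NZ2"),
                      elem = c("N", "O", "O", "N", "N", "N"),
                      resid = c(1, 2, 2, 3, 3, 4),
                      resname = c("LYS", "GLU", "GLU", "ARG", "ARG", "LYS"),
                      chain = "X",
                      charge_group = c(1L, 2L, 2L, 3L, 3L, 4L),
                      charge_sign = c(1L, -1L, -1L, 1L, 1L, 1L),
                      stringsAsFactors = FALSE)
  top <- new_topology(atoms)
  xyz <- rbind(c(0, 0, 0),      # Lys NZ
               c(3.5, 0, 0),    # Glu OE1: within 5 of NZ
               c(6.0, 0, 0),    # Glu OE2: beyond 5 of NZ
               c(3.5, 3.0, 0),  # Arg NH1: 4.6 from OE1, also near OE2
               c(30, 30, 30),   # Arg NH2 far away
               c(3.0, 0, 0))    # second Lys NZ: close to first but like-charged
  ev <- detect_salt_bridges_frame(xyz, top)
  got <- ev[order(ev$atom_a, ev$atom_b), c("atom_a", "atom_b")]
  # NZ-OE1; NH1-OE1 (4.61); NH1-OE2 (3.91); NZ2-OE1 (0.5); NZ2-OE2 (3.0)
  expect_equal(unname(as.matrix(got)),
               matrix(c(1L, 2L,  2L, 4L,  2L, 6L,  3L, 4L,  3L, 6L),
                      ncol = 2, byrow = TRUE))
  # like-charged close pair absent
  expect_false(any(ev$atom_a == 1 & ev$atom_b == 6))
})

test_that("multi-atom groups produce one event per qualifying atom pair", {
  # Arg guanidinium (NE/NH1/NH2) facing both phosphate oxygens: 6 events
  atoms <- data.frame(serial = 1:5,
                      name = c("NE", "NH1", "NH2", "OP1", "OP2"),
                      elem = c("N", "N", "N", "O", "O"),
                      resid = c(1, 1, 1, 2, 2),
                      resname = c("ARG", "ARG", "ARG", "DC", "DC"),
                      chain = "X",
                      charge_group = c(1L, 1L, 1L, 2L, 2L),
                      charge_sign = c(1L, 1L, 1L, -1L, -1L),
                      stringsAsFactors = FALSE)
  top <- new_topology(atoms)
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0),
               c(3.0, 0, 0), c(0, 3.0, 0))
  ev <- detect_salt_bridges_frame(xyz, top)
  expect_equal(nrow(ev), 6)
})

test_that("detectors reproduce an all-pairs/all-triples brute-force oracle", {
  top <- random_contact_system(n_units = 10, seed = 11)
  frames <- random_frames(nrow(top$atoms), 25, box = 8, seed = 12)
  for (f in seq_len(dim(frames)[3])) {
    xyz <- frames[, , f]
    hb <- detect_hbonds_frame(xyz, top)
    expect_equal(event_matrix(hb, c("atom_a", "hydrogen", "atom_b")),
                 unname(oracle_hbonds(xyz, top)))
    sb <- detect_salt_bridges_frame(xyz, top)
    expect_equal(event_matrix(sb, c("atom_a", "atom_b")),
                 unname(oracle_salt(xyz, top)))
  }
})

test_that("detector results are invariant under rigid motion", {
  top <- random_contact_system(n_units = 8, seed = 3)
  xyz <- random_frames(nrow(top$atoms), 1, seed = 4)[, , 1]
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  moved <- xyz %*% t(R) + matrix(rep(c(5, -3, 11), each = nrow(xyz)), ncol = 3)
  for (detect in list(detect_hbonds_frame, detect_salt_bridges_frame)) {
    a <- detect(xyz, top)
    b <- detect(moved, top)
    expect_equal(a$atom_a, b$atom_a)
    expect_equal(a$atom_b, b$atom_b)
    expect_equal(a$distance, b$distance, tolerance = 1e-9)
  }
})

test_that("contact time series recover planted per-frame truth", {
  ints <- data.frame(kind = "hbond", count = 1, occupancy = 0.4)
  tr <- plant_contact_trajectory(ints, n_frames = 10, seed = 5)
  cs <- contact_time_series(tr)
  expect_equal(nrow(cs$keys), 1)
  counts <- as.integer(cs$counts[1, ])
  on <- attr(tr, "on_frames")[[1]]
  expect_equal(which(counts == 1), on)
  expect_equal(sum(counts), 4)
  st <- series_table(cs)
  expect_equal(st$occupancy, 0.4)
})

test_that("a static frame repeated gives constant series", {
  ints <- data.frame(kind = "saltbridge", count = 2, occupancy = 1.0)
  tr <- plant_contact_trajectory(ints, n_frames = 20, seed = 2)
  cs <- contact_time_series(tr)
  expect_true(all(apply(cs$counts, 1, function(r) length(unique(r)) == 1)))
})

test_that("series obey mean/occupancy bounds", {
  top <- random_contact_system(n_units = 6, seed = 21)
  frames <- random_frames(nrow(top$atoms), 40, seed = 22)
  tr <- new_trajectory(top, frames)
  st <- series_table(contact_time_series(tr))
  expect_true(all(st$mean_count >= st$occupancy - 1e-12))
  maxc <- apply(contact_time_series(tr)$counts, 1, max)
  expect_true(all(st$mean_count <= st$occupancy * maxc + 1e-12))
})
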