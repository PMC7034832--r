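planted_series <- function(occupancies, counts, kinds = NULL,
                           n_frames = 100, seed = 1) {
  ints <- data.frame(kind = kinds %||% rep("hbond", length(occupancies)),
                     count = counts, occupancy = occupancies)
  tr <- plant_contact_trajectory(ints, n_frames = n_frames, seed = seed)
  list(trajectory = tr, series = contact_time_series(tr),
       node_map = make_node_map(tr$topology))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("merging replica series is frame-weighted concatenation", {
  p <- planted_series(c(1.0, 0.5), c(1, 1), n_frames = 40, seed = 2)
  q <- planted_series(c(1.0, 1.0), c(1, 1), n_frames = 40, seed = 3)
  m <- merge_series(list(p$series, q$series))
  expect_equal(m$n_frames, 80)
  st <- series_table(m)
  # second planted pair: occupied 0.5 in p and 1.0 in q -> merged mean 0.75
  expect_equal(sort(st$mean_count), c(0.75, 1.0))
  # single replica is the identity
  expect_identical(merge_series(list(p$series))$counts, p$series$counts)
})

test_that("merged replicas equal a single concatenated trajectory", {
  ints <- data.frame(kind = c("hbond", "saltbridge"), count = c(2, 1),
                     occupancy = c(0.6, 0.3))
  reps <- lapply(1:5, function(i)
    plant_contact_trajectory(ints, n_frames = 20, seed = 100 + i))
  per_rep <- lapply(reps, contact_time_series)
  merged <- merge_series(per_rep)
  concat <- contact_time_series(merge_trajectories(reps))
  expect_equal(merged$keys, concat$keys)
  expect_equal(merged$counts, concat$counts)
})

test_that("network aggregation sums atom counts into node weights", {
  # two hydrogen bonds always present between one residue pair -> one edge
  # with mean_count 2.0
  p <- planted_series(1.0, 2, n_frames = 30)
  net <- build_network(p$series, p$node_map, prune_occupancy = 0.15)
  expect_equal(nrow(net), 1)
  expect_equal(net$mean_count, 2.0)
  expect_equal(net$occupancy, 1.0)
})

test_that("pruning omits edges at or below the threshold, strictly", {
  for (thr in c(0.10, 0.15)) {
    p <- planted_series(c(thr, thr + 0.05), c(1, 1), n_frames = 100,
                        seed = 7)
    net <- build_network(p$series, p$node_map, prune_occupancy = thr)
    expect_equal(nrow(net), 1)
    expect_equal(net$occupancy, thr + 0.05, tolerance = 1e-12)
  }
})

test_that("raising the pruning threshold never adds edges", {
  p <- planted_series(c(0.9, 0.6, 0.3, 0.1), c(1, 1, 1, 1), seed = 9)
  edges_at <- function(thr)
    nrow(build_network(p$series, p$node_map, prune_occupancy = thr))
  ns <- vapply(c(0, 0.2, 0.5, 0.8), edges_at, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("salt-bridge precedence drops the parallel hydrogen-bond edge", {
  # same residue pair carrying both kinds: build a custom topology
  atoms <- data.frame(serial = 1:4,
                      name = c("OD1", "HD1", "NP1", "OA1"),
                      elem = c("O", "H", "N", "O"),
                      resid = c(1, 1, 1, 2), resname = c("A", "A", "A", "B"),
                      chain = "X",
                      donor = c(TRUE, FALSE, FALSE, FALSE),
                      acceptor = c(FALSE, FALSE, FALSE, TRUE),
                      hydrogen_of = c(NA, 1L, NA, NA),
                      charge_group = c(NA, NA, 1L, 2L),
                      charge_sign = c(0L, 0L, 1L, -1L),
                      stringsAsFactors = FALSE)
  top <- new_topology(atoms, bonds = cbind(1, 2))
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 3, 0), c(3, 0, 0))
  tr <- new_trajectory(top, array(rep(xyz, 10), dim = c(4, 3, 10)))
  cs <- contact_time_series(tr)
  expect_setequal(cs$keys$kind, c("hbond", "saltbridge"))
  nm <- make_node_map(top)
  with_prec <- build_network(cs, nm, 0, salt_bridge_precedence = TRUE)
  without <- build_network(cs, nm, 0, salt_bridge_precedence = FALSE)
  expect_equal(nrow(with_prec), 1)
  expect_equal(with_prec$kind, "saltbridge")
  expect_equal(nrow(without), 2)
})

test_that("total network weight equals the total event count at prune 0", {
  top <- random_contact_system(n_units = 6, seed = 31)
  tr <- new_trajectory(top, random_frames(nrow(top$atoms), 30, seed = 32))
  cs <- contact_time_series(tr)
  net <- build_network(cs, make_node_map(top), prune_occupancy = 0,
                       salt_bridge_precedence = FALSE)
  expect_equal(sum(net$mean_count * net$n_frames), sum(cs$counts))
})

test_that("network comparison subtracts edge weights with implicit zeros", {
  p <- planted_series(c(1.0, 0.8), c(2, 1), seed = 41)
  q <- planted_series(1.0, 2, seed = 42)
  a <- build_network(p$series, p$node_map, 0.15)
  b <- build_network(q$series, q$node_map, 0.15)
  d <- compare_networks(a, b)
  # the edge present only in a appears with delta = -weight
  only_a <- d[d$mean_count_b == 0 & d$mean_count_a > 0, ]
  expect_equal(only_a$delta_mean_count, -only_a$mean_count_a)
  same <- compare_networks(a, a)
  expect_true(all(same$delta_mean_count == 0))
  expect_true(all(same$delta_occupancy == 0))
})

test_that("graphml export round-trips losslessly and edgelist/dot write", {
  p <- planted_series(c(1.0, 0.6, 0.3), c(2, 1, 1),
                      kinds = c("hbond", "saltbridge", "hbond"), seed = 51)
  net <- build_network(p$series, p$node_map, 0.15)
  f <- tempfile(fileext = ".graphml")
  export_network(net, f, "graphml")
  back <- import_network_graphml(f)
  a <- as.data.frame(back)[order(back$node_a, back$node_b), ]
  b <- as.data.frame(net)[order(net$node_a, net$node_b), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, tolerance = 1e-12)
  fe <- tempfile(fileext = ".tsv")
  export_network(net, fe, "edgelist")
  expect_equal(nrow(utils::read.delim(fe)), nrow(net))
  fd <- tempfile(fileext = ".dot")
  export_network(net, fd, "dot")
  expect_true(any(grepl("--", readLines(fd))))
  # empty network still exports a valid document
  low <- planted_series(0.3, 1, seed = 52)
  empty <- build_network(low$series, low$node_map, 0.9)
  fg <- tempfile(fileext = ".graphml")
  export_network(empty, fg, "graphml")
  expect_equal(nrow(import_network_graphml(fg)), 0)
})

test_that("atom-group nodes must stay within one residue", {
  p <- planted_series(1.0, 1, seed = 61)
  top <- p$trajectory$topology
  expect_error(make_node_map(top, groups = list(bad = c(1, nrow(top$atoms)))),
               "one residue")
})
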