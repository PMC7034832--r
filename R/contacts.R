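#' Detect hydrogen bonds in a single frame
#'
#' Geometric criterion of the trajectory-analysis convention: one event per
#' (donor heavy atom D, its bonded hydrogen H, acceptor A) triple with
#' donor-acceptor heavy-atom distance <= `d_cut` and D-H-A angle >=
#' `angle_cut` (180 degrees is the ideal, collinear geometry). Donors and
#' acceptors must have been annotated with [annotate_chemistry()].
#'
#' @param xyz `n_atoms x 3` frame coordinates.
#' @param topology annotated topology.
#' @param d_cut donor-acceptor distance cutoff, Angstrom (default 4).
#' @param angle_cut D-H-A angle cutoff, degrees (default 120).
#' @param exclude_same_residue drop donor/acceptor pairs within one residue.
#' @return data.frame of events: `kind`, `atom_a` (donor heavy), `atom_b`
#'   (acceptor), `hydrogen`, `distance`, `angle`.
#' @export
detect_hbonds_frame <- function(xyz, topology, d_cut = 4.0, angle_cut = 120,
                                exclude_same_residue = FALSE) {
  stopifnot(d_cut > 0, angle_cut > 0, angle_cut <= 180)
  atoms <- topology$atoms
  donors <- which(atoms$donor)
  acceptors <- which(atoms$acceptor)
  empty <- data.frame(kind = character(0), atom_a = integer(0),
                      atom_b = integer(0), hydrogen = integer(0),
                      distance = numeric(0), angle = numeric(0))
  if (!length(donors) || !length(acceptors)) return(empty)

  hyd_of <- atoms$hydrogen_of
  hydrogens_by_donor <- split(which(!is.na(hyd_of)), hyd_of[!is.na(hyd_of)])

  d <- pair_dist(xyz[donors, , drop = FALSE], xyz[acceptors, , drop = FALSE])
  cand <- which(d <= d_cut, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)

  rkey <- residue_keys(topology)
  out <- vector("list", nrow(cand))
  k <- 0L
  for (r in seq_len(nrow(cand))) {
    D <- donors[cand[r, 1]]
    A <- acceptors[cand[r, 2]]
    if (D == A) next
    if (exclude_same_residue && rkey[D] == rkey[A]) next
    hs <- hydrogens_by_donor[[as.character(D)]]
    if (is.null(hs))
      stop_dyadmd("internal invariant violation: donor atom ", D,
                  " has no bonded hydrogen (annotation bug)")
    for (H in hs) {
      ang <- angle_deg(xyz[D, ], xyz[H, ], xyz[A, ])
      if (ang >= angle_cut) {
        k <- k + 1L
        out[[k]] <- data.frame(kind = "hbond", atom_a = D, atom_b = A,
                               hydrogen = H, distance = d[cand[r, 1], cand[r, 2]],
                               angle = ang)
      }
    }
  }
  if (!k) return(empty)
  ev <- do.call(rbind, out[seq_len(k)])
  ev <- ev[order(ev$atom_a, ev$atom_b, ev$hydrogen), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Detect salt bridges in a single frame
#'
#' One event per heavy-atom pair (a in group G1, b in group G2) with opposite
#' group signs and distance <= `d_cut`; pairs within a single residue are
#' excluded. Counting is per heavy-atom pair, so multi-atom groups (e.g. an
#' arginine guanidinium facing both phosphate oxygens) can contribute several
#' simultaneous interactions.
#'
#' @param xyz `n_atoms x 3` frame coordinates.
#' @param topology annotated topology.
#' @param d_cut heavy-atom distance cutoff, Angstrom (default 5).
#' @return data.frame of events: `kind`, `atom_a`, `atom_b`, `hydrogen`
#'   (NA), `distance`, `angle` (NA). `atom_a < atom_b`.
#' @export
detect_salt_bridges_frame <- function(xyz, topology, d_cut = 5.0) {
  stopifnot(d_cut > 0)
  atoms <- topology$atoms
  charged <- which(!is.na(atoms$charge_group))
  empty <- data.frame(kind = character(0), atom_a = integer(0),
                      atom_b = integer(0), hydrogen = integer(0),
                      distance = numeric(0), angle = numeric(0))
  if (length(charged) < 2) return(empty)
  pos <- charged[atoms$charge_sign[charged] > 0]
  neg <- charged[atoms$charge_sign[charged] < 0]
  if (!length(pos) || !length(neg)) return(empty)

  d <- pair_dist(xyz[pos, , drop = FALSE], xyz[neg, , drop = FALSE])
  cand <- which(d <= d_cut, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  rkey <- residue_keys(topology)
  a <- pos[cand[, 1]]
  b <- neg[cand[, 2]]
  keep <- rkey[a] != rkey[b]
  a <- a[keep]; b <- b[keep]
  if (!length(a)) return(empty)
  dd <- d[cand][keep]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  ord <- order(a, b)
  data.frame(kind = "saltbridge", atom_a = a[ord], atom_b = b[ord],
             hydrogen = NA_integer_, distance = dd[ord], angle = NA_real_)
}

#' Contact time series over a trajectory
#'
#' Runs the hydrogen-bond and/or salt-bridge detectors on every frame and
#' collects, for every atom pair (and kind) seen at least once, a per-frame
#' integer count series. Atom-level series are the finest granularity; node
#' aggregation happens in [build_network()].
#'
#' @param trajectory a trajectory with annotated topology.
#' @param kinds subset of `c("hbond", "saltbridge")`.
#' @param hbond_dist,hbond_angle,salt_dist detector cutoffs.
#' @param exclude_same_residue passed to the hydrogen-bond detector.
#' @return object of class `"contact_series"`: list with `keys`
#'   (data.frame `atom_a`, `atom_b`, `kind`), `counts` (integer matrix,
#'   `n_keys x n_frames`), `n_frames`, and the topology.
#' @export
contact_time_series <- function(trajectory, kinds = c("hbond", "saltbridge"),
                                hbond_dist = 4.0, hbond_angle = 120,
                                salt_dist = 5.0,
                                exclude_same_residue = FALSE) {
  nf <- n_frames(trajectory)
  if (!nf) stop_dyadmd("trajectory is empty")
  top <- trajectory$topology
  events <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- frame_xyz(trajectory, f)
    if (nrow(xyz) != n_atoms(top))
      stop_dyadmd("frame ", f, ": atom count mismatch with topology")
    ev <- list()
    if ("hbond" %in% kinds)
      ev$h <- detect_hbonds_frame(xyz, top, hbond_dist, hbond_angle,
                                  exclude_same_residue)
    if ("saltbridge" %in% kinds)
      ev$s <- detect_salt_bridges_frame(xyz, top, salt_dist)
    ev <- do.call(rbind, ev)
    if (!is.null(ev) && nrow(ev)) {
      ev$frame <- f
      events[[f]] <- ev[, c("frame", "atom_a", "atom_b", "kind")]
    }
  }
  events <- do.call(rbind, events)
  if (is.null(events) || !nrow(events)) {
    return(structure(list(keys = data.frame(atom_a = integer(0),
                                            atom_b = integer(0),
                                            kind = character(0)),
                          counts = matrix(0L, nrow = 0, ncol = nf),
                          n_frames = nf, topology = top),
                     class = "contact_series"))
  }
  key <- paste(events$atom_a, events$atom_b, events$kind, sep = "|")
  ukey <- sort(unique(key))
  counts <- unclass(table(factor(key, levels = ukey),
                          factor(events$frame, levels = seq_len(nf))))
  counts <- matrix(as.integer(counts), nrow = length(ukey),
                   dimnames = NULL)
  parts <- strsplit(ukey, "|", fixed = TRUE)
  keys <- data.frame(atom_a = as.integer(vapply(parts, `[`, "", 1)),
                     atom_b = as.integer(vapply(parts, `[`, "", 2)),
                     kind = vapply(parts, `[`, "", 3),
                     stringsAsFactors = FALSE)
  structure(list(keys = keys, counts = counts, n_frames = nf, topology = top),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("contact series: %d atom-pair keys over %d frames (%d hbond, %d saltbridge)\n",
              nrow(x$keys), x$n_frames, sum(x$keys$kind == "hbond"),
              sum(x$keys$kind == "saltbridge")))
  invisible(x)
}

#' Summary table of a contact series
#'
#' One row per pair key with occupancy (fraction of frames with at least one
#' interaction) and mean interactions per frame; exportable as TSV.
#'
#' @param series a contact_series.
#' @export
series_table <- function(series) {
  occ <- if (nrow(series$counts)) rowMeans(series$counts >= 1) else numeric(0)
  mc <- if (nrow(series$counts)) rowMeans(series$counts) else numeric(0)
  cbind(series$keys,
        data.frame(occupancy = occ, mean_count = mc,
                   n_frames = rep(series$n_frames, length(occ))))
}
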