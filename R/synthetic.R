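#' Synthetic fixtures
#'
#' Generators for every input the pipeline consumes: ideal B-form duplexes
#' (optionally with a flipped-out base), trajectories with contacts planted
#' at exact per-frame counts and occupancies, harmonic positional ensembles
#' of known magnitude, replica sets containing deliberately divergent
#' members, and noisy 1:1 binding titrations. All generators are
#' deterministic given their seed and spec.
#'
#' @name synthetic_data
NULL

#' Generate an ideal B-form DNA duplex
#'
#' Two antiparallel strands of pseudo-nucleotides placed on a regular helix
#' (default rise 3.38 Angstrom, twist 36 degrees, i.e. 10 bp/turn). Each
#' residue carries the atoms the analyses touch: backbone P/OP1/OP2, a C1'
#' anchor, and a six-membered ring (N1/C2/N3/C4/C5/C6) whose pairing
#' nitrogen points at the helix axis so that declared pairs satisfy the
#' N1-N3 proximity check. A flipped-out base can be produced by rotating one
#' strand-1 base out of the helix (its ring is displaced radially outward,
#' breaking the pairing geometry while the backbone stays in place).
#' Fidelity to real sugar chemistry is out of scope: the duplex is a
#' geometric scaffold for groove, contact and superposition analyses.
#'
#' @param sequence strand-1 base letters (length >= 4); strand 2 is the
#'   reverse complement.
#' @param rise helical rise per bp, Angstrom.
#' @param twist helical twist per bp, degrees (0 < twist < 180).
#' @param flipped_position optional strand-1 base index to flip out.
#' @param groove_phase backbone phase angle between the strands, degrees;
#'   controls the minor/major groove asymmetry (default 154, B-like).
#' @return list with `topology` (reference coordinates attached) and
#'   `pairing` (data.frame accepted by [assign_base_pairs()], with the
#'   flipped position marked unpaired).
#' @export
generate_bdna <- function(sequence = "ACGTACGTACGTAC", rise = 3.38,
                          twist = 36, flipped_position = NULL,
                          groove_phase = 154) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  nbp <- length(bases)
  stopifnot(nbp >= 4, rise > 0, twist > 0, twist < 180)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  if (!all(bases %in% names(comp))) stop_dyadmd("sequence must be A/C/G/T")

  gamma <- (180 - groove_phase) / 2      # P offset from the pair axis
  r_p <- 8.9; r_ring <- 1.45             # backbone and pairing-N radii
  deg <- pi / 180
  rows <- list(); coords <- list()
  serial <- 0L

  ring_names <- function(base) {
    # ring listed from the pairing vertex outward around the hexagon
    if (base %in% c("C", "T")) c("N3", "C2", "N1", "C6", "C5", "C4")
    else c("N1", "C2", "N3", "C4", "C5", "C6")
  }
  add_residue <- function(base, resid, chain, beta_deg, z, p_angle_deg,
                          flipped = FALSE) {
    e <- c(cos(beta_deg * deg), sin(beta_deg * deg), 0)
    perp <- c(-e[2], e[1], 0)
    pa <- p_angle_deg * deg
    p_pos <- c(r_p * cos(pa), r_p * sin(pa), z)
    op_dir <- c(cos(pa), sin(pa), 0)
    atoms <- list(P = p_pos,
                  OP1 = p_pos + 1.0 * op_dir + c(0, 0, 0.9),
                  OP2 = p_pos + 1.0 * op_dir + c(0, 0, -0.9))
    atoms$`C1'` <- 0.68 * (5.5 * e + c(0, 0, z)) + 0.32 * p_pos
    ring_shift <- if (flipped) 8.0 else 0    # push the base out of the helix
    pairing_pos <- (r_ring + ring_shift) * e + c(0, 0, z)
    centre <- pairing_pos + 1.39 * e
    rn <- ring_names(base)
    for (k in seq_along(rn)) {
      ang <- (k - 1) * 60 * deg
      # hexagon in the base plane spanned by e (radial) and perp
      offs <- 1.39 * (-cos(ang) * e + sin(ang) * perp)
      atoms[[rn[k]]] <- centre + offs
    }
    resname <- paste0("D", base)
    for (nm in names(atoms)) {
      serial <<- serial + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        serial = serial, name = nm, elem = element_from_name(nm),
        resid = resid, resname = resname, chain = chain,
        stringsAsFactors = FALSE)
      coords[[length(coords) + 1L]] <<- atoms[[nm]]
    }
  }

  for (j in seq_len(nbp)) {
    beta <- (j - 1) * twist
    z <- (j - 1) * rise
    flip <- !is.null(flipped_position) && j == flipped_position
    add_residue(bases[j], resid = j, chain = "A",
                beta_deg = beta, z = z, p_angle_deg = beta + gamma,
                flipped = flip)
  }
  for (j in seq_len(nbp)) {
    # strand 2 residue numbering runs antiparallel: residue j sits at
    # pair level nbp + 1 - j
    lv <- nbp + 1 - j
    beta <- (lv - 1) * twist
    z <- (lv - 1) * rise
    add_residue(comp[bases[lv]], resid = j, chain = "B",
                beta_deg = beta + 180, z = z,
                p_angle_deg = beta + 180 - gamma)
  }
  atoms <- do.call(rbind, rows)
  xyz <- do.call(rbind, coords)
  top <- new_topology(atoms, bonds = NULL, xyz = xyz)
  pairing <- data.frame(bp = seq_len(nbp), chain1 = "A",
                        resid1 = seq_len(nbp), chain2 = "B",
                        resid2 = nbp + 1 - seq_len(nbp))
  if (!is.null(flipped_position))
    pairing$resid2[pairing$bp == flipped_position] <- NA_integer_
  list(topology = top, pairing = pairing)
}

#' Generate a pseudo-protein C-alpha trace
#'
#' A helical C-alpha trace (non-collinear by construction) used as the
#' protein component of synthetic complexes for alignment and QC tests.
#'
#' @param n_res number of residues.
#' @param start_resid first residue number (default 432, echoing the
#'   structured-core numbering convention of SRA-domain systems).
#' @param radius,rise_per_res,turn_per_res helix parameters.
#' @param centre 3-vector offset.
#' @return a topology with coordinates attached.
#' @export
generate_ca_protein <- function(n_res = 30, start_resid = 432, radius = 18,
                                rise_per_res = 1.5, turn_per_res = 100,
                                centre = c(0, 0, 0)) {
  deg <- pi / 180
  i <- seq_len(n_res)
  xyz <- cbind(radius * cos((i - 1) * turn_per_res * deg),
               radius * sin((i - 1) * turn_per_res * deg),
               (i - 1) * rise_per_res)
  xyz <- sweep(xyz, 2, centre, "+")
  atoms <- data.frame(serial = i, name = "CA", elem = "C",
                      resid = start_resid + i - 1, resname = "ALA",
                      chain = "P", stringsAsFactors = FALSE)
  new_topology(atoms, bonds = NULL, xyz = xyz)
}

#' Combine topologies into one system
#'
#' Concatenates atoms, bonds and reference coordinates; serials are
#' renumbered consecutively. Chains must be distinct.
#' @param ... topologies with coordinates.
#' @export
combine_topologies <- function(...) {
  tops <- list(...)
  chains <- unlist(lapply(tops, function(t) unique(t$atoms$chain)))
  if (anyDuplicated(chains)) stop_dyadmd("chain ids must be distinct")
  offset <- 0L
  atoms <- list(); bonds <- list(); xyz <- list()
  for (t in tops) {
    a <- t$atoms
    a$serial <- offset + seq_len(nrow(a))
    a$hydrogen_of <- a$hydrogen_of + offset
    atoms[[length(atoms) + 1]] <- a
    if (nrow(t$bonds)) bonds[[length(bonds) + 1]] <- t$bonds + offset
    xyz[[length(xyz) + 1]] <- t$xyz
    offset <- offset + nrow(a)
  }
  new_topology(do.call(rbind, atoms),
               bonds = if (length(bonds)) do.call(rbind, bonds) else NULL,
               xyz = do.call(rbind, xyz))
}

#' Plant contacts in a synthetic trajectory
#'
#' Builds its own scaffold: for each planted interaction, a residue pair
#' carrying exactly `count` donor-hydrogen/acceptor units (hydrogen bonds)
#' or positive/negative charge-group atom pairs (salt bridges). On "on"
#' frames the partner atoms sit well inside the acceptance geometry
#' (distance cutoff minus 0.5 Angstrom, collinear D-H-A); on "off" frames
#' they sit at cutoff + 1 Angstrom, so floating-point jitter can never flip
#' a detection. The set of on frames is drawn deterministically from `seed`
#' with exactly `round(occupancy * n_frames)` members, so realized
#' occupancy equals the spec occupancy exactly whenever
#' `occupancy * n_frames` is integral.
#'
#' @param interactions data.frame with columns `kind` (`"hbond"` /
#'   `"saltbridge"`), `count` (planted interactions per on-frame, >= 1) and
#'   `occupancy` in `[0, 1]`.
#' @param n_frames number of frames.
#' @param seed RNG seed (fully determines the output).
#' @param hbond_dist,salt_dist detector cutoffs the geometry is planted
#'   against.
#' @return a trajectory whose topology is pre-annotated; the planted truth
#'   (residue labels, kind, count, occupancy, on-frames) is attached as
#'   attribute `"planted"`.
#' @export
plant_contact_trajectory <- function(interactions, n_frames = 100, seed = 1,
                                     hbond_dist = 4.0, salt_dist = 5.0) {
  stopifnot(is.data.frame(interactions),
            all(c("kind", "count", "occupancy") %in% names(interactions)),
            all(interactions$count >= 1),
            all(interactions$occupancy >= 0 & interactions$occupancy <= 1))
  ni <- nrow(interactions)
  rows <- list(); base_xyz <- list(); bonds <- list()
  serial <- 0L
  unit_spacing <- 15; pair_spacing <- 200
  add_atom <- function(name, elem, resid, resname, pos,
                       donor = FALSE, acceptor = FALSE,
                       hydrogen_of = NA_integer_,
                       charge_group = NA_integer_, charge_sign = 0L) {
    serial <<- serial + 1L
    rows[[serial]] <<- data.frame(serial = serial, name = name, elem = elem,
                                  resid = resid, resname = resname,
                                  chain = "X", donor = donor,
                                  acceptor = acceptor,
                                  hydrogen_of = hydrogen_of,
                                  charge_group = charge_group,
                                  charge_sign = charge_sign,
                                  stringsAsFactors = FALSE)
    base_xyz[[serial]] <<- pos
    serial
  }
  # partner atoms that move between on/off frames, with their two positions
  movers <- list()
  gid <- 0L
  for (j in seq_len(ni)) {
    kind <- interactions$kind[j]
    count <- interactions$count[j]
    z0 <- (j - 1) * pair_spacing
    res_a <- 2L * j - 1L
    res_b <- 2L * j
    for (u in seq_len(count)) {
      y0 <- (u - 1) * unit_spacing
      if (kind == "hbond") {
        d_id <- add_atom(paste0("OD", u), "O", res_a, "DNR",
                         c(0, y0, z0), donor = TRUE, acceptor = FALSE)
        add_atom(paste0("HD", u), "H", res_a, "DNR",
                 c(1.0, y0, z0), hydrogen_of = d_id)
        a_on <- c(hbond_dist - 0.5, y0, z0)
        a_off <- c(hbond_dist + 1.0, y0, z0)
        a_id <- add_atom(paste0("OA", u), "O", res_b, "ACC",
                         a_on, acceptor = TRUE)
        movers[[length(movers) + 1]] <- list(id = a_id, on = a_on,
                                             off = a_off, interaction = j)
      } else if (kind == "saltbridge") {
        gid <- gid + 1L
        p_id <- add_atom(paste0("NP", u), "N", res_a, "PSB",
                         c(0, y0, z0), charge_group = gid, charge_sign = 1L)
        gid <- gid + 1L
        b_on <- c(salt_dist - 0.5, y0, z0)
        b_off <- c(salt_dist + 1.0, y0, z0)
        b_id <- add_atom(paste0("ON", u), "O", res_b, "NSB",
                         b_on, charge_group = gid, charge_sign = -1L)
        movers[[length(movers) + 1]] <- list(id = b_id, on = b_on,
                                             off = b_off, interaction = j)
      } else stop_dyadmd("unknown kind: ", kind)
    }
  }
  atoms <- do.call(rbind, rows)
  xyz0 <- do.call(rbind, base_xyz)
  top <- new_topology(atoms, bonds = NULL, xyz = xyz0)

  on_frames <- with_seed(seed, lapply(seq_len(ni), function(j) {
    n_on <- round(interactions$occupancy[j] * n_frames)
    sort(sample.int(n_frames, n_on))
  }))
  coords <- array(rep(xyz0, n_frames), dim = c(nrow(xyz0), 3, n_frames))
  for (m in movers) {
    on <- on_frames[[m$interaction]]
    off <- setdiff(seq_len(n_frames), on)
    for (f in off) coords[m$id, , f] <- m$off
    for (f in on) coords[m$id, , f] <- m$on
  }
  truth <- interactions
  truth$res_a <- paste0(ifelse(truth$kind == "hbond", "DNR", "PSB"),
                        2L * seq_len(ni) - 1L)
  truth$res_b <- paste0(ifelse(truth$kind == "hbond", "ACC", "NSB"),
                        2L * seq_len(ni))
  truth$realized_occupancy <- vapply(on_frames, length, 1L) / n_frames
  tr <- new_trajectory(top, coords, replica_id = "planted",
                       system_label = "planted")
  attr(tr, "planted") <- truth
  attr(tr, "on_frames") <- on_frames
  tr
}

#' Harmonic positional ensemble
#'
#' Frames are the reference plus isotropic Gaussian noise with per-atom,
#' per-coordinate standard deviation `sigmas`; the analytic per-atom RMSF is
#' `sqrt(3) * sigma`.
#'
#' @param topology a topology.
#' @param reference `n_atoms x 3` matrix (default: the topology's xyz).
#' @param sigmas scalar or per-atom vector of Angstrom standard deviations.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param ... passed to [new_trajectory()].
#' @export
harmonic_ensemble <- function(topology, reference = NULL, sigmas = 0.5,
                              n_frames = 2000, seed = 1, ...) {
  ref <- reference %||% topology$xyz
  if (is.null(ref)) stop_dyadmd("no reference coordinates")
  na <- nrow(ref)
  sigmas <- rep_len(sigmas, na)
  stopifnot(all(sigmas >= 0))
  coords <- with_seed(seed, {
    out <- array(NA_real_, dim = c(na, 3, n_frames))
    for (f in seq_len(n_frames))
      out[, , f] <- ref + matrix(stats::rnorm(3 * na, sd = sigmas),
                                 ncol = 3)
    out
  })
  new_trajectory(topology, coords, ...)
}

#' Generate a replica set with optional divergent members
#'
#' Each replica is an independent harmonic ensemble around the reference;
#' divergent members additionally have a selection of atoms (typically the
#' DNA) rigidly displaced by `displacement` Angstrom along x in the tail
#' window, emulating a structurally diverged trajectory that replica QC
#' should exclude.
#'
#' @param topology a topology with reference coordinates.
#' @param n number of replicas.
#' @param n_frames frames per replica.
#' @param sigma harmonic noise level (Angstrom per coordinate).
#' @param divergent indices of divergent replicas.
#' @param displacement rigid displacement of the divergent selection,
#'   Angstrom.
#' @param displace_selection selection displaced in divergent members.
#' @param tail_fraction trailing fraction of frames carrying the
#'   displacement (default 1.0: the whole run is displaced).
#' @param seed base seed; replica i uses `seed * 1000 + i`.
#' @param dt frame spacing, ps.
#' @export
make_replica_set <- function(topology, n = 5, n_frames = 100, sigma = 0.15,
                             divergent = integer(0), displacement = 6,
                             displace_selection = "dna",
                             tail_fraction = 1.0, seed = 1, dt = 100) {
  idx <- as_indices(topology, displace_selection)
  lapply(seq_len(n), function(i) {
    tr <- harmonic_ensemble(topology, sigmas = sigma, n_frames = n_frames,
                            seed = seed * 1000 + i, dt = dt,
                            replica_id = paste0("r", i))
    if (i %in% divergent) {
      first_tail <- n_frames - floor(tail_fraction * n_frames) + 1
      for (f in seq.int(first_tail, n_frames))
        tr$coords[idx, 1, f] <- tr$coords[idx, 1, f] + displacement
    }
    tr
  })
}

#' Simulate a 1:1 binding titration
#'
#' Response follows the hyperbolic isotherm
#' `baseline + amplitude * c / (c + kd)` with additive Gaussian noise,
#' emulating a normalized thermophoresis or anisotropy readout.
#'
#' @param kd dissociation constant (same units as `concentrations`,
#'   typically micromolar).
#' @param concentrations titration points (> 0).
#' @param amplitude,baseline response scale.
#' @param noise_sd Gaussian noise standard deviation (response units).
#' @param seed RNG seed.
#' @return data.frame with `concentration` and `response`.
#' @export
simulate_binding_curve <- function(kd, concentrations, amplitude = 1,
                                   baseline = 0, noise_sd = 0, seed = 1) {
  stopifnot(kd > 0, all(concentrations > 0))
  resp <- baseline + amplitude * concentrations / (concentrations + kd)
  if (noise_sd > 0)
    resp <- resp + with_seed(seed, stats::rnorm(length(resp), sd = noise_sd))
  data.frame(concentration = concentrations, response = resp)
}
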