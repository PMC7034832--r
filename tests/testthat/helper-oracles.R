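# Independent brute-force oracles and random-system builders used across the
# suite. The oracles deliberately share no code with the package detectors:
# plain loops over all pairs/triples.

# Random annotated system: a mix of donor-H units, acceptors and charged
# atoms scattered in a box, as one residue per atom group so that
# same-residue exclusions do not bite.
random_contact_system <- function(n_units = 10, box = 8, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    serial <- 0L
    add <- function(name, elem, resid, donor = FALSE, acceptor = FALSE,
                    hydrogen_of = NA_integer_, charge_group = NA_integer_,
                    charge_sign = 0L) {
      serial <<- serial + 1L
      rows[[serial]] <<- data.frame(serial = serial, name = name, elem = elem,
                                    resid = resid, resname = "UNK",
                                    chain = "X", donor = donor,
                                    acceptor = acceptor,
                                    hydrogen_of = hydrogen_of,
                                    charge_group = charge_group,
                                    charge_sign = charge_sign,
                                    stringsAsFactors = FALSE)
      serial
    }
    gid <- 0L
    for (u in seq_len(n_units)) {
      d <- add(paste0("OD", u), "O", 4L * u - 3L, donor = TRUE, acceptor = TRUE)
      add(paste0("HD", u), "H", 4L * u - 3L, hydrogen_of = d)
      add(paste0("OA", u), "O", 4L * u - 2L, acceptor = TRUE)
      gid <- gid + 1L
      add(paste0("NC", u), "N", 4L * u - 1L, charge_group = gid,
          charge_sign = if (u %% 2) 1L else -1L)
    }
    atoms <- do.call(rbind, rows)
    new_topology(atoms, bonds = cbind(which(atoms$elem == "H") - 1L,
                                      which(atoms$elem == "H")))
  })
}

random_frames <- function(n_atoms, n_frames, box = 8, seed = 1) {
  withr::with_seed(seed, {
    array(stats::runif(n_atoms * 3 * n_frames, 0, box),
          dim = c(n_atoms, 3, n_frames))
  })
}

# Type-stable integer matrix from event data.frame columns (empty-safe).
event_matrix <- function(df, cols) {
  m <- matrix(0L, nrow = nrow(df), ncol = length(cols))
  for (j in seq_along(cols)) m[, j] <- as.integer(df[[cols[j]]])
  m
}

# All-triples hydrogen bond oracle.
oracle_hbonds <- function(xyz, top, d_cut = 4, angle_cut = 120) {
  at <- top$atoms
  out <- list()
  for (D in which(at$donor)) {
    for (H in which(!is.na(at$hydrogen_of) & at$hydrogen_of == D)) {
      for (A in which(at$acceptor)) {
        if (A == D) next
        dDA <- sqrt(sum((xyz[D, ] - xyz[A, ])^2))
        if (dDA > d_cut) next
        u <- xyz[D, ] - xyz[H, ]; v <- xyz[A, ] - xyz[H, ]
        ang <- acos(max(-1, min(1, sum(u * v) /
                                  sqrt(sum(u^2)) / sqrt(sum(v^2))))) * 180 / pi
        if (ang >= angle_cut)
          out[[length(out) + 1]] <- c(D, H, A)
      }
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 3))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 3], m[, 2]), , drop = FALSE]
}

# All-pairs salt bridge oracle.
oracle_salt <- function(xyz, top, d_cut = 5) {
  at <- top$atoms
  rkey <- paste(at$chain, at$resid)
  charged <- which(!is.na(at$charge_group))
  out <- list()
  for (i in charged) for (j in charged) {
    if (i >= j) next
    if (at$charge_sign[i] * at$charge_sign[j] >= 0) next
    if (rkey[i] == rkey[j]) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= d_cut)
      out[[length(out) + 1]] <- c(i, j)
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Exhaustive-orientation superposition oracle: coarse search over Euler
# angles followed by Nelder-Mead refinement of the best starts; independent
# of the Kabsch solution.
oracle_superpose_rmsd <- function(mobile, reference) {
  Pc <- sweep(mobile, 2, colMeans(mobile))
  Qc <- sweep(reference, 2, colMeans(reference))
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((Pc %*% t(rotmat(ang)) - Qc)^2)))
  grid <- seq(0, 2 * pi, length.out = 9)[-9]
  starts <- expand.grid(a = grid, b = seq(0, pi, length.out = 5), c = grid)
  vals <- apply(starts, 1, obj)
  best <- order(vals)[1:5]
  refined <- vapply(best, function(k) {
    stats::optim(as.numeric(starts[k, ]), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))$value
  }, numeric(1))
  min(refined)
}

# Small annotated complex (static CA protein + jittered DNA) shared by
# QC/pipeline tests.
make_test_complex <- function(nbp = 8, n_res = 12) {
  dna <- generate_bdna(paste(rep(c("A", "C", "G", "T"), length.out = nbp),
                             collapse = ""))
  prot <- generate_ca_protein(n_res, radius = 20)
  list(topology = combine_topologies(prot, dna$topology),
       pairing = dna$pairing, n_protein_atoms = n_res)
}
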