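#' Construct a molecular topology
#'
#' A topology holds the static description of a system: one row per atom
#' (names, elements, residue assignment), the covalent bond list, and the
#' chemical-role annotations that the contact detectors consume (hydrogen-bond
#' donors and acceptors, formal-charge groups). Coordinates of a reference
#' structure may be attached as an `n_atoms x 3` matrix.
#'
#' @param atoms data.frame with columns `serial`, `name`, `elem`, `resid`,
#'   `resname`, `chain`. Annotation columns (`donor`, `acceptor`,
#'   `hydrogen_of`, `charge_group`, `charge_sign`) are added if missing.
#' @param bonds two-column integer matrix of atom indices (1-based); stored
#'   symmetrically as unordered pairs.
#' @param xyz optional `n_atoms x 3` reference coordinate matrix (Angstrom).
#' @return An object of class `"topology"`.
#' @export
new_topology <- function(atoms, bonds = NULL, xyz = NULL) {
  stopifnot(is.data.frame(atoms))
  required <- c("serial", "name", "elem", "resid", "resname", "chain")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop_dyadmd("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key))
    stop_dyadmd("duplicate (chain, resid, name) atom identity: ",
                key[duplicated(key)][1])
  for (col in c("donor", "acceptor")) if (is.null(atoms[[col]])) atoms[[col]] <- FALSE
  if (is.null(atoms$hydrogen_of)) atoms$hydrogen_of <- NA_integer_
  if (is.null(atoms$charge_group)) atoms$charge_group <- NA_integer_
  if (is.null(atoms$charge_sign)) atoms$charge_sign <- 0L
  n <- nrow(atoms)
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds)) {
    if (any(bonds < 1 | bonds > n)) stop_dyadmd("bond index out of range")
    bonds <- t(apply(bonds, 1, sort))
    bonds <- unique(bonds)
    bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  }
  if (!is.null(xyz)) {
    xyz <- as.matrix(xyz)
    if (!all(dim(xyz) == c(n, 3)))
      stop_dyadmd("xyz must be an n_atoms x 3 matrix")
  }
  structure(list(atoms = atoms, bonds = bonds, xyz = xyz),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues, %d bonds\n",
              nrow(x$atoms), length(unique(residue_keys(x))), nrow(x$bonds)))
  cat(sprintf("  donors: %d  acceptors: %d  charge groups: %d\n",
              sum(x$atoms$donor), sum(x$atoms$acceptor),
              length(unique(stats::na.omit(x$atoms$charge_group)))))
  invisible(x)
}

#' Residue identity keys ("chain:resid") per atom
#' @param topology a topology
#' @return character vector, one entry per atom
#' @export
residue_keys <- function(topology) {
  paste(topology$atoms$chain, topology$atoms$resid, sep = ":")
}

n_atoms <- function(topology) nrow(topology$atoms)

# Index of bonded neighbours per atom, as a list.
bond_neighbours <- function(topology) {
  n <- n_atoms(topology)
  nb <- vector("list", n)
  b <- topology$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      nb[[b[k, 1]]] <- c(nb[[b[k, 1]]], b[k, 2])
      nb[[b[k, 2]]] <- c(nb[[b[k, 2]]], b[k, 1])
    }
  }
  nb
}

# Distance-rule bonds: pair bonded iff separation < 1.2 x sum of covalent radii.
distance_bonds <- function(xyz, elem) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  d <- pair_dist(xyz, xyz)
  r <- covalent_radius(elem)
  cut <- 1.2 * outer(r, r, "+")
  hit <- which(d < cut & upper.tri(d), arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  matrix(as.integer(hit), ncol = 2)
}

#' Load a topology from a PDB file
#'
#' Atom records are read with \code{bio3d::read.pdb}; covalent bonds come
#' either from CONECT records or from a covalent-radius distance rule
#' (bonded iff separation < 1.2 x sum of covalent radii). Every hydrogen is
#' assigned to its bonded heavy atom (`hydrogen_of`).
#'
#' @param path PDB file.
#' @param bond_source `"distance"` (default) or `"conect"`.
#' @return A [new_topology()] object with reference coordinates attached
#'   (first MODEL for multi-model files).
#' @export
load_topology <- function(path, bond_source = c("distance", "conect")) {
  bond_source <- match.arg(bond_source)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(is_atom)) {
    coords <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                            substr(lines[i], 39, 46),
                                            substr(lines[i], 47, 54))))
    if (anyNA(coords))
      stop_dyadmd("malformed ATOM record at line ", i, ": ", lines[i])
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  elem <- toupper(trimws(at$elesy %||% ""))
  fallback <- element_from_name(trimws(at$elety))
  elem[is.na(elem) | elem == ""] <- fallback[is.na(elem) | elem == ""]
  atoms <- data.frame(serial = at$eleno,
                      name = trimws(at$elety),
                      elem = elem,
                      resid = at$resno,
                      resname = trimws(at$resid),
                      chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
                      stringsAsFactors = FALSE)
  xyz <- cbind(at$x, at$y, at$z)

  if (bond_source == "conect") {
    conect <- lines[grepl("^CONECT", lines)]
    pairs <- list()
    for (ln in conect) {
      fields <- suppressWarnings(as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))),
                                                     "\\s+")[[1]]))
      fields <- fields[!is.na(fields)]
      if (length(fields) >= 2) {
        a <- match(fields[1], atoms$serial)
        bs <- match(fields[-1], atoms$serial)
        ok <- !is.na(bs)
        if (!is.na(a) && any(ok))
          pairs[[length(pairs) + 1]] <- cbind(a, bs[ok])
      }
    }
    bonds <- if (length(pairs)) do.call(rbind, pairs) else matrix(integer(0), ncol = 2)
  } else {
    bonds <- distance_bonds(xyz, atoms$elem)
  }
  top <- new_topology(atoms, bonds, xyz)
  assign_hydrogens(top)
}

# Attach hydrogen_of for every hydrogen: bonded heavy atom, or (fallback)
# nearest heavy atom within 1.3 Angstrom of the reference coordinates.
assign_hydrogens <- function(topology) {
  atoms <- topology$atoms
  hyd <- which(atoms$elem == "H")
  if (!length(hyd)) return(topology)
  nb <- bond_neighbours(topology)
  for (h in hyd) {
    heavies <- nb[[h]][atoms$elem[nb[[h]]] != "H"]
    if (length(heavies)) {
      atoms$hydrogen_of[h] <- heavies[1]
    } else if (!is.null(topology$xyz)) {
      heavy_idx <- which(atoms$elem != "H")
      d <- pair_dist(topology$xyz[h, , drop = FALSE],
                     topology$xyz[heavy_idx, , drop = FALSE])
      j <- which.min(d)
      if (d[j] > 1.3)
        stop_dyadmd("hydrogen with no heavy neighbour within 1.3 A: atom ",
                    atoms$serial[h], " (", atoms$name[h], " ",
                    atoms$resname[h], atoms$resid[h], ")")
      atoms$hydrogen_of[h] <- heavy_idx[j]
    } else {
      stop_dyadmd("hydrogen with no bonded heavy atom and no coordinates: atom ",
                  atoms$serial[h])
    }
  }
  topology$atoms <- atoms
  topology
}

#' Write a topology (with reference coordinates) to PDB
#'
#' @param topology a topology with `xyz` attached.
#' @param file output path.
#' @param conect write CONECT records for the stored bond list.
#' @export
write_topology <- function(topology, file, conect = TRUE) {
  if (is.null(topology$xyz)) stop_dyadmd("topology has no coordinates to write")
  at <- topology$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(topology$xyz)),
                   resno = at$resid, resid = at$resname,
                   eleno = at$serial, elety = at$name,
                   chain = at$chain, elesy = at$elem)
  if (conect && nrow(topology$bonds)) {
    lines <- readLines(file, warn = FALSE)
    lines <- lines[!grepl("^END$", lines)]
    b <- topology$bonds
    conect_lines <- sprintf("CONECT%5d%5d", at$serial[b[, 1]], at$serial[b[, 2]])
    writeLines(c(lines, conect_lines, "END"), file)
  }
  invisible(file)
}

#' Default chemical role table
#'
#' Declares, per residue name, the formal-charge groups and acceptor
#' overrides used by [annotate_chemistry()]. The charged set follows the
#' convention for classical force fields at neutral pH: Arg (NE/NH1/NH2, +),
#' Lys (NZ, +), Glu (OE1/OE2, -), Asp (OD1/OD2, -), the nucleotide phosphate
#' (OP1/OP2, -), and the carboxylate of 5-carboxylcytosine (O51/O52, -).
#' Histidine is neutral by default. Terminal groups (N-/C-termini,
#' 5'-phosphates) are excluded by default.
#'
#' @param arginine_ne include NE in the arginine guanidinium group.
#' @param histidine_charged treat His as protonated (+) on ND1/NE2.
#' @param mc_name,cac_name residue names used for 5-methyl- and
#'   5-carboxylcytosine nucleotides.
#' @return list consumed by [annotate_chemistry()].
#' @export
default_role_table <- function(arginine_ne = TRUE, histidine_charged = FALSE,
                               mc_name = "5CM", cac_name = "5CA") {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "HID", "HIE", "HIP")
  nuc <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "U", mc_name, cac_name)
  arg_atoms <- if (arginine_ne) c("NE", "NH1", "NH2") else c("NH1", "NH2")
  groups <- list(
    ARG = list(list(atoms = arg_atoms, sign = 1L)),
    LYS = list(list(atoms = "NZ", sign = 1L)),
    GLU = list(list(atoms = c("OE1", "OE2"), sign = -1L)),
    ASP = list(list(atoms = c("OD1", "OD2"), sign = -1L)))
  groups[[cac_name]] <- list(list(atoms = c("O51", "O52"), sign = -1L))
  if (histidine_charged)
    groups$HIS <- list(list(atoms = c("ND1", "NE2"), sign = 1L))
  list(amino_acids = aa,
       nucleotides = nuc,
       charge_groups = groups,
       phosphate = c("OP1", "OP2"),
       extra_acceptors = list(),   # resname -> atom names forced to acceptor
       non_acceptors = list())     # resname -> atom names never acceptor
}

#' Annotate donors, acceptors and formal-charge groups
#'
#' Donors are N/O heavy atoms bearing at least one bonded hydrogen.
#' Acceptors are all oxygens plus nitrogens without bonded hydrogen
#' (overridable per residue through `role_table$extra_acceptors` /
#' `non_acceptors`). Charge groups follow `role_table$charge_groups` plus the
#' generic nucleotide phosphate (OP1/OP2). Unknown residue names are listed
#' in a skip report (attribute `"skip_report"`), never fatal. The operation
#' is idempotent.
#'
#' @param topology a topology.
#' @param role_table see [default_role_table()].
#' @return the topology with annotation columns filled.
#' @export
annotate_chemistry <- function(topology, role_table = default_role_table()) {
  atoms <- topology$atoms
  n <- nrow(atoms)
  # reset (idempotence)
  atoms$donor <- FALSE
  atoms$acceptor <- FALSE
  atoms$charge_group <- NA_integer_
  atoms$charge_sign <- 0L
  topology$atoms <- atoms
  topology <- assign_hydrogens(topology)
  atoms <- topology$atoms

  has_h <- tabulate(stats::na.omit(atoms$hydrogen_of), nbins = n) > 0
  heavy_no <- atoms$elem %in% c("N", "O")
  atoms$donor <- heavy_no & has_h
  atoms$acceptor <- (atoms$elem == "O") | (atoms$elem == "N" & !has_h)

  known <- c(role_table$amino_acids, role_table$nucleotides,
             names(role_table$charge_groups))
  skipped <- sort(unique(atoms$resname[!(atoms$resname %in% known)]))
  if (length(skipped))
    message("annotate_chemistry: unknown residue names skipped: ",
            paste(skipped, collapse = ", "))

  for (rn in names(role_table$extra_acceptors)) {
    sel <- atoms$resname == rn & atoms$name %in% role_table$extra_acceptors[[rn]]
    atoms$acceptor[sel] <- TRUE
  }
  for (rn in names(role_table$non_acceptors)) {
    sel <- atoms$resname == rn & atoms$name %in% role_table$non_acceptors[[rn]]
    atoms$acceptor[sel] <- FALSE
  }

  rkey <- paste(atoms$chain, atoms$resid, sep = ":")
  gid <- 0L
  for (key in unique(rkey)) {
    idx <- which(rkey == key)
    rn <- atoms$resname[idx[1]]
    defs <- role_table$charge_groups[[rn]]
    if (rn %in% role_table$nucleotides) {
      defs <- c(defs, list(list(atoms = role_table$phosphate, sign = -1L)))
    }
    for (g in defs) {
      members <- idx[atoms$name[idx] %in% g$atoms]
      if (length(members)) {
        gid <- gid + 1L
        atoms$charge_group[members] <- gid
        atoms$charge_sign[members] <- g$sign
      }
    }
  }
  topology$atoms <- atoms
  attr(topology, "skip_report") <- skipped
  topology
}
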