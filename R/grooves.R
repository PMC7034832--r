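#' Declare base pairing for a duplex
#'
#' Pairing is supplied, not inferred, because a flipped-out base breaks
#' geometric pair detection. Base-pair numbering follows the order of the
#' supplied table (convention: numbered along the strand binding the
#' flipped-out base). Unpaired positions (the flipped base) carry NA for the
#' partner residue.
#'
#' @param topology a topology.
#' @param pairing data.frame with columns `bp` (base-pair number), `chain1`,
#'   `resid1`, `chain2`, `resid2`; set `resid2 = NA` for an unpaired
#'   position.
#' @param sanity_cutoff warn when a declared pair's pairing-nitrogen
#'   (N1/N3) distance in the reference coordinates exceeds this (Angstrom).
#' @return object of class `"basepair_map"`.
#' @export
assign_base_pairs <- function(topology, pairing, sanity_cutoff = 4.0) {
  required <- c("bp", "chain1", "resid1", "chain2", "resid2")
  if (!all(required %in% names(pairing)))
    stop_dyadmd("pairing needs columns: ", paste(required, collapse = ", "))
  pairing <- pairing[order(pairing$bp), , drop = FALSE]
  keys <- c(paste(pairing$chain1, pairing$resid1, sep = ":"),
            paste(pairing$chain2, pairing$resid2, sep = ":"))
  keys <- keys[!grepl(":NA$", keys)]
  if (anyDuplicated(keys))
    stop_dyadmd("residue listed twice in pairing: ", keys[duplicated(keys)][1])
  rkey <- residue_keys(topology)
  for (k in keys) {
    if (!any(rkey == k)) stop_dyadmd("pairing names unknown residue ", k)
  }
  if (!is.null(topology$xyz)) {
    for (i in seq_len(nrow(pairing))) {
      if (is.na(pairing$resid2[i])) next
      k1 <- paste(pairing$chain1[i], pairing$resid1[i], sep = ":")
      k2 <- paste(pairing$chain2[i], pairing$resid2[i], sep = ":")
      nn <- function(k) which(rkey == k & topology$atoms$name %in% c("N1", "N3"))
      i1 <- nn(k1); i2 <- nn(k2)
      if (length(i1) && length(i2)) {
        d <- min(pair_dist(topology$xyz[i1, , drop = FALSE],
                           topology$xyz[i2, , drop = FALSE]))
        if (d > sanity_cutoff)
          warning(sprintf("pair %d (%s / %s): N1-N3 distance %.2f A exceeds %.1f A",
                          pairing$bp[i], k1, k2, d, sanity_cutoff))
      }
    }
  }
  structure(list(pairing = pairing), class = "basepair_map")
}

#' @export
print.basepair_map <- function(x, ...) {
  cat(sprintf("base-pair map: %d positions (%d unpaired)\n",
              nrow(x$pairing), sum(is.na(x$pairing$resid2))))
  invisible(x)
}

#' Minor and major groove widths (El Hassan-Calladine construction)
#'
#' Groove widths at base-pair level i are cross-strand phosphate-phosphate
#' distances with opposite offsets: minor width is the distance between the
#' P atom of the strand-1 residue at level i+offset and the P of the
#' strand-2 residue at level i-offset; major width pairs strand-1 at
#' i-offset with strand-2 at i+offset. Positions lacking a required
#' phosphate (termini, the gap left by a flipped base) are NA, never
#' zero-filled. Raw P-P distances are reported by default;
#' `radius_subtract` removes 5.8 Angstrom (twice the phosphate group
#' radius) for comparison with tools that report accessible widths.
#'
#' @param trajectory a trajectory (or a single-frame topology+xyz).
#' @param pair_map a [assign_base_pairs()] map.
#' @param offset cross-strand offset in base-pair levels (default 2).
#' @param radius_subtract subtract 5.8 Angstrom from every width.
#' @return object of class `"groove_profile"`: list with `minor`, `major`
#'   (`n_frames x n_bp` matrices, NA where undefined) and `summary`
#'   (per-base-pair mean and sd over frames).
#' @export
groove_widths <- function(trajectory, pair_map, offset = 2,
                          radius_subtract = FALSE) {
  top <- trajectory$topology
  p <- pair_map$pairing
  nbp <- nrow(p)
  rkey <- residue_keys(top)
  p_index <- function(chain, resid) {
    if (is.na(resid)) return(NA_integer_)
    i <- which(rkey == paste(chain, resid, sep = ":") & top$atoms$name == "P")
    if (length(i)) i[1] else NA_integer_
  }
  p1 <- mapply(p_index, p$chain1, p$resid1)
  p2 <- mapply(p_index, p$chain2, p$resid2)
  if (all(is.na(p1)) || all(is.na(p2)))
    stop_dyadmd("no phosphorus atoms found for the declared strands")

  nf <- n_frames(trajectory)
  minor <- matrix(NA_real_, nf, nbp)
  major <- matrix(NA_real_, nf, nbp)
  at_level <- function(v, lv) if (lv >= 1 && lv <= nbp) v[lv] else NA_integer_
  sub <- if (radius_subtract) 5.8 else 0
  for (f in seq_len(nf)) {
    xyz <- frame_xyz(trajectory, f)
    for (i in seq_len(nbp)) {
      a <- at_level(p1, i + offset); b <- at_level(p2, i - offset)
      if (!is.na(a) && !is.na(b))
        minor[f, i] <- vec_norm(xyz[a, ] - xyz[b, ]) - sub
      a <- at_level(p1, i - offset); b <- at_level(p2, i + offset)
      if (!is.na(a) && !is.na(b))
        major[f, i] <- vec_norm(xyz[a, ] - xyz[b, ]) - sub
    }
  }
  summary <- data.frame(
    bp = p$bp,
    minor_mean = colMeans(minor), minor_sd = apply(minor, 2, stats::sd),
    major_mean = colMeans(major), major_sd = apply(major, 2, stats::sd),
    defined = !is.na(colMeans(minor)) | !is.na(colMeans(major)))
  structure(list(minor = minor, major = major, summary = summary,
                 offset = offset, radius_subtract = radius_subtract),
            class = "groove_profile")
}

#' @export
print.groove_profile <- function(x, ...) {
  cat(sprintf("groove profile: %d frames x %d base pairs (offset %d)\n",
              nrow(x$minor), ncol(x$minor), x$offset))
  print(x$summary)
  invisible(x)
}
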