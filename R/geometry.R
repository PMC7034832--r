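#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between the
#' `fit_set` atoms of a mobile structure and a reference.
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices over the same
#'   atom indexing.
#' @param fit_set atom indices (or selection) used for fitting; at least 3
#'   non-collinear atoms.
#' @param topology optional topology for resolving `fit_set` expressions.
#' @return list with `rotation` (3x3, determinant +1), the fit centroids
#'   `centre_mobile` / `centre_reference`, and `rmsd` over the fit set after
#'   fitting. Apply with [apply_transform()].
#' @export
superpose <- function(mobile, reference, fit_set = NULL, topology = NULL) {
  idx <- if (is.null(fit_set)) seq_len(nrow(mobile))
         else as_indices(topology, fit_set)
  if (length(idx) < 3) stop_dyadmd("fit set needs at least 3 atoms")
  P <- mobile[idx, , drop = FALSE]
  Q <- reference[idx, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (qr(Pc)$rank < 2 || qr(Qc)$rank < 2)
    stop_dyadmd("degenerate (collinear) fit geometry")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v) * det(s$u))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(rotation = R, centre_mobile = cp, centre_reference = cq, rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#' @param xyz `n x 3` matrix
#' @param fit result of [superpose()]
#' @export
apply_transform <- function(xyz, fit) {
  sweep(sweep(xyz, 2, fit$centre_mobile) %*% t(fit$rotation),
        2, fit$centre_reference, "+")
}

rmsd_between <- function(a, b, idx) {
  sqrt(mean(rowSums((a[idx, , drop = FALSE] - b[idx, , drop = FALSE])^2)))
}

#' Per-frame RMSD series with separate fit and calculation sets
#'
#' Every frame is first fitted to the reference on `fit_set` (e.g. protein
#' C-alpha atoms of the structured core), then the RMSD is computed over
#' `calc_set` without refitting — the convention for reporting, say, DNA
#' deviation after a protein-frame alignment.
#'
#' @param trajectory a trajectory.
#' @param fit_set,calc_set selections (objects, expressions, or indices).
#' @param reference `n_atoms x 3` matrix; defaults to the first frame.
#' @return object of class `"rmsd_series"`: data.frame with `frame`, `time`
#'   and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(trajectory, fit_set, calc_set, reference = NULL) {
  top <- trajectory$topology
  fit_idx <- as_indices(top, fit_set)
  calc_idx <- as_indices(top, calc_set)
  if (!length(calc_idx)) stop_dyadmd("empty calc set")
  ref <- reference %||% frame_xyz(trajectory, 1)
  nf <- n_frames(trajectory)
  vals <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_xyz(trajectory, f)
    fit <- superpose(xyz, ref, fit_idx)
    vals[f] <- rmsd_between(apply_transform(xyz, fit), ref, calc_idx)
  }
  structure(data.frame(frame = seq_len(nf), time = trajectory$times,
                       rmsd = vals),
            class = c("rmsd_series", "data.frame"),
            replica_id = trajectory$replica_id)
}

#' Per-residue RMSF profile
#'
#' Two-pass protocol: (1) fit all frames to the first frame on `fit_set`;
#' (2) compute the mean structure; (3) refit all frames to that mean on
#' `fit_set`; (4) per heavy atom, RMSF is the root mean squared deviation
#' from its mean position; (5) the per-residue value is the unweighted mean
#' over the residue's heavy atoms in `calc_set`.
#'
#' @param trajectory a trajectory (>= 2 frames).
#' @param fit_set alignment selection.
#' @param calc_set atoms to report; default all non-hydrogen atoms.
#' @return object of class `"rmsf_profile"`: data.frame with `chain`,
#'   `resid`, `resname`, `rmsf` (Angstrom) and `n_atoms`; per-atom values in
#'   attribute `"per_atom"`.
#' @export
rmsf_profile <- function(trajectory, fit_set, calc_set = "heavy") {
  nf <- n_frames(trajectory)
  if (nf < 2) stop_dyadmd("RMSF needs at least 2 frames")
  top <- trajectory$topology
  fit_idx <- as_indices(top, fit_set)
  calc_idx <- as_indices(top, calc_set)
  calc_idx <- calc_idx[top$atoms$elem[calc_idx] != "H"]
  na <- n_atoms(top)

  align_all <- function(reference) {
    out <- array(NA_real_, dim = c(na, 3, nf))
    for (f in seq_len(nf)) {
      xyz <- frame_xyz(trajectory, f)
      out[, , f] <- apply_transform(xyz, superpose(xyz, reference, fit_idx))
    }
    out
  }
  pass1 <- align_all(frame_xyz(trajectory, 1))
  mean1 <- apply(pass1, c(1, 2), mean)
  pass2 <- align_all(mean1)
  mean2 <- apply(pass2, c(1, 2), mean)

  dev2 <- sweep(pass2, c(1, 2), mean2)
  per_atom <- sqrt(apply(dev2^2, 1, sum) / nf)   # sum over xyz and frames

  at <- top$atoms
  rkey <- residue_keys(top)[calc_idx]
  vals <- tapply(per_atom[calc_idx], rkey, mean)
  counts <- tapply(per_atom[calc_idx], rkey, length)
  first <- calc_idx[!duplicated(rkey)]
  ord_keys <- unique(rkey)
  df <- data.frame(chain = at$chain[first], resid = at$resid[first],
                   resname = at$resname[first],
                   rmsf = as.numeric(vals[ord_keys]),
                   n_atoms = as.integer(counts[ord_keys]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chain, df$resid), , drop = FALSE]
  rownames(df) <- NULL
  # residues of calc_set with no heavy atom were dropped implicitly; warn
  want_res <- unique(residue_keys(top)[as_indices(top, calc_set)])
  if (length(setdiff(want_res, unique(residue_keys(top)[calc_idx]))))
    warning("residues without heavy atoms in calc_set were omitted")
  structure(df, class = c("rmsf_profile", "data.frame"),
            per_atom = data.frame(atom = seq_len(na), rmsf = per_atom))
}

#' Replica quality control by tail-window RMSD
#'
#' Reproduces the divergence screen applied before merging replicas: each
#' replica's trailing window is aligned to the reference on `fit_set`
#' (protein C-alpha convention) and the RMSD computed over `calc_set`
#' (typically all DNA atoms). A replica is excluded when its mean tail RMSD
#' exceeds `threshold` (default 4 Angstrom); mean and max are both reported
#' and exclusions are always explicit in the returned table.
#'
#' @param replicas list of trajectories.
#' @param fit_set,calc_set selections.
#' @param reference reference coordinates (e.g. the crystal structure);
#'   defaults to the first frame of each replica.
#' @param threshold exclusion threshold, Angstrom.
#' @param tail_frames number of trailing frames to analyse (NULL = all).
#' @return data.frame with `replica_id`, `mean_rmsd`, `max_rmsd`, `status`
#'   (`"pass"` / `"excluded"`).
#' @export
qc_replicas <- function(replicas, fit_set, calc_set, reference = NULL,
                        threshold = 4.0, tail_frames = NULL) {
  stopifnot(length(replicas) >= 1)
  rows <- lapply(replicas, function(tr) {
    tt <- if (is.null(tail_frames)) tr else
      slice_tail(tr, last_n_frames = tail_frames)
    rs <- rmsd_series(tt, fit_set, calc_set,
                      reference = reference %||% frame_xyz(tr, 1))
    data.frame(replica_id = tr$replica_id,
               mean_rmsd = mean(rs$rmsd), max_rmsd = max(rs$rmsd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$status <- ifelse(out$mean_rmsd > threshold, "excluded", "pass")
  if (any(out$status == "excluded"))
    message("qc_replicas: excluded ", sum(out$status == "excluded"),
            " replica(s) with mean tail RMSD > ", threshold, " A: ",
            paste(out$replica_id[out$status == "excluded"], collapse = ", "))
  out
}

#' Distance series between two ring centroids
#'
#' Per frame, the Euclidean distance between the unweighted geometric
#' centres of two atom selections (e.g. a tyrosine phenyl ring and the
#' pyrimidine ring of a flipped-out base). A Gaussian kernel density
#' estimate is attached when the samples have nonzero variance.
#'
#' @param trajectory a trajectory.
#' @param ring_a,ring_b selections with at least 3 atoms each.
#' @param bandwidth passed to [gaussian_kde()].
#' @return object of class `"distance_distribution"`: list with `samples`
#'   (Angstrom per frame), `kde` (or NULL), `bandwidth`.
#' @export
ring_distance_series <- function(trajectory, ring_a, ring_b,
                                 bandwidth = "scott") {
  top <- trajectory$topology
  ia <- as_indices(top, ring_a)
  ib <- as_indices(top, ring_b)
  if (length(ia) < 3 || length(ib) < 3)
    stop_dyadmd("each ring selection needs at least 3 atoms")
  nf <- n_frames(trajectory)
  d <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_xyz(trajectory, f)
    d[f] <- vec_norm(colMeans(xyz[ia, , drop = FALSE]) -
                     colMeans(xyz[ib, , drop = FALSE]))
  }
  kde <- if (length(d) >= 2 && stats::sd(d) > 0) gaussian_kde(d, bandwidth) else NULL
  structure(list(samples = d, kde = kde,
                 bandwidth = if (is.null(kde)) NA_real_ else kde$bandwidth),
            class = "distance_distribution")
}

#' Gaussian kernel density estimate
#'
#' The estimate is the mean of Gaussian kernels centred on the samples.
#' Default bandwidth is Scott's rule, `sd(x) * n^(-1/5)`.
#'
#' @param samples numeric vector (>= 2 values, nonzero variance).
#' @param bandwidth `"scott"` or a fixed numeric bandwidth (same units as
#'   the samples).
#' @return object of class `"gkde"`; evaluate with `predict(kde, x)`.
#' @export
gaussian_kde <- function(samples, bandwidth = "scott") {
  if (length(samples) < 2) stop_dyadmd("need at least 2 samples")
  s <- stats::sd(samples)
  if (s == 0) stop_dyadmd("degenerate input: zero variance")
  h <- if (identical(bandwidth, "scott")) s * length(samples)^(-1/5)
       else as.numeric(bandwidth)
  if (h <= 0) stop_dyadmd("bandwidth must be positive")
  structure(list(samples = samples, bandwidth = h), class = "gkde")
}

#' @export
predict.gkde <- function(object, x, ...) {
  vapply(x, function(xi)
    mean(stats::dnorm(xi, mean = object$samples, sd = object$bandwidth)),
    numeric(1))
}

#' @export
print.gkde <- function(x, ...) {
  cat(sprintf("gaussian kde: %d samples, bandwidth %.4g\n",
              length(x$samples), x$bandwidth))
  invisible(x)
}
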