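# Internal helpers shared across modules.

# Pairwise Euclidean distance matrix between rows of A (n x 3) and B (m x 3).
pair_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

vec_norm <- function(v) sqrt(sum(v^2))

# Angle (degrees) at vertex `h` formed by points a-h-b.
angle_deg <- function(a, h, b) {
  u <- a - h
  v <- b - h
  cosang <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All generator randomness funnels through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Covalent radii (Angstrom) for the elements the pipeline meets.
covalent_radius <- function(elem) {
  radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, P = 1.07, S = 1.05,
             F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, ZN = 1.22, MG = 1.41,
             NA. = 1.66, K = 2.03)
  names(radii)[names(radii) == "NA."] <- "NA"
  r <- radii[toupper(elem)]
  if (anyNA(r)) {
    r[is.na(r)] <- 0.77  # generic fallback, carbon-like
  }
  unname(r)
}

# Element symbol from a PDB atom name (standard nomenclature: strip leading
# digits, take the leading alphabetic run; two-letter elements are resolved
# through the explicit element column when available).
element_from_name <- function(name) {
  stripped <- sub("^[0-9']+", "", name)
  first <- toupper(substr(stripped, 1, 1))
  first[first == ""] <- "C"
  first
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dyadmd <- function(...) stop(..., call. = FALSE)
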