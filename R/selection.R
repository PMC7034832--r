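#' Atom selections
#'
#' A small deterministic selection grammar in the style of trajectory
#' analysis tools:
#'
#' ```
#' expr    := term ("or" term)*
#' term    := factor ("and" factor)*
#' factor  := "not" factor | "(" expr ")" | primary
#' primary := "all" | "none" | "protein" | "dna" | "nucleic"
#'          | "heavy" | "noh" | "hydrogen"
#'          | "name" value+ | "resname" value+ | "elem" value+
#'          | "chain" value+ | "resid" range+
#' ```
#'
#' `resid` accepts single ids and ranges (`432-586`); an empty range
#' (`1-0`) yields an empty selection. Resolution is deterministic and
#' order-preserving (ascending atom index).
#'
#' @name selection
NULL

.sel_keywords <- c("all", "none", "protein", "dna", "nucleic", "heavy", "noh",
                   "hydrogen", "name", "resname", "elem", "chain", "resid",
                   "and", "or", "not", "(", ")")

.protein_resnames <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                       "HIS", "HID", "HIE", "HIP", "ILE", "LEU", "LYS", "MET",
                       "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

.nucleic_resnames <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "U",
                       "5CM", "5CA")

sel_tokenize <- function(expression) {
  x <- gsub("\\(", " ( ", expression)
  x <- gsub("\\)", " ) ", x)
  tokens <- strsplit(trimws(x), "\\s+")[[1]]
  tokens[tokens != ""]
}

# Recursive-descent parser over a token stream held in a mutable environment.
sel_parse <- function(tokens, topology, nucleic_extra) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$pos <- 1L
  peek <- function() if (env$pos <= length(env$tokens)) env$tokens[env$pos] else NA_character_
  advance <- function() { t <- peek(); env$pos <- env$pos + 1L; t }
  fail <- function(msg) stop_dyadmd("selection syntax error at token ", env$pos,
                                    " ('", peek() %||% "<end>", "'): ", msg)

  atoms <- topology$atoms
  n <- nrow(atoms)
  nuc_names <- c(.nucleic_resnames, nucleic_extra)

  values <- function() {
    out <- character(0)
    while (!is.na(peek()) && !(peek() %in% .sel_keywords)) out <- c(out, advance())
    if (!length(out)) fail("expected one or more values")
    out
  }

  primary <- function() {
    tok <- peek()
    if (is.na(tok)) fail("unexpected end of expression")
    if (tok == "(") {
      advance()
      m <- expr()
      if (!identical(peek(), ")")) fail("expected ')'")
      advance()
      return(m)
    }
    advance()
    switch(tok,
      all = rep(TRUE, n),
      none = rep(FALSE, n),
      protein = atoms$resname %in% .protein_resnames,
      dna = ,
      nucleic = atoms$resname %in% nuc_names,
      heavy = ,
      noh = atoms$elem != "H",
      hydrogen = atoms$elem == "H",
      name = atoms$name %in% values(),
      resname = atoms$resname %in% values(),
      elem = atoms$elem %in% toupper(values()),
      chain = atoms$chain %in% values(),
      resid = {
        ids <- integer(0)
        for (v in values()) {
          if (grepl("^-?[0-9]+--?[0-9]+$", v) || grepl("^[0-9]+-[0-9]+$", v)) {
            parts <- as.integer(strsplit(v, "(?<=[0-9])-", perl = TRUE)[[1]])
            if (parts[1] <= parts[2]) ids <- c(ids, parts[1]:parts[2])
          } else if (grepl("^-?[0-9]+$", v)) {
            ids <- c(ids, as.integer(v))
          } else fail(paste0("bad resid token '", v, "'"))
        }
        atoms$resid %in% ids
      },
      fail("unknown keyword"))
  }

  factor_ <- function() {
    if (identical(peek(), "not")) { advance(); return(!factor_()) }
    primary()
  }
  term <- function() {
    m <- factor_()
    while (identical(peek(), "and")) { advance(); m <- m & factor_() }
    m
  }
  expr <- function() {
    m <- term()
    while (identical(peek(), "or")) { advance(); m <- m | term() }
    m
  }

  mask <- expr()
  if (!is.na(peek())) fail("trailing tokens")
  mask
}

#' Resolve a selection expression against a topology
#'
#' @param topology a topology.
#' @param expression selection string (see [selection]).
#' @param nucleic_extra additional residue names to treat as nucleic.
#' @return object of class `"selection"` with fields `expression` and
#'   `indices` (ascending atom indices).
#' @export
resolve_selection <- function(topology, expression, nucleic_extra = character()) {
  tokens <- sel_tokenize(expression)
  if (!length(tokens)) stop_dyadmd("selection syntax error: empty expression")
  mask <- sel_parse(tokens, topology, nucleic_extra)
  structure(list(expression = expression, indices = which(mask)),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("selection '%s': %d atoms\n", x$expression, length(x$indices)))
  invisible(x)
}

# Accept a selection object, an index vector, or an expression string.
as_indices <- function(topology, sel) {
  if (inherits(sel, "selection")) return(sel$indices)
  if (is.character(sel)) return(resolve_selection(topology, sel)$indices)
  as.integer(sel)
}
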