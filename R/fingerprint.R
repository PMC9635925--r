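#' Extended-connectivity (ECFP4) fingerprints from SMILES
#'
#' Computes folded circular-substructure fingerprints of diameter 4
#' (Morgan radius 2), the standard structural descriptor for
#' similarity-based clustering of screening hits. Parsing and fingerprint
#' generation are done with OpenBabel (via ChemmineOB); the native
#' 4096-bit vector is OR-folded in halves down to `n_bits`. Identical
#' molecules written as different SMILES yield identical bitsets.
#'
#' @param smiles Character vector of SMILES strings.
#' @param compound_id Optional character vector of ids (defaults to the
#'   SMILES themselves); carried into the result and used in error
#'   messages.
#' @param n_bits Folded length, a power-of-two divisor of 4096
#'   (default 2048).
#' @return An object of class `fingerprint_set`: a logical matrix with one
#'   row per compound (rownames = compound ids) and `n_bits` columns.
#' @examples
#' \donttest{
#' fps <- fingerprint_compounds(c("CCO", "CCN"), c("ethanol", "ethylamine"))
#' tanimoto(fps["ethanol", ], fps["ethylamine", ])
#' }
#' @export
fingerprint_compounds <- function(smiles, compound_id = NULL, n_bits = 2048L) {
  if (!length(smiles)) abort("`smiles` must be non-empty.")
  compound_id <- compound_id %||% as.character(smiles)
  if (length(compound_id) != length(smiles)) {
    abort("`compound_id` and `smiles` lengths differ.")
  }
  if (anyDuplicated(compound_id)) abort("`compound_id` must be unique.")
  n_bits <- as.integer(n_bits)
  if (n_bits < 1L || 4096L %% n_bits != 0L || bitwAnd(n_bits, n_bits - 1L) != 0L) {
    abort("`n_bits` must be a power of two dividing 4096.")
  }
  bits <- matrix(FALSE, length(smiles), n_bits,
                 dimnames = list(compound_id, NULL))
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    if (is.na(s) || !nzchar(trimws(s))) {
      abort(sprintf("Compound %s: empty or missing SMILES.", compound_id[i]))
    }
    raw <- tryCatch({
      mol <- ChemmineOB::forEachMol("SMILES", s, identity)
      ChemmineOB::fingerprint_OB(mol, "ECFP4")
    }, error = function(e) NULL)
    if (is.null(raw) || !length(raw) || !any(raw > 0)) {
      abort(sprintf("Compound %s: unparseable SMILES '%s'.", compound_id[i], s))
    }
    bits[i, ] <- fold_bits(as.logical(raw > 0), n_bits)
  }
  structure(bits, class = c("fingerprint_set", "matrix", "array"),
            radius = 2L, n_bits = n_bits)
}

# OR-fold a bit vector in halves down to n_bits.
fold_bits <- function(bits, n_bits) {
  while (length(bits) > n_bits) {
    half <- length(bits) / 2L
    bits <- bits[seq_len(half)] | bits[half + seq_len(half)]
  }
  bits
}

# Cheap parse check used by read_compound_table().
smiles_is_valid <- function(smiles) {
  if (is.na(smiles) || !nzchar(trimws(smiles))) return(FALSE)
  raw <- tryCatch({
    mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
    ChemmineOB::fingerprint_OB(mol, "ECFP4")
  }, error = function(e) NULL)
  !is.null(raw) && length(raw) > 0 && any(raw > 0)
}

#' Tanimoto similarity of fingerprints
#'
#' `tanimoto()` is the intersection-over-union of two bitsets;
#' `tanimoto_matrix()` computes all pairwise similarities of a
#' [fingerprint_compounds()] set. Two empty bitsets have similarity 1 by
#' convention (with a warning); an empty against a non-empty bitset is 0.
#'
#' @param a,b Logical (or 0/1 numeric) vectors of equal length.
#' @return A similarity in [0, 1]; for `tanimoto_matrix()`, a symmetric
#'   matrix with unit diagonal and compound ids as dimnames.
#' @examples
#' tanimoto(c(TRUE, TRUE, TRUE, FALSE), c(FALSE, TRUE, TRUE, TRUE))
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  if (length(a) != length(b)) {
    abort("Fingerprints have different lengths; cannot compare.")
  }
  union_n <- sum(a | b)
  if (union_n == 0L) {
    warn("Both fingerprints empty; Tanimoto defined as 1.")
    return(1)
  }
  sum(a & b) / union_n
}

#' @rdname tanimoto
#' @param fps A `fingerprint_set` (or logical matrix, rows = compounds).
#' @export
tanimoto_matrix <- function(fps) {
  m <- unclass(fps) * 1L
  inter <- tcrossprod(m)
  pop <- diag(inter)
  union_n <- outer(pop, pop, `+`) - inter
  sim <- ifelse(union_n == 0, 1, inter / union_n)
  dimnames(sim) <- list(rownames(fps), rownames(fps))
  sim
}
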