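# Circular (Morgan/ECFP-style) fingerprints, radius 3 = ECFP_6 diameter
# convention, hashed to a fixed-length bit set with 32-bit FNV-1a arithmetic
# carried out exactly in doubles. Neighbor lists are sorted before hashing so
# the bits are invariant to atom numbering.

.FNV_OFFSET <- 2166136261
.FNV_PRIME <- 16777619
.TWO32 <- 2^32

# 32-bit xor on doubles via 16-bit halves (bitwXor needs < 2^31)
xor32 <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
}

# (h * prime) mod 2^32 without losing precision
mul32 <- function(h) {
  lo <- (h %% 65536) * .FNV_PRIME
  hi <- ((h %/% 65536) * .FNV_PRIME) %% 65536
  (hi * 65536 + lo) %% .TWO32
}

# FNV-1a over a vector of non-negative integers (< 2^32)
fnv_hash <- function(values) {
  h <- .FNV_OFFSET
  for (x in values) h <- mul32(xor32(h, x %% .TWO32))
  h
}

#' Circular fingerprint of a molecule
#'
#' Iterative neighborhood hashing in the Morgan/ECFP family. The default
#' radius 3 corresponds to the ECFP_6 diameter-6 convention; the bit length
#' is configurable (2048 by default).
#'
#' @param mol An `mt_mol` or SMILES string.
#' @param radius Number of neighborhood-growing iterations.
#' @param n_bits Length of the bit set.
#' @return Object of class `mt_fp`: list with `bits` (sorted 1-based on-bit
#'   positions), `n_bits` and `radius`.
#' @export
fingerprint <- function(mol, radius = 3L, n_bits = 2048L) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "mt_mol"), radius >= 0L, n_bits >= 1L)
  a <- mol$atoms
  n <- mol$n_atoms
  el <- match(a$element, .ELEMENTS, nomatch = length(.ELEMENTS) + 1L)
  inv <- vapply(seq_len(n), function(i) {
    fnv_hash(c(el[i], a$degree[i], a$charge[i] + 16L, a$n_h[i],
               as.integer(a$aromatic[i]), as.integer(a$in_ring[i])))
  }, numeric(1))
  all_inv <- inv
  if (radius > 0L && nrow(mol$bonds) > 0L) {
    b <- mol$bonds
    bond_code <- ifelse(b$order == "ar", 4L,
                 ifelse(b$order == "2", 2L,
                 ifelse(b$order == "3", 3L, 1L)))
    nbrs <- lapply(seq_len(n), function(i) {
      j1 <- which(b$a1 == i); j2 <- which(b$a2 == i)
      list(atom = c(b$a2[j1], b$a1[j2]), code = c(bond_code[j1], bond_code[j2]))
    })
    for (r in seq_len(radius)) {
      new_inv <- inv
      for (i in seq_len(n)) {
        nb <- nbrs[[i]]
        if (length(nb$atom) == 0L) next
        o <- order(nb$code, inv[nb$atom])
        seqv <- c(r, inv[i], rbind(nb$code[o], inv[nb$atom][o]))
        new_inv[i] <- fnv_hash(seqv)
      }
      inv <- new_inv
      all_inv <- c(all_inv, inv)
    }
  }
  fp <- list(bits = sort(unique(as.integer(all_inv %% n_bits) + 1L)),
             n_bits = as.integer(n_bits), radius = as.integer(radius))
  class(fp) <- "mt_fp"
  fp
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A n B| / |A u B|`; defined as 0 when both bit sets are empty (which
#' cannot happen for a valid molecule).
#'
#' @param a,b `mt_fp` objects of identical bit length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "mt_fp"), inherits(b, "mt_fp"))
  if (a$n_bits != b$n_bits)
    stop("fingerprint length mismatch: ", a$n_bits, " vs ", b$n_bits)
  inter <- length(intersect(a$bits, b$bits))
  uni <- length(union(a$bits, b$bits))
  if (uni == 0L) return(0)
  inter / uni
}

#' Fingerprints of many molecules as a logical bit matrix
#'
#' @param smiles Character vector of SMILES (or list of `mt_mol`).
#' @inheritParams fingerprint
#' @return Logical matrix (molecules x bits). Rows of unparsable molecules
#'   are all-`FALSE` and reported in the `failures` attribute.
#' @export
fingerprint_matrix <- function(smiles, radius = 3L, n_bits = 2048L) {
  if (is.character(smiles)) {
    parsed <- parse_smiles_batch(smiles)
    mols <- parsed$mols
    fail <- parsed$failures
  } else {
    mols <- smiles
    fail <- which(vapply(mols, is.null, logical(1)))
  }
  m <- matrix(FALSE, length(mols), n_bits)
  for (i in seq_along(mols)) {
    if (i %in% fail) next
    m[i, fingerprint(mols[[i]], radius = radius, n_bits = n_bits)$bits] <- TRUE
  }
  attr(m, "failures") <- fail
  m
}

#' Pairwise Tanimoto similarity between two fingerprint matrices
#'
#' @param a,b Logical bit matrices with equal numbers of columns (rows are
#'   molecules), as from [fingerprint_matrix()].
#' @return Numeric matrix `nrow(a) x nrow(b)` of similarities.
#' @export
tanimoto_matrix <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b))
  if (ncol(a) != ncol(b)) stop("fingerprint length mismatch")
  am <- matrix(as.numeric(a), nrow(a))
  bm <- matrix(as.numeric(b), nrow(b))
  inter <- am %*% t(bm)
  uni <- outer(rowSums(am), rowSums(bm), `+`) - inter
  out <- inter / uni
  out[uni == 0] <- 0
  out
}
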