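# Dataset curation: similarity-biased test selection against a reference set
# (e.g. challenge molecules), Tanimoto leakage filtering of the training
# pool, and scaffold-balanced / random splits.

records_n <- function(x) {
  if (is.data.frame(x)) nrow(x) else if (is.numeric(x) && length(x) == 1L)
    as.integer(x) else length(x)
}

records_smiles <- function(x) {
  if (is.data.frame(x)) x$smiles else as.character(x)
}

new_split <- function(train, validation, test, provenance) {
  s <- list(train = as.integer(train), validation = as.integer(validation),
            test = as.integer(test), provenance = provenance)
  class(s) <- "mt_split"
  s
}

#' @export
print.mt_split <- function(x, ...) {
  cat(sprintf("<mt_split> train %d / validation %d / test %d\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

#' Select a similarity-biased test set
#'
#' A pool molecule enters the test set iff its maximum Tanimoto similarity
#' (circular fingerprints, radius 3) to any reference molecule is strictly
#' greater than `threshold`. This mimics building a test set that resembles
#' an external challenge set.
#'
#' @param pool Records data frame or character vector of SMILES.
#' @param references Reference molecules (data frame or SMILES vector).
#' @param threshold Similarity cut-off (default 0.25).
#' @param radius,n_bits Fingerprint settings.
#' @return Integer indices of the selected pool molecules; the maximum
#'   similarities are attached as attribute `max_similarity`.
#' @export
select_biased_test <- function(pool, references, threshold = 0.25,
                               radius = 3L, n_bits = 2048L) {
  ps <- records_smiles(pool); rs <- records_smiles(references)
  stopifnot(length(ps) >= 1L, length(rs) >= 1L)
  fp_p <- fingerprint_matrix(ps, radius = radius, n_bits = n_bits)
  fp_r <- fingerprint_matrix(rs, radius = radius, n_bits = n_bits)
  tc <- tanimoto_matrix(fp_p, fp_r)
  max_sim <- apply(tc, 1L, max)
  sel <- which(max_sim > threshold)
  attr(sel, "max_similarity") <- max_sim
  sel
}

#' Remove training molecules too similar to the test set
#'
#' A molecule is kept iff its maximum Tanimoto similarity to every test
#' molecule is at most `threshold`; molecules above it are leakage and are
#' removed (count logged).
#'
#' @param pool Candidate training molecules (records or SMILES vector).
#' @param test Test molecules (records or SMILES vector).
#' @param threshold Removal cut-off (default 0.4; kept iff `<= threshold`).
#' @param radius,n_bits Fingerprint settings.
#' @return Integer indices of the kept pool molecules, with attribute
#'   `removed` (the dropped indices).
#' @export
filter_training <- function(pool, test, threshold = 0.4, radius = 3L,
                            n_bits = 2048L) {
  ps <- records_smiles(pool); ts <- records_smiles(test)
  stopifnot(length(ts) >= 1L)
  fp_p <- fingerprint_matrix(ps, radius = radius, n_bits = n_bits)
  fp_t <- fingerprint_matrix(ts, radius = radius, n_bits = n_bits)
  max_sim <- apply(tanimoto_matrix(fp_p, fp_t), 1L, max)
  keep <- which(max_sim <= threshold)
  removed <- setdiff(seq_along(ps), keep)
  message(sprintf("filter_training: removed %d molecules with similarity > %g to the test set",
                  length(removed), threshold))
  attr(keep, "removed") <- removed
  keep
}

#' Seeded random split
#'
#' Shuffles the record indices with the given seed and slices them into
#' contiguous train/validation/test blocks.
#'
#' @param records Records data frame, SMILES vector, or a single count.
#' @param fractions Length-3 fractions summing to 1.
#' @param seed Integer seed.
#' @return `mt_split`.
#' @export
random_split <- function(records, fractions = c(0.9, 0.1, 0), seed) {
  n <- records_n(records)
  stopifnot(n >= 1L, length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  n_tr <- floor(fractions[1L] * n)
  n_va <- floor(fractions[2L] * n)
  n_te <- n - n_tr - n_va
  # leftover rows from flooring go to train
  if (fractions[3L] == 0 && n_te > 0L) { n_tr <- n_tr + n_te; n_te <- 0L }
  if (fractions[2L] == 0 && n_va > 0L) { n_tr <- n_tr + n_va; n_va <- 0L }
  new_split(perm[seq_len(n_tr)],
            if (n_va) perm[n_tr + seq_len(n_va)] else integer(),
            if (n_te) perm[n_tr + n_va + seq_len(n_te)] else integer(),
            provenance = list(type = "random", fractions = fractions,
                              seed = seed))
}

#' Scaffold-balanced split
#'
#' Molecules are grouped by Bemis-Murcko scaffold and whole groups are
#' assigned to partitions, so no scaffold spans two partitions. Groups larger
#' than half the validation/test targets are placed in train first; the
#' remaining groups are shuffled with the seed and assigned greedily to the
#' partition with the largest remaining deficit.
#'
#' @param records Records data frame or SMILES vector.
#' @param fractions Length-3 train/validation/test fractions summing to 1.
#' @param seed Integer seed.
#' @return `mt_split`; a warning is emitted if one scaffold alone exceeds
#'   the train target (it is still assigned to train).
#' @export
scaffold_balanced_split <- function(records, fractions = c(0.8, 0.1, 0.1),
                                    seed) {
  smiles <- records_smiles(records)
  n <- length(smiles)
  stopifnot(n >= 1L, length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  scaff <- murcko_scaffolds(smiles)
  scaff[is.na(scaff)] <- ""
  groups <- split(seq_len(n), scaff)
  sizes <- lengths(groups)
  targets <- fractions * n
  big_cut <- if (any(fractions[2:3] > 0))
    min(targets[2:3][fractions[2:3] > 0]) / 2 else Inf
  big <- which(sizes > big_cut)
  rest <- setdiff(seq_along(groups), big)
  ord_big <- big[order(sizes[big], decreasing = TRUE)]
  ord_rest <- withr::with_seed(as.integer(seed), sample(rest))
  parts <- list(integer(), integer(), integer())
  fill <- numeric(3L)
  for (gi in ord_big) {
    parts[[1L]] <- c(parts[[1L]], groups[[gi]])
    fill[1L] <- fill[1L] + sizes[gi]
  }
  for (gi in ord_rest) {
    deficit <- targets - fill
    deficit[fractions == 0] <- -Inf
    k <- which.max(deficit)
    parts[[k]] <- c(parts[[k]], groups[[gi]])
    fill[k] <- fill[k] + sizes[gi]
  }
  if (any(sizes > targets[1L]) && targets[1L] > 0)
    warning("a single scaffold group exceeds the train fraction; assigned to train",
            call. = FALSE)
  new_split(parts[[1L]], parts[[2L]], parts[[3L]],
            provenance = list(type = "scaffold_balanced",
                              fractions = fractions, seed = seed,
                              n_scaffolds = length(groups)))
}

#' End-to-end curation: biased test selection plus leakage filtering
#'
#' Runs [select_biased_test()] against the reference molecules, removes the
#' test molecules from the pool, applies [filter_training()] at the training
#' threshold, and optionally carves a random validation fraction out of the
#' surviving training molecules.
#'
#' @param pool Records data frame (see [make_records()]) or SMILES vector.
#' @param references Reference molecules biasing the test selection.
#' @param test_threshold Similarity above which a pool molecule becomes test.
#' @param train_threshold Similarity above which a remaining molecule is
#'   removed as leakage.
#' @param val_fraction Fraction of the final training molecules moved to
#'   validation (seeded random draw).
#' @param seed Integer seed.
#' @param radius,n_bits Fingerprint settings.
#' @return `mt_split` whose provenance records thresholds, seed and removal
#'   counts.
#' @export
curate_split <- function(pool, references, test_threshold = 0.25,
                         train_threshold = 0.4, val_fraction = 0.1, seed = 0L,
                         radius = 3L, n_bits = 2048L) {
  ps <- records_smiles(pool)
  test_idx <- select_biased_test(ps, references, threshold = test_threshold,
                                 radius = radius, n_bits = n_bits)
  remainder <- setdiff(seq_along(ps), test_idx)
  if (length(test_idx)) {
    kept_rel <- filter_training(ps[remainder], ps[test_idx],
                                threshold = train_threshold, radius = radius,
                                n_bits = n_bits)
    removed <- remainder[attr(kept_rel, "removed")]
    train_idx <- remainder[kept_rel]
  } else {
    removed <- integer()
    train_idx <- remainder
  }
  val_idx <- integer()
  if (val_fraction > 0 && length(train_idx) > 1L) {
    n_va <- floor(val_fraction * length(train_idx))
    if (n_va > 0L) {
      pick <- withr::with_seed(as.integer(seed),
                               sample(seq_along(train_idx), n_va))
      val_idx <- train_idx[pick]
      train_idx <- train_idx[-pick]
    }
  }
  s <- new_split(train_idx, val_idx, as.integer(test_idx),
                 provenance = list(type = "similarity_biased",
                                   test_threshold = test_threshold,
                                   train_threshold = train_threshold,
                                   val_fraction = val_fraction, seed = seed,
                                   n_removed_leakage = length(removed),
                                   removed = removed))
  s
}
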