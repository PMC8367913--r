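# Similarity-biased test selection, leakage filtering, splits.

fixture <- function() {
  pool <- utils::read.csv(system.file("extdata", "split_pool.csv",
                                      package = "mtlogp"),
                          stringsAsFactors = FALSE)
  refs <- utils::read.csv(system.file("extdata", "split_references.csv",
                                      package = "mtlogp"),
                          stringsAsFactors = FALSE)
  tc <- jsonlite::read_json(system.file("extdata", "split_pool_tc.json",
                                        package = "mtlogp"),
                            simplifyVector = TRUE)
  list(pool = pool, refs = refs,
       tc_pool_ref = matrix(unlist(tc$tc_pool_ref), nrow(pool),
                            byrow = FALSE),
       tc_pool_pool = matrix(unlist(tc$tc_pool_pool), nrow(pool),
                             byrow = FALSE))
}

test_that("biased test selection matches the brute-force filter on the fixture", {
  fx <- fixture()
  sel <- select_biased_test(fx$pool, fx$refs, threshold = 0.25)
  brute <- which(apply(fx$tc_pool_ref, 1L, max) > 0.25)
  expect_equal(sort(as.integer(sel)), brute)
  expect_gt(length(sel), 0L)
  expect_lt(length(sel), nrow(fx$pool))
})

test_that("selection boundary cases behave as stated", {
  smis <- c("CCO", "c1ccccc1", "CC(=O)NC")
  # references = pool: self-similarity 1 selects everything
  sel <- select_biased_test(smis, smis, threshold = 0.25)
  expect_equal(as.integer(sel), 1:3)
  # threshold 1: nothing is strictly greater than 1
  expect_length(select_biased_test(smis, c("CCCCCCCCCC"), threshold = 1), 0L)
  # duplicates of a reference survive threshold just below 1
  sel2 <- select_biased_test(c("CCO", "CCC"), c("OCC"), threshold = 0.999)
  expect_equal(as.integer(sel2), 1L)
})

test_that("leakage filtering equals the brute-force result and is airtight", {
  fx <- fixture()
  sel <- select_biased_test(fx$pool, fx$refs, threshold = 0.25)
  rest <- setdiff(seq_len(nrow(fx$pool)), sel)
  kept <- suppressMessages(
    filter_training(fx$pool$smiles[rest], fx$pool$smiles[sel],
                    threshold = 0.4))
  brute_kept <- which(apply(fx$tc_pool_pool[rest, sel, drop = FALSE], 1L,
                            max) <= 0.4)
  expect_equal(as.integer(kept), brute_kept)
  expect_gt(length(attr(kept, "removed")), 0L)
  # exhaustive recheck: no surviving train molecule above the threshold
  final_tc <- fx$tc_pool_pool[rest[kept], sel, drop = FALSE]
  expect_equal(sum(final_tc > 0.4), 0L)
})

test_that("filtering leaves dissimilar pools untouched and drops duplicates", {
  train <- c("OCC(O)CO", "NCCCCN", "CSCCSC")
  test <- c("c1ccccc1c1ccccc1", "Clc1ccc(Cl)cc1Cl")
  kept <- suppressMessages(filter_training(train, test))
  expect_equal(as.integer(kept), 1:3)
  kept2 <- suppressMessages(
    filter_training(c("CCO", "NCCCCN"), c("OCC")))
  expect_equal(as.integer(kept2), 2L)
})

test_that("random_split slices by seeded permutation", {
  s <- random_split(100L, c(0.9, 0.1, 0), seed = 42L)
  expect_length(s$train, 90L)
  expect_length(s$validation, 10L)
  expect_length(s$test, 0L)
  expect_equal(sort(c(s$train, s$validation)), 1:100)
  expect_identical(random_split(100L, c(0.9, 0.1, 0), seed = 42L), s)
  s2 <- random_split(50L, c(1, 0, 0), seed = 1L)
  expect_length(s2$train, 50L)
  # different seeds give different permutations
  diffs <- vapply(1:5, function(k) {
    a <- random_split(100L, c(0.9, 0.1, 0), seed = k)
    b <- random_split(100L, c(0.9, 0.1, 0), seed = k + 100L)
    !identical(a$train, b$train)
  }, logical(1))
  expect_true(any(diffs))
})

test_that("scaffold split keeps scaffolds whole and balances sizes", {
  # k singleton scaffolds: sizes must land within 1 of the targets
  smis <- c("c1ccccc1C", "c1ccncc1C", "c1ccsc1C", "c1ccoc1C",
            "C1CCCCC1C", "C1CCNCC1C", "C1CCOCC1C", "C1CCSCC1C")
  s <- scaffold_balanced_split(smis, c(0.5, 0.25, 0.25), seed = 7L)
  expect_equal(sort(c(s$train, s$validation, s$test)), 1:8)
  expect_lte(abs(length(s$train) - 4L), 1L)
  expect_lte(abs(length(s$validation) - 2L), 1L)
  expect_lte(abs(length(s$test) - 2L), 1L)
  expect_identical(scaffold_balanced_split(smis, c(0.5, 0.25, 0.25),
                                           seed = 7L), s)

  # scaffold purity on a mixed set
  smis2 <- c("Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1",
             "Cc1ccncc1", "CCc1ccncc1", "CCCCCC", "CCCCC")
  s2 <- scaffold_balanced_split(smis2, c(0.6, 0.2, 0.2), seed = 1L)
  scaff <- murcko_scaffolds(smis2)
  parts <- list(s2$train, s2$validation, s2$test)
  for (sc in unique(scaff)) {
    hit <- vapply(parts, function(p) any(scaff[p] == sc), logical(1))
    expect_lte(sum(hit), 1L)
  }
})

test_that("one dominating scaffold goes to train with a warning", {
  smis <- c("Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1", "CCCCc1ccccc1")
  expect_warning(s <- scaffold_balanced_split(smis, c(0.5, 0.25, 0.25),
                                              seed = 2L),
                 "train")
  expect_length(s$train, 4L)
  expect_length(s$validation, 0L)
})

test_that("curate_split records provenance and removes leakage end to end", {
  fx <- fixture()
  s <- suppressMessages(curate_split(fx$pool, fx$refs, val_fraction = 0,
                                     seed = 3L))
  expect_s3_class(s, "mt_split")
  expect_equal(s$provenance$test_threshold, 0.25)
  expect_gt(s$provenance$n_removed_leakage, 0L)
  # invariants: disjoint, and train has no molecule above 0.4 to test
  expect_length(intersect(s$train, s$test), 0L)
  tc <- fx$tc_pool_pool[s$train, s$test, drop = FALSE]
  expect_equal(sum(tc > 0.4), 0L)
})
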