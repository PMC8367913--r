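# Regenerates the shipped split fixture under inst/extdata/ from
# fixture_split_pool(). Run from the package root after changing the fixture
# molecules:  Rscript tools/make_fixtures.R
suppressMessages(library(mtlogp))

fx <- fixture_split_pool(seed = 1)
dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
utils::write.csv(fx$pool, "inst/extdata/split_pool.csv", row.names = FALSE)
utils::write.csv(fx$references, "inst/extdata/split_references.csv",
                 row.names = FALSE)
# brute-force pairwise Tanimoto matrices so split assertions are data-driven
jsonlite::write_json(
  list(pool_ids = fx$pool$id, reference_ids = fx$references$id,
       tc_pool_ref = round(unname(fx$tc_pool_ref), 6),
       tc_pool_pool = round(unname(fx$tc_pool_pool), 6)),
  "inst/extdata/split_pool_tc.json", digits = NA, auto_unbox = TRUE)
cat("wrote", nrow(fx$pool), "pool molecules and TC matrices\n")
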