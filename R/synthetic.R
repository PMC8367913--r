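# Synthetic benchmark: molecules assembled from a fragment library with an
# additive ground-truth logP (group-contribution style), noisy "measured"
# labels, and simulated external-predictor columns (helper logP and a
# rule-based helper logD that subtracts an ionization penalty for basic
# amines). Everything is deterministic given a seed, so the whole modelling
# stack can be exercised without any external download.

#' The built-in fragment library
#'
#' About two dozen common organic fragments written so that plain SMILES
#' concatenation yields a valid molecule (every fragment starts and ends on
#' an atom with spare valence). Each fragment carries a fixed lipophilicity
#' contribution in the spirit of group-contribution logP models; the exact
#' weights are arbitrary by design -- they define the synthetic ground
#' truth, they do not estimate real logP.
#'
#' @return Data frame with columns `smiles`, `weight`, `basic` (fragment
#'   contains a basic amine).
#' @export
fragment_library <- function() {
  data.frame(
    smiles = c(
      "C",         "CC",        "CCC",       "C(C)C",     "CCCC",
      "C(C)(C)C",  "C=CC",      "c1ccccc1",  "Cc1ccccc1", "c1ccncc1",
      "c1ccsc1",   "c1ccoc1",   "CO",        "CCO",       "CC(C)O",
      "CCOC",      "CC(=O)OC",  "CC(=O)N",   "CN",        "CCN",
      "CCN(C)C",   "CCS",       "CC(=O)C",   "CC(F)C",    "CC(Cl)C",
      "CC(Br)C",   "CC(C#N)C"
    ),
    weight = c(
      0.55,  1.00,  1.50,  1.45,  2.00,
      1.90,  0.95,  1.90,  2.40,  0.65,
      1.60,  1.20, -0.25,  0.30,  0.75,
      0.80,  0.20, -0.70, -0.50, -0.30,
      0.10,  0.70,  0.00,  1.10,  1.55,
      1.85, -0.30
    ),
    basic = c(
      FALSE, FALSE, FALSE, FALSE, FALSE,
      FALSE, FALSE, FALSE, FALSE, FALSE,
      FALSE, FALSE, FALSE, FALSE, FALSE,
      FALSE, FALSE, FALSE, TRUE,  TRUE,
      TRUE,  FALSE, FALSE, FALSE, FALSE,
      FALSE, FALSE
    ),
    stringsAsFactors = FALSE
  )
}

# Rule-based ionization penalty emulating the logP -> logD7.4 drop of
# ionizable molecules: -1.5 if the molecule contains a basic amine
# (non-aromatic sp3 nitrogen). A deliberately crude stand-in for a pKa model.
ionization_penalty <- function(mol) {
  a <- mol$atoms
  basic_n <- a$element == "N" & !a$aromatic & a$hyb == "sp3"
  if (any(basic_n)) 1.5 else 0
}

#' Generate a synthetic additive-logP dataset
#'
#' Molecules are assembled by seeded sampling of 2-6 fragments from the
#' library and concatenating their SMILES. The hidden ground truth is
#' `true_logp = sum(fragment weights) + 0.02 * n_heavy_atoms`; the observed
#' label adds Gaussian measurement noise. Helper columns emulate an external
#' predictor: `helper_logp = true + helper_bias + noise`, and `helper_logd =
#' helper_logp - ionization_penalty` (-1.5 for molecules with a basic
#' amine), mirroring the logP/logD relationship a multitask model can
#' exploit.
#'
#' @param n_molecules Number of molecules.
#' @param noise_sd Standard deviation of the measurement noise on
#'   `logp_observed`.
#' @param helper_bias Systematic offset of the simulated helper predictor.
#' @param helper_noise_sd Noise of the simulated helper predictor.
#' @param seed Integer seed (assembly and all noise draws).
#' @param library Fragment library (see [fragment_library()]).
#' @param n_frag_range Range of fragments per molecule.
#' @return Data frame with columns `id`, `smiles`, `true_logp` (hidden
#'   ground truth), `logp_observed`, `helper_logp`, `helper_logd`.
#' @export
generate_synthetic <- function(n_molecules = 2000L, noise_sd = 0.3,
                               helper_bias = 0, helper_noise_sd = 0.2,
                               seed = 1L, library = fragment_library(),
                               n_frag_range = c(2L, 6L)) {
  stopifnot(n_molecules >= 1L, noise_sd >= 0, helper_noise_sd >= 0)
  withr::with_seed(as.integer(seed), {
    smiles <- character(n_molecules)
    weight_sum <- numeric(n_molecules)
    pending <- seq_len(n_molecules)
    for (round in seq_len(20L)) {
      if (!length(pending)) break
      nf <- sample(seq(n_frag_range[1L], n_frag_range[2L]), length(pending),
                   replace = TRUE)
      pick <- lapply(nf, function(k)
        sample.int(nrow(library), k, replace = TRUE))
      cand <- vapply(pick, function(p)
        paste(library$smiles[p], collapse = ""), character(1))
      parsed <- parse_smiles_batch(cand)
      ok <- setdiff(seq_along(cand), parsed$failures)
      smiles[pending[ok]] <- cand[ok]
      weight_sum[pending[ok]] <- vapply(pick[ok], function(p)
        sum(library$weight[p]), numeric(1))
      if (length(ok)) pending <- pending[-ok]
      if (round == 20L && length(pending))
        stop("could not assemble valid molecules after 20 rounds")
    }
    mols <- parse_smiles_batch(smiles)$mols
    n_heavy <- vapply(mols, `[[`, integer(1), "n_atoms")
    penalty <- vapply(mols, ionization_penalty, numeric(1))
    true_logp <- weight_sum + 0.02 * n_heavy
    logp_observed <- true_logp + stats::rnorm(n_molecules, 0, noise_sd)
    helper_logp <- true_logp + helper_bias +
      stats::rnorm(n_molecules, 0, helper_noise_sd)
    helper_logd <- helper_logp - penalty
    data.frame(id = sprintf("syn%04d", seq_len(n_molecules)),
               smiles = smiles, true_logp = true_logp,
               logp_observed = logp_observed, helper_logp = helper_logp,
               helper_logd = helper_logd, stringsAsFactors = FALSE)
  })
}

#' Training records from a synthetic dataset
#'
#' Drops the hidden `true_logp` column and declares `logp_observed` as the
#' primary task, optionally with the simulated external-predictor columns as
#' helper tasks.
#'
#' @param df Output of [generate_synthetic()].
#' @param helpers Include `helper_logp` / `helper_logd` as helper tasks?
#' @return `mt_records`.
#' @export
synthetic_records <- function(df, helpers = FALSE) {
  cols <- c("smiles", "id", "logp_observed",
            if (helpers) c("helper_logp", "helper_logd"))
  tasks <- rbind(task_spec("logp_observed", "primary", "synthetic"),
                 if (helpers) task_spec("helper_logp", "helper",
                                        "external_predictor"),
                 if (helpers) task_spec("helper_logd", "helper",
                                        "external_predictor"))
  make_records(df[, cols], tasks)
}

#' Simulated external-predictor provider
#'
#' Returns a provider function for [attach_helper_tasks()] that computes
#' helper logP/logD columns for arbitrary molecules from the additive ground
#' truth of the fragment generator: it stands in for a commercial property
#' calculator. Unparsable molecules get `NA`.
#'
#' @param helper_bias,helper_noise_sd Corruption of the simulated predictor.
#' @param seed Integer seed.
#' @return Function `smiles -> data.frame(helper_logp, helper_logd)`.
#' @export
synthetic_provider <- function(helper_bias = 0, helper_noise_sd = 0.2,
                               seed = 1L) {
  force(helper_bias); force(helper_noise_sd); force(seed)
  function(smiles) {
    mols <- parse_smiles_batch(smiles)$mols
    ok <- !vapply(mols, is.null, logical(1))
    # without the assembly record the additive truth is approximated from
    # heavy-atom count; this provider is meant for plumbing tests only
    base <- rep(NA_real_, length(smiles))
    base[ok] <- vapply(mols[ok], function(m)
      0.25 * m$n_atoms, numeric(1))
    pen <- rep(0, length(smiles))
    pen[ok] <- vapply(mols[ok], ionization_penalty, numeric(1))
    withr::with_seed(as.integer(seed), {
      hp <- base + helper_bias + stats::rnorm(length(smiles), 0,
                                              helper_noise_sd)
    })
    data.frame(helper_logp = hp, helper_logd = hp - pen)
  }
}

# Fixed molecule sets for the similarity-split fixture: clusters of close
# analogues plus structural singletons.
split_fixture_molecules <- function() {
  # homolog series varying one alkyl site keep within-cluster Tanimoto high
  clusters <- list(
    arylamine = c("CCc1ccccc1CCNC(C)CCc1ccccc1",
                  "CCc1ccccc1CCNC(CC)CCc1ccccc1",
                  "CCc1ccccc1CCNC(CCC)CCc1ccccc1",
                  "CCc1ccccc1CCNC(CCCC)CCc1ccccc1"),
    sulfonamide = c("CS(=O)(=O)Nc1ccc(cc1)C(=O)NCCc1ccsc1",
                    "CCS(=O)(=O)Nc1ccc(cc1)C(=O)NCCc1ccsc1",
                    "CCCS(=O)(=O)Nc1ccc(cc1)C(=O)NCCc1ccsc1",
                    "CCCCS(=O)(=O)Nc1ccc(cc1)C(=O)NCCc1ccsc1"),
    diaryl_ether = c("COc1ccc(OC)cc1CCOCCOc1ccccc1",
                     "COc1ccc(OCC)cc1CCOCCOc1ccccc1",
                     "COc1ccc(OCCC)cc1CCOCCOc1ccccc1",
                     "COc1ccc(OCCCC)cc1CCOCCOc1ccccc1"),
    pyridyl_amide = c("CC(=O)Nc1ccncc1CCNC(=O)c1ccccc1",
                      "CCC(=O)Nc1ccncc1CCNC(=O)c1ccccc1",
                      "CCCC(=O)Nc1ccncc1CCNC(=O)c1ccccc1",
                      "CCCCC(=O)Nc1ccncc1CCNC(=O)c1ccccc1"),
    thienyl_ester = c("CCOC(=O)c1ccsc1CCOC(=O)CCc1ccccc1",
                      "CCCOC(=O)c1ccsc1CCOC(=O)CCc1ccccc1",
                      "CCCCOC(=O)c1ccsc1CCOC(=O)CCc1ccccc1",
                      "CCCCCOC(=O)c1ccsc1CCOC(=O)CCc1ccccc1"),
    dichloroaryl = c("Clc1ccc(Cl)cc1CCNCCCc1ccc(F)cc1",
                     "Clc1ccc(Cl)cc1CCNCCCCc1ccc(F)cc1",
                     "Clc1ccc(Cl)cc1CCNCCCCCc1ccc(F)cc1",
                     "Clc1ccc(Cl)cc1CCNCCCCCCc1ccc(F)cc1"),
    cyclohexyl_acid = c("OC(=O)CC1CCCCC1CCCOCC1CCCCC1",
                        "OC(=O)CCC1CCCCC1CCCOCC1CCCCC1",
                        "OC(=O)CCCC1CCCCC1CCCOCC1CCCCC1",
                        "OC(=O)CCCCC1CCCCC1CCCOCC1CCCCC1"),
    piperazine = c("CN1CCN(CC1)CCCNC(=O)c1ccncc1",
                   "CN1CCN(CC1)CCCCNC(=O)c1ccncc1",
                   "CN1CCN(CC1)CCCCCNC(=O)c1ccncc1",
                   "CN1CCN(CC1)CCCCCCNC(=O)c1ccncc1"),
    # hybrid: the sulfonamide head ties the first member to a reference,
    # the morpholine tail ties it to the other two -- which therefore end
    # up as train/test leakage that the similarity filter must remove
    morpholine_hybrid = c("CS(=O)(=O)Nc1ccc(cc1)C(=O)NCCOCCCN1CCOCC1",
                          "CC(=O)NCCOCCCN1CCOCC1",
                          "CCC(=O)NCCOCCCN1CCOCC1")
  )
  singletons <- c(
    "OCC(O)C(O)C(O)C(O)CO", "NC(=O)C(N)CC(=O)O", "CNC(=O)NC(=O)NC",
    "OCCOCCOCCO", "CSCCSC", "NCCCCN", "OC(=O)CCC(=O)O",
    "CC(O)C(O)C(O)C", "NC(=O)NCC(=O)N", "COCOCOC",
    "CC#CC#CC", "OCC1CO1", "C1CC1C1CC1", "NC1CC1", "OC1CCOC1",
    "FC(F)(F)C(F)(F)F", "CNC(=O)OC", "SCC(=O)NC", "OCC=CCO",
    "NCCSCCN", "CC(C)(O)C(C)(C)O", "OC1COC(O)C1O", "CN(C)C(=O)N(C)C",
    "CCOP(=O)(OCC)OCC", "O=S(=O)(O)CCO", "NC(CO)CO", "OCc1coc(CO)c1"
  )
  list(clusters = clusters, singletons = singletons)
}

#' Deterministic fixture pool for split testing
#'
#' About 60 molecules with hand-checkable similarity structure: clusters of
#' near-duplicate analogues (high pairwise Tanimoto) and structural
#' singletons (low similarity to everything else), plus 5 reference
#' molecules drawn from distinct clusters. Pairwise Tanimoto matrices are
#' computed by brute force and returned alongside, so split assertions can
#' be data-driven.
#'
#' @param seed Integer seed (shuffles the pool order only; the molecule
#'   content is fixed).
#' @param radius,n_bits Fingerprint settings.
#' @return List with `pool` (data frame: `id`, `smiles`, `cluster`),
#'   `references` (data frame: `id`, `smiles`), `tc_pool_ref` and
#'   `tc_pool_pool` (similarity matrices aligned to the pool rows).
#' @export
fixture_split_pool <- function(seed = 1L, radius = 3L, n_bits = 2048L) {
  sets <- split_fixture_molecules()
  pool <- do.call(rbind, c(
    lapply(names(sets$clusters), function(nm)
      data.frame(smiles = sets$clusters[[nm]], cluster = nm,
                 stringsAsFactors = FALSE)),
    list(data.frame(smiles = sets$singletons, cluster = "singleton",
                    stringsAsFactors = FALSE))))
  ord <- withr::with_seed(as.integer(seed), sample.int(nrow(pool)))
  pool <- pool[ord, , drop = FALSE]
  rownames(pool) <- NULL
  pool <- data.frame(id = sprintf("fix%02d", seq_len(nrow(pool))),
                     pool, stringsAsFactors = FALSE)
  # next homolog of five of the clusters: similar (TC > 0.25) to their
  # cluster, dissimilar to the singletons
  refs <- data.frame(
    id = paste0("ref", 1:5),
    smiles = c("CCc1ccccc1CCNC(CCCCC)CCc1ccccc1",
               "CCCCCS(=O)(=O)Nc1ccc(cc1)C(=O)NCCc1ccsc1",
               "COc1ccc(OCCCCC)cc1CCOCCOc1ccccc1",
               "CCCCCC(=O)Nc1ccncc1CCNC(=O)c1ccccc1",
               "CN1CCN(CC1)CCCCCCCNC(=O)c1ccncc1"),
    stringsAsFactors = FALSE)
  fp_pool <- fingerprint_matrix(pool$smiles, radius = radius, n_bits = n_bits)
  fp_ref <- fingerprint_matrix(refs$smiles, radius = radius, n_bits = n_bits)
  list(pool = pool, references = refs,
       tc_pool_ref = tanimoto_matrix(fp_pool, fp_ref),
       tc_pool_pool = tanimoto_matrix(fp_pool, fp_pool))
}
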