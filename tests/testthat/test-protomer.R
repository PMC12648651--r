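# Titratable-site enumeration, charge-model construction, two-tier ranking
# and Boltzmann mole fractions.

test_that("site enumeration finds deprotonation sites on glycine and none on alkanes", {
  gly <- glycine_molecule()
  sites <- enumerate_sites(gly, "[M-H]-")
  # amine N-H and carboxyl O-H
  expect_identical(sort(sites$element), c("N", "O"))
  expect_true(all(sites$mode == "deprotonation"))

  expect_error(enumerate_sites(fixture_smiles("C1CCCCC1", "cyclohexane"),
                               "[M+H]+"), "no titratable site")
  expect_error(enumerate_sites(fixture_smiles("C1CCCCC1", "cyclohexane"),
                               "[M-H]-"), "no titratable site")

  w <- water_molecule()
  sw <- enumerate_sites(w, "[M-H]-")
  expect_identical(nrow(sw), 1L)
  expect_identical(sw$element, "O")
})

test_that("valence-saturated nitrogens are excluded from protonation sites", {
  # N,N-dimethylformamide: amide N (3 single bonds) is a site, carbonyl O is a site
  dmf <- fixture_smiles("CN(C)C=O", "dmf")
  sites <- enumerate_sites(dmf, "[M+H]+")
  expect_setequal(sites$element, c("N", "O"))
  # quaternary-equivalent N with bond-order sum 4 never appears:
  bos <- vapply(sites$atom_index, function(a) confocus:::bond_order_sum(dmf, a),
                numeric(1))
  expect_true(all(bos[sites$element == "N"] <= 3))
})

test_that("charge models keep exact atom-count and charge bookkeeping", {
  w <- water_molecule()
  prot <- build_charge_model(w, list(atom_index = 1, mode = "protonation"))
  expect_identical(length(prot$molecule$elements), 4L)
  expect_identical(prot$molecule$formal_charge, 1L)
  expect_identical(prot$adduct, "[M+H]+")

  deprot <- build_charge_model(w, list(atom_index = 1, mode = "deprotonation"))
  expect_identical(length(deprot$molecule$elements), 2L)
  expect_identical(deprot$molecule$formal_charge, -1L)
  expect_identical(deprot$adduct, "[M-H]-")

  # property over a multi-site molecule: deltas are exactly (+1,+1) / (-1,-1)
  gly <- glycine_molecule()
  for (adduct in c("[M+H]+", "[M-H]-")) {
    sites <- enumerate_sites(gly, adduct)
    for (k in seq_len(nrow(sites))) {
      cm <- build_charge_model(gly, sites[k, ])
      delta <- length(cm$molecule$elements) - length(gly$elements)
      expect_identical(delta, ifelse(adduct == "[M+H]+", 1L, -1L))
      expect_identical(cm$molecule$formal_charge,
                       ifelse(adduct == "[M+H]+", 1L, -1L))
    }
  }
})

test_that("deprotonation leaves all non-site coordinates bitwise unchanged", {
  gly <- glycine_molecule()
  sites <- enumerate_sites(gly, "[M-H]-")
  o_site <- sites[sites$element == "O", ][1, ]
  cm <- build_charge_model(gly, o_site)
  removed_h <- min(confocus:::h_neighbors(gly, o_site$atom_index))
  keep <- setdiff(seq_along(gly$elements), removed_h)
  expect_identical(cm$molecule$coords, gly$coords[keep, , drop = FALSE])
  expect_identical(cm$molecule$elements, gly$elements[keep])
})

test_that("protonation plants the proton at the standard bond length", {
  gly <- glycine_molecule()
  sites <- enumerate_sites(gly, "[M+H]+")
  for (k in seq_len(nrow(sites))) {
    cm <- build_charge_model(gly, sites[k, ])
    n <- length(cm$molecule$elements)
    d <- sqrt(sum((cm$molecule$coords[n, ] -
                     cm$molecule$coords[sites$atom_index[k], ])^2))
    expected <- ifelse(sites$element[k] == "N", 1.01, 0.96)
    expect_equal(d, expected, tolerance = 1e-9)
    # untouched remainder
    expect_identical(cm$molecule$coords[seq_len(n - 1), ], gly$coords)
  }
})

test_that("mole fractions follow closed-form Boltzmann statistics", {
  expect_equal(mole_fractions(c(5, 5)), c(0.5, 0.5))
  expect_equal(mole_fractions(7.3), 1.0)

  # dE = RT ln 2 -> 2:1 population
  rt <- 1.98720425864e-3 * 298.15
  x <- mole_fractions(c(0, rt * log(2)))
  expect_equal(x, c(2 / 3, 1 / 3), tolerance = 1e-12)

  expect_error(mole_fractions(numeric(0)), "non-empty")
  expect_error(mole_fractions(c(0, 1), temperature = 0), "> 0")
})

test_that("mole fractions sum to one and shift-invariance holds", {
  for (seed in 1:10) {
    e <- withr::with_seed(seed, stats::runif(6, 0, 30))
    x <- mole_fractions(e)
    expect_lt(abs(sum(x) - 1), 1e-12)
    expect_true(all(x > 0 & x <= 1))
    expect_equal(x, mole_fractions(e + 123.4), tolerance = 1e-12)
  }
})

test_that("secondary scorer ranking supersedes the primary ranking", {
  gly <- glycine_molecule()
  sites <- enumerate_sites(gly, "[M-H]-")
  models <- lapply(seq_len(nrow(sites)), function(k) build_charge_model(gly, sites[k, ]))

  primary <- function(m) if (m$site$element == "O") 1 else 2   # O first
  secondary <- function(m) if (m$site$element == "O") 2 else 1 # N first
  ranked <- rank_charge_models(models, primary, secondary)
  expect_identical(ranked[[1]]$site$element, "N")
  expect_identical(vapply(ranked, `[[`, integer(1), "rank"),
                   seq_along(ranked))

  # secondary = primary: supersession is a no-op
  same <- rank_charge_models(models, primary, primary)
  expect_identical(same[[1]]$site$element, "O")
})

test_that("ranking orders by score, is a permutation, and tolerates scorer failure", {
  gly <- glycine_molecule()
  sites <- enumerate_sites(gly, "[M+H]+")
  models <- lapply(seq_len(nrow(sites)), function(k) build_charge_model(gly, sites[k, ]))
  stopifnot(length(models) >= 3)

  fixed <- c(5.0, 3.0, 4.0)
  scorer <- local({
    calls <- 0
    function(m) {
      idx <- which(vapply(models, function(x) x$site$atom_index, integer(1)) ==
                     m$site$atom_index)[1]
      fixed[((idx - 1) %% 3) + 1]
    }
  })
  ranked <- rank_charge_models(models[1:3], scorer, scorer)
  got <- vapply(ranked, function(m) m$site$atom_index, integer(1))
  want <- vapply(models[c(2, 3, 1)], function(m) m$site$atom_index, integer(1))
  expect_identical(got, want)

  # single model: rank 1 regardless of score
  one <- rank_charge_models(models[1], function(m) 99)
  expect_identical(one[[1]]$rank, 1L)

  # failure on one model drops it with a warning; all failing errors out
  flaky <- function(m) if (m$site$atom_index == models[[1]]$site$atom_index)
    stop("boom") else 1
  expect_warning(r2 <- rank_charge_models(models[1:2], flaky, flaky),
                 "dropped")
  expect_length(r2, 1)
  expect_error(suppressWarnings(
    rank_charge_models(models[1:2], function(m) stop("boom"))), "all charge models")
})

test_that("the built-in surrogate scorer is deterministic and chemically ordered", {
  # 2-methoxyethylamine: sp3 amine N vs ether O protonation
  moe <- fixture_smiles("COCCN", "methoxyethylamine")
  sites <- enumerate_sites(moe, "[M+H]+")
  models <- lapply(seq_len(nrow(sites)), function(k) build_charge_model(moe, sites[k, ]))
  scores <- vapply(models, builtin_surrogate_scorer, numeric(1))
  n_score <- scores[vapply(models, function(m) m$site$element, "") == "N"]
  o_scores <- scores[vapply(models, function(m) m$site$element, "") == "O"]
  expect_true(all(n_score < o_scores))

  # stability over repeated calls
  rep_scores <- replicate(100, builtin_surrogate_scorer(models[[1]]))
  expect_identical(length(unique(rep_scores)), 1L)
})
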