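# Kabsch/SVD RMSD, ensemble RMSD statistics, and the normal-walk reduction.

test_that("svd_rmsd is zero on identity and rigid transforms", {
  mol <- glycine_molecule()
  expect_lt(svd_rmsd(mol$coords, mol$coords), 1e-12)
  for (seed in 1:5) {
    moved <- withr::with_seed(seed, rigid_transform(mol$coords))
    expect_lt(svd_rmsd(mol$coords, moved), 1e-9)
  }
  expect_error(svd_rmsd(mol$coords, mol$coords[-1, ]), "equal atom counts")
})

test_that("svd_rmsd agrees with a brute-force rotational search oracle", {
  # random 4-8 atom pairs; the oracle minimizes RMSD over a rotation grid
  # with local polish, independently of the SVD closed form
  for (seed in 1:20) {
    pq <- withr::with_seed(seed, {
      n <- sample(4:8, 1)
      P <- matrix(stats::rnorm(3 * n, sd = 1.5), n, 3)
      Q <- P + matrix(stats::rnorm(3 * n, sd = 0.2), n, 3)
      list(P = P, Q = rigid_transform(Q))
    })
    expect_equal(svd_rmsd(pq$P, pq$Q), grid_rmsd_oracle(pq$P, pq$Q),
                 tolerance = 1e-6)
  }
})

test_that("svd_rmsd is symmetric and invariant to a common rigid transform", {
  for (seed in 1:10) {
    pq <- withr::with_seed(seed, {
      P <- matrix(stats::rnorm(18), 6, 3)
      Q <- matrix(stats::rnorm(18), 6, 3)
      rot <- confocus:::random_rotation()
      shift <- stats::runif(3)
      list(P = P, Q = Q,
           Pm = sweep(P %*% t(rot), 2, -shift),
           Qm = sweep(Q %*% t(rot), 2, -shift))
    })
    expect_equal(svd_rmsd(pq$P, pq$Q), svd_rmsd(pq$Q, pq$P), tolerance = 1e-12)
    expect_equal(svd_rmsd(pq$Pm, pq$Qm), svd_rmsd(pq$P, pq$Q), tolerance = 1e-9)
  }
})

test_that("walk step count is 20 per rotatable bond, floored at one", {
  expect_identical(walk_steps(1), 20L)
  expect_identical(walk_steps(5), 100L)
  expect_identical(walk_steps(0), 1L)
  expect_error(walk_steps(-1), "non-negative")
})

test_that("ensemble RMSD statistics match a hand-computed oracle", {
  mol <- water_molecule()
  # reference (energy 0) plus two members displaced on one atom; the
  # expected statistics are recomputed arithmetically from the two
  # member-to-reference RMSDs
  c1 <- mol$coords
  c2 <- mol$coords; c2[2, 1] <- c2[2, 1] + 0.4
  c3 <- mol$coords; c3[2, 1] <- c3[2, 1] + 1.2
  ens <- ensemble(mol, list(
    conformer("ref", c1, energy = 0),
    conformer("a", c2, energy = 1),
    conformer("b", c3, energy = 2)
  ), 1L)
  rep_ <- ensemble_rmsd_stats(ens, rot = 1)
  r_a <- svd_rmsd(c1, c2); r_b <- svd_rmsd(c1, c3)
  expect_identical(rep_$reference_id, "ref")
  expect_equal(unname(rep_$rmsds[["ref"]]), 0)
  expect_equal(rep_$mean, mean(c(r_a, r_b)), tolerance = 1e-12)
  expect_equal(rep_$sd, sqrt(mean((c(r_a, r_b) - mean(c(r_a, r_b)))^2)),
               tolerance = 1e-12)
  expect_equal(rep_$rmsd_min, min(r_a, r_b))
  expect_equal(rep_$rmsd_max, max(r_a, r_b))
  expect_identical(rep_$steps, 20L)
  expect_error(ensemble_rmsd_stats(ensemble(mol, list(
    conformer("only", c1)), 1L)), ">= 2")
})

test_that("identical ensembles give all-zero RMSD statistics", {
  mol <- water_molecule()
  ens <- synth_ensemble(mol, 6, noise_sd = 0, seed = 2)
  rep_ <- ensemble_rmsd_stats(ens, rot = 0)
  expect_equal(max(abs(rep_$rmsds)), 0, tolerance = 1e-9)
  expect_equal(rep_$mean, 0, tolerance = 1e-9)
  expect_equal(rep_$sd, 0, tolerance = 1e-9)
})

test_that("ensembles at or below the size threshold bypass the walk", {
  mol <- water_molecule()
  ens <- synth_ensemble(mol, 40, noise_sd = 0.2, seed = 8)
  expect_identical(normal_walk_reduce(ens, size_threshold = 50), ens)
})

test_that("degenerate (all-identical) oversized ensembles collapse", {
  mol <- glycine_molecule()
  ens <- synth_ensemble(mol, 60, noise_sd = 0, seed = 3)
  expect_warning(out <- normal_walk_reduce(ens, size_threshold = 50, rot = 2),
                 "degenerate")
  expect_lte(length(out), 2)
  expect_true(confocus:::ensemble_ids(ens)[confocus:::reference_index(ens)] %in%
                confocus:::ensemble_ids(out))
})

test_that("normal-walk invariants hold over many seeded synthetic ensembles", {
  mol <- glycine_molecule()
  cases <- expand.grid(seed = 1:10, rot = c(1, 2, 4, 6))
  sizes <- withr::with_seed(77, sample(60:300, nrow(cases), replace = TRUE))
  for (k in seq_len(nrow(cases))) {
    rot <- cases$rot[k]
    ens <- synth_ensemble(mol, sizes[k], noise_sd = 0.3,
                          seed = 1000 + cases$seed[k])
    out <- normal_walk_reduce(ens, size_threshold = 50, rot = rot)
    ids_in <- confocus:::ensemble_ids(ens)
    ids_out <- confocus:::ensemble_ids(out)
    # subset, survivor cap, reference retention
    expect_true(all(ids_out %in% ids_in))
    expect_lte(length(out), 20 * rot + 1)
    e <- confocus:::ensemble_energies(ens)
    expect_true(ids_in[which.min(e)] %in% ids_out)
    # determinism
    out2 <- normal_walk_reduce(ens, size_threshold = 50, rot = rot)
    expect_identical(ids_out, confocus:::ensemble_ids(out2))
    # idempotence once under the threshold
    if (length(out) <= 50) {
      expect_identical(
        confocus:::ensemble_ids(normal_walk_reduce(out, size_threshold = 50,
                                                   rot = rot)),
        ids_out)
    }
  }
})

test_that("each occupied walk interval keeps exactly its minimum-energy member", {
  mol <- glycine_molecule()
  ens <- synth_ensemble(mol, 200, noise_sd = 0.3, seed = 55)
  rot <- 2
  out <- normal_walk_reduce(ens, size_threshold = 50, rot = rot)
  expect_lte(length(out), 20 * rot + 1)

  # brute-force oracle: recompute interval assignment and per-interval minima
  rep_ <- ensemble_rmsd_stats(ens, rot = rot)
  edges <- seq(rep_$rmsd_min, rep_$rmsd_max, length.out = rep_$steps + 1)
  e <- confocus:::ensemble_energies(ens)
  member <- setdiff(seq_along(rep_$rmsds), rep_$reference_index)
  bin <- findInterval(rep_$rmsds[member], edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  expected <- rep_$reference_index
  for (b in unique(bin)) {
    in_bin <- member[bin == b]
    expected <- c(expected, in_bin[order(e[in_bin], in_bin)][1])
  }
  expect_identical(confocus:::ensemble_ids(out),
                   confocus:::ensemble_ids(ens)[sort(unique(expected))])
})

test_that("survivor count is monotone non-decreasing in ROT", {
  mol <- glycine_molecule()
  ens <- synth_ensemble(mol, 150, noise_sd = 0.3, seed = 60)
  counts <- vapply(c(1, 2, 3, 5), function(rot)
    length(normal_walk_reduce(ens, size_threshold = 50, rot = rot)),
    integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the quantile walk variant also respects the core invariants", {
  mol <- glycine_molecule()
  ens <- synth_ensemble(mol, 120, noise_sd = 0.3, seed = 65)
  out <- normal_walk_reduce(ens, size_threshold = 50, rot = 2,
                            variant = "quantile")
  expect_true(all(confocus:::ensemble_ids(out) %in% confocus:::ensemble_ids(ens)))
  expect_lte(length(out), 41)
  e <- confocus:::ensemble_energies(ens)
  expect_true(confocus:::ensemble_ids(ens)[which.min(e)] %in%
                confocus:::ensemble_ids(out))
})
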