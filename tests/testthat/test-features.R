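# lean configuration keeping the feature tests fast
lean_config <- function(...) {
  feature_config(elements = "C", grid0 = c(2, 4, 6), grid12 = c(2, 4),
                 dims = 0:1, r_mut = 8, r_bind = 10, ...)
}

test_that("spectral statistics split harmonic and non-harmonic parts", {
  mk <- function(ev) structure(list(k = 0, t = 0, p = 0, eigenvalues = ev,
                                    zero_tol = 1e-8),
                               class = "LaplacianSpectrum")
  expect_equal(unname(spectral_statistics(mk(c(0, 0, 3, 3)))),
               c(2, 3, 3, 3, 0, 6, 0, 1))
  expect_equal(unname(spectral_statistics(mk(0))),
               c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(spectral_statistics(mk(c(0, 2, 4)))),
               c(1, 2, 4, 3, 1, 6, 1, 1))
})

test_that("feature vectors have a fixed schema with finite values", {
  s <- make_toy_dimer(residues_per_chain = 10, interface_contacts = 2,
                      seed = 2)
  mut <- toy_mutation(s, "5")
  fv <- filtration_features(s, mut, lean_config())
  expect_true(all(is.finite(fv)))
  expect_false(is.null(names(fv)))
  expect_false(anyDuplicated(names(fv)) > 0)
  # schema blocks: 2 site types x 1 element pair x (3 + 2 grid values) x 8
  expect_length(fv, 2 * 1 * (3 + 2) * 8)

  # denser grid doubles a block's length; shared grid values are unchanged
  # for non-persistent spectra (the persistence offset tracks the grid step)
  cfg_a <- lean_config(persistence = "none")
  cfg_b <- feature_config(elements = "C", grid0 = c(1, 2, 3, 4, 5, 6),
                          grid12 = c(2, 4), dims = 0:1, r_mut = 8,
                          r_bind = 10, persistence = "none")
  fva <- filtration_features(s, mut, cfg_a)
  fvb <- filtration_features(s, mut, cfg_b)
  expect_equal(length(fvb[grep("_k0_", names(fvb))]),
               2 * length(fva[grep("_k0_", names(fva))]))
  shared <- intersect(names(fva), names(fvb))
  expect_true(length(shared) > 0)
  expect_equal(fvb[shared], fva[shared])
})

test_that("merging components shows up as a harmonic-count drop", {
  # one cross contact at about 4 A: below that scale the C clouds on the
  # two sides are disconnected, above it two components merge
  s <- make_toy_dimer(residues_per_chain = 10, interface_contacts = 1,
                      seed = 6)
  mut <- toy_mutation(s, "5")
  sub <- site_subsets(s, mut, r_mut = 8, r_bind = 10)
  ia <- filter_by_element(s, sub$a_p1, "C")
  ib <- filter_by_element(s, sub$a_p2, "C")
  dm <- pairwise_distances(s, c(ia, ib), mode = "mod",
                           grouping = s$partition[s$atoms$chain])
  cx <- build_rips(dm, max_dim = 1, max_filtration = 10)
  b_lo <- betti_by_rank(snapshot(cx, 3.5), 0)
  b_hi <- betti_by_rank(snapshot(cx, 4.5), 0)
  expect_lt(b_hi, b_lo)
  sp_lo <- spectrum(combinatorial_laplacian(snapshot(cx, 3.5), 0))
  sp_hi <- spectrum(combinatorial_laplacian(snapshot(cx, 4.5), 0))
  expect_equal(betti_from_spectrum(sp_lo), b_lo)
  expect_equal(betti_from_spectrum(sp_hi), b_hi)
})

test_that("same-partner subsets under the modified distance stay discrete", {
  s <- make_toy_dimer(residues_per_chain = 8, interface_contacts = 2,
                      seed = 3)
  idx <- which(s$atoms$chain == "A")[1:10]
  dm <- pairwise_distances(s, idx, mode = "mod",
                           grouping = s$partition[s$atoms$chain])
  cx <- build_rips(dm, max_dim = 1, max_filtration = 12)
  expect_equal(nrow(cx$simplices[[2]]), 0)
  for (t in c(2, 6, 12)) {
    expect_equal(betti_by_rank(snapshot(cx, t), 0), length(idx))
  }
})

test_that("identity mutation gives an all-zero difference block", {
  s <- make_toy_dimer(residues_per_chain = 10, interface_contacts = 2,
                      seed = 2)
  mut <- toy_mutation(s, "5")
  av <- assemble_features(s, s, mut, lean_config())
  expect_true(all(av[grep("^diff_", names(av))] == 0))
  expect_false(is.null(attr(av, "config_hash")))
})

test_that("a real structural change moves dimension-0 statistics", {
  s <- make_toy_dimer(residues_per_chain = 10, interface_contacts = 2,
                      seed = 2)
  mut <- toy_mutation(s, "5")
  ms <- build_mutant(s, mut)
  expect_lt(nrow(ms$atoms), nrow(s$atoms))  # side chain truncated
  av <- assemble_features(s, ms, mut, lean_config())
  diff_k0 <- av[grep("^diff_.*_k0_", names(av))]
  expect_gt(sum(diff_k0 != 0), 0)
})

test_that("features are invariant under rigid motion and atom reordering", {
  s <- make_toy_dimer(residues_per_chain = 10, interface_contacts = 2,
                      seed = 12)
  mut <- toy_mutation(s, "5")
  cfg <- lean_config()
  fv <- filtration_features(s, mut, cfg)

  rot <- random_rotation(seed = 99)
  moved <- s
  moved$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rot), 2,
          c(5, -3, 11), "+")
  expect_equal(filtration_features(moved, mut, cfg), fv, tolerance = 1e-6)

  set.seed(4)
  shuffled <- s
  shuffled$atoms <- s$atoms[sample(nrow(s$atoms)), , drop = FALSE]
  expect_equal(filtration_features(shuffled, mut, cfg), fv,
               tolerance = 1e-9)
})

test_that("feature extraction is deterministic and local", {
  s <- make_toy_dimer(residues_per_chain = 10, interface_contacts = 2,
                      seed = 2)
  mut <- toy_mutation(s, "5")
  cfg <- lean_config()
  expect_identical(filtration_features(s, mut, cfg),
                   filtration_features(s, mut, cfg))
  # atoms far from both the mutation site and the interface are irrelevant:
  # translate a far-away decoy residue even farther
  decoy <- s
  far <- decoy$atoms$chain == "B" & decoy$atoms$res_seq == "1"
  decoy$atoms$z[far] <- decoy$atoms$z[far] + 500
  base <- s
  base$atoms$z[far] <- base$atoms$z[far] + 900
  expect_equal(filtration_features(decoy, mut, cfg),
               filtration_features(base, mut, cfg))
})

test_that("plugin features append with a prefix and schema checks fire", {
  s <- make_toy_dimer(residues_per_chain = 10, interface_contacts = 2,
                      seed = 2)
  mut <- toy_mutation(s, "5")
  av <- assemble_features(s, s, mut, lean_config(),
                          plugin = c(esm1 = 0.5, esm2 = -1))
  expect_true(all(c("plugin_esm1", "plugin_esm2") %in% names(av)))
  expect_error(assemble_features(s, s, mut, lean_config(), plugin = 1:3),
               "named")
})
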