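rot_from_axis <- function(w) {
  # Rodrigues formula for the numeric-minimization oracle
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

test_that("Kabsch superposition is exact on rigid copies", {
  set.seed(1)
  X <- matrix(rnorm(30), 10)
  al <- kabsch_superpose(X, X)
  expect_equal(al$rmsd, 0, tolerance = 1e-12)
  expect_equal(al$rotation, diag(3), tolerance = 1e-9)

  R <- random_rotation(seed = 5)
  Y <- X %*% t(R) + matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  al2 <- kabsch_superpose(X, Y)
  expect_lt(al2$rmsd, 1e-9)
  expect_equal(det(al2$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(al2$rotation), diag(3), tolerance = 1e-9)

  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("minimized RMSD matches an independent numerical minimization", {
  # unit square with one vertex displaced by 1 along z
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  sq2 <- sq; sq2[2, 3] <- 1
  al <- kabsch_superpose(sq, sq2)

  obj <- function(par) {
    Rm <- rot_from_axis(par[1:3])
    moved <- sweep(sq %*% t(Rm), 2, par[4:6], "+")
    sqrt(mean(rowSums((moved - sq2)^2)))
  }
  set.seed(2)
  best <- min(vapply(1:20, function(i) {
    stats::optim(c(rnorm(3, 0, 1), rnorm(3, 0, 1)), obj,
                 method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))$value
  }, 0))
  expect_equal(al$rmsd, best, tolerance = 1e-5)
  expect_lte(al$rmsd, best + 1e-8)
})

test_that("Kabsch RMSD agrees with the bio3d fitting route", {
  set.seed(6)
  X <- matrix(rnorm(60), 20)
  Y <- X + matrix(rnorm(60, 0, 0.5), 20)
  al <- kabsch_superpose(X, Y)
  xyz_moved <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(Y)),
                                               mobile = as.numeric(t(X))))
  rmsd_bio3d <- sqrt(mean(rowSums(
    (matrix(xyz_moved, ncol = 3, byrow = TRUE) - Y)^2)))
  expect_equal(al$rmsd, rmsd_bio3d, tolerance = 1e-6)
})

test_that("superposition is symmetric between the two structures", {
  set.seed(9)
  X <- matrix(rnorm(45), 15)
  Y <- X %*% t(random_rotation(seed = 2)) +
    matrix(rnorm(45, 0, 0.3), 15)
  expect_equal(kabsch_superpose(X, Y)$rmsd, kabsch_superpose(Y, X)$rmsd,
               tolerance = 1e-9)
})

test_that("chain mapping recovers renamed and swapped chains", {
  s <- make_toy_dimer(residues_per_chain = 15, interface_contacts = 2,
                      seed = 4)
  renamed <- s
  renamed$atoms$chain <- ifelse(s$atoms$chain == "A", "X", "Y")
  renamed$partition <- c(X = "P1", Y = "P2")
  expect_equal(map_chains(renamed, s), c(X = "A", Y = "B"))

  # predicted copy missing a chain is reported
  half <- new_structure("H", s$atoms[s$atoms$chain == "A", ], c(A = "P1"))
  expect_error(map_chains(half, s), "B")
})

test_that("homodimer chain assignment picks the lower-RMSD pairing", {
  a <- make_toy_dimer(residues_per_chain = 12, interface_contacts = 0,
                      seed = 5)
  at <- a$atoms[a$atoms$chain == "A", ]
  bt <- at
  bt$chain <- "B"
  bt$x <- bt$x + 12   # identical sequence, different placement
  homo <- new_structure("HOMO", rbind(at, bt), c(A = "P1", B = "P2"))
  swapped <- homo
  swapped$atoms$chain <- ifelse(homo$atoms$chain == "A", "B", "A")
  swapped$partition <- c(A = "P2", B = "P1")
  mp <- map_chains(swapped, homo)
  al <- superpose_structures(swapped, homo, chain_map = mp)
  expect_lt(al$rmsd, 1e-6)
})

test_that("per-residue backbone RMSD isolates the displaced residue", {
  s <- make_toy_dimer(residues_per_chain = 20, interface_contacts = 0,
                      seed = 8)
  moved <- s
  sel <- moved$atoms$chain == "A" & moved$atoms$res_seq == "10"
  moved$atoms$y[sel] <- moved$atoms$y[sel] + 2
  al <- superpose_structures(moved, s)
  tab <- al$per_residue
  worst <- tab[which.max(tab$rmsd), ]
  expect_equal(worst$chain, "A")
  expect_equal(worst$res_seq, "10")
  expect_equal(worst$rmsd, 2, tolerance = 0.15)
  expect_lt(stats::median(tab$rmsd), 0.1)

  # identical structures give all-zero residues
  al0 <- superpose_structures(s, s)
  expect_true(all(al0$per_residue$rmsd < 1e-9))
})

test_that("missing backbone atoms shrink the residue average, not break it", {
  s <- make_toy_dimer(residues_per_chain = 10, interface_contacts = 0,
                      seed = 2)
  pred <- s
  drop <- which(pred$atoms$chain == "A" & pred$atoms$res_seq == "5" &
                pred$atoms$name == "O")
  pred$atoms <- pred$atoms[-drop, ]
  al <- superpose_structures(pred, s)
  expect_true("5" %in% al$per_residue$res_seq[al$per_residue$chain == "A"])
  expect_true(all(al$per_residue$rmsd < 1e-9))
})

test_that("B-factor joins carry flexibility, error and residue type", {
  s <- make_toy_dimer(residues_per_chain = 25, interface_contacts = 0,
                      seed = 3)
  key <- unique(paste(s$atoms$chain, s$atoms$res_seq))
  bres <- tapply(s$atoms$b_factor, paste(s$atoms$chain, s$atoms$res_seq),
                 mean)[key]
  pred <- perturb_structure(s, 0.04 * as.numeric(bres), seed = 3,
                            rigid = TRUE)
  al <- superpose_structures(pred, s)
  tab <- bfactor_rmsd_table(s, al$per_residue)
  expect_true(all(c("b_factor", "rmsd", "aa") %in% names(tab)))
  expect_lte(length(unique(tab$aa)), 20)
  expect_gte(stats::cor(tab$b_factor, tab$rmsd, method = "spearman"), 0.8)

  al0 <- superpose_structures(s, s)
  tab0 <- bfactor_rmsd_table(s, al0$per_residue)
  expect_true(all(tab0$rmsd < 1e-9))

  szero <- s; szero$atoms$b_factor <- 0
  expect_warning(bfactor_rmsd_table(szero, al0$per_residue), "zero")
})

test_that("summaries count confidence bands and intersect rankings", {
  ev <- data.frame(
    complex_id = sprintf("C%02d", 1:10),
    rmsd = c(9, 8, 7, 6, 5, 1, 1, 1, 1, 1),
    iptm = c(0.3, 0.4, 0.5, 0.55, 0.58, 0.9, 0.92, 0.95, 0.85, 0.7),
    ptm = c(0.4, 0.6, 0.7, 0.8, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9))
  sm <- summarize_and_rank(ev, top_n = 5)
  expect_equal(unname(sm$fractions["iptm_high"]), 4 / 10)
  expect_equal(unname(sm$fractions["iptm_low"]), 5 / 10)
  expect_equal(unname(sm$fractions["ptm_ok"]), 9 / 10)
  expect_equal(sm$n_rmsd_outliers, 5)
  expect_equal(sm$top_rmsd, c("C01", "C02", "C03", "C04", "C05"))
  expect_equal(sm$low_iptm, c("C01", "C02", "C03", "C04", "C05"))
  expect_length(sm$poor_both, 5)

  # fraction example: {0.9, 0.7, 0.85} with threshold 0.8 -> 2/3
  ev3 <- data.frame(complex_id = c("A", "B", "C"), rmsd = 1,
                    iptm = c(0.9, 0.7, 0.85), ptm = 0.9)
  expect_equal(unname(summarize_and_rank(ev3)$fractions["iptm_high"]),
               2 / 3)
  # single complex: means equal its values
  sm1 <- summarize_and_rank(ev3[1, ])
  expect_equal(unname(sm1$summary), c(1, 0.9, 0.9))
})

test_that("rankings are input-order invariant with stable tie-breaks", {
  set.seed(12)
  ev <- data.frame(complex_id = sprintf("X%02d", 1:12),
                   rmsd = rep(c(3, 2, 1), each = 4),
                   iptm = rep(c(0.5, 0.7, 0.9), 4),
                   ptm = 0.8)
  sm1 <- summarize_and_rank(ev, top_n = 6)
  sm2 <- summarize_and_rank(ev[sample(12), ], top_n = 6)
  expect_identical(sm1$top_rmsd, sm2$top_rmsd)
  expect_identical(sm1$low_iptm, sm2$low_iptm)
  expect_identical(sm1$poor_both, sm2$poor_both)
})

test_that("manifest-driven batch evaluation writes the three outputs", {
  out <- withr::local_tempdir()
  mf <- make_fixtures(file.path(out, "fx"), seed = 3, n_complexes = 2)
  res <- evaluate_manifest(mf, file.path(out, "ev"))
  expect_equal(nrow(res$evaluations), 2)
  expect_true(all(res$evaluations$rmsd >= 0))
  expect_true(file.exists(file.path(out, "ev", "complex_evaluations.csv")))
  expect_true(file.exists(file.path(out, "ev", "per_residue_rmsd.csv")))
  expect_true(file.exists(file.path(out, "ev", "summary.txt")))
})
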