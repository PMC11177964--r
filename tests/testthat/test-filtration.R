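expect_closed <- function(cx) {
  # every face present with a filtration value no larger than its coface
  for (k in seq_len(cx$max_dim)) {
    mat <- cx$simplices[[k + 1]]
    if (nrow(mat) == 0) next
    vals <- cx$values[[k + 1]]
    fk <- topoddg:::simplex_keys(cx$simplices[[k]])
    fv <- cx$values[[k]]
    for (i in seq_len(ncol(mat))) {
      faces <- topoddg:::simplex_keys(mat[, -i, drop = FALSE])
      idx <- match(faces, fk)
      expect_false(anyNA(idx))
      expect_true(all(fv[idx] <= vals + 1e-9))
    }
  }
}

test_that("Rips filtration of an equilateral triangle matches enumeration", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  cx <- build_rips(d, max_dim = 2, max_filtration = 2)
  expect_equal(nrow(cx$simplices[[1]]), 3)
  expect_equal(cx$values[[1]], rep(0, 3))
  expect_equal(nrow(cx$simplices[[2]]), 3)
  expect_equal(cx$values[[2]], rep(1, 3))
  expect_equal(nrow(cx$simplices[[3]]), 1)
  expect_equal(cx$values[[3]], 1)
  expect_closed(cx)

  # threshold below all distances leaves vertices only
  cx0 <- build_rips(d, max_dim = 2, max_filtration = 0.5)
  expect_equal(nrow(cx0$simplices[[2]]), 0)
  expect_equal(nrow(cx0$simplices[[1]]), 3)
})

test_that("infinite (modified) distances exclude simplices from Rips", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- Inf
  cx <- build_rips(d, max_dim = 2, max_filtration = 2)
  expect_equal(nrow(cx$simplices[[2]]), 2)   # the Inf edge is gone
  expect_equal(nrow(cx$simplices[[3]]), 0)   # and so is the 2-simplex
  expect_error(build_rips(matrix(c(0, -1, -1, 0), 2), 1, 1), "negative")
})

test_that("alpha filtration values match closed-form circumradii", {
  # unit regular tetrahedron enters at its circumradius sqrt(6)/4
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  a <- build_alpha(pts)
  expect_equal(nrow(a$simplices[[4]]), 1)
  expect_equal(a$values[[4]], sqrt(6) / 4, tolerance = 1e-9)
  expect_closed(a)

  # two points at distance d: the edge appears at d/2 (radius scale)
  e <- build_alpha(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(e$values[[2]], 1, tolerance = 1e-12)

  # single point
  v <- build_alpha(matrix(c(0, 0, 0), 1))
  expect_equal(nrow(v$simplices[[1]]), 1)
  expect_equal(v$values[[1]], 0)
})

test_that("alpha truncation reproduces the full filtration below the cutoff", {
  set.seed(21)
  for (rep in 1:5) {
    P <- matrix(runif(36, 0, 3), ncol = 3)
    full <- build_alpha(P)
    cut <- build_alpha(P, max_filtration = 1.2)
    for (k in 1:3) {
      keep <- full$values[[k + 1]] <= 1.2
      kf <- topoddg:::simplex_keys(full$simplices[[k + 1]])[keep]
      kc <- topoddg:::simplex_keys(cut$simplices[[k + 1]])
      expect_setequal(kf, kc)
      expect_equal(sort(full$values[[k + 1]][keep]),
                   sort(cut$values[[k + 1]]), tolerance = 1e-12)
    }
  }
})

test_that("degenerate clouds are perturbed into general position", {
  sq <- cbind(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5), 0)  # coplanar
  expect_message(a <- build_alpha(sq), "general-position")
  expect_closed(a)
  expect_equal(betti_by_rank(snapshot(a, 3), 0), 1)
})

test_that("cross-only pruning removes same-group simplices and keeps closure", {
  # triangle with two P1 vertices and one P2 vertex
  d <- matrix(1, 3, 3); diag(d) <- 0
  cx <- build_rips(d, max_dim = 2, max_filtration = 2)
  pruned <- prune_cross_only(cx, c("P1", "P1", "P2"))
  expect_equal(nrow(pruned$simplices[[1]]), 3)
  expect_equal(nrow(pruned$simplices[[2]]), 2)    # P1-P1 edge removed
  expect_equal(nrow(pruned$simplices[[3]]), 0)    # 2-simplex removed
  expect_closed(pruned)

  # all vertices in one group: vertices only
  all1 <- prune_cross_only(cx, rep("P1", 3))
  expect_equal(nrow(all1$simplices[[2]]), 0)

  # bipartite square with alternating groups keeps all four cross edges
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  a <- suppressMessages(build_alpha(sq))
  pr <- prune_cross_only(a, c("P1", "P2", "P1", "P2"))
  edges <- pr$simplices[[2]]
  # brute-force rule check: exactly the cross-group pairs survive
  grp <- c("P1", "P2", "P1", "P2")
  expected <- which(outer(grp, grp, "!=") & upper.tri(diag(4)),
                    arr.ind = TRUE)
  expect_equal(nrow(edges), nrow(expected))
  expect_setequal(topoddg:::simplex_keys(edges),
                  paste(pmin(expected[, 1], expected[, 2]),
                        pmax(expected[, 1], expected[, 2]), sep = "-"))
  expect_error(prune_cross_only(cx, c("P1", NA, "P2")), "label")
})

test_that("snapshots are nested and reproduce hand enumeration", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  cx <- build_rips(d, max_dim = 2, max_filtration = 2)
  s0 <- snapshot(cx, 0.5)
  expect_equal(nrow(s0$simplices[[2]]), 0)
  s1 <- snapshot(cx, 1)
  expect_equal(nrow(s1$simplices[[2]]), 3)
  expect_equal(nrow(s1$simplices[[3]]), 1)

  set.seed(3)
  P <- matrix(runif(27, 0, 2), ncol = 3)
  a <- build_alpha(P)
  counts <- vapply(seq(0, 3, 0.25), function(t) {
    sn <- snapshot(a, t)
    sum(vapply(sn$simplices, nrow, 0L))
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("boundary matrices have alternating-sign incidence and B.B = 0", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  sn <- snapshot(build_rips(d, 2, 2), 1)
  B1 <- boundary_matrix(sn, 1)
  expect_equal(dim(B1$entries), c(3, 3))
  expect_true(all(colSums(B1$entries != 0) == 2))
  expect_true(all(colSums(B1$entries) == 0))   # +1 and -1 per column
  B2 <- boundary_matrix(sn, 2)
  expect_equal(dim(B2$entries), c(3, 1))
  expect_true(all(B1$entries %*% B2$entries == 0))   # exact, integer
  B0 <- boundary_matrix(sn, 0)
  expect_equal(dim(B0$entries), c(0, 3))
  expect_error(boundary_matrix(sn, 5), "out of range")
})

test_that("complexes serialize to one simplex per line", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  cx <- build_rips(d, 2, 2)
  f <- withr::local_tempfile(fileext = ".txt")
  write_complex(cx, f)
  lines <- readLines(f)
  expect_length(lines, 7)   # 3 vertices + 3 edges + 1 triangle
  expect_match(lines[1], "^0 ")
})
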