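# Superposition, TM-score, structure alignment and label transfer.

test_that("kabsch recovers exact rigid transforms and beats random search", {
  set.seed(3)
  a <- matrix(rnorm(30), ncol = 3)
  rot <- sprotannot:::random_rotation()
  b <- sweep(a %*% rot, 2, c(3, -2, 5), `+`)
  fit <- kabsch(a, b)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # rmsd equals brute-force recomputation under the returned transform
  fitted <- sweep(b %*% t(fit$rotation), 2, fit$translation, `+`)
  expect_equal(fit$rmsd, sqrt(mean(rowSums((fitted - a)^2))), tolerance = 1e-9)

  expect_error(kabsch(a[1:2, ], b[1:2, ]), "3 point")
})

test_that("kabsch rmsd is a lower bound over random rigid transforms", {
  # 4-point asymmetric fixture vs a large randomized rigid search
  a <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0), c(1, 1, 2))
  b <- rbind(c(0.2, 0, 0), c(2.1, -0.3, 0), c(-0.2, 2.8, 0.4), c(1, 1.4, 1.8))
  opt <- kabsch(a, b)$rmsd
  set.seed(7)
  best <- Inf
  for (k in seq_len(1e4)) {
    rot <- sprotannot:::random_rotation()
    br <- b %*% t(rot)
    br <- sweep(br, 2, colMeans(a) - colMeans(br), `+`)
    best <- min(best, sqrt(mean(rowSums((br - a)^2))))
  }
  expect_lte(opt, best + 1e-9)
})

test_that("TM-score: identity gives 1, d0 clamps for short chains", {
  ch <- ideal_helix(25)
  n <- length(ch)
  tm <- tm_score_fixed(ch, ch, cbind(1:n, 1:n), n)
  expect_equal(tm$tm, 1, tolerance = 1e-6)
  # 1.24 * (20 - 15)^(1/3) - 1.8 = 0.32 < 0.5, so the clamp engages
  expect_equal(tm_d0(20), 0.5)
  expect_gt(tm_d0(100), 3)
  expect_error(tm_score_fixed(ch, ch, cbind(1:n, 1:n), 4), "norm_length")
})

test_that("tm_score_fixed is symmetric and bounded by 1", {
  ch <- small_bundle(seed = 4)
  p <- perturb_model(ch, 6, seed = 9)
  n <- length(ch)
  pairs <- cbind(1:n, 1:n)
  t1 <- tm_score_fixed(ch, p, pairs, n)$tm
  t2 <- tm_score_fixed(p, ch, pairs, n)$tm
  expect_equal(t1, t2, tolerance = 1e-6)
  expect_lte(t1, 1)
  expect_gt(t1, 0)
})

test_that("iterative TM search matches a coarse exhaustive transform grid", {
  # small fixture: compare iterative subset search against many random
  # rigid transforms (stochastic lower-bound oracle on the TM objective)
  ch <- small_bundle(seed = 6)
  p <- perturb_model(ch, 12, seed = 3)
  n <- length(ch)
  pairs <- cbind(1:n, 1:n)
  res <- tm_score_fixed(ch, p, pairs, n)
  d0 <- res$d0
  a <- ch$xyz$CA; b <- p$xyz$CA
  set.seed(5)
  best <- 0
  for (k in seq_len(2000)) {
    rot <- sprotannot:::random_rotation()
    br <- b %*% t(rot)
    br <- sweep(br, 2, colMeans(a) - colMeans(br), `+`)
    best <- max(best, sum(1 / (1 + rowSums((br - a)^2) / d0^2)) / n)
  }
  expect_gte(res$tm, best - 0.01)
})

test_that("align_structures recovers perturbed copies and separates folds", {
  tops <- default_topologies()
  f1 <- small_bundle(seed = 3)
  n <- length(f1)
  tms <- vapply(1:5, function(s) {
    p <- perturb_model(f1, 5, seed = s)
    al <- align_structures(f1, p)
    truth <- tm_score_fixed(f1, p, cbind(1:n, 1:n), n)$tm
    expect_gte(al$tm_score, 0.9 * truth)
    al$tm_score
  }, 0)
  expect_gt(mean(tms), 0.5)

  self <- align_structures(f1, f1)
  expect_equal(self$tm_score, 1, tolerance = 1e-6)
  expect_equal(self$aligned_identity, 1)

  sheet <- make_fold(tops$sheet$spec,
                     paste(rep("V", tops$sheet$spec$total_length),
                           collapse = ""), seed = 4)
  expect_lt(align_structures(f1, sheet)$tm_score, 0.4)
})

test_that("library search is exhaustive, sorted and finds self", {
  lib <- make_labeled_library(2, seed = 5)
  q <- lib$entries[[1]]$chain
  hits <- search_library(q, lib)
  expect_setequal(hits$id, names(lib$entries))
  expect_true(all(diff(hits$tm_score) <= 1e-12))
  expect_equal(hits$id[1], lib$entries[[1]]$id)
  expect_equal(hits$tm_score[1], 1, tolerance = 1e-6)
})

test_that("classification transfers labels only at the TM gate", {
  lib <- make_labeled_library(2, seed = 5)
  q <- perturb_model(lib$parents$bundle, 6, seed = 2)
  cl <- classify_by_nearest(q, lib)
  expect_true(cl$significant)
  expect_equal(cl$label, "1.10.1")
  expect_equal(cl$class, "1")

  # below the gate: nothing is transferred (force with a high min_tm)
  cl2 <- classify_by_nearest(q, lib, min_tm = 0.999)
  expect_false(cl2$significant)
  expect_true(is.na(cl2$label))
})

test_that("TM between original and perturbed models degrades with noise", {
  ch <- small_bundle(seed = 10)
  n <- length(ch)
  noise <- c(2, 8, 25)
  m <- vapply(noise, function(nd) {
    mean(vapply(1:8, function(s) {
      p <- perturb_model(ch, nd, seed = s)
      tm_score_fixed(ch, p, cbind(1:n, 1:n), n)$tm
    }, 0))
  }, 0)
  expect_true(all(diff(m) < 0))
})
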