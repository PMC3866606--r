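# Binding annotation: site transfer, clustering, screening, deduplication
# and metal prediction.

test_that("site centers transfer exactly for identical templates and move rigidly", {
  q <- small_bundle(seed = 2)
  site <- q$xyz$CA[10, ] + c(3, 0, 0)
  tpl <- list(list(id = "t1", chain = q, site = site, kind = "ligand",
                   metal_type = NULL, fingerprint = rep(1L, 64)))
  ct <- transfer_site_centers(q, tpl)
  expect_equal(as.numeric(ct[1, c("x", "y", "z")]), site, tolerance = 1e-4)

  set.seed(4)
  rot <- sprotannot:::random_rotation(); tr <- c(10, -5, 3)
  qr <- sprotannot:::transform_chain(q, rot, tr)
  ctr <- transfer_site_centers(qr, tpl)
  expect_equal(as.numeric(ctr[1, c("x", "y", "z")]),
               as.numeric(rot %*% site + tr), tolerance = 1e-3)
})

test_that("holo-template transfer localizes the planted site", {
  q <- small_bundle(seed = 6)
  model <- perturb_model(q, 2, seed = 11)
  hs <- make_holo_templates(q, 5, "ligand", seed = 7)
  ct <- transfer_site_centers(model, hs)
  expect_gte(nrow(ct), 4)
  pockets <- cluster_sites(ct, model)
  expect_gte(length(pockets), 1)
  n <- length(model$aa)
  fit <- tm_score_fixed(model, q, cbind(1:n, 1:n), n)$superposition
  truth <- as.numeric(fit$rotation %*% hs$true_site + fit$translation)
  expect_lt(sqrt(sum((pockets[[1]]$center - truth)^2)), 4)
})

test_that("clustering splits distant sites and rewards support", {
  q <- small_bundle(seed = 2)
  mk <- function(x, tm) data.frame(template = paste0("t", x), tm = tm,
                                   x = x, y = 0, z = 0,
                                   metal_type = NA_character_,
                                   stringsAsFactors = FALSE)
  close3 <- do.call(rbind, lapply(c(0, 0.5, 1), mk, tm = 0.8))
  p1 <- cluster_sites(close3, q)
  expect_equal(length(p1), 1L)
  twosites <- rbind(close3, mk(30, 0.7), mk(30.4, 0.7))
  p2 <- cluster_sites(twosites, q)
  expect_equal(length(p2), 2L)
  expect_equal(nrow(p2[[1]]$supporting_templates), 3L)
  # an added concordant template raises rank-sum and site confidence
  more <- rbind(close3, mk(0.2, 0.8))
  p3 <- cluster_sites(more, q)
  expect_gt(p3[[1]]$rank_sum, p1[[1]]$rank_sum)
  expect_gte(p3[[1]]$site_confidence, p1[[1]]$site_confidence)
})

test_that("screening ranks the probe first and flags confident screens", {
  lib <- make_compound_library(300, n_actives = 1, similarity_to_probe = 1,
                               seed = 5)
  pocket <- list(fingerprints = list(t1 = lib$probe))
  sr <- screen_library(pocket, lib)
  expect_equal(sr$ranking$id[1], lib$active_ids[1])
  expect_true(sr$confident)
  expect_gte(sr$z_top, 2)
  # degenerate library
  same <- lib
  same$fingerprints <- matrix(rep(lib$probe, each = 12), nrow = 12,
                              dimnames = list(sprintf("c%d", 1:12), NULL))
  expect_error(screen_library(pocket, same), "degenerate")
  expect_error(screen_library(pocket, lib$fingerprints[1:5, ]), "10")
})

test_that("library deduplication follows the greedy Tanimoto rule", {
  fp <- matrix(0L, 6, 64, dimnames = list(sprintf("c%d", 1:6), NULL))
  fp[1, 1:16] <- 1L
  fp[2, 1:16] <- 1L               # duplicate of c1 -> dropped
  fp[3, c(1:14, 17, 18)] <- 1L    # tanimoto to c1 = 14/18 = 0.78 -> kept
  fp[4, 33:48] <- 1L              # disjoint -> kept
  fp[5, c(1:15, 17)] <- 1L        # 15/17 = 0.88 to c1 -> dropped
  fp[6, c(33:47, 1)] <- 1L        # 15/17 to c4 -> dropped
  kept <- dedupe_library(fp, 0.8)
  expect_equal(rownames(kept), c("c1", "c3", "c4"))
  # all-dissimilar input is unchanged
  expect_equal(nrow(dedupe_library(fp[c(1, 4), ], 0.8)), 2L)
})

test_that("metal prediction votes by TM weight and reports apt residues", {
  q <- small_bundle(seed = 6)
  hs <- make_holo_templates(q, 5, "metal", metal_type = "ZN", seed = 9)
  # the target carries the apt coordination shell of its source fold
  model <- perturb_model(hs$apt_query, 2, seed = 3)
  mp <- predict_metal_sites(model, hs)
  expect_gte(length(mp), 1)
  top <- mp[[1]]
  expect_equal(top$metal_type, "ZN")
  expect_equal(top$conf_type, 1)
  n <- length(model$aa)
  fit <- tm_score_fixed(model, q, cbind(1:n, 1:n), n)$superposition
  truth <- as.numeric(fit$rotation %*% hs$true_site + fit$translation)
  expect_lt(sqrt(sum((top$position - truth)^2)), 3)
  expect_gte(sum(model$aa[top$binding_residues] %in% c("C", "H", "D", "E")),
             2)
  expect_true(all(c(top$conf_site, top$conf_residues, top$conf_type) >= 0 &
                    c(top$conf_site, top$conf_residues, top$conf_type) <= 1))

  # TM-weighted vote: recompute the expected share from the supporting
  # templates' own TM-scores
  hs2 <- hs
  for (i in 1:3) hs2$templates[[i]]$metal_type <- "CA"
  mp2 <- predict_metal_sites(model, hs2)
  sup <- mp2[[1]]$supporting_templates
  ca_ids <- vapply(hs2$templates[1:3], `[[`, "", "id")
  expected <- sum(sup$tm[sup$template %in% ca_ids]) / sum(sup$tm)
  if (expected > 0.5) {
    expect_equal(mp2[[1]]$metal_type, "CA")
    expect_equal(mp2[[1]]$conf_type, expected, tolerance = 1e-9)
  }
})
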