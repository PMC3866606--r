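# Seeded generators: determinism, planted-signal strength, type invariants.

test_that("sequence generator respects range, composition and determinism", {
  r <- make_sprotein_sequences(100, c(50, 100), seed = 1)
  expect_equal(nrow(r), 100L)
  expect_true(all(nchar(r$sequence) >= 50 & nchar(r$sequence) <= 100))
  expect_identical(r, make_sprotein_sequences(100, c(50, 100), seed = 1))
  expect_error(make_sprotein_sequences(0), "positive")
  expect_error(make_sprotein_sequences(5, c(5, 700)), "\\[10, 600\\]")

  # length histogram uniform by chi-square
  big <- make_sprotein_sequences(6000, c(50, 100), seed = 2)
  tab <- table(factor(nchar(big$sequence), levels = 50:100))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("make_fold realizes the requested secondary structure elements", {
  helix30 <- fold_spec(list(c("helix", 30)), "bundle")
  ch <- make_fold(helix30, paste(rep("A", 30), collapse = ""), seed = 1)
  expect_gte(mean(assign_secondary_structure(ch) == "H"), 0.8)

  hp <- ideal_hairpin(8)
  ss <- assign_secondary_structure(hp)
  expect_gte(sum(ss == "E"), 8)

  spec <- default_topologies()$bundle$spec
  s <- paste(rep("A", spec$total_length), collapse = "")
  expect_equal(make_fold(spec, s, seed = 9)$xyz$CA,
               make_fold(spec, s, seed = 9)$xyz$CA)
  expect_error(make_fold(spec, "SHORT", seed = 1), "length")
})

test_that("perturb_model is exact at zero noise and calibrated at low noise", {
  ch <- small_bundle(seed = 1)
  n <- length(ch)
  p0 <- perturb_model(ch, 0, seed = 5)
  expect_equal(tm_score_fixed(ch, p0, cbind(1:n, 1:n), n)$tm, 1,
               tolerance = 1e-6)
  # 2-degree noise keeps models in the high-similarity regime
  h60 <- make_fold(fold_spec(list(c("helix", 25), c("loop", 4),
                                  c("helix", 25), c("loop", 6)), "bundle"),
                   paste(rep("A", 60), collapse = ""), seed = 2)
  tms <- vapply(1:20, function(s) {
    p <- perturb_model(h60, 2, seed = s)
    tm_score_fixed(h60, p, cbind(1:60, 1:60), 60)$tm
  }, 0)
  expect_gte(mean(tms > 0.7), 0.9)
})

test_that("dimer templates carry self-consistent labeled interfaces", {
  for (s in 1:4) {
    d <- make_dimer_template(seed = s, id = sprintf("d%d", s))
    expect_lt(length(d$ligand_chain), length(d$receptor_chain))
    expect_gt(length(d$ligand_interface), 0)
    expect_gt(length(d$receptor_interface), 0)
    iface <- template_interface(d)
    expect_equal(iface$ligand_interface, d$ligand_interface)
    expect_equal(iface$receptor_interface, d$receptor_interface)
    # no inter-chain clash
    dmin <- sqrt(min(sprotannot:::distsq_matrix(d$ligand_chain$xyz$CA,
                                                d$receptor_chain$xyz$CA)))
    expect_gte(dmin, 3.8 - 1e-9)
    validate_chain(d$ligand_chain)
    validate_chain(d$receptor_chain)
  }
  expect_error(make_dimer_template(default_topologies()$bundle$spec,
                                   default_topologies()$bundle$spec),
               "shorter")
})

test_that("labeled library separates topologies structurally", {
  lib <- make_labeled_library(2, seed = 3)
  labs <- vapply(lib$entries, `[[`, "", "label")
  expect_true(all(grepl("^[0-9]+\\.[0-9]+\\.[0-9]+$", labs)))
  ids <- names(lib$entries)
  within <- c(); cross <- c()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      tm <- align_structures(lib$entries[[i]]$chain,
                             lib$entries[[j]]$chain)$tm_score
      if (labs[i] == labs[j]) within <- c(within, tm) else cross <- c(cross, tm)
    }
  }
  expect_gt(mean(within), mean(cross))
  expect_gt(min(within), 0.4)
  lib2 <- make_labeled_library(2, seed = 3)
  expect_equal(lib$entries[[1]]$chain$xyz$CA, lib2$entries[[1]]$chain$xyz$CA)
})

test_that("proteome planting follows the mutation rate", {
  rec <- c(r1 = make_sprotein_sequences(1, c(200, 200), seed = 4)$sequence)
  p0 <- make_proteome(0, rec, mutation_rate = 0, seed = 1)
  expect_equal(p0$sequence[1], unname(rec))
  ident <- vapply(1:10, function(s) {
    p <- make_proteome(0, rec, mutation_rate = 0.3, seed = s)
    seq_identity(p$sequence[1], rec)
  }, 0)
  expect_true(all(ident >= 0.6 & ident <= 0.8))
  # background sequences are unrelated to the receptor
  bg <- make_proteome(15, character(), seed = 2, length_range = c(150, 250))
  bgid <- vapply(bg$sequence[1:10], seq_identity, 0, b = rec)
  expect_lt(mean(bgid), 0.35)
})

test_that("compound libraries plant actives at the requested similarity", {
  lib1 <- make_compound_library(20, n_actives = 3, similarity_to_probe = 1,
                                seed = 1)
  for (i in 1:3) expect_equal(lib1$fingerprints[i, ], lib1$probe,
                              ignore_attr = TRUE)
  lib <- make_compound_library(400, n_actives = 100,
                               similarity_to_probe = 0.8, seed = 2)
  tans <- apply(lib$fingerprints[1:100, ], 1, function(f)
    sum(f & lib$probe) / sum(f | lib$probe))
  expect_equal(mean(tans), 0.8, tolerance = 0.05)
  bg <- apply(lib$fingerprints[101:400, ], 1, function(f)
    sum(f & lib$probe) / sum(f | lib$probe))
  expect_lt(mean(bg), 0.4)
  expect_identical(lib$fingerprints,
                   make_compound_library(400, n_actives = 100,
                                         similarity_to_probe = 0.8,
                                         seed = 2)$fingerprints)
})

test_that("holo templates plant consistent sites with apt metal shells", {
  q <- small_bundle(seed = 6)
  hs <- make_holo_templates(q, 5, "metal", metal_type = "ZN", seed = 3)
  for (tpl in hs$templates) {
    # nearest residues to the metal are chemically apt for zinc
    d <- sqrt(rowSums(sweep(tpl$chain$xyz$CA, 2, tpl$site)^2))
    nearest <- tpl$chain$aa[order(d)[1:4]]
    expect_gte(sum(nearest %in% c("C", "H")), 2)
    # superposing the template back onto the query carries the site home
    fit <- kabsch(q$xyz$CA, tpl$chain$xyz$CA)
    back <- as.numeric(fit$rotation %*% tpl$site + fit$translation)
    expect_lt(sqrt(sum((back - hs$true_site)^2)), 8)
  }
  hs2 <- make_holo_templates(q, 5, "metal", metal_type = "ZN", seed = 3)
  expect_equal(hs$templates[[2]]$chain$xyz$CA, hs2$templates[[2]]$chain$xyz$CA)
  expect_equal(hs$templates[[2]]$site, hs2$templates[[2]]$site)
})
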