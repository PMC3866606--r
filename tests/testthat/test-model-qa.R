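# QA layer: torsions, H-bonds, secondary structure, Ramachandran, tiers.

test_that("torsion_angles matches a hand-placed dihedral and flags termini", {
  # four atoms with an exact 90-degree dihedral, computed by vector algebra
  a <- c(1, 0, 0); b <- c(0, 0, 0); cc <- c(0, 1, 0); d <- c(0, 1, 1)
  expect_equal(sprotannot:::dihedral4(a, b, cc, d), 90, tolerance = 0.01)

  ch <- ideal_helix(2)
  tor <- torsion_angles(ch)
  expect_true(is.na(tor[1, "phi"]))
  expect_true(is.na(tor[2, "psi"]))
  expect_false(is.na(tor[1, "psi"]))
})

test_that("ideal helix has a complete i->i+4 main-chain H-bond ladder", {
  ch <- ideal_helix(20)
  hb <- detect_hbonds(ch)
  mm <- hb[hb$category == "main-main", ]
  # donors 5..20 each bond back to residue i-4
  expect_true(all((5:20) %in% mm$donor_res))
  expect_true(all(mm$acceptor_res == mm$donor_res - 4))
  expect_true(all(mm$energy < -0.5))

  # a single extended strand has no backbone partners in range
  expect_equal(nrow(detect_hbonds(ideal_strand(10))), 0L)
})

test_that("main-main H-bond detection equals a brute-force rescan", {
  ch <- small_bundle(seed = 8)
  hb <- detect_hbonds(ch)
  mm <- hb[hb$category == "main-main", c("donor_res", "acceptor_res")]
  # independent re-scan over all donor/acceptor pairs
  H <- sprotannot:::.amide_h(ch)
  n <- length(ch$aa)
  found <- list()
  for (i in seq_len(n)) {
    if (!is.finite(H[i, 1])) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 3 || !is.finite(ch$xyz$O[j, 1])) next
      e <- sprotannot:::.dssp_energy(ch$xyz$N[i, ], H[i, ], ch$xyz$O[j, ],
                                     ch$xyz$C[j, ])
      if (e < -0.5) found[[length(found) + 1]] <- c(i, j)
    }
  }
  brute <- do.call(rbind, found)
  expect_equal(nrow(mm), nrow(brute))
  expect_setequal(paste(mm$donor_res, mm$acceptor_res),
                  paste(brute[, 1], brute[, 2]))
})

test_that("side-chain donors near backbone oxygens yield main-side bonds", {
  ch <- ideal_strand(6, aa = "S")
  # plant a Ser OG 2.9 A from residue 1's backbone O at a favorable angle
  o <- ch$xyz$O[1, ]
  cb <- ch$xyz$CB[4, ]
  og <- o + 2.9 * sprotannot:::unitv(cb - o)
  ch$extra <- data.frame(res = 4, name = "OG", element = "O",
                         x = og[1], y = og[2], z = og[3])
  hb <- detect_hbonds(ch)
  expect_true(any(hb$category == "main-side" & hb$donor_atom == "OG" &
                    hb$acceptor_res == 1))
})

test_that("secondary structure follows the H-bond pattern rules", {
  expect_gte(mean(assign_secondary_structure(ideal_helix(30)) == "H"), 0.8)
  expect_false(any(assign_secondary_structure(ideal_helix(30)) == "E"))

  hp <- ideal_hairpin(8)
  ss <- assign_secondary_structure(hp)
  expect_gte(sum(ss[1:8] == "E"), 4)
  expect_gte(sum(ss[11:18] == "E"), 4)

  # chains under 5 residues are all coil
  expect_equal(assign_secondary_structure(ideal_helix(4)), rep("C", 4))

  # random coils are neither helix nor sheet on average
  spec <- fold_spec(list(c("loop", 15), c("loop", 15)), "bundle")
  fr <- vapply(1:10, function(s) {
    ch <- make_fold(spec, paste(rep("G", 30), collapse = ""), seed = s)
    mean(assign_secondary_structure(ch) %in% c("H", "E"))
  }, 0)
  expect_lt(mean(fr), 0.2)
})

test_that("Ramachandran grid classifies cores and forgives glycine", {
  g <- rama_grid()
  lev <- function(phi, psi) g[floor((phi + 180) / 10) + 1,
                              floor((psi + 180) / 10) + 1]
  expect_equal(lev(-57, -47), 4L)    # alpha core
  expect_equal(lev(-120, 120), 4L)   # beta core
  expect_equal(lev(60, 45), 4L)      # left-handed alpha core
  expect_equal(lev(60, -60), 1L)     # disallowed for non-Gly

  n <- 8
  tor <- matrix(rep(c(60, -60, 180), n), ncol = 3, byrow = TRUE)
  bad <- chain_from_torsions(paste(rep("A", n), collapse = ""), tor)
  ra <- ramachandran_classify(bad)
  expect_true(all(ra$region[2:(n - 1)] == "disallowed"))
  gly <- chain_from_torsions(paste(rep("G", n), collapse = ""), tor)
  rg <- ramachandran_classify(gly)
  expect_true(all(rg$region[2:(n - 1)] == "generously allowed"))
  expect_true(all(is.na(ra$region[c(1, n)])))
})

test_that("qa_report fractions are consistent and favorable for ideal helices", {
  r <- qa_report(ideal_helix(30))
  expect_gte(r$ss_fractions[["H"]], 0.8)
  expect_gte(r$rama_fractions[["most favored"]], 0.9)
  expect_equal(sum(r$rama_fractions), 1, tolerance = 1e-9)
  expect_equal(sum(r$ss_fractions), 1, tolerance = 1e-9)

  tiny <- qa_report(ideal_helix(4))
  expect_equal(tiny$ss_fractions[["C"]], 1)
  expect_true(all(tiny$hbond_per_residue == 0))
})

test_that("QA assignment is invariant under rigid motion", {
  ch <- small_bundle(seed = 2)
  ss0 <- assign_secondary_structure(ch)
  ra0 <- ramachandran_classify(ch)$region
  set.seed(11)
  for (k in 1:3) {
    rot <- sprotannot:::random_rotation()
    tr <- rnorm(3, 0, 30)
    chr <- sprotannot:::transform_chain(ch, rot, tr)
    expect_equal(assign_secondary_structure(chr), ss0)
    expect_equal(ramachandran_classify(chr)$region, ra0)
  }
})

test_that("helix content decreases monotonically with torsion noise", {
  h <- ideal_helix(30)
  noise <- c(0, 4, 10, 20, 35)
  hfrac <- vapply(noise, function(nd) {
    mean(vapply(1:6, function(s) {
      mean(assign_secondary_structure(perturb_model(h, nd, seed = s)) == "H")
    }, 0))
  }, 0)
  expect_lt(cor(noise, hfrac, method = "spearman"), 0)
  expect_true(all(diff(hfrac) <= 0.05))
})

test_that("confidence tiers respect the 0.7 and 0.4 cutoffs exactly", {
  expect_equal(confidence_tier(0.70)$tier, "high")
  expect_equal(confidence_tier(0.699)$tier, "moderate")
  expect_equal(confidence_tier(0.40)$tier, "moderate")
  expect_equal(confidence_tier(0.399)$tier, "low")
  expect_equal(confidence_tier(NULL)$tier, "none")
  expect_error(confidence_tier(1.2), "0, 1")
})
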