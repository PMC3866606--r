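# Interaction inference: interfaces, binding residues, gates, potential,
# calibration and probabilities.

# two stacked extended chains with chosen sequences: a minimal "dimer" with
# abundant, composition-controlled cross-chain contacts
make_contact_dimer <- function(lig_seq, rec_seq, id = "fake") {
  n1 <- nchar(lig_seq); n2 <- nchar(rec_seq)
  tor <- function(n) matrix(rep(c(-120, 120, 180), n), ncol = 3, byrow = TRUE)
  lig <- chain_from_torsions(lig_seq, tor(n1), chain_id = "L")
  rec <- chain_from_torsions(rec_seq, tor(n2), chain_id = "R")
  rec <- sprotannot:::transform_chain(rec, diag(3), c(0, 0, 5.5))
  list(id = id, ligand_chain = lig, receptor_chain = rec)
}

test_that("template interfaces follow the CB contact rule", {
  d <- make_contact_dimer(strrep("A", 20), strrep("G", 21))
  iface <- template_interface(d)
  expect_gt(length(iface$ligand_interface), 0)
  # far-apart chains have empty interfaces
  far <- d
  far$receptor_chain <- sprotannot:::transform_chain(far$receptor_chain,
                                                     diag(3), c(0, 0, 100))
  f2 <- template_interface(far)
  expect_equal(length(f2$ligand_interface), 0L)
  # shrinking the cutoff never grows the interface
  i8 <- template_interface(d, 8)$ligand_interface
  i6 <- template_interface(d, 6)$ligand_interface
  i4 <- template_interface(d, 4)$ligand_interface
  expect_true(all(i6 %in% i8) && all(i4 %in% i6))
})

test_that("binding-residue scores are surface patches, invariant to motion", {
  ch <- small_bundle(seed = 4)
  b <- predict_binding_residues(ch)
  expect_gt(length(b$predicted_set), 0)
  expect_true(all(b$exposure[b$predicted_set] > 0.3))
  set.seed(2)
  rot <- sprotannot:::random_rotation()
  chr <- sprotannot:::transform_chain(ch, rot, c(5, -8, 11))
  br <- predict_binding_residues(chr)
  expect_equal(br$score, b$score, tolerance = 1e-9)
  expect_equal(br$predicted_set, b$predicted_set)
  expect_error(predict_binding_residues(ideal_helix(10)), "20")
})

test_that("mcc matches hand-computed tables and handles edge cases", {
  expect_equal(mcc(1:4, 3:6, 1:10), 4 / 24)
  expect_equal(mcc(1:3, 1:3, 1:8), 1)
  expect_equal(mcc(4:8, 1:3, 1:8), -1)
  expect_equal(mcc(integer(), 1:3, 1:8), 0)   # a zero factor
  expect_error(mcc(1, 1, integer()), "universe")
})

test_that("template usability applies the TM and MCC gates inclusively", {
  d <- make_dimer_template(seed = 5, id = "d5")
  model <- perturb_model(d$ligand_chain, 3, seed = 2)
  binding <- predict_binding_residues(model)
  al <- align_structures(model, d$ligand_chain)
  # inclusive TM gate: accepted at exactly its own TM, rejected just above
  u_at <- usable_templates(model, list(d), tm_min = al$tm_score,
                           mcc_min = -1, binding = binding)
  u_above <- usable_templates(model, list(d), tm_min = al$tm_score + 1e-9,
                              mcc_min = -1, binding = binding)
  expect_equal(length(u_at), 1L)
  expect_equal(length(u_above), 0L)
  # inclusive MCC gate at the realized MCC value
  m <- u_at[[1]]$mcc
  expect_equal(length(usable_templates(model, list(d), tm_min = 0.4,
                                       mcc_min = m, binding = binding)), 1L)
  expect_equal(length(usable_templates(model, list(d), tm_min = 0.4,
                                       mcc_min = m + 1e-9,
                                       binding = binding)), 0L)
  expect_equal(length(usable_templates(model, list())), 0L)
})

test_that("profile mapping recovers planted homologs and rejects background", {
  rec <- make_sprotein_sequences(1, c(110, 110), seed = 8)$sequence
  prof <- build_profile(rec)
  # the receptor's own sequence: certain mapping with identity threading
  own <- data.frame(id = "self", sequence = rec)
  cand <- map_receptors("r", prof, own, seed = 1)
  expect_equal(length(cand), 1L)
  expect_gt(cand[[1]]$map_probability, 0.9)
  expect_true(all(cand[[1]]$alignment[, 1] == cand[[1]]$alignment[, 2]))
  # planted homologs at 20% mutation are retained almost always
  homs <- do.call(rbind, lapply(1:10, function(s) {
    data.frame(id = sprintf("h%d", s),
               sequence = make_proteome(0, c(r = rec), 0.2, seed = s)$sequence)
  }))
  ch <- map_receptors("r", prof, homs, seed = 2)
  expect_gte(length(ch), 9)
  # random background is rejected in at least 95% of cases
  bg <- make_proteome(40, character(), seed = 3, length_range = c(80, 200))
  cb <- map_receptors("r", prof, bg, seed = 4)
  expect_lte(length(cb), 2)
  # out-of-window sequences are skipped
  short <- data.frame(id = "tiny", sequence = strrep("A", 20))
  expect_equal(length(map_receptors("r", prof, short, seed = 1)), 0L)
})

test_that("contact potential recovers planted pair preferences", {
  set.seed(31)
  rseq <- function(n) paste(sample(rownames(as.matrix(interface_propensity)),
                                   n, TRUE), collapse = "")
  # library with E-K rich interfaces: ligand glutamates face receptor lysines
  enriched <- lapply(1:35, function(i) {
    lig <- paste(sample(c("E", sample(sprotannot:::AA1, 30, TRUE)),
                        60, TRUE, prob = c(0.4, rep(0.6 / 30, 30))),
                 collapse = "")
    rec <- paste(sample(c("K", sample(sprotannot:::AA1, 30, TRUE)),
                        61, TRUE, prob = c(0.4, rep(0.6 / 30, 30))),
                 collapse = "")
    make_contact_dimer(lig, rec, id = sprintf("e%d", i))
  })
  pot <- train_pdp(enriched)
  offdiag <- pot$e[upper.tri(pot$e)]
  expect_lt(pot$e["E", "K"], stats::median(offdiag))
  expect_equal(pot$e, t(pot$e))

  # uniform contacts: all entries near zero. Glycine is excluded from the
  # fixture sequences: it contacts through CA (no CB), which in the stacked
  # geometry systematically inflates its contact counts — a property of the
  # contact rule, not of the estimator.
  nog <- setdiff(sprotannot:::AA1, "G")
  rseq2 <- function(n) paste(sample(nog, n, TRUE), collapse = "")
  uniform <- lapply(1:150, function(i) {
    make_contact_dimer(rseq2(120), rseq2(121), id = sprintf("u%d", i))
  })
  potu <- train_pdp(uniform)
  expect_lt(max(abs(potu$e[nog, nog])), 0.3)

  expect_error(train_pdp(enriched[1:10]), "30 dimers")
})

test_that("interaction energies are contact sums over threaded sequences", {
  d <- make_contact_dimer(strrep("A", 20), strrep("G", 21))
  iface <- template_interface(d)
  # zero potential gives zero energy under identity threading
  pot0 <- list(e = matrix(0, 20, 20, dimnames = list(sprotannot:::AA1,
                                                     sprotannot:::AA1)))
  n <- 20
  al <- list(pairs = cbind(1:n, 1:n),
             superposition = list(rotation = diag(3), translation = rep(0, 3)))
  e0 <- score_interaction(d$ligand_chain, al, NULL, NULL, d, pot0)
  expect_equal(e0, 0)
  # hand-set potential: E equals the hand-computed per-residue sum
  pot1 <- pot0
  pot1$e["A", "G"] <- pot1$e["G", "A"] <- -0.5
  cp <- iface$pairs
  expected <- (-0.5 * nrow(cp)) /
    (length(unique(cp[, 1])) + length(unique(cp[, 2])))
  e1 <- score_interaction(d$ligand_chain, al, NULL, NULL, d, pot1)
  expect_equal(e1, expected)
  # identity threading reproduces the reference energy of the template
  expect_equal(e1, reference_energies(list(d), pot1))
})

test_that("Gaussian calibration and probabilities behave analytically", {
  set.seed(9)
  e <- rnorm(1e4, -0.30, 0.15)
  cal <- calibrate(e)
  # mu within 3 standard errors; sigma within 5% (relative tolerances)
  expect_equal(cal$mu, -0.30, tolerance = 3 * (0.15 / sqrt(1e4)) / 0.30)
  expect_equal(cal$sigma, 0.15, tolerance = 0.05)
  expect_error(calibrate(rep(0.5, 40)), "degenerate")
  expect_error(calibrate(rnorm(10)), "30")
  cal2 <- calibrate(e + 1)
  expect_equal(cal2$mu, cal$mu + 1)
  expect_equal(cal2$sigma, cal$sigma)

  cal3 <- list(mu = -0.30, sigma = 0.15)
  expect_equal(interaction_probability(-0.30, cal3), 0.5)
  expect_equal(interaction_probability(-0.45, cal3), 1 - pnorm(-1),
               tolerance = 1e-12)
  expect_gt(interaction_probability(-10, cal3), 0.999999)
  # strictly decreasing in energy; the more favorable complex outranks
  es <- seq(-1, 1, by = 0.1)
  ps <- interaction_probability(es, cal3)
  expect_true(all(diff(ps) < 0))
  expect_gt(interaction_probability(-0.67, cal3),
            interaction_probability(-0.39, cal3))
})

test_that("calibration probabilities of Gaussian references are KS-uniform", {
  set.seed(17)
  e <- rnorm(3000, -0.2, 0.12)
  cal <- calibrate(e)
  u <- interaction_probability(e, cal)
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})
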