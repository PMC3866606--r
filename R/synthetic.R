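# Seeded generators emulating the external datasets the pipeline consumes:
# small-protein sequences and folds, quality-tiered perturbed models, dimer
# templates with labeled interfaces, labeled fold libraries, planted-homolog
# proteomes, fingerprint compound libraries and holo (ligand/metal) template
# sets. Every generator is a pure function of (parameters, seed).

random_sequence <- function(len, exclude = character()) {
  p <- AA_BACKGROUND
  p[exclude] <- 0
  paste(sample(AA1, len, replace = TRUE, prob = p), collapse = "")
}

mutate_sequence <- function(sequence, rate) {
  aa <- strsplit(sequence, "")[[1]]
  hit <- stats::runif(length(aa)) < rate
  if (any(hit)) {
    aa[hit] <- vapply(aa[hit], function(a) {
      sample(setdiff(AA1, a), 1)
    }, "")
  }
  paste(aa, collapse = "")
}

#' Alignment-based sequence identity
#'
#' Global alignment (match 1 / mismatch 0, affine gaps: open 2, extend 0.2)
#' of two amino-acid strings; identity is the number of identical aligned
#' pairs divided by the shorter length.
#'
#' @param a,b Amino-acid strings.
#' @return Identity fraction in [0, 1].
#' @export
seq_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  if (length(va) == length(vb)) return(mean(va == vb))
  s <- outer(va, vb, function(x, y) as.numeric(x == y))
  p <- nw_pairs(s, 2, 0.2, FALSE)$pairs
  if (nrow(p) == 0) return(0)
  sum(va[p[, 1]] == vb[p[, 2]]) / min(length(va), length(vb))
}

#' Generate random small-protein sequences
#'
#' @param n Number of records (> 0).
#' @param length_range Closed length range, within [10, 600]; lengths are
#'   uniform on the range. Default (50, 100), the small-protein window.
#' @param seed RNG seed; identical calls are bit-identical.
#' @return Data frame (id, sequence) of `n` records with composition drawn
#'   from the background amino-acid frequency table.
#' @export
make_sprotein_sequences <- function(n, length_range = c(50, 100), seed = 1) {
  if (n <= 0) stop("n must be positive")
  if (length_range[1] < 10 || length_range[2] > 600 ||
      length_range[1] > length_range[2]) {
    stop("length_range must lie within [10, 600]")
  }
  with_seed(seed, {
    pool <- seq(length_range[1], length_range[2])
    lens <- pool[sample.int(length(pool), n, replace = TRUE)]
    data.frame(id = sprintf("sprot%04d", seq_len(n)),
               sequence = vapply(lens, random_sequence, ""),
               stringsAsFactors = FALSE)
  })
}

#' Fold specification
#'
#' @param elements List of c(kind, length) pairs, kind in
#'   {helix, strand, loop}, element lengths >= 2 (>= 3 for helix/strand);
#'   total length >= 10.
#' @param packing Element placement rule: "bundle", "sheet" or "extended".
#'   Sheet packing closes short strand-to-strand loops with canonical turn
#'   torsions so the strands pair; the other rules randomize loops.
#' @return Object of class `fold_spec` with a `total_length`.
#' @export
fold_spec <- function(elements, packing = c("bundle", "sheet", "extended")) {
  packing <- match.arg(packing)
  kinds <- vapply(elements, function(e) e[[1]], "")
  lens <- vapply(elements, function(e) as.integer(e[[2]]), 1L)
  stopifnot(all(kinds %in% c("helix", "strand", "loop")), all(lens >= 2),
            sum(lens) >= 10)
  structure(list(elements = Map(list, kind = kinds, length = lens),
                 packing = packing, total_length = sum(lens)),
            class = "fold_spec")
}

#' Default fold topologies for the synthetic libraries
#'
#' Three distinct small-protein topologies: a mainly-alpha helix bundle
#' (CATH-style class 1), a mainly-beta meander sheet (class 2) and a mixed
#' alpha-beta fold (class 3), with dotted C.A.T labels.
#'
#' @return Named list of list(spec, label).
#' @export
default_topologies <- function() {
  list(
    bundle = list(
      spec = fold_spec(list(c("helix", 18), c("loop", 4), c("helix", 18),
                            c("loop", 4), c("helix", 14)), "bundle"),
      label = "1.10.1"),
    sheet = list(
      spec = fold_spec(list(c("strand", 10), c("loop", 2), c("strand", 10),
                            c("loop", 2), c("strand", 10), c("loop", 2),
                            c("strand", 10)), "sheet"),
      label = "2.40.2"),
    mixed = list(
      spec = fold_spec(list(c("helix", 14), c("loop", 3), c("strand", 8),
                            c("loop", 2), c("strand", 8), c("loop", 3),
                            c("helix", 12)), "bundle"),
      label = "3.30.3"))
}

.fold_torsions <- function(spec, jitter_sd = 2) {
  n <- spec$total_length
  tor <- matrix(c(-120, 120, 180), n, 3, byrow = TRUE)
  kinds <- vapply(spec$elements, function(e) e$kind, "")
  lens <- vapply(spec$elements, function(e) e$length, 1L)
  pos <- 1L
  for (k in seq_along(kinds)) {
    idx <- pos:(pos + lens[k] - 1L)
    if (kinds[k] == "helix") {
      tor[idx, 1:2] <- matrix(TORSION_HELIX, lens[k], 2, byrow = TRUE)
    } else if (kinds[k] == "strand") {
      tor[idx, 1:2] <- matrix(TORSION_STRAND, lens[k], 2, byrow = TRUE)
    } else {
      between_strands <- k > 1 && k < length(kinds) &&
        kinds[k - 1] == "strand" && kinds[k + 1] == "strand"
      if (spec$packing == "sheet" && between_strands && lens[k] <= 3) {
        turn <- TORSION_TURN[rep_len(1:2, lens[k]), , drop = FALSE]
        tor[idx, 1:2] <- turn + matrix(stats::rnorm(2 * lens[k], 0, jitter_sd),
                                       ncol = 2)
      } else if (spec$packing == "extended") {
        tor[idx, 1] <- stats::runif(lens[k], -150, -60)
        tor[idx, 2] <- stats::runif(lens[k], 100, 170)
      } else {
        tor[idx, 1] <- stats::runif(lens[k], -170, -50)
        tor[idx, 2] <- stats::runif(lens[k], -180, 180)
      }
    }
    pos <- pos + lens[k]
  }
  tor
}

.has_clash <- function(chain, min_dist = 3.5, min_sep = 2) {
  ca <- chain$xyz$CA
  n <- nrow(ca)
  d2 <- distsq_matrix(ca, ca)
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  any(d2[sep >= min_sep] < min_dist^2)
}

#' Build a folded chain from a fold specification
#'
#' Helices are built at (-57, -47), strands at (-120, 120), loops with
#' randomized torsions (sheet packing closes short inter-strand loops with
#' canonical turn torsions). Loop torsions are resampled until the chain is
#' free of steric clashes (no CA pair under 3.5 A between residues separated
#' by 2 or more positions), up to a bounded number of retries.
#'
#' @param spec A `fold_spec`.
#' @param sequence Amino-acid string of length `spec$total_length`.
#' @param seed RNG seed.
#' @param chain_id Chain identifier.
#' @param max_retries Retry bound before a generation error.
#' @return A `protein_chain`.
#' @export
make_fold <- function(spec, sequence, seed = 1, chain_id = "A",
                      max_retries = 100) {
  if (nchar(sequence) != spec$total_length) {
    stop("sequence length must equal the fold total length")
  }
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      tor <- .fold_torsions(spec)
      ch <- chain_from_torsions(sequence, tor, chain_id = chain_id)
      if (!.has_clash(ch)) return(ch)
    }
    stop("could not build a clash-free fold in ", max_retries, " retries")
  })
}

#' Perturb a model in torsion space
#'
#' Adds Gaussian noise (standard deviation `torsion_noise_deg`) to every phi
#' and psi and rebuilds the chain with ideal covalent geometry; this is the
#' package's model-quality surrogate. Zero noise reproduces the input
#' structure up to a rigid motion (TM-score 1).
#'
#' @param chain A `protein_chain` (no breaks).
#' @param torsion_noise_deg Noise standard deviation in degrees, >= 0.
#' @param seed RNG seed.
#' @return A `protein_chain` with the same sequence.
#' @export
perturb_model <- function(chain, torsion_noise_deg, seed = 1) {
  stopifnot(torsion_noise_deg >= 0)
  tor <- torsion_angles(chain)
  tor[is.na(tor[, 1]), 1] <- -120
  tor[is.na(tor[, 2]), 2] <- 120
  tor[is.na(tor[, 3]), 3] <- 180
  with_seed(seed, {
    n <- nrow(tor)
    tor[, 1:2] <- tor[, 1:2] + matrix(stats::rnorm(2 * n, 0, torsion_noise_deg),
                                      ncol = 2)
    chain_from_torsions(chain$aa, tor, chain_id = chain$chain_id)
  })
}

# Rewrite interface residues of a docked dimer with complementary "sticky"
# residue pairs (carriers of the docking-potential signal and of the high
# interface propensity used by binding-residue prediction).
.stickify_interface <- function(lig, rec, stickiness) {
  # two passes: mutating glycines moves their contact point from CA to CB,
  # which can recruit residues into the interface, so rewrite, recompute and
  # rewrite once more
  for (pass in 1:2) {
    iface <- template_interface(list(ligand_chain = lig, receptor_chain = rec))
    if (length(iface$ligand_interface) == 0) break
    cbl <- cb_coords(lig); cbr <- cb_coords(rec)
    for (i in iface$ligand_interface) {
      if (pass == 1 && stats::runif(1) > stickiness) next
      if (pass == 2 && lig$aa[i] %in% unique(unlist(STICKY_PAIRS))) next
      if (pass == 2 && stats::runif(1) > stickiness) next
      d2 <- colSums((t(cbr[iface$receptor_interface, , drop = FALSE]) - cbl[i, ])^2)
      j <- iface$receptor_interface[which.min(d2)]
      pair <- STICKY_PAIRS[[sample(length(STICKY_PAIRS), 1)]]
      lig$aa[i] <- pair[1]
      rec$aa[j] <- pair[2]
    }
  }
  list(lig = lig, rec = rec)
}

#' Generate a dimer template with a labeled interface
#'
#' Folds a ligand chain (the shorter monomer, the small-protein stand-in) and
#' a receptor chain (the longer monomer), then rigidly docks the ligand
#' against the receptor along a random approach direction so that at least
#' `min_contacts` residues per side are in cross-chain contact (CB-CB <= 8 A)
#' while no inter-chain CA pair comes closer than 3.8 A. Interface residues
#' are rewritten with complementary residue pairs at rate `stickiness` and the
#' final interface sets are recorded as ground truth.
#'
#' @param ligand_spec,receptor_spec `fold_spec` objects; ligand total length
#'   must be the smaller one and both must lie in [50, 600]. Defaults: the
#'   bundle topology for the ligand, a larger mixed fold for the receptor.
#' @param seed RNG seed.
#' @param stickiness Fraction of interface positions rewritten with
#'   complementary pairs (0 = background composition).
#' @param min_contacts Minimum interface residues per side.
#' @param id Template identifier.
#' @param max_retries Docking retry bound.
#' @return List of class `dimer_template`: id, ligand_chain, receptor_chain,
#'   ligand_interface, receptor_interface.
#' @export
make_dimer_template <- function(ligand_spec = NULL, receptor_spec = NULL,
                                seed = 1, stickiness = 0.8, min_contacts = 8,
                                id = "dimer1", max_retries = 60) {
  if (is.null(ligand_spec)) ligand_spec <- default_topologies()$bundle$spec
  if (is.null(receptor_spec)) {
    receptor_spec <- fold_spec(list(c("helix", 22), c("loop", 4),
                                    c("helix", 22), c("loop", 4),
                                    c("helix", 20), c("loop", 4),
                                    c("helix", 18)), "bundle")
  }
  if (ligand_spec$total_length >= receptor_spec$total_length) {
    stop("ligand must be shorter than the receptor")
  }
  if (ligand_spec$total_length < 50 || receptor_spec$total_length > 600) {
    stop("monomer lengths must lie in [50, 600]")
  }
  with_seed(seed, {
    # non-interface positions are depleted of the strongly interface-prone
    # residue types, so the rewritten binding patch stands out
    # compositionally (the planted signal the binding-residue score detects)
    depleted <- c("W", "F", "M", "Y", "I", "L")
    lig <- make_fold(ligand_spec,
                     random_sequence(ligand_spec$total_length, depleted),
                     seed = sample.int(1e6, 1), chain_id = "L")
    rec <- make_fold(receptor_spec,
                     random_sequence(receptor_spec$total_length, depleted),
                     seed = sample.int(1e6, 1), chain_id = "R")
    # center the receptor at the origin
    rec <- transform_chain(rec, diag(3), -colMeans(rec$xyz$CA))
    r_rec <- sqrt(max(rowSums(rec$xyz$CA^2)))

    for (try in seq_len(max_retries)) {
      u <- unitv(stats::rnorm(3))
      # present an exposed ligand face to the receptor: rotate the ligand so
      # that the outward direction of a protruding surface residue points
      # back along the approach axis (interfaces form on exposed patches)
      cen_l <- colMeans(lig$xyz$CA)
      dmax <- sqrt(rowSums(sweep(lig$xyz$CA, 2, cen_l)^2))
      anchor <- sample(order(-dmax)[1:8], 1)
      face <- unitv(lig$xyz$CA[anchor, ] - cen_l)
      rot <- rotation_about_axis(u, stats::runif(1, 0, 360)) %*%
        rotation_between(face, -u)
      ligc <- transform_chain(lig, rot, -as.numeric(rot %*% cen_l))
      r_lig <- sqrt(max(rowSums(ligc$xyz$CA^2)))
      t_out <- r_rec + r_lig + 5
      placed <- NULL
      t_cur <- t_out
      while (t_cur > 0) {
        cand <- transform_chain(ligc, diag(3), t_cur * u)
        mind <- sqrt(min(distsq_matrix(cand$xyz$CA, rec$xyz$CA)))
        if (mind < 3.8) break
        placed <- cand
        t_cur <- t_cur - 0.5
      }
      if (is.null(placed)) next
      dimer0 <- list(ligand_chain = placed, receptor_chain = rec)
      iface <- template_interface(dimer0)
      if (length(iface$ligand_interface) >= min_contacts &&
          length(iface$receptor_interface) >= min_contacts) {
        st <- .stickify_interface(placed, rec, stickiness)
        iface <- template_interface(list(ligand_chain = st$lig,
                                         receptor_chain = st$rec))
        return(structure(list(id = id, ligand_chain = st$lig,
                              receptor_chain = st$rec,
                              ligand_interface = iface$ligand_interface,
                              receptor_interface = iface$receptor_interface),
                         class = "dimer_template"))
      }
    }
    stop("could not dock a dimer with >= ", min_contacts,
         " interface residues per side in ", max_retries, " retries")
  })
}

#' Generate a labeled fold library
#'
#' Members of one topology are perturbed, re-threaded (point-mutated)
#' variants of a common parent fold, so within-topology structural similarity
#' exceeds cross-topology similarity and within-topology sequence identity
#' stays below 95%.
#'
#' @param n_per_topology Members per topology.
#' @param topologies Named list of list(spec, label) (>= 2 entries); default
#'   [default_topologies()].
#' @param seed RNG seed.
#' @param noise_deg Torsion noise for members, degrees.
#' @param mutation_rate Point-mutation rate for member sequences.
#' @param parents Optional named list of `protein_chain` parents (one per
#'   topology name); generated from the specs when absent. Supplying parents
#'   ties the library to existing fold realizations (loop conformations are
#'   random, so two independent builds of one spec are distinct folds).
#' @return List of class `fold_library` with `entries`: list of
#'   list(id, chain, label), plus `parents`.
#' @export
make_labeled_library <- function(n_per_topology, topologies = default_topologies(),
                                 seed = 1, noise_deg = 6, mutation_rate = 0.1,
                                 parents = NULL) {
  stopifnot(length(topologies) >= 2)
  with_seed(seed, {
    entries <- list()
    out_parents <- list()
    for (t in seq_along(topologies)) {
      top <- topologies[[t]]
      tname <- names(topologies)[t]
      if (!is.null(parents) && tname %in% names(parents)) {
        parent <- parents[[tname]]
        pseq <- chain_sequence(parent)
      } else {
        pseq <- random_sequence(top$spec$total_length)
        parent <- make_fold(top$spec, pseq, seed = sample.int(1e6, 1),
                            chain_id = paste0("T", t))
      }
      out_parents[[tname]] <- parent
      for (m in seq_len(n_per_topology)) {
        mseq <- mutate_sequence(pseq, mutation_rate)
        tor <- torsion_angles(parent)
        tor[is.na(tor)] <- matrix(c(-120, 120, 180), nrow(tor), 3,
                                  byrow = TRUE)[is.na(tor)]
        tor[, 1:2] <- tor[, 1:2] +
          matrix(stats::rnorm(2 * nrow(tor), 0, noise_deg), ncol = 2)
        idm <- sprintf("%s_m%02d", names(topologies)[t], m)
        entries[[idm]] <- list(id = idm,
                               chain = chain_from_torsions(mseq, tor, idm),
                               label = top$label)
      }
    }
    structure(list(entries = entries, parents = out_parents),
              class = "fold_library")
  })
}

#' Generate a stand-in proteome with planted receptor homologs
#'
#' Background sequences are random draws from the background composition;
#' each planted entry is derived from a dimer receptor sequence by point
#' mutation at `mutation_rate`. Planted identifiers are recorded as truth.
#'
#' @param n_background Number of background sequences.
#' @param receptors_to_plant Named character vector of receptor sequences.
#' @param mutation_rate Point-mutation rate in [0, 0.6].
#' @param seed RNG seed.
#' @param length_range Background sequence length range (study window
#'   50-600).
#' @return Data frame (id, sequence) with attribute `truth`: data frame
#'   (id, parent).
#' @export
make_proteome <- function(n_background, receptors_to_plant = character(),
                          mutation_rate = 0.2, seed = 1,
                          length_range = c(50, 600)) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 0.6)
  with_seed(seed, {
    pool <- seq(length_range[1], length_range[2])
    lens <- pool[sample.int(length(pool), n_background, replace = TRUE)]
    bg <- data.frame(id = sprintf("bg%05d", seq_len(n_background)),
                     sequence = vapply(lens, random_sequence, ""),
                     stringsAsFactors = FALSE)
    pl <- data.frame(id = character(), sequence = character(),
                     stringsAsFactors = FALSE)
    if (length(receptors_to_plant) > 0) {
      pl <- data.frame(
        id = paste0("hom_", names(receptors_to_plant)),
        sequence = vapply(receptors_to_plant, mutate_sequence, "",
                          rate = mutation_rate),
        stringsAsFactors = FALSE)
    }
    out <- rbind(pl, bg)
    rownames(out) <- NULL
    attr(out, "truth") <- data.frame(id = pl$id,
                                     parent = names(receptors_to_plant),
                                     stringsAsFactors = FALSE)
    out
  })
}

#' Generate a bit-fingerprint compound library with planted actives
#'
#' Background fingerprints have independent random bits at a fixed density;
#' actives are derived from a probe fingerprint by flipping bits so the
#' expected Tanimoto to the probe equals `similarity_to_probe`.
#'
#' @param n Library size.
#' @param n_bits Fingerprint length (>= 64).
#' @param n_actives Number of planted actives (< n).
#' @param similarity_to_probe Target expected Tanimoto of actives vs probe.
#' @param seed RNG seed.
#' @param density Bit density of background fingerprints and the probe.
#' @param probe Optional 0/1 probe fingerprint of length `n_bits` (e.g. the
#'   probe of a holo template set); generated when NULL.
#' @return List of class `compound_library`: `fingerprints` (n x n_bits 0/1
#'   matrix with compound ids as rownames), `probe` (0/1 vector), `active_ids`.
#' @export
make_compound_library <- function(n, n_bits = 256, n_actives = 0,
                                  similarity_to_probe = 0.9, seed = 1,
                                  density = 0.2, probe = NULL) {
  stopifnot(n_bits >= 64, n_actives < n)
  if (!is.null(probe)) stopifnot(length(probe) == n_bits)
  with_seed(seed, {
    if (is.null(probe)) probe <- as.integer(stats::runif(n_bits) < density)
    k <- sum(probe)
    tt <- similarity_to_probe
    flip <- if (tt >= 1) 0 else k * (1 - tt) / (k + tt * (n_bits - k))
    fp <- matrix(0L, n, n_bits)
    ids <- sprintf("cmpd%05d", seq_len(n))
    act <- integer(0)
    if (n_actives > 0) {
      act <- seq_len(n_actives)
      for (i in act) {
        f <- probe
        hit <- stats::runif(n_bits) < flip
        f[hit] <- 1L - f[hit]
        fp[i, ] <- f
      }
      ids[act] <- sprintf("active%03d", act)
    }
    for (i in setdiff(seq_len(n), act)) {
      fp[i, ] <- as.integer(stats::runif(n_bits) < density)
    }
    rownames(fp) <- ids
    structure(list(fingerprints = fp, probe = probe,
                   active_ids = ids[act]),
              class = "compound_library")
  })
}

# outward-pointing surface site on a chain: CA of an exposed residue pushed
# away from the centroid
.pick_surface_site <- function(chain, offset = 3.0) {
  ca <- chain$xyz$CA
  cen <- colMeans(ca)
  d <- sqrt(rowSums(sweep(ca, 2, cen)^2))
  anchor <- which.max(d * 0.5 + stats::runif(nrow(ca)) * mean(d))
  dir <- unitv(ca[anchor, ] - cen)
  list(site = ca[anchor, ] + offset * dir, anchor = anchor)
}

#' Generate holo templates with a planted binding site
#'
#' Each template is a mildly perturbed copy of the query fold, carrying a
#' ligand centroid (with a bit-fingerprint) or a metal atom placed at a
#' common pocket: after superposition onto the query, all template site
#' centers fall within the site-clustering cutoff of the planted true site.
#' For metal templates, residues coordinating the metal are mutated to
#' chemically apt types (e.g. Zn -> Cys/His, Ca/Mg -> Asp/Glu/Asn).
#'
#' @param query_fold A `protein_chain` (the modeling target's true fold).
#' @param n_templates Number of templates (>= 1).
#' @param site_kind "ligand" or "metal".
#' @param metal_type Metal element for metal templates (one of
#'   Ca, Zn, Mg, Ni, Fe, Cu, Mn, Co; case-insensitive).
#' @param seed RNG seed.
#' @param noise_deg Torsion perturbation of template copies.
#' @param n_bits Fingerprint length for ligand templates.
#' @return List of class `holo_template_set`: `templates` (each: id, chain,
#'   site, kind, metal_type, fingerprint), `true_site` (query frame),
#'   `probe` fingerprint, `query_shell` (query residues coordinating the
#'   site) and `apt_query` (the query fold with a chemically apt shell for
#'   metal sites — the modeling target is itself a binder).
#' @export
make_holo_templates <- function(query_fold, n_templates, site_kind = "ligand",
                                metal_type = "ZN", seed = 1, noise_deg = 3,
                                n_bits = 256) {
  stopifnot(n_templates >= 1, site_kind %in% c("ligand", "metal"))
  metal_type <- toupper(metal_type)
  if (site_kind == "metal" && !(metal_type %in% METAL_TYPES)) {
    stop("unknown metal type: ", metal_type)
  }
  with_seed(seed, {
    sp <- .pick_surface_site(query_fold)
    true_site <- sp$site
    probe <- as.integer(stats::runif(n_bits) < 0.2)
    # the modeling target is itself a binder: for metal sites, give the query
    # fold a chemically apt coordination shell (recorded as truth)
    dq <- sqrt(rowSums(sweep(query_fold$xyz$CA, 2, true_site)^2))
    query_shell <- sort(union(which(dq <= 6.0), order(dq)[1:4]))
    apt_query <- query_fold
    if (site_kind == "metal") {
      apt_query$aa[query_shell] <- sample(METAL_SHELL_ALPHABET[[metal_type]],
                                          length(query_shell), replace = TRUE)
    }
    templates <- list()
    for (t in seq_len(n_templates)) {
      tc <- perturb_model(query_fold, noise_deg, seed = sample.int(1e6, 1))
      tc$chain_id <- sprintf("holo%02d", t)
      # carry the site into the rebuilt template frame via the identity pairing
      fit <- kabsch(tc$xyz$CA, query_fold$xyz$CA)
      site_t <- as.numeric(fit$rotation %*% true_site + fit$translation) +
        stats::rnorm(3, 0, 0.5)
      if (site_kind == "metal") {
        dsite <- sqrt(rowSums(sweep(tc$xyz$CA, 2, site_t)^2))
        # coordination shell: everything within 6 A CA, and always the four
        # nearest residues so the planted shell is never sparse
        near <- union(which(dsite <= 6.0), order(dsite)[1:4])
        shell <- METAL_SHELL_ALPHABET[[metal_type]]
        tc$aa[near] <- sample(shell, length(near), replace = TRUE)
      }
      fp <- probe
      nflip <- max(1L, round(0.02 * n_bits))
      ix <- sample(n_bits, nflip)
      fp[ix] <- 1L - fp[ix]
      # random re-orientation so that site transfer is a real alignment task
      rot <- random_rotation(); tr <- stats::rnorm(3, 0, 20)
      tc <- transform_chain(tc, rot, tr)
      site_t <- as.numeric(rot %*% site_t + tr)
      templates[[t]] <- list(
        id = tc$chain_id, chain = tc, site = site_t, kind = site_kind,
        metal_type = if (site_kind == "metal") metal_type else NA_character_,
        fingerprint = if (site_kind == "ligand") fp else NULL)
    }
    structure(list(templates = templates, true_site = true_site,
                   probe = probe, query_shell = query_shell,
                   apt_query = apt_query),
              class = "holo_template_set")
  })
}
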