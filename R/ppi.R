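# Template-based protein-protein interaction inference: interface definition,
# empirical binding-residue prediction, the MCC template-usability gate,
# profile-based receptor mapping, a quasi-chemical contact potential with
# Gaussian calibration, and proteome-scale interaction calls.

#' Interface residues of a dimer template
#'
#' Residue pairs across the two chains with CB-CB distance (CA for glycine or
#' missing CB) at or below the contact cutoff define both interface sets.
#'
#' @param dimer A `dimer_template` (or any list with `ligand_chain` and
#'   `receptor_chain`).
#' @param contact_cutoff Contact distance in Angstroms (default 8).
#' @return List: `ligand_interface`, `receptor_interface` (sorted index
#'   vectors) and `pairs` (k x 2 matrix of contacting residue pairs).
#' @export
template_interface <- function(dimer, contact_cutoff = 8.0) {
  cbl <- cb_coords(dimer$ligand_chain)
  cbr <- cb_coords(dimer$receptor_chain)
  cp <- contact_pairs(cbl, cbr, contact_cutoff)
  list(ligand_interface = sort(unique(cp[, 1])),
       receptor_interface = sort(unique(cp[, 2])),
       pairs = cp)
}

#' Empirical binding-residue prediction
#'
#' Surface-patch score per residue:
#' u_i = w1 * propensity(aa_i) + w2 * exposure_i, plus w3 times the mean of
#' u over spatial neighbours (CB within 10 A). Exposure comes from the CB
#' neighbour count within 10 A, mapped linearly so the least-buried residue
#' scores 1. The predicted set is the top 25% of surface residues (exposure
#' above 0.3) by score; a pathological all-buried chain falls back to the top
#' 25% by score overall.
#'
#' @param chain A `protein_chain` with >= 20 residues.
#' @param config Pipeline configuration (weights, exposure and top-fraction
#'   cutoffs).
#' @return List of class `binding_prediction`: `score` (per residue),
#'   `exposure`, `predicted_set` (residue indices).
#' @export
predict_binding_residues <- function(chain, config = default_config()) {
  n <- length(chain$aa)
  if (n < 20) stop("chain must have at least 20 residues")
  w <- config$pinup_weights
  cb <- cb_coords(chain)
  d2 <- distsq_matrix(cb, cb)
  nb <- d2 <= 100 & upper.tri(d2, diag = FALSE) | d2 <= 100 & lower.tri(d2)
  cnt <- rowSums(nb)
  # linear in the neighbour count, anchored so the least-buried residue
  # scores 1; fixed slope (24 excess neighbours = fully buried) keeps the
  # scale comparable across chains
  exposure <- pmax(0, 1 - (cnt - min(cnt)) / 24)
  prop <- interface_propensity[chain$aa]
  prop[is.na(prop)] <- mean(interface_propensity)
  u <- w[1] * prop + w[2] * exposure
  nbavg <- vapply(seq_len(n), function(i) {
    j <- which(nb[i, ])
    if (length(j) == 0) 0 else mean(u[j])
  }, 0)
  score <- u + w[3] * nbavg
  surface <- which(exposure > config$pinup_exposure_min)
  if (length(surface) == 0) {
    k <- max(1L, ceiling(config$pinup_top_frac * n))
    predicted <- order(-score)[seq_len(k)]
  } else {
    k <- max(1L, ceiling(config$pinup_top_frac * length(surface)))
    predicted <- surface[order(-score[surface])][seq_len(k)]
  }
  structure(list(score = unname(score), exposure = exposure,
                 predicted_set = sort(predicted)),
            class = "binding_prediction")
}

#' Matthews correlation coefficient over residue sets
#'
#' MCC of the 2x2 table induced by a predicted and a reference residue set
#' within a universe; defined as 0 when any marginal factor is 0.
#'
#' @param predicted,reference Residue index sets (subsets of `universe`).
#' @param universe Residue index set.
#' @return MCC in [-1, 1].
#' @export
mcc <- function(predicted, reference, universe) {
  if (length(universe) == 0) stop("universe must be non-empty")
  stopifnot(all(predicted %in% universe), all(reference %in% universe))
  tp <- length(intersect(predicted, reference))
  fp <- length(setdiff(predicted, reference))
  fn <- length(setdiff(reference, predicted))
  tn <- length(universe) - tp - fp - fn
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  ((tp * tn) - (fp * fn)) / sqrt(den)
}

#' Select usable dimer templates for a small-protein model
#'
#' A dimer template is usable when (i) its ligand chain aligns to the model
#' at TM-score >= `tm_min` and (ii) the template's ligand interface, mapped
#' through the alignment onto model residues, overlaps the model's predicted
#' binding residues with MCC >= `mcc_min` (universe: all model residues).
#'
#' @param sprotein_model A `protein_chain`.
#' @param dimer_library List of `dimer_template`s.
#' @param tm_min TM-score gate (default 0.4).
#' @param mcc_min MCC gate (default 0.5).
#' @param binding Optional precomputed [predict_binding_residues] result.
#' @param config Pipeline configuration.
#' @return List of records: template, alignment, mcc, mapped_interface.
#' @export
usable_templates <- function(sprotein_model, dimer_library, tm_min = 0.4,
                             mcc_min = 0.5, binding = NULL,
                             config = default_config()) {
  if (length(dimer_library) == 0) return(list())
  if (is.null(binding)) {
    binding <- predict_binding_residues(sprotein_model, config)
  }
  universe <- seq_along(sprotein_model$aa)
  out <- list()
  for (dimer in dimer_library) {
    al <- align_structures(sprotein_model, dimer$ligand_chain, config = config)
    if (al$tm_score < tm_min || al$n_aligned == 0) next
    mapped <- al$pairs[al$pairs[, 2] %in% dimer$ligand_interface, 1]
    m <- mcc(binding$predicted_set, mapped, universe)
    if (m >= mcc_min) {
      out[[length(out) + 1]] <- list(template = dimer, alignment = al,
                                     mcc = m, mapped_interface = sort(mapped))
    }
  }
  out
}

#' Build a position frequency profile from homologous sequences
#'
#' Column frequencies over an equal-length (alignment-free) homolog set, with
#' background-frequency pseudocounts; stores per-column log-odds scores.
#'
#' @param sequences Character vector of equal-length amino-acid strings.
#' @return List of class `sequence_profile`: `freq` (L x 20), `logodds`
#'   (L x 20), `length`.
#' @export
build_profile <- function(sequences) {
  stopifnot(length(sequences) >= 1)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) {
    stop("profile sequences must have equal length")
  }
  L <- lens[1]
  mat <- do.call(rbind, strsplit(sequences, ""))
  freq <- matrix(0, L, 20, dimnames = list(NULL, AA1))
  for (j in seq_len(L)) {
    tab <- table(factor(mat[, j], levels = AA1))
    freq[j, ] <- (as.numeric(tab) + 2 * AA_BACKGROUND) /
      (nrow(mat) + 2)
  }
  logodds <- log(sweep(freq, 2, AA_BACKGROUND, `/`))
  structure(list(freq = freq, logodds = logodds, length = L),
            class = "sequence_profile")
}

.profile_align <- function(profile, aa_idx, gap_open = 3, gap_extend = 0.3) {
  s <- t(profile$logodds[, aa_idx, drop = FALSE])  # seq positions x profile
  nw_pairs(s, gap_open, gap_extend, TRUE)
}

#' Map a receptor profile onto a proteome
#'
#' Each proteome sequence is globally aligned (free end gaps, affine penalty)
#' against the receptor's position profile; the score is standardized against
#' a seeded shuffled-sequence null (z-score over `n_shuffles` shuffles) and
#' converted to a mapping probability with a fixed logistic. Candidates with
#' probability > 0.5 are retained, each carrying the alignment that threads
#' the proteome sequence onto receptor residue positions. Sequences outside
#' 50-600 residues are skipped.
#'
#' @param receptor_id Identifier of the template receptor.
#' @param profile A `sequence_profile` built for the receptor.
#' @param proteome Data frame (id, sequence).
#' @param seed RNG seed for the shuffle null.
#' @param config Pipeline configuration.
#' @return List of retained candidates: id, receptor_id, map_probability, z,
#'   alignment (k x 2: sequence position, receptor position).
#' @export
map_receptors <- function(receptor_id, profile, proteome, seed = 1,
                          config = default_config()) {
  out <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(proteome))) {
      sq <- proteome$sequence[i]
      L <- nchar(sq)
      if (L < 50 || L > 600) next
      aa_idx <- match(strsplit(sq, "")[[1]], AA1)
      aa_idx[is.na(aa_idx)] <- match("A", AA1)
      res <- .profile_align(profile, aa_idx)
      s <- t(profile$logodds[, aa_idx, drop = FALSE])
      null_scores <- nw_shuffled_scores(s, config$n_shuffles, 3, 0.3, TRUE)
      sdn <- stats::sd(null_scores)
      z <- if (sdn < 1e-9) 0 else (res$score - mean(null_scores)) / sdn
      p <- stats::plogis((z - config$map_z0) / config$map_zs)
      if (p > config$map_min) {
        out[[length(out) + 1]] <- list(
          id = proteome$id[i], receptor_id = receptor_id,
          map_probability = p, z = z,
          alignment = res$pairs[, c(1, 2), drop = FALSE])
      }
    }
  })
  out
}

#' Train a quasi-chemical residue contact potential
#'
#' Over all cross-interface contact pairs (CB-CB <= cutoff) of the dimer
#' library, with each contact counted in both orders:
#' e(a, b) = -ln[(n(a, b) + p) / (N f(a) f(b) g)], pseudocount p = 1,
#' f the amino-acid frequencies over all interface residues and g the
#' normalizer matching total expectation to total (pseudocounted) counts.
#' The table is symmetric by construction.
#'
#' @param dimer_library List of `dimer_template`s (>= 30).
#' @param contact_cutoff Contact distance, Angstroms.
#' @param pseudocount Smoothing count p.
#' @return List of class `potential_table`: `e` (20 x 20 symmetric matrix),
#'   `f` (background frequencies), `n_contacts`.
#' @export
train_pdp <- function(dimer_library, contact_cutoff = 8.0, pseudocount = 1) {
  if (length(dimer_library) < 30) stop("at least 30 dimers are required")
  counts <- matrix(0, 20, 20, dimnames = list(AA1, AA1))
  fcount <- stats::setNames(rep(0, 20), AA1)
  total_pairs <- 0
  for (dimer in dimer_library) {
    iface <- template_interface(dimer, contact_cutoff)
    cp <- iface$pairs
    total_pairs <- total_pairs + nrow(cp)
    la <- dimer$ligand_chain$aa[cp[, 1]]
    rb <- dimer$receptor_chain$aa[cp[, 2]]
    keep <- la %in% AA1 & rb %in% AA1
    for (k in which(keep)) {
      counts[la[k], rb[k]] <- counts[la[k], rb[k]] + 1
      counts[rb[k], la[k]] <- counts[rb[k], la[k]] + 1
    }
    ia <- dimer$ligand_chain$aa[iface$ligand_interface]
    ib <- dimer$receptor_chain$aa[iface$receptor_interface]
    tab <- table(factor(c(ia, ib), levels = AA1))
    fcount <- fcount + as.numeric(tab)
  }
  if (total_pairs < 200) {
    stop("fewer than 200 interface contacts in the library; cannot calibrate")
  }
  f <- (fcount + 1) / sum(fcount + 1)
  N <- sum(counts)
  g <- (N + pseudocount * 400) / N
  expected <- N * outer(f, f) * g
  e <- -log((counts + pseudocount) / expected)
  structure(list(e = e, f = f, n_contacts = total_pairs),
            class = "potential_table")
}

#' Interaction energy of a modeled complex
#'
#' The modeled complex lives in the template's geometry: the small protein is
#' aligned onto the template's ligand chain and the receptor candidate's
#' sequence is threaded onto the template receptor structure. The energy sums
#' potential entries over the template complex's cross-chain residue contacts
#' (CB-CB <= cutoff in the template), with amino acids read through the two
#' alignments (model residue at each ligand position, threaded proteome
#' residue at each receptor position; unaligned positions are skipped), and
#' is divided by the number of distinct interface residues involved. Lower is
#' more favorable.
#'
#' @param sprotein_model A `protein_chain`.
#' @param alignment The `alignment_result` of the model onto the template's
#'   ligand chain (supplies the model-to-ligand residue mapping).
#' @param receptor_threading k x 2 matrix threading proteome-sequence
#'   positions (col 1) onto receptor residue positions (col 2); NULL for the
#'   template's own sequence (identity threading).
#' @param receptor_sequence The threaded proteome sequence (string).
#' @param template A `dimer_template`.
#' @param potential A `potential_table`.
#' @param contact_cutoff Contact distance, Angstroms.
#' @return Per-residue energy (numeric), or NA when no template contact is
#'   covered by both alignments.
#' @export
score_interaction <- function(sprotein_model, alignment, receptor_threading,
                              receptor_sequence, template, potential,
                              contact_cutoff = 8.0) {
  cp <- template_interface(template, contact_cutoff)$pairs
  if (nrow(cp) == 0) return(NA_real_)

  lig_to_model <- rep(NA_integer_, length(template$ligand_chain$aa))
  lig_to_model[alignment$pairs[, 2]] <- alignment$pairs[, 1]
  rec_aa <- rep(NA_character_, length(template$receptor_chain$aa))
  if (is.null(receptor_threading)) {
    rec_aa <- template$receptor_chain$aa
  } else {
    seq_aa <- strsplit(receptor_sequence, "")[[1]]
    rec_aa[receptor_threading[, 2]] <- seq_aa[receptor_threading[, 1]]
  }
  mi <- lig_to_model[cp[, 1]]
  a <- ifelse(is.na(mi), NA_character_, sprotein_model$aa[mi])
  b <- rec_aa[cp[, 2]]
  keep <- !is.na(a) & !is.na(b) & a %in% AA1 & b %in% AA1
  if (!any(keep)) return(NA_real_)
  total <- sum(potential$e[cbind(a[keep], b[keep])])
  n_iface <- length(unique(cp[keep, 1])) + length(unique(cp[keep, 2]))
  total / n_iface
}

#' Per-residue energies of the template library's own complexes
#'
#' Scores each dimer template against itself (identity threading, native
#' placement); these reference energies feed the Gaussian calibration.
#'
#' @param dimer_library List of `dimer_template`s.
#' @param potential A `potential_table`.
#' @param contact_cutoff Contact distance, Angstroms.
#' @return Numeric vector of per-residue energies.
#' @export
reference_energies <- function(dimer_library, potential,
                               contact_cutoff = 8.0) {
  vapply(dimer_library, function(dimer) {
    iface <- template_interface(dimer, contact_cutoff)
    cp <- iface$pairs
    a <- dimer$ligand_chain$aa[cp[, 1]]
    b <- dimer$receptor_chain$aa[cp[, 2]]
    keep <- a %in% AA1 & b %in% AA1
    if (!any(keep)) return(NA_real_)
    total <- sum(potential$e[cbind(a[keep], b[keep])])
    n_iface <- length(unique(cp[keep, 1])) + length(unique(cp[keep, 2]))
    total / n_iface
  }, 0)
}

#' Gaussian calibration of reference energies
#'
#' Maximum-likelihood Gaussian fit (mean and standard deviation) to the
#' per-residue energies of known complexes.
#'
#' @param energies Numeric vector of reference energies (>= 30 finite).
#' @return List of class `calibration_model`: mu, sigma, n_ref.
#' @export
calibrate <- function(energies) {
  e <- energies[is.finite(energies)]
  if (length(e) < 30) stop("at least 30 finite reference energies required")
  mu <- mean(e)
  sigma <- stats::sd(e) * sqrt((length(e) - 1) / length(e))
  if (sigma < 1e-6) stop("degenerate reference energy distribution")
  structure(list(mu = mu, sigma = sigma, n_ref = length(e)),
            class = "calibration_model")
}

#' Interaction probability of an energy under a calibration
#'
#' p = 1 - Phi((E - mu) / sigma): the fraction of reference complexes with a
#' less favorable per-residue score. Strictly decreasing in energy.
#'
#' @param energy Per-residue energy (vectorized).
#' @param calibration A `calibration_model`.
#' @return Probability in [0, 1].
#' @export
interaction_probability <- function(energy, calibration) {
  1 - stats::pnorm((energy - calibration$mu) / calibration$sigma)
}

#' Proteome-scale interaction map
#'
#' Trains the contact potential and its Gaussian calibration on the dimer
#' library, maps every template receptor onto the proteome, selects usable
#' templates per model, and assigns every (model, proteome sequence) pair the
#' best probability over usable template x receptor candidate combinations.
#' Pairs at probability >= 0.5 are called.
#'
#' @param sproteins Named list of `protein_chain` models.
#' @param proteome Data frame (id, sequence).
#' @param dimer_library List of `dimer_template`s (>= 30).
#' @param seed RNG seed (shuffle nulls).
#' @param config Pipeline configuration.
#' @return List of class `interaction_map`: `probability` (models x proteome
#'   matrix), `calls` (data frame sprotein, receptor, template, energy,
#'   probability, called), `sprotein_counts`, `receptor_counts`,
#'   `calibration`, `potential`.
#' @export
build_interaction_map <- function(sproteins, proteome, dimer_library,
                                  seed = 1, config = default_config()) {
  potential <- train_pdp(dimer_library, config$contact_cutoff)
  calib <- calibrate(reference_energies(dimer_library, potential,
                                        config$contact_cutoff))
  # receptor candidates per template
  cand_by_template <- list()
  for (dimer in dimer_library) {
    profile <- build_profile(chain_sequence(dimer$receptor_chain))
    cands <- map_receptors(dimer$id, profile, proteome,
                           seed = seed + length(cand_by_template),
                           config = config)
    cand_by_template[[dimer$id]] <- cands
  }
  ids_s <- names(sproteins)
  if (is.null(ids_s)) ids_s <- vapply(sproteins, function(s) s$chain_id, "")
  prob <- matrix(0, length(sproteins), nrow(proteome),
                 dimnames = list(ids_s, proteome$id))
  rows <- list()
  for (s in seq_along(sproteins)) {
    model <- sproteins[[s]]
    usable <- usable_templates(model, dimer_library, config$tm_min,
                               config$mcc_min, config = config)
    if (length(usable) == 0) next
    for (u in usable) {
      tid <- u$template$id
      for (cand in cand_by_template[[tid]]) {
        e <- score_interaction(model, u$alignment, cand$alignment,
                               proteome$sequence[match(cand$id, proteome$id)],
                               u$template, potential, config$contact_cutoff)
        if (!is.finite(e)) next
        p <- interaction_probability(e, calib)
        if (p > prob[ids_s[s], cand$id]) {
          prob[ids_s[s], cand$id] <- p
          rows[[paste(ids_s[s], cand$id)]] <- data.frame(
            sprotein = ids_s[s], receptor = cand$id, template = tid,
            energy = e, probability = p, called = p >= config$call_min,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  calls <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(sprotein = character(), receptor = character(),
               template = character(), energy = numeric(),
               probability = numeric(), called = logical(),
               stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  called <- calls[calls$called, , drop = FALSE]
  s_counts <- sort(table(factor(called$sprotein, levels = ids_s)),
                   decreasing = TRUE)
  r_counts <- sort(table(called$receptor), decreasing = TRUE)
  structure(list(probability = prob, calls = calls,
                 sprotein_counts = s_counts, receptor_counts = r_counts,
                 calibration = calib, potential = potential),
            class = "interaction_map")
}
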