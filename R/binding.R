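# Template-transfer binding annotation: ligand-site transfer and clustering,
# fingerprint virtual screening with Z-score confidence, compound-library
# deduplication, and metal-site prediction with three confidence channels.

#' Transfer template binding-site centers into the query frame
#'
#' Aligns every holo template to the query; templates below the TM-score gate
#' are discarded and the remaining site positions are mapped through each
#' alignment's rigid transform into the query frame.
#'
#' @param query A `protein_chain`.
#' @param holo_templates A `holo_template_set` or list of holo templates
#'   (each: id, chain, site, kind, metal_type, fingerprint).
#' @param tm_min TM-score gate (default 0.4).
#' @param config Pipeline configuration.
#' @return Data frame: template, tm, x, y, z, metal_type; attribute
#'   `fingerprints` (named list) for ligand templates.
#' @export
transfer_site_centers <- function(query, holo_templates, tm_min = 0.4,
                                  config = default_config()) {
  templates <- if (inherits(holo_templates, "holo_template_set"))
    holo_templates$templates else holo_templates
  rows <- list()
  fps <- list()
  for (tpl in templates) {
    al <- align_structures(query, tpl$chain, config = config)
    if (al$tm_score < tm_min || is.null(al$superposition)) next
    # the superposition maps template coordinates into the query frame
    center <- as.numeric(al$superposition$rotation %*% tpl$site +
                           al$superposition$translation)
    rows[[length(rows) + 1]] <- data.frame(
      template = tpl$id, tm = al$tm_score,
      x = center[1], y = center[2], z = center[3],
      metal_type = if (is.null(tpl$metal_type)) NA_character_ else tpl$metal_type,
      stringsAsFactors = FALSE)
    if (!is.null(tpl$fingerprint)) fps[[tpl$id]] <- tpl$fingerprint
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(template = character(), tm = numeric(), x = numeric(),
               y = numeric(), z = numeric(), metal_type = character(),
               stringsAsFactors = FALSE)
  attr(out, "fingerprints") <- fps
  out
}

#' Cluster transferred site centers into pocket predictions
#'
#' Average-linkage agglomerative clustering of the transferred centers, cut
#' at `cutoff`; each cluster becomes a pocket with TM-weighted mean center.
#' Pockets are ranked by the sum of member TM-scores. Site confidence is a
#' fixed logistic in the supporting fraction and the mean member TM-score;
#' binding residues are query residues with CA within 6 A of the center.
#'
#' @param centers Data frame from [transfer_site_centers].
#' @param query A `protein_chain`.
#' @param cutoff Clustering cutoff, Angstroms (default 8).
#' @param config Pipeline configuration.
#' @return List of pocket predictions, ranked: center, supporting_templates
#'   (data frame template/tm), binding_residues, site_confidence, rank_sum,
#'   fingerprints (supporting subset).
#' @export
cluster_sites <- function(centers, query, cutoff = 8.0,
                          config = default_config()) {
  if (nrow(centers) == 0) return(list())
  xyz <- as.matrix(centers[, c("x", "y", "z")])
  cl <- if (nrow(centers) == 1) 1L else {
    hc <- stats::hclust(stats::dist(xyz), method = "average")
    stats::cutree(hc, h = cutoff)
  }
  fps <- attr(centers, "fingerprints")
  n_total <- nrow(centers)
  pockets <- lapply(unique(cl), function(k) {
    m <- which(cl == k)
    w <- centers$tm[m] / sum(centers$tm[m])
    center <- as.numeric(t(xyz[m, , drop = FALSE]) %*% w)
    support_frac <- length(m) / n_total
    mean_tm <- mean(centers$tm[m])
    conf <- stats::plogis(config$site_conf_a * support_frac +
                            config$site_conf_b * mean_tm + config$site_conf_c)
    dres <- sqrt(rowSums(sweep(query$xyz$CA, 2, center)^2))
    list(center = center,
         supporting_templates = centers[m, c("template", "tm"), drop = FALSE],
         binding_residues = which(dres <= config$pocket_residue_ca),
         site_confidence = conf,
         rank_sum = sum(centers$tm[m]),
         member_rows = m,
         fingerprints = if (length(fps) > 0)
           fps[intersect(names(fps), centers$template[m])] else list())
  })
  pockets[order(-vapply(pockets, function(p) p$rank_sum, 0))]
}

# Tanimoto similarity of two vectors (binary or continuous, via min/max)
tanimoto <- function(a, b) {
  den <- sum(pmax(a, b))
  if (den == 0) return(0)
  sum(pmin(a, b)) / den
}

#' Virtual screening of a compound library against a pocket
#'
#' Builds the pocket's consensus fingerprint (per-bit mean over supporting
#' template fingerprints) and ranks all library compounds by Tanimoto-style
#' similarity sum(min)/sum(max) to the consensus, ties broken by compound id.
#' The screen is confident when the Z-score of the top compound (against the
#' library score distribution) is >= 2.
#'
#' @param pocket A pocket from [cluster_sites] with non-empty fingerprints.
#' @param compound_library A `compound_library` (or a 0/1 matrix with ids as
#'   rownames), >= 10 compounds.
#' @param config Pipeline configuration.
#' @return List of class `screening_result`: `ranking` (data frame id,
#'   score, rank), `z_top`, `confident`.
#' @export
screen_library <- function(pocket, compound_library,
                           config = default_config()) {
  fp <- if (inherits(compound_library, "compound_library"))
    compound_library$fingerprints else compound_library
  if (nrow(fp) < 10) stop("compound library must contain at least 10 compounds")
  if (length(pocket$fingerprints) == 0) {
    stop("pocket carries no supporting-template fingerprints")
  }
  consensus <- colMeans(do.call(rbind, pocket$fingerprints))
  scores <- apply(fp, 1, tanimoto, b = consensus)
  sdv <- stats::sd(scores)
  if (sdv < 1e-12) stop("degenerate score distribution (zero variance)")
  ord <- order(-scores, rownames(fp))
  ranking <- data.frame(id = rownames(fp)[ord], score = scores[ord],
                        rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  z_top <- (ranking$score[1] - mean(scores)) / sdv
  structure(list(ranking = ranking, z_top = z_top,
                 confident = z_top >= config$z_min),
            class = "screening_result")
}

#' Deduplicate a fingerprint library at a Tanimoto cutoff
#'
#' Greedy selection in input order: a compound is kept iff its Tanimoto
#' similarity to every already-kept compound is strictly below `t_max`.
#'
#' @param compound_library A `compound_library` or fingerprint matrix.
#' @param t_max Tanimoto cutoff in (0, 1].
#' @return Object of the same kind with only the kept compounds.
#' @export
dedupe_library <- function(compound_library, t_max = 0.8) {
  stopifnot(t_max > 0, t_max <= 1)
  fp <- if (inherits(compound_library, "compound_library"))
    compound_library$fingerprints else compound_library
  kept <- integer()
  for (i in seq_len(nrow(fp))) {
    ok <- TRUE
    for (j in kept) {
      if (tanimoto(fp[i, ], fp[j, ]) >= t_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  if (inherits(compound_library, "compound_library")) {
    out <- compound_library
    out$fingerprints <- fp[kept, , drop = FALSE]
    out$active_ids <- intersect(out$active_ids, rownames(out$fingerprints))
    out
  } else {
    fp[kept, , drop = FALSE]
  }
}

#' Predict metal binding sites with three confidence channels
#'
#' Metal template sites are transferred and clustered like ligand sites. Per
#' cluster, the metal type is the TM-weighted majority vote of member
#' templates (conf_type = vote share of the winner); conf_site is the pocket
#' site confidence; binding residues are query residues near the predicted
#' position (side-chain/CB atom within 3 A or CA within 6 A) filtered by a
#' per-metal chemistry table; conf_residues is the mean fraction of each
#' member's transferred coordinating residues that land on the reported
#' binding residues.
#'
#' @param query A `protein_chain`.
#' @param metal_templates A `holo_template_set` of kind "metal" (possibly
#'   mixed metal types).
#' @param tm_min TM-score gate.
#' @param config Pipeline configuration.
#' @return List of `metal_prediction`s: position, metal_type,
#'   binding_residues, conf_site, conf_residues, conf_type.
#' @export
predict_metal_sites <- function(query, metal_templates, tm_min = 0.4,
                                config = default_config()) {
  centers <- transfer_site_centers(query, metal_templates, tm_min, config)
  if (nrow(centers) == 0) return(list())
  pockets <- cluster_sites(centers, query, config$cluster_cutoff, config)
  templates <- if (inherits(metal_templates, "holo_template_set"))
    metal_templates$templates else metal_templates
  tpl_by_id <- stats::setNames(templates, vapply(templates, `[[`, "", "id"))

  lapply(pockets, function(p) {
    sup <- p$supporting_templates
    votes <- tapply(sup$tm, sup$metal_type <- centers$metal_type[p$member_rows],
                    sum)
    winner <- names(votes)[order(-votes, names(votes))][1]
    conf_type <- as.numeric(votes[winner]) / sum(votes)

    # candidate coordinating residues near the predicted position
    dca <- sqrt(rowSums(sweep(query$xyz$CA, 2, p$center)^2))
    cb <- cb_coords(query)
    dcb <- sqrt(rowSums(sweep(cb, 2, p$center)^2))
    near <- which(dca <= config$metal_ca_cutoff |
                    dcb <= config$metal_side_cutoff)
    apt <- METAL_CHEMISTRY[[winner]]
    binding <- near[query$aa[near] %in% apt]
    if (winner %in% c("CA", "MG")) {
      ob <- query$xyz$O
      okO <- is.finite(ob[, 1])
      dob <- rep(Inf, length(query$aa))
      dob[okO] <- sqrt(rowSums(sweep(ob[okO, , drop = FALSE], 2, p$center)^2))
      binding <- sort(union(binding, which(dob <= 3.5)))
    }
    # residue-channel confidence: agreement of member coordination shells
    fracs <- vapply(p$member_rows, function(m) {
      tpl <- tpl_by_id[[centers$template[m]]]
      al <- align_structures(query, tpl$chain, config = config)
      if (al$n_aligned == 0) return(0)
      dtp <- sqrt(rowSums(sweep(tpl$chain$xyz$CA, 2, tpl$site)^2))
      coord_t <- which(dtp <= config$metal_ca_cutoff)
      mapped <- al$pairs[al$pairs[, 2] %in% coord_t, 1]
      if (length(mapped) == 0) return(0)
      length(intersect(mapped, binding)) / length(mapped)
    }, 0)
    structure(list(position = p$center, metal_type = winner,
                   binding_residues = sort(binding),
                   conf_site = p$site_confidence,
                   conf_residues = mean(fracs),
                   conf_type = conf_type,
                   supporting_templates = sup),
              class = "metal_prediction")
  })
}
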