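# Rigid-body superposition, TM-score, heuristic structure alignment, library
# search and nearest-neighbour fold-label transfer.

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares fit of `coords_b` onto `coords_a` over all rotations and
#' translations, reflections excluded. The returned transform maps b into the
#' frame of a: b' = b R^T + t.
#'
#' @param coords_a,coords_b Equal-length n x 3 coordinate matrices, n >= 3.
#' @return List with `rotation` (3 x 3, det +1), `translation` (3-vector) and
#'   `rmsd` over the fitted pairs.
#' @export
kabsch <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (nrow(a) != nrow(b)) stop("coordinate sets must have equal length")
  if (nrow(a) < 3) stop("at least 3 point pairs are required")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  h <- t(bc) %*% ac
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- ca - as.numeric(rot %*% cb)
  fitted <- apply_rigid(b, rot, trans)
  rmsd <- sqrt(mean(rowSums((fitted - a)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

#' TM-score distance scale d0
#'
#' d0(L) = 1.24 (L - 15)^(1/3) - 1.8, clamped below at 0.5 Angstroms (the
#' formula turns negative for chains of 21 residues or fewer).
#'
#' @param norm_length Normalization length L.
#' @return d0 in Angstroms.
#' @export
tm_d0 <- function(norm_length) {
  max(0.5, 1.24 * sign(norm_length - 15) * abs(norm_length - 15)^(1 / 3) - 1.8)
}

# TM-score of a fixed transform: mean over norm_length of 1/(1+(d/d0)^2)
# evaluated on the paired coordinates.
.tm_of_transform <- function(a, b, rot, trans, norm_length, d0) {
  fitted <- apply_rigid(b, rot, trans)
  d2 <- rowSums((fitted - a)^2)
  sum(1 / (1 + d2 / d0^2)) / norm_length
}

#' TM-score for a fixed residue correspondence
#'
#' Maximizes the TM-score sum over rigid transforms by iterative fitting on
#' shrinking inlier subsets (the TM-score protocol): starting from the full
#' pair set and from sliding windows, each seed is refined by alternating a
#' Kabsch fit on the current subset with re-selection of pairs within a
#' distance cutoff. The returned score is never below the score of the plain
#' full-set Kabsch superposition.
#'
#' @param chain_a,chain_b `protein_chain` objects (or n x 3 CA matrices).
#' @param pairs k x 2 matrix of residue index correspondences (a, b).
#' @param norm_length Normalization length (>= 5).
#' @return List: `tm`, `d0`, `superposition` (rotation/translation/rmsd over
#'   the inlier subset that realized the maximum).
#' @export
tm_score_fixed <- function(chain_a, chain_b, pairs, norm_length) {
  if (norm_length < 5) stop("norm_length must be >= 5")
  ca_a <- if (inherits(chain_a, "protein_chain")) chain_a$xyz$CA else as.matrix(chain_a)
  ca_b <- if (inherits(chain_b, "protein_chain")) chain_b$xyz$CA else as.matrix(chain_b)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  k <- nrow(pairs)
  if (k < 3) return(list(tm = 0, d0 = tm_d0(norm_length), superposition = NULL))
  a <- ca_a[pairs[, 1], , drop = FALSE]
  b <- ca_b[pairs[, 2], , drop = FALSE]
  d0 <- tm_d0(norm_length)

  best <- list(tm = -Inf, superposition = NULL)
  try_subset <- function(idx, best) {
    for (iter in 1:20) {
      if (length(idx) < 3) break
      fit <- kabsch(a[idx, , drop = FALSE], b[idx, , drop = FALSE])
      tm <- .tm_of_transform(a, b, fit$rotation, fit$translation,
                             norm_length, d0)
      if (tm > best$tm) best <- list(tm = tm, superposition = fit)
      dist <- sqrt(rowSums((apply_rigid(b, fit$rotation, fit$translation) - a)^2))
      dcut <- max(d0, 3.0)
      repeat {
        new_idx <- which(dist < dcut)
        if (length(new_idx) >= 3) break
        dcut <- dcut + 0.5
      }
      if (length(new_idx) == length(idx) && all(new_idx == idx)) break
      idx <- new_idx
    }
    best
  }

  best <- try_subset(seq_len(k), best)
  win <- max(4L, k %/% 4L)
  starts <- unique(c(seq(1L, max(1L, k - win + 1L), by = max(1L, win %/% 2L)),
                     max(1L, k - win + 1L)))
  for (s in starts) {
    best <- try_subset(s:min(k, s + win - 1L), best)
  }
  list(tm = best$tm, d0 = d0, superposition = best$superposition)
}

# quick TM for a pair set: one Kabsch fit on all pairs (no subset search)
.tm_quick <- function(a_all, b_all, pairs, norm_length, d0) {
  if (nrow(pairs) < 3) return(-Inf)
  a <- a_all[pairs[, 1], , drop = FALSE]
  b <- b_all[pairs[, 2], , drop = FALSE]
  fit <- kabsch(a, b)
  .tm_of_transform(a, b, fit$rotation, fit$translation, norm_length, d0)
}

# distance-based DP re-pairing given a transform
.repair_pairs <- function(a_all, b_all, rot, trans, d0, gap_open) {
  bt <- apply_rigid(b_all, rot, trans)
  s <- 1 / (1 + distsq_matrix(a_all, bt) / d0^2)
  res <- nw_pairs(s, gap_open, 0, TRUE)
  res$pairs
}

#' Heuristic structure alignment of two chains
#'
#' Deterministic TM-align-family heuristic. Initial correspondences come from
#' (a) gapless threading at all offsets, (b) dynamic-programming alignment of
#' the two secondary-structure strings and (c) the best-superposing
#' 15-residue fragment pair. Each seed is refined by iterating
#' {Kabsch superposition on the current pairs -> re-pairing by
#' dynamic programming on the distance score 1/(1 + (d_ij/d0)^2) with gap
#' open 0.6} until the pair set is stable or `max_iter` iterations; the
#' maximum-TM result is reported. TM-score is normalized by the query length
#' by default.
#'
#' @param query,target `protein_chain` objects with >= 10 residues each.
#' @param norm_length Normalization length; defaults to the query length.
#' @param config Pipeline configuration (gap penalty, iteration cap).
#' @return List of class `alignment_result`: `pairs` (k x 2 index matrix,
#'   query then target), `tm_score`, `d0`, `norm_length`, `aligned_identity`,
#'   `superposition` (maps target into the query frame), `n_aligned`.
#' @export
align_structures <- function(query, target, norm_length = NULL,
                             config = default_config()) {
  if (length(query$aa) < 10 || length(target$aa) < 10) {
    stop("both chains must have at least 10 residues")
  }
  la <- length(query$aa); lb <- length(target$aa)
  if (is.null(norm_length)) norm_length <- la
  d0 <- tm_d0(norm_length)
  a_all <- query$xyz$CA; b_all <- target$xyz$CA
  gap <- config$align_gap_open

  seeds <- list()
  # (a) gapless threading at all offsets, pre-ranked by quick TM
  offs <- seq(-(lb - 5L), la - 5L)
  off_tm <- vapply(offs, function(o) {
    i <- max(1L, 1L + o):min(la, lb + o)
    if (length(i) < 5) return(-Inf)
    p <- cbind(i, i - o)
    .tm_quick(a_all, b_all, p, norm_length, d0)
  }, 0)
  for (o in offs[order(-off_tm)][seq_len(min(3, length(offs)))]) {
    i <- max(1L, 1L + o):min(la, lb + o)
    if (length(i) >= 5) seeds[[length(seeds) + 1]] <- cbind(i, i - o)
  }
  # (b) secondary-structure string alignment
  ssq <- assign_secondary_structure(query)
  sst <- assign_secondary_structure(target)
  sm <- outer(ssq, sst, function(x, y) ifelse(x == y, ifelse(x == "C", 0.2, 1), -0.3))
  sp <- nw_pairs(sm, 0.6, 0, TRUE)$pairs
  if (nrow(sp) >= 5) seeds[[length(seeds) + 1]] <- sp
  # (c) best 15-residue fragment pair
  if (la >= 15 && lb >= 15) {
    bestf <- NULL; bestr <- Inf
    for (i in seq(1L, la - 14L, by = 4L)) {
      for (j in seq(1L, lb - 14L, by = 4L)) {
        r <- kabsch(a_all[i:(i + 14L), ], b_all[j:(j + 14L), ])$rmsd
        if (r < bestr) { bestr <- r; bestf <- c(i, j) }
      }
    }
    if (!is.null(bestf)) {
      seeds[[length(seeds) + 1]] <-
        cbind(bestf[1]:(bestf[1] + 14L), bestf[2]:(bestf[2] + 14L))
    }
  }

  best <- list(tm = 0, pairs = matrix(integer(), 0, 2))
  for (seed in seeds) {
    pairs <- seed
    seen <- character()
    for (iter in seq_len(config$align_max_iter)) {
      if (nrow(pairs) < 3) break
      res <- tm_score_fixed(a_all, b_all, pairs, norm_length)
      if (is.null(res$superposition)) break
      if (res$tm > best$tm) best <- list(tm = res$tm, pairs = pairs)
      fit <- res$superposition
      new_pairs <- .repair_pairs(a_all, b_all, fit$rotation, fit$translation,
                                 d0, gap)
      key <- paste(new_pairs, collapse = ",")
      if (key %in% seen) break
      seen <- c(seen, key)
      pairs <- new_pairs
    }
  }

  if (nrow(best$pairs) < 5) {
    return(structure(list(pairs = matrix(integer(), 0, 2), tm_score = 0,
                          d0 = d0, norm_length = norm_length,
                          aligned_identity = 0, superposition = NULL,
                          n_aligned = 0L),
                     class = "alignment_result"))
  }
  polish <- tm_score_fixed(query, target, best$pairs, norm_length)
  tm <- max(best$tm, polish$tm)
  ident <- mean(query$aa[best$pairs[, 1]] == target$aa[best$pairs[, 2]])
  structure(list(pairs = best$pairs, tm_score = min(1, tm), d0 = d0,
                 norm_length = norm_length, aligned_identity = ident,
                 superposition = polish$superposition,
                 n_aligned = nrow(best$pairs)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment: %d pairs, TM %.3f (d0 %.2f, L %d), identity %.2f>\n",
              x$n_aligned, x$tm_score, x$d0, x$norm_length,
              x$aligned_identity))
  invisible(x)
}

#' Search a labeled fold library with a query structure
#'
#' Aligns the query against every library entry and returns one hit per
#' entry, sorted by TM-score descending with ties broken by aligned sequence
#' identity and then entry id.
#'
#' @param query A `protein_chain`.
#' @param library A fold library: list with `entries`, each a list with
#'   `id`, `chain` and `label` (dotted C.A.T string).
#' @param config Pipeline configuration.
#' @return Data frame: id, label, tm_score, aligned_identity, n_aligned.
#' @export
search_library <- function(query, library, config = default_config()) {
  entries <- library$entries
  stopifnot(length(entries) > 0)
  hits <- lapply(entries, function(e) {
    al <- align_structures(query, e$chain, config = config)
    data.frame(id = e$id, label = e$label, tm_score = al$tm_score,
               aligned_identity = al$aligned_identity,
               n_aligned = al$n_aligned, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  hits[order(-hits$tm_score, -hits$aligned_identity, hits$id), , drop = FALSE]
}

#' Fold classification by nearest structural neighbour
#'
#' Transfers the Class.Architecture.Topology label of the best library hit
#' when its TM-score reaches the significance threshold (default 0.4);
#' otherwise the query is left unclassified.
#'
#' @param query A `protein_chain`.
#' @param library A labeled fold library (see [search_library]).
#' @param min_tm TM-score significance gate.
#' @param config Pipeline configuration.
#' @return List: query_id, class, architecture, topology, label, tm_score,
#'   significant.
#' @export
classify_by_nearest <- function(query, library, min_tm = 0.4,
                                config = default_config()) {
  hits <- search_library(query, library, config = config)
  top <- hits[1, ]
  sig <- top$tm_score >= min_tm
  parts <- if (sig) strsplit(top$label, ".", fixed = TRUE)[[1]] else
    rep(NA_character_, 3)
  list(query_id = query$chain_id,
       class = parts[1], architecture = parts[2], topology = parts[3],
       label = if (sig) top$label else NA_character_,
       best_hit = top$id, tm_score = top$tm_score, significant = sig)
}
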