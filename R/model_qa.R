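# Model quality assessment: backbone torsions, hydrogen-bond detection,
# DSSP-style secondary-structure assignment, Ramachandran region
# classification, per-model QA reports and model-confidence tiers.

#' Backbone torsion angles of a chain
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i), psi(i) = N(i)-CA(i)-C(i)-N(i+1),
#' omega(i) = CA(i-1)-C(i-1)-N(i)-CA(i). Angles undefined at termini, across
#' recorded chain breaks, or where a backbone atom is missing are NA.
#'
#' @param chain A `protein_chain`.
#' @return n x 3 matrix (phi, psi, omega) in degrees, NA where undefined.
#' @export
torsion_angles <- function(chain) {
  n <- length(chain$aa)
  N <- chain$xyz$N; CA <- chain$xyz$CA; C <- chain$xyz$C
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("phi", "psi", "omega")))
  brk <- chain$breaks
  okN <- is.finite(N[, 1]); okCA <- is.finite(CA[, 1]); okC <- is.finite(C[, 1])
  for (i in seq_len(n)) {
    if (i > 1 && !((i - 1) %in% brk)) {
      if (okC[i - 1] && okN[i] && okCA[i] && okC[i]) {
        out[i, 1] <- dihedral4(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
      }
      if (okCA[i - 1] && okC[i - 1] && okN[i] && okCA[i]) {
        out[i, 3] <- dihedral4(CA[i - 1, ], C[i - 1, ], N[i, ], CA[i, ])
      }
    }
    if (i < n && !(i %in% brk)) {
      if (okN[i] && okCA[i] && okC[i] && okN[i + 1]) {
        out[i, 2] <- dihedral4(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
      }
    }
  }
  out
}

# Geometrically constructed amide H positions (NA for first residue, prolines
# and post-break residues): 1.0 A from N on the bisector of C(i-1) and CA(i).
.amide_h <- function(chain) {
  n <- length(chain$aa)
  N <- chain$xyz$N; CA <- chain$xyz$CA; C <- chain$xyz$C
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)[-1]) {
    if ((i - 1) %in% chain$breaks) next
    if (chain$aa[i] == "P") next
    if (!all(is.finite(c(N[i, ], CA[i, ], C[i - 1, ])))) next
    d <- unitv(unitv(N[i, ] - C[i - 1, ]) + unitv(N[i, ] - CA[i, ]))
    H[i, ] <- N[i, ] + d
  }
  H
}

# DSSP electrostatic H-bond energy (kcal/mol) for donor residue i (N-H) and
# acceptor residue j (C=O).
.dssp_energy <- function(Ni, Hi, Oj, Cj) {
  rON <- vnorm(Oj - Ni); rCH <- vnorm(Cj - Hi)
  rOH <- vnorm(Oj - Hi); rCN <- vnorm(Cj - Ni)
  if (min(rON, rCH, rOH, rCN) < 0.5) return(-9.9)
  0.084 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN) * 332
}

#' Detect hydrogen bonds in a chain
#'
#' Backbone-backbone bonds use the DSSP electrostatic criterion
#' E = 0.084 (1/rON + 1/rCH - 1/rOH - 1/rCN) * 332 < -0.5 kcal/mol with amide
#' hydrogens constructed geometrically (1.0 A from N on the C(i-1)/CA
#' bisector); proline does not donate. Bonds involving side-chain N/O/S atoms
#' use a geometric criterion: donor-acceptor distance <= 3.5 A and
#' donor-antecedent-acceptor angle >= 90 degrees. Each bond is categorized
#' main-main, main-side or side-side.
#'
#' @param chain A `protein_chain`.
#' @return Data frame: donor_res, donor_atom, acceptor_res, acceptor_atom,
#'   category, energy (kcal/mol, NA for geometric bonds).
#' @export
detect_hbonds <- function(chain) {
  n <- length(chain$aa)
  N <- chain$xyz$N; C <- chain$xyz$C; O <- chain$xyz$O
  H <- .amide_h(chain)
  rows <- list()
  # backbone-backbone: donor/acceptor pairs at sequence separation >= 3
  # (the assignment rules only consult n-turns with n >= 3 and bridges at
  # |i - j| >= 3; closer pairs in extended geometry are sterically strained)
  don <- which(is.finite(H[, 1]) & is.finite(N[, 1]))
  acc <- which(is.finite(O[, 1]) & is.finite(C[, 1]))
  for (i in don) {
    for (j in acc) {
      if (abs(i - j) < 3) next
      e <- .dssp_energy(N[i, ], H[i, ], O[j, ], C[j, ])
      if (e < -0.5) {
        rows[[length(rows) + 1]] <- data.frame(
          donor_res = i, donor_atom = "N", acceptor_res = j,
          acceptor_atom = "O", category = "main-main", energy = e,
          stringsAsFactors = FALSE)
      }
    }
  }
  # side-chain participants: extra atoms with element N, O or S
  ex <- chain$extra
  if (!is.null(ex) && nrow(ex) > 0) {
    pol <- ex[toupper(substr(ex$element, 1, 1)) %in% c("N", "O", "S"), ,
              drop = FALSE]
    if (nrow(pol) > 0) {
      antecedent <- function(res, pos) {
        cands <- rbind(chain$xyz$CA[res, ], chain$xyz$C[res, ],
                       chain$xyz$N[res, ], chain$xyz$CB[res, ])
        exr <- ex[ex$res == res, , drop = FALSE]
        if (nrow(exr) > 0) cands <- rbind(cands, as.matrix(exr[, c("x", "y", "z")]))
        cands <- cands[is.finite(cands[, 1]), , drop = FALSE]
        d <- sqrt(rowSums(sweep(cands, 2, pos)^2))
        d[d < 1e-6] <- Inf
        cands[which.min(d), ]
      }
      geo_bond <- function(dpos, dant, apos) {
        vnorm(dpos - apos) <= 3.5 && angle3(dant, dpos, apos) >= 90
      }
      for (k in seq_len(nrow(pol))) {
        spos <- c(pol$x[k], pol$y[k], pol$z[k])
        sres <- pol$res[k]
        sant <- antecedent(sres, spos)
        # side donor -> backbone O acceptor (main-side)
        for (j in which(is.finite(O[, 1]))) {
          if (j == sres) next
          if (geo_bond(spos, sant, O[j, ])) {
            rows[[length(rows) + 1]] <- data.frame(
              donor_res = sres, donor_atom = pol$name[k], acceptor_res = j,
              acceptor_atom = "O", category = "main-side", energy = NA_real_,
              stringsAsFactors = FALSE)
          }
        }
        # backbone N donor -> side acceptor (main-side)
        for (i in which(is.finite(N[, 1]))) {
          if (i == sres || chain$aa[i] == "P") next
          if (geo_bond(N[i, ], chain$xyz$CA[i, ], spos)) {
            rows[[length(rows) + 1]] <- data.frame(
              donor_res = i, donor_atom = "N", acceptor_res = sres,
              acceptor_atom = pol$name[k], category = "main-side",
              energy = NA_real_, stringsAsFactors = FALSE)
          }
        }
        # side-side (unordered pairs, k < m)
        if (k < nrow(pol)) {
          for (m in seq(k + 1, nrow(pol))) {
            if (pol$res[m] == sres) next
            mpos <- c(pol$x[m], pol$y[m], pol$z[m])
            if (geo_bond(spos, sant, mpos)) {
              rows[[length(rows) + 1]] <- data.frame(
                donor_res = sres, donor_atom = pol$name[k],
                acceptor_res = pol$res[m], acceptor_atom = pol$name[m],
                category = "side-side", energy = NA_real_,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(donor_res = integer(), donor_atom = character(),
                      acceptor_res = integer(), acceptor_atom = character(),
                      category = character(), energy = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Assign secondary structure by hydrogen-bond pattern rules
#'
#' DSSP-style assignment from backbone H-bonds: two consecutive n-turns
#' (i -> i+3/4/5) give G/H/I helices, inter-strand bridge patterns give E
#' (an isolated bridge gives B), turn neighbourhoods give T and the remainder
#' C. Class priority is H > E > G > I > B > T > C. Chains shorter than five
#' residues are all coil.
#'
#' @param chain A `protein_chain`.
#' @return Character vector of per-residue classes in
#'   {H, G, I, E, B, T, C}.
#' @export
assign_secondary_structure <- function(chain) {
  n <- length(chain$aa)
  ss <- rep("C", n)
  if (n < 5) return(ss)
  hb <- detect_hbonds(chain)
  hb <- hb[hb$category == "main-main", , drop = FALSE]
  bond <- matrix(FALSE, n, n)  # bond[i, j]: N-H of i donates to C=O of j
  if (nrow(hb) > 0) bond[cbind(hb$donor_res, hb$acceptor_res)] <- TRUE

  turn <- function(nn) {
    t <- rep(FALSE, n)
    idx <- seq_len(n - nn)
    t[idx] <- bond[cbind(idx + nn, idx)]
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)

  helix_mask <- function(t, nn) {
    m <- rep(FALSE, n)
    for (i in which(t)) {
      if (i > 1 && t[i - 1]) m[i:(i + nn - 1)] <- TRUE
    }
    m
  }
  mH <- helix_mask(t4, 4)
  mG <- helix_mask(t3, 3)
  mI <- helix_mask(t5, 5)

  # bridges
  bnd <- function(i, j) i >= 1 && j >= 1 && i <= n && j <= n && bond[i, j]
  bridge <- matrix(FALSE, n, n)
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) < 3) next
      par <- (bnd(i - 1, j) && bnd(j, i + 1)) || (bnd(j - 1, i) && bnd(i, j + 1))
      anti <- (bnd(i, j) && bnd(j, i)) ||
        (bnd(i - 1, j + 1) && bnd(j - 1, i + 1))
      if (par || anti) bridge[i, j] <- TRUE
    }
  }
  mE <- rep(FALSE, n); mB <- rep(FALSE, n)
  for (i in seq_len(n)) {
    js <- which(bridge[i, ])
    for (j in js) {
      ladder <- (i > 1 && any(abs(which(bridge[i - 1, ]) - j) <= 1)) ||
        (i < n && any(abs(which(bridge[i + 1, ]) - j) <= 1))
      if (ladder) mE[i] <- TRUE else mB[i] <- TRUE
    }
  }
  mT <- rep(FALSE, n)
  for (nn in c(3, 4, 5)) {
    t <- turn(nn)
    for (i in which(t)) mT[(i + 1):(i + nn - 1)] <- TRUE
  }

  ss[mC <- rep(TRUE, n)] <- "C"
  ss[mT] <- "T"
  ss[mB & ss %in% c("C", "T")] <- "B"
  ss[mI & ss %in% c("C", "T", "B")] <- "I"
  ss[mG & ss %in% c("C", "T", "B", "I")] <- "G"
  ss[mE & ss %in% c("C", "T", "B", "I", "G")] <- "E"
  ss[mH] <- "H"
  ss
}

#' Classify backbone torsions into Ramachandran regions
#'
#' Looks up each residue's (phi, psi) in the shipped 10 x 10 degree region
#' grid ([rama_grid]). Residues with undefined phi or psi (termini, breaks)
#' are NA and excluded from fraction reports. Glycine is exempt from
#' "disallowed" and reported at best "generously allowed".
#'
#' @param chain A `protein_chain`.
#' @return Data frame: residue, aa, phi, psi, region (factor over the four
#'   region names, NA where unclassifiable).
#' @export
ramachandran_classify <- function(chain) {
  tor <- torsion_angles(chain)
  g <- rama_grid()
  cell <- function(x) pmin(36L, pmax(1L, floor((x + 180) / 10) + 1L))
  n <- length(chain$aa)
  lev <- rep(NA_integer_, n)
  ok <- is.finite(tor[, 1]) & is.finite(tor[, 2])
  lev[ok] <- g[cbind(cell(tor[ok, 1]), cell(tor[ok, 2]))]
  gly <- chain$aa == "G" & !is.na(lev) & lev == 1L
  lev[gly] <- 2L
  data.frame(residue = seq_len(n), aa = chain$aa,
             phi = tor[, 1], psi = tor[, 2],
             region = factor(RAMA_LEVELS[lev], levels = RAMA_LEVELS),
             stringsAsFactors = FALSE)
}

#' Full QA report for a model
#'
#' Combines secondary-structure class fractions (denominator: all residues,
#' every residue carries a class), hydrogen-bond counts per category
#' normalized per residue, and Ramachandran region fractions over
#' classifiable non-glycine, non-terminal residues.
#'
#' @param chain A `protein_chain`.
#' @return List with elements `ss_fractions`, `hbond_per_residue`,
#'   `rama_fractions`.
#' @export
qa_report <- function(chain) {
  n <- length(chain$aa)
  ss <- assign_secondary_structure(chain)
  classes <- c("H", "G", "I", "E", "B", "T", "C")
  ssf <- vapply(classes, function(k) mean(ss == k), 0)
  hb <- detect_hbonds(chain)
  cats <- c("main-main", "side-side", "main-side")
  hbf <- vapply(cats, function(k) sum(hb$category == k) / n, 0)
  ra <- ramachandran_classify(chain)
  use <- !is.na(ra$region) & ra$aa != "G"
  if (any(use)) {
    raf <- table(ra$region[use]) / sum(use)
    raf <- as.numeric(raf[RAMA_LEVELS])
    raf[is.na(raf)] <- 0
  } else {
    raf <- rep(0, 4)
  }
  names(raf) <- RAMA_LEVELS
  list(ss_fractions = ssf, hbond_per_residue = hbf, rama_fractions = raf)
}

#' Model confidence tier from an estimated TM-score
#'
#' Tiers follow the fixed cutoffs: high for estimated TM-score >= 0.7,
#' moderate for >= 0.4, low below 0.4, and "none" when no estimate exists
#' (no templates were found for the model).
#'
#' @param estimated_tm Estimated TM-score in [0, 1], or NULL/NA when absent.
#' @return List with `tier` (one of "high", "moderate", "low", "none") and
#'   `estimated_tm`.
#' @export
confidence_tier <- function(estimated_tm = NULL) {
  if (is.null(estimated_tm) || length(estimated_tm) == 0 ||
      is.na(estimated_tm)) {
    return(list(tier = "none", estimated_tm = NA_real_))
  }
  if (!is.numeric(estimated_tm) || estimated_tm < 0 || estimated_tm > 1) {
    stop("estimated_tm must lie in [0, 1]")
  }
  tier <- if (estimated_tm >= 0.7) "high"
  else if (estimated_tm >= 0.4) "moderate"
  else "low"
  list(tier = tier, estimated_tm = estimated_tm)
}
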