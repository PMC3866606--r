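# Authoritative constants: ideal covalent geometry for the synthetic backbone
# builder, amino-acid tables, the Ramachandran region grid, the interface
# propensity table and the metal coordination chemistry rules. Everything the
# pipeline treats as a fixed, versioned fixture lives here.

#' Ideal backbone geometry used by the chain builder
#'
#' Bond lengths in Angstroms, bond angles in degrees. These are the standard
#' Engh/Huber-style ideal values; every synthetic chain in the package is
#' built from this single table.
#'
#' @format Named list of bond lengths and angles.
#' @export
ideal_geometry <- list(
  b_n_ca   = 1.458,
  b_ca_c   = 1.525,
  b_c_n    = 1.329,
  b_c_o    = 1.231,
  b_ca_cb  = 1.521,
  a_n_ca_c = 111.2,
  a_ca_c_n = 116.2,
  a_c_n_ca = 121.7,
  a_ca_c_o = 120.8,
  a_n_ca_cb = 110.5,
  # improper dihedral C-N-CA-CB fixing L-chirality of the side chain
  d_c_n_ca_cb = 122.6
)

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
         X = "UNK")

AA3_TO_1 <- stats::setNames(names(AA3), AA3)

# Background amino-acid frequencies (Robinson & Robinson style composition),
# used by the sequence generators and as the shuffle-null composition.
AA_BACKGROUND <- c(
  A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
  Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.052,
  L = 0.090, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
  S = 0.071, T = 0.059, W = 0.013, Y = 0.032, V = 0.064)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

#' Interface propensity table
#'
#' Per-residue propensity to occur in a protein-protein interface, on an
#' arbitrary 0-1 scale: aromatic and large hydrophobic residues score high,
#' small polar residues low, charged residues intermediate (salt bridges).
#' Used by the empirical binding-residue score.
#'
#' @format Named numeric vector over the 20 standard amino acids.
#' @export
interface_propensity <- c(
  W = 1.00, F = 0.90, M = 0.85, Y = 0.80, I = 0.75, L = 0.75, V = 0.60,
  C = 0.50, R = 0.45, H = 0.45, K = 0.40, E = 0.40, D = 0.35, Q = 0.30,
  N = 0.25, T = 0.20, A = 0.20, S = 0.15, P = 0.10, G = 0.05)

# Residue alphabet the dimer generator plants at interfaces ("sticky" set);
# complementary pairs carry the docking-potential signal.
STICKY_PAIRS <- list(
  c("L", "I"), c("I", "L"), c("F", "L"), c("L", "F"), c("W", "I"),
  c("I", "W"), c("F", "F"), c("L", "L"), c("Y", "M"), c("M", "Y"),
  c("E", "K"), c("K", "E"), c("D", "R"), c("R", "D"))

# Metal coordination chemistry: allowed coordinating residue types per metal.
METAL_CHEMISTRY <- list(
  ZN = c("C", "H", "D", "E"),
  CA = c("D", "E", "N", "Q", "S", "T"),
  MG = c("D", "E", "N", "Q", "S", "T"),
  FE = c("H", "C", "M", "Y"),
  CU = c("H", "C", "M"),
  MN = c("H", "D", "E"),
  NI = c("H", "D", "E"),
  CO = c("H", "D", "E"))

# Residue types the holo-template generator mutates coordination shells to.
METAL_SHELL_ALPHABET <- list(
  ZN = c("C", "H"),
  CA = c("D", "E", "N"),
  MG = c("D", "E", "N"),
  FE = c("H", "C"),
  CU = c("H", "M"),
  MN = c("H", "D", "E"),
  NI = c("H", "D", "E"),
  CO = c("H", "D", "E"))

METAL_TYPES <- names(METAL_CHEMISTRY)

# Canonical backbone torsions used by the fold generator.
TORSION_HELIX  <- c(phi = -57, psi = -47)
TORSION_STRAND <- c(phi = -120, psi = 120)
# Two-residue turn used to close beta hairpins so that the flanking strands
# actually pair (values chosen to maximize cross-strand H-bonding of the
# ideal-geometry backbone; see the methods vignette).
TORSION_TURN <- matrix(c(30, -150, -50, 0), ncol = 2, byrow = TRUE,
                       dimnames = list(NULL, c("phi", "psi")))

#' Default pipeline configuration
#'
#' All thresholds used across the pipeline, in one place: model confidence
#' tier cutoffs (0.7 high / 0.4 moderate), the TM-score significance gate
#' (0.4), the interface-overlap MCC gate (0.5), the receptor mapping
#' probability gate (0.5), the interaction-call probability (0.5), the
#' virtual-screening Z-score gate (2.0) and the library deduplication
#' Tanimoto cutoff (0.8).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    tier_high = 0.7,
    tier_moderate = 0.4,
    tm_min = 0.4,
    mcc_min = 0.5,
    map_min = 0.5,
    call_min = 0.5,
    z_min = 2.0,
    dedupe_tanimoto = 0.8,
    contact_cutoff = 8.0,
    cluster_cutoff = 8.0,
    # binding-residue score weights: propensity, exposure, neighbourhood
    pinup_weights = c(0.5, 0.3, 0.2),
    pinup_exposure_min = 0.3,
    pinup_top_frac = 0.25,
    # distance-matrix alignment: gap-open penalty on the 1/(1+(d/d0)^2) score
    align_gap_open = 0.6,
    align_max_iter = 30,
    # logistic map for receptor-mapping probability: plogis((z - z0) / zs)
    map_z0 = 3.0,
    map_zs = 1.0,
    n_shuffles = 100,
    # pocket confidence logistic: plogis(a * support_fraction + b * mean_tm + c)
    site_conf_a = 3.0,
    site_conf_b = 4.0,
    site_conf_c = -3.5,
    pocket_residue_ca = 6.0,
    metal_side_cutoff = 3.0,
    metal_ca_cutoff = 6.0
  )
}

# --- Ramachandran region grid -----------------------------------------------

# Regions are encoded 4 = most favored, 3 = additional allowed,
# 2 = generously allowed, 1 = disallowed. The grid is 10 x 10 degree cells
# built from explicit core rectangles (alpha, beta, left-handed alpha) with
# 20-degree "additional" and further 20-degree "generous" expansion bands.
RAMA_LEVELS <- c("disallowed", "generously allowed", "additional allowed",
                 "most favored")

rama_core_rects <- list(
  alpha = list(phi = c(-140, -40), psi = c(-70, -5)),
  beta1 = list(phi = c(-180, -45), psi = c(90, 180)),
  beta2 = list(phi = c(-180, -45), psi = c(-180, -170)),
  lalpha = list(phi = c(35, 85), psi = c(15, 80)))

expand_rect <- function(r, by) {
  list(phi = c(max(-180, r$phi[1] - by), min(180, r$phi[2] + by)),
       psi = c(max(-180, r$psi[1] - by), min(180, r$psi[2] + by)))
}

in_rect <- function(phi, psi, r) {
  phi >= r$phi[1] & phi <= r$phi[2] & psi >= r$psi[1] & psi <= r$psi[2]
}

# Region level (1-4) for torsions in degrees; vectorized.
rama_level <- function(phi, psi) {
  lev <- rep(1L, length(phi))
  for (r in rama_core_rects) {
    g <- expand_rect(r, 40)
    lev[in_rect(phi, psi, g)] <- pmax(lev[in_rect(phi, psi, g)], 2L)
  }
  for (r in rama_core_rects) {
    a <- expand_rect(r, 20)
    lev[in_rect(phi, psi, a)] <- pmax(lev[in_rect(phi, psi, a)], 3L)
  }
  for (r in rama_core_rects) {
    lev[in_rect(phi, psi, r)] <- 4L
  }
  lev
}

#' Ramachandran region grid (10 x 10 degrees)
#'
#' 36 x 36 integer matrix over phi (rows) and psi (columns), cell centers at
#' -175, -165, ..., 175; values 1 (disallowed) to 4 (most favored). The grid
#' is the package's stereochemical-region fixture: classification looks up
#' the cell containing (phi, psi).
#'
#' @return Integer matrix with phi/psi cell-center dimnames.
#' @export
rama_grid <- function() {
  centers <- seq(-175, 175, by = 10)
  g <- outer(centers, centers, function(p, s) rama_level(p, s))
  g <- matrix(as.integer(g), 36, 36,
              dimnames = list(phi = centers, psi = centers))
  g
}
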