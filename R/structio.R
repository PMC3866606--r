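# Core data model and standard-format I/O: protein chains with backbone (and
# optional side-chain) coordinates, PDB and FASTA reading/writing, and the
# ideal-geometry backbone builder that powers every synthetic structure.

#' Construct a protein chain
#'
#' A chain is an ordered list of residues, each with backbone atoms N, CA, C
#' (O and CB optional, required by some operations) stored as n x 3 coordinate
#' matrices in Angstroms. Residue indexing is 1-based and sequential; original
#' author numbering is discarded on read. `breaks` lists residue positions
#' after which the chain is discontinuous.
#'
#' @param chain_id Short chain identifier.
#' @param aa Character vector of one-letter amino-acid codes (20 standard + X).
#' @param xyz Named list of n x 3 matrices for atoms N, CA, C and optionally
#'   O and CB; missing atoms are NA rows.
#' @param breaks Integer vector of residue positions followed by a chain break.
#' @param extra Optional data frame of additional (side-chain) atoms with
#'   columns res, name, element, x, y, z.
#' @return Object of class `protein_chain`.
#' @export
protein_chain <- function(chain_id, aa, xyz, breaks = integer(),
                          extra = NULL) {
  n <- length(aa)
  stopifnot(n >= 1)
  aa <- toupper(aa)
  bad <- setdiff(unique(aa), c(AA1, "X"))
  if (length(bad) > 0) {
    stop("invalid amino-acid code(s): ", paste(bad, collapse = ", "))
  }
  for (nm in c("N", "CA", "C")) {
    if (is.null(xyz[[nm]])) stop("backbone atom ", nm, " missing from chain")
    if (!is.matrix(xyz[[nm]]) || nrow(xyz[[nm]]) != n || ncol(xyz[[nm]]) != 3) {
      stop("coordinate matrix for ", nm, " must be ", n, " x 3")
    }
  }
  for (nm in c("O", "CB")) {
    if (is.null(xyz[[nm]])) {
      xyz[[nm]] <- matrix(NA_real_, n, 3)
    }
  }
  obj <- structure(
    list(chain_id = chain_id, aa = aa,
         xyz = xyz[c("N", "CA", "C", "O", "CB")],
         breaks = sort(unique(as.integer(breaks))),
         extra = extra),
    class = "protein_chain")
  validate_chain(obj)
  obj
}

#' Validate protein-chain invariants
#'
#' Checks that backbone CA coordinates are finite and that consecutive
#' residues not separated by a recorded break have CA-CA distance in
#' [2.5, 4.5] Angstroms.
#'
#' @param chain A `protein_chain`.
#' @return Invisibly TRUE; errors on violation.
#' @export
validate_chain <- function(chain) {
  ca <- chain$xyz$CA
  if (any(!is.finite(ca))) stop("non-finite CA coordinates")
  n <- nrow(ca)
  if (n >= 2) {
    d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
    ok <- d >= 2.5 & d <= 4.5
    ok[chain$breaks[chain$breaks < n]] <- TRUE
    if (!all(ok)) {
      stop("CA-CA distance out of [2.5, 4.5] A at residue(s) ",
           paste(which(!ok), collapse = ", "), " (no break recorded)")
    }
  }
  invisible(TRUE)
}

#' @export
length.protein_chain <- function(x) length(x$aa)

#' @export
print.protein_chain <- function(x, ...) {
  cat(sprintf("<protein_chain %s: %d residues, %d break(s)>\n",
              x$chain_id, length(x$aa), length(x$breaks)))
  invisible(x)
}

#' Chain sequence as a single string
#' @param chain A `protein_chain`.
#' @return Character scalar.
#' @export
chain_sequence <- function(chain) paste(chain$aa, collapse = "")

# CB coordinates with CA fallback (Gly or missing CB); n x 3 matrix.
cb_coords <- function(chain) {
  cb <- chain$xyz$CB
  miss <- !is.finite(cb[, 1])
  cb[miss, ] <- chain$xyz$CA[miss, , drop = FALSE]
  cb
}

# Apply a rigid transform to every atom of a chain.
transform_chain <- function(chain, rotation, translation) {
  for (nm in names(chain$xyz)) {
    m <- chain$xyz[[nm]]
    ok <- is.finite(m[, 1])
    if (any(ok)) {
      m[ok, ] <- apply_rigid(m[ok, , drop = FALSE], rotation, translation)
    }
    chain$xyz[[nm]] <- m
  }
  if (!is.null(chain$extra) && nrow(chain$extra) > 0) {
    xyzm <- as.matrix(chain$extra[, c("x", "y", "z")])
    xyzm <- apply_rigid(xyzm, rotation, translation)
    chain$extra[, c("x", "y", "z")] <- xyzm
  }
  chain
}

# --- PDB ---------------------------------------------------------------------

.pdb_text_to_file <- function(stream) {
  if (length(stream) == 1 && file.exists(stream) &&
      !grepl("\n", stream, fixed = TRUE)) {
    return(stream)
  }
  lines <- unlist(strsplit(stream, "\n", fixed = TRUE))
  tmp <- tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  tmp
}

#' Read protein chains from PDB-format text
#'
#' Parses ATOM records into `protein_chain` objects keyed by chain identifier
#' (via bio3d's PDB reader). HETATM records are collected separately and
#' returned in the `ligand_atoms` attribute, not as residues. Alternate
#' locations are resolved to the highest occupancy (then first listed);
#' author numbering and insertion codes are folded into a sequential 1-based
#' index. Chain breaks are recorded where consecutive CA atoms are more than
#' 4.5 Angstroms apart.
#'
#' @param stream Path to a PDB file, or PDB-format text.
#' @return Named list of `protein_chain` objects, with attribute
#'   `ligand_atoms`: a data frame (name, element, resname, x, y, z).
#' @export
read_pdb <- function(stream) {
  path <- .pdb_text_to_file(stream)
  raw <- readLines(path)
  rec <- grepl("^(ATOM  |HETATM)", raw)
  if (any(rec)) {
    coords <- cbind(substr(raw[rec], 31, 38), substr(raw[rec], 39, 46),
                    substr(raw[rec], 47, 54))
    numbad <- apply(coords, 1, function(v) any(is.na(suppressWarnings(as.numeric(v)))))
    if (any(numbad)) {
      stop("malformed coordinate field at line ", which(rec)[which(numbad)[1]])
    }
  }
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom

  het <- at[at$type == "HETATM", , drop = FALSE]
  lig <- data.frame(name = character(), element = character(),
                    resname = character(), x = numeric(), y = numeric(),
                    z = numeric(), stringsAsFactors = FALSE)
  if (nrow(het) > 0) {
    elt <- het$elesy
    if (is.null(elt) || all(is.na(elt) | elt == "")) {
      elt <- toupper(substr(trimws(het$elety), 1, 2))
    }
    lig <- data.frame(name = trimws(het$elety), element = trimws(elt),
                      resname = trimws(het$resid),
                      x = het$x, y = het$y, z = het$z,
                      stringsAsFactors = FALSE)
  }

  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records found")
  # altloc: highest occupancy first, stable within ties, then deduplicate
  occ <- at$o
  occ[is.na(occ)] <- 1
  at <- at[order(-occ), , drop = FALSE]
  ins <- at$insert
  ins[is.na(ins)] <- ""
  key <- paste(at$chain, at$resno, ins, at$elety, sep = "|")
  at <- at[!duplicated(key), , drop = FALSE]
  at <- at[order(as.integer(rownames(at))), , drop = FALSE]

  chains <- list()
  for (cid in unique(at$chain)) {
    ca <- at[at$chain == cid, , drop = FALSE]
    insc <- ca$insert
    insc[is.na(insc)] <- ""
    reskey <- paste(ca$resno, insc, sep = "|")
    resix <- match(reskey, unique(reskey))
    n <- max(resix)
    if (!any(ca$elety == "CA")) {
      stop("chain ", cid, " contains no CA atoms")
    }
    aa <- rep("X", n)
    xyz <- list(N = matrix(NA_real_, n, 3), CA = matrix(NA_real_, n, 3),
                C = matrix(NA_real_, n, 3), O = matrix(NA_real_, n, 3),
                CB = matrix(NA_real_, n, 3))
    extra <- list()
    for (k in seq_len(nrow(ca))) {
      i <- resix[k]
      code <- AA3_TO_1[trimws(ca$resid[k])]
      if (!is.na(code)) aa[i] <- code
      nm <- trimws(ca$elety[k])
      pos <- c(ca$x[k], ca$y[k], ca$z[k])
      if (nm %in% c("N", "CA", "C", "O", "CB")) {
        xyz[[nm]][i, ] <- pos
      } else {
        elt <- ca$elesy[k]
        if (is.null(elt) || is.na(elt) || elt == "") elt <- substr(nm, 1, 1)
        extra[[length(extra) + 1]] <- data.frame(
          res = i, name = nm, element = trimws(elt),
          x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
      }
    }
    extra_df <- if (length(extra) > 0) do.call(rbind, extra) else NULL
    keep <- is.finite(xyz$CA[, 1])
    if (!all(keep)) {
      remap <- cumsum(keep)
      for (nm in names(xyz)) xyz[[nm]] <- xyz[[nm]][keep, , drop = FALSE]
      aa <- aa[keep]
      if (!is.null(extra_df)) {
        extra_df <- extra_df[keep[extra_df$res], , drop = FALSE]
        extra_df$res <- remap[extra_df$res]
      }
      n <- sum(keep)
    }
    cam <- xyz$CA
    breaks <- integer()
    if (n >= 2) {
      d <- sqrt(rowSums((cam[-1, , drop = FALSE] - cam[-n, , drop = FALSE])^2))
      breaks <- which(d < 2.5 | d > 4.5)
    }
    chains[[cid]] <- protein_chain(cid, aa, xyz, breaks = breaks,
                                   extra = extra_df)
  }
  attr(chains, "ligand_atoms") <- lig
  chains
}

.fmt_atom_name <- function(nm) {
  # atom names up to 3 chars start in column 14; 4-char names in column 13
  if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
}

.pdb_atom_line <- function(rectype, serial, name, resname, chain, resno,
                           pos, element) {
  if (any(abs(pos) >= 10000)) {
    stop("coordinate magnitude >= 10000 A cannot be formatted")
  }
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rectype, serial %% 100000, .fmt_atom_name(name), resname,
          substr(chain, 1, 1), resno %% 10000, pos[1], pos[2], pos[3], 1, 0,
          element)
}

#' Write chains (and optional ligand atoms) as PDB-format text
#'
#' Emits fixed-column ATOM records with coordinates to three decimals, a TER
#' record after each chain, and HETATM records for ligand/metal atoms.
#'
#' @param chains A `protein_chain` or list of them.
#' @param ligand_atoms Optional data frame (name, element, resname, x, y, z).
#' @param file Optional path; when given the text is also written there.
#' @return PDB text as a single character scalar, invisibly when `file` set.
#' @export
write_pdb <- function(chains, ligand_atoms = NULL, file = NULL) {
  if (inherits(chains, "protein_chain")) chains <- list(chains)
  if (length(chains) == 0) stop("chains must be non-empty")
  out <- character()
  serial <- 0L
  for (ch in chains) {
    n <- length(ch$aa)
    for (i in seq_len(n)) {
      resname <- AA3[[ch$aa[i]]]
      for (nm in c("N", "CA", "C", "O", "CB")) {
        pos <- ch$xyz[[nm]][i, ]
        if (!all(is.finite(pos))) next
        serial <- serial + 1L
        out <- c(out, .pdb_atom_line("ATOM", serial, nm, resname,
                                     ch$chain_id, i, pos, substr(nm, 1, 1)))
      }
      if (!is.null(ch$extra)) {
        ex <- ch$extra[ch$extra$res == i, , drop = FALSE]
        for (k in seq_len(nrow(ex))) {
          serial <- serial + 1L
          out <- c(out, .pdb_atom_line("ATOM", serial, ex$name[k], resname,
                                       ch$chain_id, i,
                                       c(ex$x[k], ex$y[k], ex$z[k]),
                                       ex$element[k]))
        }
      }
    }
    serial <- serial + 1L
    out <- c(out, sprintf("%-6s%5d      %-3s %1s%4d", "TER", serial,
                          AA3[[ch$aa[n]]], substr(ch$chain_id, 1, 1), n))
  }
  if (!is.null(ligand_atoms) && nrow(ligand_atoms) > 0) {
    for (k in seq_len(nrow(ligand_atoms))) {
      serial <- serial + 1L
      out <- c(out, .pdb_atom_line(
        "HETATM", serial, ligand_atoms$name[k],
        substr(ligand_atoms$resname[k], 1, 3), "X", k,
        c(ligand_atoms$x[k], ligand_atoms$y[k], ligand_atoms$z[k]),
        ligand_atoms$element[k]))
    }
  }
  out <- c(out, "END")
  txt <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

# --- FASTA -------------------------------------------------------------------

#' Read amino-acid sequences from FASTA text
#'
#' @param stream Path to a FASTA file, or FASTA-format text.
#' @return Data frame with columns `id` and `sequence`; sequences upper-cased,
#'   whitespace stripped. Errors when a sequence character falls outside the
#'   20 standard amino acids + X.
#' @export
read_fasta <- function(stream) {
  if (length(stream) == 1 && file.exists(stream) &&
      !grepl("\n", stream, fixed = TRUE)) {
    lines <- readLines(stream)
  } else {
    lines <- unlist(strsplit(stream, "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (length(lines) == 0 || !any(hdr)) {
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  if (!hdr[1]) stop("FASTA must start with a '>' header line")
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  seqs <- toupper(gsub("\\s", "", seqs[as.character(seq_along(ids))]))
  seqs[is.na(seqs)] <- ""
  if (any(!nzchar(seqs))) stop("empty sequence for record ",
                               ids[which(!nzchar(seqs))[1]])
  allchr <- unique(unlist(strsplit(seqs, "")))
  bad <- setdiff(allchr, c(AA1, "X"))
  if (length(bad) > 0) {
    stop("invalid sequence character(s): ", paste(bad, collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequence records as FASTA text
#'
#' @param records Data frame with columns `id` and `sequence`.
#' @param file Optional output path.
#' @param width Line-wrap width.
#' @return FASTA text as a character scalar, invisibly when `file` set.
#' @export
write_fasta <- function(records, file = NULL, width = 60) {
  out <- character()
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    out <- c(out, paste0(">", records$id[i]),
             substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }
  txt <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

# --- Backbone builder --------------------------------------------------------

#' Build a backbone chain from torsion angles with ideal geometry
#'
#' Places N, CA, C and O (plus CB for non-glycine) for each residue using the
#' ideal bond lengths and angles of [ideal_geometry] and the supplied
#' (phi, psi, omega) torsions in degrees. Convention: `phi[i]` is
#' C(i-1)-N(i)-CA(i)-C(i), `psi[i]` is N(i)-CA(i)-C(i)-N(i+1) and `omega[i]`
#' is the peptide dihedral CA(i-1)-C(i-1)-N(i)-CA(i) preceding residue i, so
#' phi and omega of the first residue and psi of the last are unused.
#' Re-measuring torsions on the output recovers the inputs to within 0.5
#' degrees.
#'
#' @param sequence Amino-acid string (or character vector) of length n.
#' @param torsions n x 3 numeric matrix of (phi, psi, omega) in degrees.
#' @param chain_id Chain identifier for the result.
#' @return A `protein_chain`.
#' @export
chain_from_torsions <- function(sequence, torsions, chain_id = "A") {
  aa <- if (length(sequence) == 1) strsplit(sequence, "")[[1]] else sequence
  aa <- toupper(aa)
  n <- length(aa)
  if (is.null(dim(torsions))) torsions <- matrix(torsions, ncol = 3, byrow = TRUE)
  if (nrow(torsions) != n || ncol(torsions) != 3) {
    stop("torsions must be a ", n, " x 3 matrix matching the sequence length")
  }
  g <- ideal_geometry
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N; CB <- N

  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * DEG
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(th), sin(th), 0)

  for (i in seq_len(n)[-1]) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         g$b_c_n, g$a_ca_c_n, torsions[i - 1, 2])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$b_n_ca, g$a_c_n_ca, torsions[i, 3])
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         g$b_ca_c, g$a_n_ca_c, torsions[i, 1])
  }
  for (i in seq_len(n)) {
    psi_eff <- if (i < n) torsions[i, 2] else 180
    chi <- psi_eff + 180
    if (chi > 180) chi <- chi - 360
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o, chi)
    if (aa[i] != "G") {
      CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ],
                            g$b_ca_cb, g$a_n_ca_cb, g$d_c_n_ca_cb)
    }
  }
  protein_chain(chain_id, aa, list(N = N, CA = CA, C = C, O = O, CB = CB))
}
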