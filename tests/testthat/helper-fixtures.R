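# Shared fixtures built in code.

ideal_helix <- function(n = 20, aa = "A") {
  tor <- matrix(rep(c(-57, -47, 180), n), ncol = 3, byrow = TRUE)
  chain_from_torsions(paste(rep(aa, n), collapse = ""), tor)
}

ideal_strand <- function(n = 10, aa = "V") {
  tor <- matrix(rep(c(-120, 120, 180), n), ncol = 3, byrow = TRUE)
  chain_from_torsions(paste(rep(aa, n), collapse = ""), tor)
}

ideal_hairpin <- function(strand_len = 8) {
  spec <- fold_spec(list(c("strand", strand_len), c("loop", 2),
                         c("strand", strand_len)), "sheet")
  make_fold(spec, paste(rep("V", spec$total_length), collapse = ""), seed = 1)
}

small_bundle <- function(seed = 3, len_seq = NULL) {
  spec <- default_topologies()$bundle$spec
  if (is.null(len_seq)) len_seq <- paste(rep("A", spec$total_length),
                                         collapse = "")
  make_fold(spec, len_seq, seed = seed)
}

# three-residue two-chain PDB fixture (chains A: 2 residues, B: 1 residue)
tiny_pdb_text <- function() {
  paste(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       4.000   2.800   0.100  1.00  0.00           C",
    "ATOM      7  C   GLY A   2       5.500   2.700   0.200  1.00  0.00           C",
    "ATOM      8  O   GLY A   2       6.100   1.650   0.300  1.00  0.00           O",
    "TER       9      GLY A   2",
    "ATOM     10  N   SER B   1       9.000   9.000   9.000  1.00  0.00           N",
    "ATOM     11  CA  SER B   1      10.458   9.000   9.000  1.00  0.00           C",
    "ATOM     12  C   SER B   1      11.009  10.420   9.000  1.00  0.00           C",
    "ATOM     13  O   SER B   1      10.251  11.390   9.000  1.00  0.00           O",
    "TER      14      SER B   1",
    "END", sep = "\n")
}
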