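# Amino-acid lookup tables used by the coarse-grained model.

# three-letter -> one-letter codes (standard residues only)
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "C", PYL = "K"
)

AA1 <- sort(unique(unname(AA3TO1)))

# Canonical CA -> side-chain-centroid distances (nm), one per residue type.
# Used when a side-chain bead has to be rebuilt along an existing CA->SC
# direction (sequence threading). Values are typical heavy-atom centroid
# distances for relaxed rotamers; glycine has no side-chain bead.
CA_SC_DIST <- c(
  A = 0.153, C = 0.208, D = 0.250, E = 0.312, F = 0.341,
  H = 0.316, I = 0.231, K = 0.351, L = 0.261, M = 0.296,
  N = 0.249, P = 0.188, Q = 0.312, R = 0.414, S = 0.193,
  T = 0.196, V = 0.197, W = 0.389, Y = 0.385
)

# Preferred HLA-A*02:01 anchor residues by peptide position (position 2 and
# the C-terminal position of a 9-mer); used by the sequence-aware Go fixture.
ANCHOR_PREFERENCE <- list(`2` = c("L", "M", "I"), `9` = c("V", "L", "I"))

# backbone atom names never counted into the side-chain centroid
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
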