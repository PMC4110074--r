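# Residue templates: all-atom partial charges (CHARMM36-style protein
# values), bond lists, hybridization flags, hydrogen->parent map and an
# ideal-geometry Z-matrix for side-chain heavy atoms.  Radii are
# simplified per-element-class Rmin/2 values; they only set the
# dielectric cavity.
#
# Backbone charges (non-GLY/PRO): N -0.47, HN 0.31, CA 0.07, HA 0.09,
# C 0.51, O -0.51.  Every template sums to its integer net charge.

BACKBONE_Q <- c(N = -0.47, HN = 0.31, CA = 0.07, HA = 0.09,
                C = 0.51, O = -0.51)
BACKBONE_BONDS <- c("N CA", "CA C", "C O", "N HN", "CA HA")

ELEMENT_RADII <- c(C = 2.00, N = 1.85, O = 1.70, S = 2.00, P = 2.15,
                   FE = 0.65, H = 1.32, `NA` = 1.36, CL = 2.27,
                   K = 1.76, MG = 1.19, ZN = 1.09, CA = 1.37)
POLAR_H_RADIUS <- 0.2245
H_BOND_LENGTH <- c(C = 1.09, N = 1.00, O = 0.96, S = 1.34)

# atom, bond-to, angle-ref, torsion-ref, length A, angle deg, torsion deg
zrow <- function(atom, r1, r2, r3, b, a, t) {
  list(atom = atom, r1 = r1, r2 = r2, r3 = r3, b = b, a = a, t = t)
}
zcb <- zrow("CB", "CA", "N", "C", 1.53, 110.5, 122.5)

make_template <- function(name, side_q, side_bonds = character(),
                          sp2 = character(), hydrogens = character(),
                          zmat = list(), backbone = TRUE,
                          net = NULL) {
  q <- if (backbone) c(BACKBONE_Q, side_q) else side_q
  bonds <- c(if (backbone) BACKBONE_BONDS, side_bonds)
  h <- c(if (backbone) c(HN = "N", HA = "CA"), hydrogens)
  tot <- sum(q)
  if (is.null(net)) net <- round(tot)
  if (abs(tot - net) > 1e-6)
    stop("template ", name, " charge sum ", tot, " != ", net)
  list(name = name, charges = q, bonds = bonds, sp2 = c("C", sp2),
       hydrogens = h, zmat = zmat, net = net)
}

hb2 <- c(HB1 = "CB", HB2 = "CB")
hg2 <- c(HG1 = "CG", HG2 = "CG")
hd2 <- c(HD1 = "CD", HD2 = "CD")

build_templates <- function() {
  tpl <- list()

  tpl$ALA <- make_template("ALA",
    c(CB = -0.27, HB1 = 0.09, HB2 = 0.09, HB3 = 0.09),
    side_bonds = c("CA CB"),
    hydrogens = c(HB1 = "CB", HB2 = "CB", HB3 = "CB"),
    zmat = list(zcb))

  tpl$GLY <- make_template("GLY",
    c(N = -0.47, HN = 0.31, CA = -0.02, HA1 = 0.09, HA2 = 0.09,
      C = 0.51, O = -0.51),
    side_bonds = c("N CA", "CA C", "C O", "N HN"),
    hydrogens = c(HN = "N", HA1 = "CA", HA2 = "CA"),
    backbone = FALSE)

  tpl$SER <- make_template("SER",
    c(CB = 0.05, HB1 = 0.09, HB2 = 0.09, OG = -0.66, HG1 = 0.43),
    side_bonds = c("CA CB", "CB OG", "OG HG1"),
    hydrogens = c(hb2, HG1 = "OG"),
    zmat = list(zcb, zrow("OG", "CB", "CA", "N", 1.42, 110.5, 180)))

  tpl$CYS <- make_template("CYS",
    c(CB = -0.11, HB1 = 0.09, HB2 = 0.09, SG = -0.23, HG1 = 0.16),
    side_bonds = c("CA CB", "CB SG", "SG HG1"),
    hydrogens = c(hb2, HG1 = "SG"),
    zmat = list(zcb, zrow("SG", "CB", "CA", "N", 1.82, 112.5, 180)))

  # thiolate (deprotonated, metal-ligating) cysteine
  tpl$CYM <- make_template("CYM",
    c(CB = -0.38, HB1 = 0.09, HB2 = 0.09, SG = -0.80),
    side_bonds = c("CA CB", "CB SG"),
    hydrogens = hb2,
    zmat = list(zcb, zrow("SG", "CB", "CA", "N", 1.82, 112.5, 180)))

  tpl$THR <- make_template("THR",
    c(CB = 0.14, HB1 = 0.09, OG1 = -0.66, HG1 = 0.43,
      CG2 = -0.27, HG21 = 0.09, HG22 = 0.09, HG23 = 0.09),
    side_bonds = c("CA CB", "CB OG1", "OG1 HG1", "CB CG2"),
    hydrogens = c(HB1 = "CB", HG1 = "OG1", HG21 = "CG2", HG22 = "CG2",
                  HG23 = "CG2"),
    zmat = list(zcb, zrow("OG1", "CB", "CA", "N", 1.42, 109.5, 180),
                zrow("CG2", "CB", "CA", "N", 1.53, 110.5, -60)))

  tpl$VAL <- make_template("VAL",
    c(CB = -0.09, HB1 = 0.09,
      CG1 = -0.27, HG11 = 0.09, HG12 = 0.09, HG13 = 0.09,
      CG2 = -0.27, HG21 = 0.09, HG22 = 0.09, HG23 = 0.09),
    side_bonds = c("CA CB", "CB CG1", "CB CG2"),
    hydrogens = c(HB1 = "CB", HG11 = "CG1", HG12 = "CG1", HG13 = "CG1",
                  HG21 = "CG2", HG22 = "CG2", HG23 = "CG2"),
    zmat = list(zcb, zrow("CG1", "CB", "CA", "N", 1.53, 110.5, 180),
                zrow("CG2", "CB", "CA", "N", 1.53, 110.5, -60)))

  tpl$LEU <- make_template("LEU",
    c(CB = -0.18, HB1 = 0.09, HB2 = 0.09, CG = -0.09, HG1 = 0.09,
      CD1 = -0.27, HD11 = 0.09, HD12 = 0.09, HD13 = 0.09,
      CD2 = -0.27, HD21 = 0.09, HD22 = 0.09, HD23 = 0.09),
    side_bonds = c("CA CB", "CB CG", "CG CD1", "CG CD2"),
    hydrogens = c(hb2, HG1 = "CG", HD11 = "CD1", HD12 = "CD1",
                  HD13 = "CD1", HD21 = "CD2", HD22 = "CD2", HD23 = "CD2"),
    zmat = list(zcb, zrow("CG", "CB", "CA", "N", 1.53, 113, 180),
                zrow("CD1", "CG", "CB", "CA", 1.53, 110.5, 180),
                zrow("CD2", "CG", "CB", "CA", 1.53, 110.5, -60)))

  tpl$ILE <- make_template("ILE",
    c(CB = -0.09, HB1 = 0.09,
      CG2 = -0.27, HG21 = 0.09, HG22 = 0.09, HG23 = 0.09,
      CG1 = -0.18, HG11 = 0.09, HG12 = 0.09,
      CD1 = -0.27, HD11 = 0.09, HD12 = 0.09, HD13 = 0.09),
    side_bonds = c("CA CB", "CB CG1", "CB CG2", "CG1 CD1"),
    hydrogens = c(HB1 = "CB", HG21 = "CG2", HG22 = "CG2", HG23 = "CG2",
                  HG11 = "CG1", HG12 = "CG1", HD11 = "CD1", HD12 = "CD1",
                  HD13 = "CD1"),
    zmat = list(zcb, zrow("CG1", "CB", "CA", "N", 1.53, 110.5, 180),
                zrow("CG2", "CB", "CA", "N", 1.53, 110.5, -60),
                zrow("CD1", "CG1", "CB", "CA", 1.53, 113, 180)))

  tpl$MET <- make_template("MET",
    c(CB = -0.18, HB1 = 0.09, HB2 = 0.09, CG = -0.14, HG1 = 0.09,
      HG2 = 0.09, SD = -0.09, CE = -0.22, HE1 = 0.09, HE2 = 0.09,
      HE3 = 0.09),
    side_bonds = c("CA CB", "CB CG", "CG SD", "SD CE"),
    hydrogens = c(hb2, hg2, HE1 = "CE", HE2 = "CE", HE3 = "CE"),
    zmat = list(zcb, zrow("CG", "CB", "CA", "N", 1.53, 113, 180),
                zrow("SD", "CG", "CB", "CA", 1.82, 112.5, 180),
                zrow("CE", "SD", "CG", "CB", 1.79, 100, 180)))

  tpl$PRO <- make_template("PRO",
    c(N = -0.29, CD = 0.00, HD1 = 0.09, HD2 = 0.09, CA = 0.02,
      HA = 0.09, CB = -0.18, HB1 = 0.09, HB2 = 0.09, CG = -0.18,
      HG1 = 0.09, HG2 = 0.09, C = 0.51, O = -0.51),
    side_bonds = c("N CA", "CA C", "C O", "CA CB", "CB CG", "CG CD",
                   "CD N"),
    hydrogens = c(HA = "CA", hb2, hg2, HD1 = "CD", HD2 = "CD"),
    zmat = list(zcb, zrow("CG", "CB", "CA", "N", 1.53, 104, 30),
                zrow("CD", "N", "CA", "C", 1.46, 112, 115)),
    backbone = FALSE)

  tpl$PHE <- make_template("PHE",
    c(CB = -0.18, HB1 = 0.09, HB2 = 0.09, CG = 0.00,
      CD1 = -0.115, HD1 = 0.115, CD2 = -0.115, HD2 = 0.115,
      CE1 = -0.115, HE1 = 0.115, CE2 = -0.115, HE2 = 0.115,
      CZ = -0.115, HZ = 0.115),
    side_bonds = c("CA CB", "CB CG", "CG CD1", "CG CD2", "CD1 CE1",
                   "CD2 CE2", "CE1 CZ", "CE2 CZ"),
    sp2 = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    hydrogens = c(hb2, HD1 = "CD1", HD2 = "CD2", HE1 = "CE1",
                  HE2 = "CE2", HZ = "CZ"),
    zmat = list(zcb, zrow("CG", "CB", "CA", "N", 1.50, 114, 180),
                zrow("CD1", "CG", "CB", "CA", 1.39, 120, 90),
                zrow("CD2", "CG", "CB", "CA", 1.39, 120, -90),
                zrow("CE1", "CD1", "CG", "CB", 1.39, 120, 180),
                zrow("CE2", "CD2", "CG", "CB", 1.39, 120, 180),
                zrow("CZ", "CE1", "CD1", "CG", 1.39, 120, 0)))

  tpl$TYR <- make_template("TYR",
    c(CB = -0.18, HB1 = 0.09, HB2 = 0.09, CG = 0.00,
      CD1 = -0.115, HD1 = 0.115, CD2 = -0.115, HD2 = 0.115,
      CE1 = -0.115, HE1 = 0.115, CE2 = -0.115, HE2 = 0.115,
      CZ = 0.11, OH = -0.54, HH = 0.43),
    side_bonds = c("CA CB", "CB CG", "CG CD1", "CG CD2", "CD1 CE1",
                   "CD2 CE2", "CE1 CZ", "CE2 CZ", "CZ OH", "OH HH"),
    sp2 = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    hydrogens = c(hb2, HD1 = "CD1", HD2 = "CD2", HE1 = "CE1",
                  HE2 = "CE2", HH = "OH"),
    zmat = list(zcb, zrow("CG", "CB", "CA", "N", 1.50, 114, 180),
                zrow("CD1", "CG", "CB", "CA", 1.39, 120, 90),
                zrow("CD2", "CG", "CB", "CA", 1.39, 120, -90),
                zrow("CE1", "CD1", "CG", "CB", 1.39, 120, 180),
                zrow("CE2", "CD2", "CG", "CB", 1.39, 120, 180),
                zrow("CZ", "CE1", "CD1", "CG", 1.39, 120, 0),
                zrow("OH", "CZ", "CE1", "CD1", 1.38, 120, 180)))

  tpl$TRP <- make_template("TRP",
    c(CB = -0.18, HB1 = 0.09, HB2 = 0.09, CG = -0.03,
      CD1 = 0.035, HD1 = 0.115, NE1 = -0.61, HE1 = 0.38, CE2 = 0.13,
      CD2 = -0.02, CE3 = -0.115, HE3 = 0.115, CZ3 = -0.115,
      HZ3 = 0.115, CZ2 = -0.115, HZ2 = 0.115, CH2 = -0.115,
      HH2 = 0.115),
    side_bonds = c("CA CB", "CB CG", "CG CD1", "CG CD2", "CD1 NE1",
                   "NE1 CE2", "CE2 CD2", "CD2 CE3", "CE3 CZ3",
                   "CZ3 CH2", "CH2 CZ2", "CZ2 CE2"),
    sp2 = c("CG", "CD1", "NE1", "CE2", "CD2", "CE3", "CZ3", "CZ2",
            "CH2"),
    hydrogens = c(hb2, HD1 = "CD1", HE1 = "NE1", HE3 = "CE3",
                  HZ3 = "CZ3", HZ2 = "CZ2", HH2 = "CH2"),
    zmat = list(zcb, zrow("CG", "CB", "CA", "N", 1.50, 114, 180),
                zrow("CD1", "CG", "CB", "CA", 1.37, 127, 90),
                zrow("CD2", "CG", "CB", "CA", 1.43, 126, -90),
                zrow("NE1", "CD1", "CG", "CB", 1.38, 110, 180),
                zrow("CE2", "NE1", "CD1", "CG", 1.37, 109, 0),
                zrow("CE3", "CD2", "CG", "CD1", 1.40, 134, 180),
                zrow("CZ3", "CE3", "CD2", "CG", 1.39, 120, 180),
                zrow("CZ2", "CE2", "NE1", "CD1", 1.40, 130, 180),
                zrow("CH2", "CZ2", "CE2", "NE1", 1.39, 120, 180)))

  tpl$ASP <- make_template("ASP",
    c(CB = -0.28, HB1 = 0.09, HB2 = 0.09, CG = 0.62, OD1 = -0.76,
      OD2 = -0.76),
    side_bonds = c("CA CB", "CB CG", "CG OD1", "CG OD2"),
    sp2 = c("CG"),
    hydrogens = hb2,
    zmat = list(zcb, zrow("CG", "CB", "CA", "N", 1.52, 113, 180),
                zrow("OD1", "CG", "CB", "CA", 1.25, 119, 0),
                zrow("OD2", "CG", "CB", "CA", 1.25, 119, 180)))

  # protonated Asp (neutral); proton on OD2
  tpl$ASPP <- make_template("ASPP",
    c(CB = -0.21, HB1 = 0.09, HB2 = 0.09, CG = 0.75, OD1 = -0.55,
      OD2 = -0.61, HD2 = 0.44),
    side_bonds = c("CA CB", "CB CG", "CG OD1", "CG OD2", "OD2 HD2"),
    sp2 = c("CG", "OD2"),
    hydrogens = c(hb2, HD2 = "OD2"),
    zmat = tpl$ASP$zmat)

  tpl$ASN <- make_template("ASN",
    c(CB = -0.18, HB1 = 0.09, HB2 = 0.09, CG = 0.55, OD1 = -0.55,
      ND2 = -0.62, HD21 = 0.32, HD22 = 0.30),
    side_bonds = c("CA CB", "CB CG", "CG OD1", "CG ND2", "ND2 HD21",
                   "ND2 HD22"),
    sp2 = c("CG", "ND2"),
    hydrogens = c(hb2, HD21 = "ND2", HD22 = "ND2"),
    zmat = list(zcb, zrow("CG", "CB", "CA", "N", 1.52, 113, 180),
                zrow("OD1", "CG", "CB", "CA", 1.23, 121, 0),
                zrow("ND2", "CG", "CB", "CA", 1.33, 116, 180)))

  tpl$GLU <- make_template("GLU",
    c(CB = -0.18, HB1 = 0.09, HB2 = 0.09, CG = -0.28, HG1 = 0.09,
      HG2 = 0.09, CD = 0.62, OE1 = -0.76, OE2 = -0.76),
    side_bonds = c("CA CB", "CB CG", "CG CD", "CD OE1", "CD OE2"),
    sp2 = c("CD"),
    hydrogens = c(hb2, hg2),
    zmat = list(zcb, zrow("CG", "CB", "CA", "N", 1.53, 113, 180),
                zrow("CD", "CG", "CB", "CA", 1.52, 113, 180),
                zrow("OE1", "CD", "CG", "CB", 1.25, 119, 0),
                zrow("OE2", "CD", "CG", "CB", 1.25, 119, 180)))

  tpl$GLUP <- make_template("GLUP",
    c(CB = -0.18, HB1 = 0.09, HB2 = 0.09, CG = -0.21, HG1 = 0.09,
      HG2 = 0.09, CD = 0.75, OE1 = -0.55, OE2 = -0.61, HE2 = 0.44),
    side_bonds = c("CA CB", "CB CG", "CG CD", "CD OE1", "CD OE2",
                   "OE2 HE2"),
    sp2 = c("CD", "OE2"),
    hydrogens = c(hb2, hg2, HE2 = "OE2"),
    zmat = tpl$GLU$zmat)

  tpl$GLN <- make_template("GLN",
    c(CB = -0.18, HB1 = 0.09, HB2 = 0.09, CG = -0.18, HG1 = 0.09,
      HG2 = 0.09, CD = 0.55, OE1 = -0.55, NE2 = -0.62, HE21 = 0.32,
      HE22 = 0.30),
    side_bonds = c("CA CB", "CB CG", "CG CD", "CD OE1", "CD NE2",
                   "NE2 HE21", "NE2 HE22"),
    sp2 = c("CD", "NE2"),
    hydrogens = c(hb2, hg2, HE21 = "NE2", HE22 = "NE2"),
    zmat = list(zcb, zrow("CG", "CB", "CA", "N", 1.53, 113, 180),
                zrow("CD", "CG", "CB", "CA", 1.52, 113, 180),
                zrow("OE1", "CD", "CG", "CB", 1.23, 121, 0),
                zrow("NE2", "CD", "CG", "CB", 1.33, 116, 180)))

  tpl$LYS <- make_template("LYS",
    c(CB = -0.18, HB1 = 0.09, HB2 = 0.09, CG = -0.18, HG1 = 0.09,
      HG2 = 0.09, CD = -0.18, HD1 = 0.09, HD2 = 0.09, CE = 0.21,
      HE1 = 0.05, HE2 = 0.05, NZ = -0.30, HZ1 = 0.33, HZ2 = 0.33,
      HZ3 = 0.33),
    side_bonds = c("CA CB", "CB CG", "CG CD", "CD CE", "CE NZ",
                   "NZ HZ1", "NZ HZ2", "NZ HZ3"),
    hydrogens = c(hb2, hg2, hd2, HE1 = "CE", HE2 = "CE", HZ1 = "NZ",
                  HZ2 = "NZ", HZ3 = "NZ"),
    zmat = list(zcb, zrow("CG", "CB", "CA", "N", 1.53, 113, 180),
                zrow("CD", "CG", "CB", "CA", 1.53, 111, 180),
                zrow("CE", "CD", "CG", "CB", 1.53, 111, 180),
                zrow("NZ", "CE", "CD", "CG", 1.49, 111, 180)))

  # neutral lysine
  tpl$LSN <- make_template("LSN",
    c(CB = -0.18, HB1 = 0.09, HB2 = 0.09, CG = -0.18, HG1 = 0.09,
      HG2 = 0.09, CD = -0.18, HD1 = 0.09, HD2 = 0.09, CE = 0.13,
      HE1 = 0.075, HE2 = 0.075, NZ = -0.96, HZ1 = 0.34, HZ2 = 0.34),
    side_bonds = c("CA CB", "CB CG", "CG CD", "CD CE", "CE NZ",
                   "NZ HZ1", "NZ HZ2"),
    hydrogens = c(hb2, hg2, hd2, HE1 = "CE", HE2 = "CE", HZ1 = "NZ",
                  HZ2 = "NZ"),
    zmat = tpl$LYS$zmat)

  tpl$ARG <- make_template("ARG",
    c(CB = -0.18, HB1 = 0.09, HB2 = 0.09, CG = -0.18, HG1 = 0.09,
      HG2 = 0.09, CD = 0.20, HD1 = 0.09, HD2 = 0.09, NE = -0.70,
      HE = 0.44, CZ = 0.64, NH1 = -0.80, HH11 = 0.46, HH12 = 0.46,
      NH2 = -0.80, HH21 = 0.46, HH22 = 0.46),
    side_bonds = c("CA CB", "CB CG", "CG CD", "CD NE", "NE HE",
                   "NE CZ", "CZ NH1", "CZ NH2", "NH1 HH11", "NH1 HH12",
                   "NH2 HH21", "NH2 HH22"),
    sp2 = c("NE", "CZ", "NH1", "NH2"),
    hydrogens = c(hb2, hg2, hd2, HE = "NE", HH11 = "NH1", HH12 = "NH1",
                  HH21 = "NH2", HH22 = "NH2"),
    zmat = list(zcb, zrow("CG", "CB", "CA", "N", 1.53, 113, 180),
                zrow("CD", "CG", "CB", "CA", 1.53, 111, 180),
                zrow("NE", "CD", "CG", "CB", 1.46, 112, 180),
                zrow("CZ", "NE", "CD", "CG", 1.33, 124, 180),
                zrow("NH1", "CZ", "NE", "CD", 1.33, 120, 0),
                zrow("NH2", "CZ", "NE", "CD", 1.33, 120, 180)))

  his_bonds <- c("CA CB", "CB CG", "CG ND1", "CG CD2", "ND1 CE1",
                 "CE1 NE2", "NE2 CD2")
  his_zmat <- list(zcb, zrow("CG", "CB", "CA", "N", 1.50, 114, 180),
                   zrow("ND1", "CG", "CB", "CA", 1.38, 122, 90),
                   zrow("CE1", "ND1", "CG", "CB", 1.32, 108, 180),
                   zrow("NE2", "CE1", "ND1", "CG", 1.32, 110, 0),
                   zrow("CD2", "NE2", "CE1", "ND1", 1.37, 107, 0))
  his_sp2 <- c("CG", "ND1", "CD2", "CE1", "NE2")

  # delta-protonated neutral His (default tautomer)
  tpl$HSD <- make_template("HSD",
    c(CB = -0.09, HB1 = 0.09, HB2 = 0.09, CG = -0.05, ND1 = -0.36,
      HD1 = 0.32, CE1 = 0.25, HE1 = 0.13, NE2 = -0.70, CD2 = 0.22,
      HD2 = 0.10),
    side_bonds = c(his_bonds, "ND1 HD1"),
    sp2 = his_sp2,
    hydrogens = c(hb2, HD1 = "ND1", HE1 = "CE1", HD2 = "CD2"),
    zmat = his_zmat)

  # epsilon-protonated neutral His
  tpl$HSE <- make_template("HSE",
    c(CB = -0.08, HB1 = 0.09, HB2 = 0.09, CG = 0.22, ND1 = -0.70,
      CE1 = 0.25, HE1 = 0.13, NE2 = -0.36, HE2 = 0.32, CD2 = -0.05,
      HD2 = 0.09),
    side_bonds = c(his_bonds, "NE2 HE2"),
    sp2 = his_sp2,
    hydrogens = c(hb2, HE1 = "CE1", HE2 = "NE2", HD2 = "CD2"),
    zmat = his_zmat)

  # doubly protonated His (+1)
  tpl$HSP <- make_template("HSP",
    c(CB = -0.05, HB1 = 0.09, HB2 = 0.09, CG = 0.19, ND1 = -0.51,
      HD1 = 0.44, CE1 = 0.32, HE1 = 0.18, NE2 = -0.51, HE2 = 0.44,
      CD2 = 0.19, HD2 = 0.13),
    side_bonds = c(his_bonds, "ND1 HD1", "NE2 HE2"),
    sp2 = his_sp2,
    hydrogens = c(hb2, HD1 = "ND1", HE1 = "CE1", HE2 = "NE2",
                  HD2 = "CD2"),
    zmat = his_zmat)

  # deprotonated tyrosine (-1)
  tpl$TYRO <- tpl$TYR
  tpl$TYRO$name <- "TYRO"
  tpl$TYRO$charges <- tpl$TYR$charges[setdiff(names(tpl$TYR$charges), "HH")]
  tpl$TYRO$charges[c("CZ", "OH", "CE1", "CE2")] <-
    c(0.11, -0.76, -0.29, -0.29)
  tpl$TYRO$bonds <- setdiff(tpl$TYR$bonds, "OH HH")
  tpl$TYRO$hydrogens <- tpl$TYR$hydrogens[names(tpl$TYR$hydrogens) != "HH"]
  tpl$TYRO$net <- -1
  stopifnot(abs(sum(tpl$TYRO$charges) + 1) < 1e-6)

  tpl
}

# Good heteroatom templates (no backbone): charges + element radii.
build_het_templates <- function() {
  het <- list(
    HOH = list(charges = c(O = -0.834, H1 = 0.417, H2 = 0.417),
               bonds = c("O H1", "O H2"),
               hydrogens = c(H1 = "O", H2 = "O"), sp2 = character(),
               net = 0),
    SO4 = list(charges = c(S = 1.08, O1 = -0.77, O2 = -0.77,
                           O3 = -0.77, O4 = -0.77),
               bonds = c("S O1", "S O2", "S O3", "S O4"),
               hydrogens = character(), sp2 = character(), net = -2),
    CL = list(charges = c(CL = -1), bonds = character(),
              hydrogens = character(), sp2 = character(), net = -1),
    NA. = list(charges = c(NA. = 1), bonds = character(),
               hydrogens = character(), sp2 = character(), net = 1),
    K = list(charges = c(K = 1), bonds = character(),
             hydrogens = character(), sp2 = character(), net = 1),
    MG = list(charges = c(MG = 2), bonds = character(),
              hydrogens = character(), sp2 = character(), net = 2),
    ZN = list(charges = c(ZN = 2), bonds = character(),
              hydrogens = character(), sp2 = character(), net = 2),
    CA = list(charges = c(CA = 2), bonds = character(),
              hydrogens = character(), sp2 = character(), net = 2))
  names(het)[names(het) == "NA."] <- "NA"
  names(het$`NA`$charges) <- "NA"
  het
}

.tpl_env <- new.env(parent = emptyenv())

templates <- function() {
  if (is.null(.tpl_env$tpl)) .tpl_env$tpl <- build_templates()
  .tpl_env$tpl
}

het_templates <- function() {
  if (is.null(.tpl_env$het)) .tpl_env$het <- build_het_templates()
  .tpl_env$het
}

#' Names of residues the charge/radius templates cover
#' @return character vector of residue template names
#' @export
template_residues <- function() names(templates())

# Amino-acid residue names as they appear in PDB files, mapped to the
# default-protonation template (pH 7: Asp-, Glu-, Lys+, Arg+, His
# neutral delta tautomer).
PDB_TO_TEMPLATE <- c(ALA = "ALA", ARG = "ARG", ASN = "ASN", ASP = "ASP",
                     CYS = "CYS", GLN = "GLN", GLU = "GLU", GLY = "GLY",
                     HIS = "HSD", HSD = "HSD", HSE = "HSE", HSP = "HSP",
                     ILE = "ILE", LEU = "LEU", LYS = "LYS", MET = "MET",
                     PHE = "PHE", PRO = "PRO", SER = "SER", THR = "THR",
                     TRP = "TRP", TYR = "TYR", VAL = "VAL", CYM = "CYM",
                     ASPP = "ASPP", GLUP = "GLUP", LSN = "LSN",
                     TYRO = "TYRO")

is_amino <- function(resname) resname %in% names(PDB_TO_TEMPLATE)

# Radius assignment: polar hydrogens (bonded to N/O/S) get the small
# polar-H radius, everything else its element-class value.
radius_for <- function(atom_name, element, tpl) {
  n <- length(atom_name)
  out <- ELEMENT_RADII[element]
  out[is.na(out)] <- 1.8
  if (!is.null(tpl)) {
    hpar <- tpl$hydrogens
    for (i in seq_len(n)) {
      if (element[i] == "H" && atom_name[i] %in% names(hpar)) {
        parent <- hpar[[atom_name[i]]]
        pel <- substr(parent, 1, 1)
        if (pel %in% c("N", "O", "S")) out[i] <- POLAR_H_RADIUS
      }
    }
  }
  unname(out)
}

# Normalize PDB hydrogen/terminal naming variants to template names.
normalize_atom_name <- function(name) {
  out <- name
  out[out == "H"] <- "HN"
  out[out == "OXT"] <- "OT2"
  # 1HB -> HB1 style
  m <- grepl("^[0-9]", out) & grepl("H", out)
  out[m] <- paste0(substr(out[m], 2, nchar(out[m])), substr(out[m], 1, 1))
  out
}
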