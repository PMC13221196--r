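# Builds inst/extdata/ff14sb_subset.csv, the embedded nonbonded parameter subset
# (Amber ff94/ff99 partial charges as retained by ff14SB, Amber LJ well types).
# Each row: res_name, atom_name, charge_e, sigma_A, epsilon_kcal_mol,
# bonded_heavy_atom (non-empty only for hydrogens).
#
# Run from the package root:  Rscript data-raw/make_ff_table.R

# Amber LJ types: Rmin/2 (A), epsilon (kcal/mol). sigma = 2*(Rmin/2)/2^(1/6).
lj_types <- list(
  N  = c(1.8240, 0.1700), N2 = c(1.8240, 0.1700), N3 = c(1.8240, 0.1700),
  NA. = c(1.8240, 0.1700), NB = c(1.8240, 0.1700),
  C  = c(1.9080, 0.0860), CA = c(1.9080, 0.0860), CB = c(1.9080, 0.0860),
  CC = c(1.9080, 0.0860), CN = c(1.9080, 0.0860), CR = c(1.9080, 0.0860),
  CV = c(1.9080, 0.0860), CW = c(1.9080, 0.0860), Cstar = c(1.9080, 0.0860),
  CT = c(1.9080, 0.1094),
  O  = c(1.6612, 0.2100), O2 = c(1.6612, 0.2100), OH = c(1.7210, 0.2104),
  S  = c(2.0000, 0.2500), SH = c(2.0000, 0.2500),
  H  = c(0.6000, 0.0157), HO = c(0.2000, 0.0000), HS = c(0.6000, 0.0157),
  HC = c(1.4870, 0.0157), H1 = c(1.3870, 0.0157), HP = c(1.1000, 0.0157),
  HA = c(1.4590, 0.0150), H4 = c(1.4090, 0.0150), H5 = c(1.3590, 0.0150)
)

row_ <- function(atom, charge, type, bh = "") {
  data.frame(atom_name = atom, charge_e = charge, type = type,
             bonded_heavy_atom = bh, stringsAsFactors = FALSE)
}

# backbone block; flavor selects the charge set shared by residue families
backbone <- function(ca, ha, flavor = c("neutral", "acid", "base")) {
  flavor <- match.arg(flavor)
  bb <- switch(flavor,
    neutral = list(N = -0.4157, H = 0.2719, C = 0.5973, O = -0.5679),
    acid    = list(N = -0.5163, H = 0.2936, C = 0.5366, O = -0.5819),
    base    = list(N = -0.3479, H = 0.2747, C = 0.7341, O = -0.5894))
  rbind(
    row_("N", bb$N, "N"), row_("H", bb$H, "H", "N"),
    row_("CA", ca, "CT"), row_("HA", ha, "H1", "CA"),
    row_("C", bb$C, "C"), row_("O", bb$O, "O"))
}

h3 <- function(stem, q, type, bh) {
  rbind(row_(paste0(stem, "1"), q, type, bh),
        row_(paste0(stem, "2"), q, type, bh),
        row_(paste0(stem, "3"), q, type, bh))
}
h2 <- function(stem, q, type, bh) {
  rbind(row_(paste0(stem, "2"), q, type, bh),
        row_(paste0(stem, "3"), q, type, bh))
}

res <- list()

res$ALA <- rbind(backbone(0.0337, 0.0823),
  row_("CB", -0.1825, "CT"), h3("HB", 0.0603, "HC", "CB"))

res$GLY <- rbind(
  row_("N", -0.4157, "N"), row_("H", 0.2719, "H", "N"),
  row_("CA", -0.0252, "CT"), h2("HA", 0.0698, "H1", "CA"),
  row_("C", 0.5973, "C"), row_("O", -0.5679, "O"))

res$SER <- rbind(backbone(-0.0249, 0.0843),
  row_("CB", 0.2117, "CT"), h2("HB", 0.0352, "H1", "CB"),
  row_("OG", -0.6546, "OH"), row_("HG", 0.4275, "HO", "OG"))

res$THR <- rbind(backbone(-0.0389, 0.1007),
  row_("CB", 0.3654, "CT"), row_("HB", 0.0043, "H1", "CB"),
  row_("CG2", -0.2438, "CT"), h3("HG2", 0.0642, "HC", "CG2"),
  row_("OG1", -0.6761, "OH"), row_("HG1", 0.4102, "HO", "OG1"))

res$CYS <- rbind(backbone(0.0213, 0.1124),
  row_("CB", -0.1231, "CT"), h2("HB", 0.1112, "H1", "CB"),
  row_("SG", -0.3119, "SH"), row_("HG", 0.1933, "HS", "SG"))

res$VAL <- rbind(backbone(-0.0875, 0.0969),
  row_("CB", 0.2985, "CT"), row_("HB", -0.0297, "HC", "CB"),
  row_("CG1", -0.3192, "CT"), h3("HG1", 0.0791, "HC", "CG1"),
  row_("CG2", -0.3192, "CT"), h3("HG2", 0.0791, "HC", "CG2"))

res$LEU <- rbind(backbone(-0.0518, 0.0922),
  row_("CB", -0.1102, "CT"), h2("HB", 0.0457, "HC", "CB"),
  row_("CG", 0.3531, "CT"), row_("HG", -0.0361, "HC", "CG"),
  row_("CD1", -0.4121, "CT"), h3("HD1", 0.1000, "HC", "CD1"),
  row_("CD2", -0.4121, "CT"), h3("HD2", 0.1000, "HC", "CD2"))

res$ILE <- rbind(backbone(-0.0597, 0.0869),
  row_("CB", 0.1303, "CT"), row_("HB", 0.0187, "HC", "CB"),
  row_("CG2", -0.3204, "CT"), h3("HG2", 0.0882, "HC", "CG2"),
  row_("CG1", -0.0430, "CT"),
  row_("HG12", 0.0236, "HC", "CG1"), row_("HG13", 0.0236, "HC", "CG1"),
  row_("CD1", -0.0660, "CT"), h3("HD1", 0.0186, "HC", "CD1"))

res$MET <- rbind(backbone(-0.0237, 0.0880),
  row_("CB", 0.0342, "CT"), h2("HB", 0.0241, "HC", "CB"),
  row_("CG", 0.0018, "CT"), h2("HG", 0.0440, "H1", "CG"),
  row_("SD", -0.2737, "S"),
  row_("CE", -0.0536, "CT"), h3("HE", 0.0684, "H1", "CE"))

res$PRO <- rbind(
  row_("N", -0.2548, "N"),
  row_("CD", 0.0192, "CT"), h2("HD", 0.0391, "H1", "CD"),
  row_("CG", 0.0189, "CT"), h2("HG", 0.0213, "HC", "CG"),
  row_("CB", -0.0070, "CT"), h2("HB", 0.0253, "HC", "CB"),
  row_("CA", -0.0266, "CT"), row_("HA", 0.0641, "H1", "CA"),
  row_("C", 0.5896, "C"), row_("O", -0.5748, "O"))

res$PHE <- rbind(backbone(-0.0024, 0.0978),
  row_("CB", -0.0343, "CT"), h2("HB", 0.0295, "HC", "CB"),
  row_("CG", 0.0118, "CA"),
  row_("CD1", -0.1256, "CA"), row_("HD1", 0.1330, "HA", "CD1"),
  row_("CD2", -0.1256, "CA"), row_("HD2", 0.1330, "HA", "CD2"),
  row_("CE1", -0.1704, "CA"), row_("HE1", 0.1430, "HA", "CE1"),
  row_("CE2", -0.1704, "CA"), row_("HE2", 0.1430, "HA", "CE2"),
  row_("CZ", -0.1072, "CA"), row_("HZ", 0.1297, "HA", "CZ"))

res$TYR <- rbind(backbone(-0.0014, 0.0876),
  row_("CB", -0.0152, "CT"), h2("HB", 0.0295, "HC", "CB"),
  row_("CG", -0.0011, "CA"),
  row_("CD1", -0.1906, "CA"), row_("HD1", 0.1699, "HA", "CD1"),
  row_("CD2", -0.1906, "CA"), row_("HD2", 0.1699, "HA", "CD2"),
  row_("CE1", -0.2341, "CA"), row_("HE1", 0.1656, "HA", "CE1"),
  row_("CE2", -0.2341, "CA"), row_("HE2", 0.1656, "HA", "CE2"),
  row_("CZ", 0.3226, "C"),
  row_("OH", -0.5579, "OH"), row_("HH", 0.3992, "HO", "OH"))

res$TRP <- rbind(backbone(-0.0275, 0.1123),
  row_("CB", -0.0050, "CT"), h2("HB", 0.0339, "HC", "CB"),
  row_("CG", -0.1415, "Cstar"),
  row_("CD1", -0.1638, "CW"), row_("HD1", 0.2062, "H4", "CD1"),
  row_("NE1", -0.3418, "NA."), row_("HE1", 0.3412, "H", "NE1"),
  row_("CE2", 0.1380, "CN"),
  row_("CZ2", -0.2601, "CA"), row_("HZ2", 0.1572, "HA", "CZ2"),
  row_("CH2", -0.1134, "CA"), row_("HH2", 0.1417, "HA", "CH2"),
  row_("CZ3", -0.1972, "CA"), row_("HZ3", 0.1447, "HA", "CZ3"),
  row_("CE3", -0.2387, "CA"), row_("HE3", 0.1700, "HA", "CE3"),
  row_("CD2", 0.1243, "CB"))

res$ASN <- rbind(backbone(0.0143, 0.1048),
  row_("CB", -0.2041, "CT"), h2("HB", 0.0797, "HC", "CB"),
  row_("CG", 0.7130, "C"), row_("OD1", -0.5931, "O"),
  row_("ND2", -0.9191, "N"),
  row_("HD21", 0.4196, "H", "ND2"), row_("HD22", 0.4196, "H", "ND2"))

res$GLN <- rbind(backbone(-0.0031, 0.0850),
  row_("CB", -0.0036, "CT"), h2("HB", 0.0171, "HC", "CB"),
  row_("CG", -0.0645, "CT"), h2("HG", 0.0352, "HC", "CG"),
  row_("CD", 0.6951, "C"), row_("OE1", -0.6086, "O"),
  row_("NE2", -0.9407, "N"),
  row_("HE21", 0.4251, "H", "NE2"), row_("HE22", 0.4251, "H", "NE2"))

res$ASP <- rbind(backbone(0.0381, 0.0880, "acid"),
  row_("CB", -0.0303, "CT"), h2("HB", -0.0122, "HC", "CB"),
  row_("CG", 0.7994, "C"),
  row_("OD1", -0.8014, "O2"), row_("OD2", -0.8014, "O2"))

res$GLU <- rbind(backbone(0.0397, 0.1105, "acid"),
  row_("CB", 0.0560, "CT"), h2("HB", -0.0173, "HC", "CB"),
  row_("CG", 0.0136, "CT"), h2("HG", -0.0425, "HC", "CG"),
  row_("CD", 0.8054, "C"),
  row_("OE1", -0.8188, "O2"), row_("OE2", -0.8188, "O2"))

res$LYS <- rbind(backbone(-0.2400, 0.1426, "base"),
  row_("CB", -0.0094, "CT"), h2("HB", 0.0362, "HC", "CB"),
  row_("CG", 0.0187, "CT"), h2("HG", 0.0103, "HC", "CG"),
  row_("CD", -0.0479, "CT"), h2("HD", 0.0621, "HC", "CD"),
  row_("CE", -0.0143, "CT"), h2("HE", 0.1135, "HP", "CE"),
  row_("NZ", -0.3854, "N3"), h3("HZ", 0.3400, "H", "NZ"))

res$ARG <- rbind(backbone(-0.2637, 0.1560, "base"),
  row_("CB", -0.0007, "CT"), h2("HB", 0.0327, "HC", "CB"),
  row_("CG", 0.0390, "CT"), h2("HG", 0.0285, "HC", "CG"),
  row_("CD", 0.0486, "CT"), h2("HD", 0.0687, "H1", "CD"),
  row_("NE", -0.5295, "N2"), row_("HE", 0.3456, "H", "NE"),
  row_("CZ", 0.8076, "CA"),
  row_("NH1", -0.8627, "N2"),
  row_("HH11", 0.4478, "H", "NH1"), row_("HH12", 0.4478, "H", "NH1"),
  row_("NH2", -0.8627, "N2"),
  row_("HH21", 0.4478, "H", "NH2"), row_("HH22", 0.4478, "H", "NH2"))

# Histidine tautomers: HIE (NE2-protonated, the pH 7 default), HID, HIP (+1).
res$HIE <- rbind(backbone(-0.0581, 0.1360),
  row_("CB", -0.0074, "CT"), h2("HB", 0.0367, "HC", "CB"),
  row_("CG", 0.1868, "CC"),
  row_("ND1", -0.5432, "NB"),
  row_("CE1", 0.1635, "CR"), row_("HE1", 0.1435, "H5", "CE1"),
  row_("NE2", -0.2795, "NA."), row_("HE2", 0.3339, "H", "NE2"),
  row_("CD2", -0.2207, "CW"), row_("HD2", 0.1862, "H4", "CD2"))

res$HID <- rbind(backbone(0.0188, 0.0881),
  row_("CB", -0.0462, "CT"), h2("HB", 0.0402, "HC", "CB"),
  row_("CG", -0.0266, "CC"),
  row_("ND1", -0.3811, "NA."), row_("HD1", 0.3649, "H", "ND1"),
  row_("CE1", 0.2057, "CR"), row_("HE1", 0.1392, "H5", "CE1"),
  row_("NE2", -0.5727, "NB"),
  row_("CD2", 0.1292, "CV"), row_("HD2", 0.1147, "H4", "CD2"))

res$HIP <- rbind(backbone(-0.1354, 0.1212, "base"),
  row_("CB", -0.0414, "CT"), h2("HB", 0.0810, "HC", "CB"),
  row_("CG", -0.0012, "CC"),
  row_("ND1", -0.1513, "NA."), row_("HD1", 0.3866, "H", "ND1"),
  row_("CE1", -0.0170, "CR"), row_("HE1", 0.2681, "H5", "CE1"),
  row_("NE2", -0.1718, "NA."), row_("HE2", 0.3911, "H", "NE2"),
  row_("CD2", -0.1141, "CW"), row_("HD2", 0.2317, "H4", "CD2"))

tab <- do.call(rbind, lapply(names(res), function(rn) {
  d <- res[[rn]]
  lj <- t(vapply(d$type, function(ty) lj_types[[ty]], numeric(2)))
  data.frame(res_name = rn, atom_name = d$atom_name,
             charge_e = d$charge_e,
             sigma_A = round(2 * lj[, 1] / 2^(1 / 6), 6),
             epsilon_kcal_mol = lj[, 2],
             bonded_heavy_atom = d$bonded_heavy_atom,
             stringsAsFactors = FALSE)
}))
rownames(tab) <- NULL

# formal charges
formal <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1, HIP = 1)
net <- tapply(tab$charge_e, tab$res_name, sum)
for (rn in names(net)) {
  want <- if (rn %in% names(formal)) formal[[rn]] else 0
  if (abs(net[[rn]] - want) > 1e-3)
    stop(sprintf("%s net charge %.4f != %d", rn, net[[rn]], want))
}
stopifnot(!anyDuplicated(tab[c("res_name", "atom_name")]))

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.csv(tab, "inst/extdata/ff14sb_subset.csv", row.names = FALSE, quote = FALSE)
cat(sprintf("wrote %d rows for %d residue templates\n",
            nrow(tab), length(unique(tab$res_name))))
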