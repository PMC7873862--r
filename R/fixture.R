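#' Demo fixture: a compact oleaginous-yeast metabolic model
#'
#' A hand-curated, fully mass- and charge-balanced network (~110
#' reactions, compartments c/m/x/e/r/l) built to exercise every stage of
#' the package on a realistic but desk-scale problem.  It contains:
#'
#' * a glycolysis / pentose-phosphate / TCA / oxidative-phosphorylation
#'   skeleton with ATP-citrate lyase supplying cytosolic acetyl-CoA (the
#'   oleaginous-yeast route) and ubiquinone-9 (nine isoprenyl units) as
#'   the respiratory quinone;
#' * the pentose utilization route through D-arabinitol and D-ribulose to
#'   D-ribulose-5-phosphate (genes 9774/13562 reductase, 12977/12974
#'   dehydrogenases, 9837/8905 D-arabinitol 4-dehydrogenase, 9990
#'   D-arabinitol 2-dehydrogenase, 14368 D-ribulose kinase), plus the
#'   conventional xylulokinase (16850) whose product is deliberately left
#'   unconnected -- the enzyme is not expressed in vivo, and here its
#'   route dead-ends so that flux must pass through the arabinitol loop;
#' * L-arabinose entry via L-arabinitol and L-xylulose to xylitol
#'   (genes 13562/9774, 12974, 8988);
#' * peroxisomal p-coumarate degradation by a beta-oxidation-like route
#'   (CoA activation 12555/16635, hydration 16515, NAD-dependent
#'   oxidation 9469, thiolysis 9065, thioesterase 14934) to
#'   4-hydroxybenzoate, cytosolic hydroxylation to protocatechuate
#'   (12923), ortho-cleavage (12623), lactonization/decarboxylation
#'   (12622, 12620), mitochondrial import on the oxodicarboxylate
#'   carrier (10635) and conversion to succinyl-CoA + acetyl-CoA
#'   (13090, 15228);
#' * lumped fatty-acid synthesis (palmitate, oleate, linoleate),
#'   triacylglycerol and ergosteryl-ester formation into the lipid
#'   droplet, and the biomass/demand/sink wiring produced by
#'   [assemble_biomass()] from a segmented-regression fit of the
#'   packaged fatty-acid composition data.
#'
#' The model grows on glucose, D-xylose, L-arabinose, D-arabinitol and
#' p-coumarate as sole carbon sources (see [demo_media()]).
#'
#' @param with_biomass attach the biomass objective and lipid-droplet
#'   demand/sink reactions (default TRUE).
#' @return a `metabolic_model`.
#' @export
demo_model <- function(with_biomass = TRUE) {
  model <- new_model("rt_demo", c(
    c = "cytosol", m = "mitochondrion", x = "peroxisome",
    e = "extracellular", r = "endoplasmic reticulum", l = "lipid droplet"))

  M <- list(
    # id_base, formula, charge, name, compartments
    list("glc__D", "C6H12O6", 0, "D-glucose", c("c", "e")),
    list("g6p", "C6H11O9P", -2, "D-glucose 6-phosphate", "c"),
    list("f6p", "C6H11O9P", -2, "D-fructose 6-phosphate", "c"),
    list("fdp", "C6H10O12P2", -4, "D-fructose 1,6-bisphosphate", "c"),
    list("dhap", "C3H5O6P", -2, "dihydroxyacetone phosphate", "c"),
    list("g3p", "C3H5O6P", -2, "glyceraldehyde 3-phosphate", "c"),
    list("13dpg", "C3H4O10P2", -4, "1,3-bisphosphoglycerate", "c"),
    list("3pg", "C3H4O7P", -3, "3-phosphoglycerate", "c"),
    list("2pg", "C3H4O7P", -3, "2-phosphoglycerate", "c"),
    list("pep", "C3H2O6P", -3, "phosphoenolpyruvate", "c"),
    list("pyr", "C3H3O3", -1, "pyruvate", c("c", "m")),
    list("6pgl", "C6H9O9P", -2, "6-phosphogluconolactone", "c"),
    list("6pgc", "C6H10O10P", -3, "6-phosphogluconate", "c"),
    list("ru5p__D", "C5H9O8P", -2, "D-ribulose 5-phosphate", "c"),
    list("xu5p__D", "C5H9O8P", -2, "D-xylulose 5-phosphate", "c"),
    list("xyl__D", "C5H10O5", 0, "D-xylose", c("c", "e")),
    list("xylt", "C5H12O5", 0, "xylitol", "c"),
    list("xylu__D", "C5H10O5", 0, "D-xylulose", "c"),
    list("abt__D", "C5H12O5", 0, "D-arabinitol", c("c", "e")),
    list("rbl__D", "C5H10O5", 0, "D-ribulose", "c"),
    list("arab__L", "C5H10O5", 0, "L-arabinose", c("c", "e")),
    list("abt__L", "C5H12O5", 0, "L-arabinitol", "c"),
    list("xylu__L", "C5H10O5", 0, "L-xylulose", "c"),
    list("atp", "C10H12N5O13P3", -4, "ATP", c("c", "m", "x")),
    list("adp", "C10H12N5O10P2", -3, "ADP", c("c", "m", "x")),
    list("pi", "HO4P", -2, "phosphate", c("c", "m", "x", "e")),
    list("h", "H", 1, "proton", c("c", "m", "x", "e")),
    list("h2o", "H2O", 0, "water", c("c", "m", "x", "e")),
    list("co2", "CO2", 0, "carbon dioxide", c("c", "m", "e")),
    list("o2", "O2", 0, "oxygen", c("c", "m", "e")),
    list("nh4", "H4N", 1, "ammonium", c("c", "e")),
    list("nad", "C21H26N7O14P2", -1, "NAD+", c("c", "m", "x")),
    list("nadh", "C21H27N7O14P2", -2, "NADH", c("c", "m", "x")),
    list("nadp", "C21H25N7O17P3", -3, "NADP+", c("c", "m")),
    list("nadph", "C21H26N7O17P3", -4, "NADPH", c("c", "m")),
    list("coa", "C21H32N7O16P3S", -4, "coenzyme A", c("c", "m", "x")),
    list("accoa", "C23H34N7O17P3S", -4, "acetyl-CoA", c("c", "m", "x")),
    list("oaa", "C4H2O5", -2, "oxaloacetate", c("c", "m")),
    list("cit", "C6H5O7", -3, "citrate", c("c", "m")),
    list("icit", "C6H5O7", -3, "isocitrate", "m"),
    list("akg", "C5H4O5", -2, "2-oxoglutarate", c("c", "m")),
    list("succoa", "C25H35N7O19P3S", -5, "succinyl-CoA", "m"),
    list("succ", "C4H4O4", -2, "succinate", "m"),
    list("fum", "C4H2O4", -2, "fumarate", "m"),
    list("mal__L", "C4H4O5", -2, "L-malate", c("c", "m")),
    list("q9", "C54H82O4", 0, "ubiquinone-9 (9 isoprenyl units)", "m"),
    list("q9h2", "C54H84O4", 0, "ubiquinol-9 (9 isoprenyl units)", "m"),
    list("glu__L", "C5H8NO4", -1, "L-glutamate", "c"),
    list("ala__L", "C3H7NO2", 0, "L-alanine", "c"),
    list("asp__L", "C4H6NO4", -1, "L-aspartate", "c"),
    list("glucan", "C6H10O5", 0, "glycogen (glucan residue)", "c"),
    list("glyc", "C3H8O3", 0, "glycerol", "c"),
    list("glyc3p", "C3H7O6P", -2, "glycerol 3-phosphate", "c"),
    list("hdca", "C16H31O2", -1, "palmitate (C16:0)", "c"),
    list("ocdcea", "C18H33O2", -1, "oleate (C18:1)", "c"),
    list("lnlc", "C18H31O2", -1, "linoleate (C18:2)", "c"),
    list("ergst", "C28H44O", 0, "ergosterol", "r"),
    list("tag_hdca", "C51H98O6", 0, "tripalmitoylglycerol", "l"),
    list("tag_ocdcea", "C57H104O6", 0, "trioleoylglycerol", "l"),
    list("tag_lnlc", "C57H98O6", 0, "trilinoleoylglycerol", "l"),
    list("se", "C46H76O2", 0, "ergosteryl oleate", "l"),
    list("T4hcinnm", "C9H7O3", -1, "p-coumarate (trans-4-hydroxycinnamate)",
         c("c", "x", "e")),
    list("coucoa", "C30H38N7O18P3S", -4, "p-coumaroyl-CoA", "x"),
    list("hcoucoa", "C30H40N7O19P3S", -4,
         "3-hydroxy-3-(4-hydroxyphenyl)propanoyl-CoA", "x"),
    list("ocoucoa", "C30H38N7O19P3S", -4,
         "3-oxo-3-(4-hydroxyphenyl)propanoyl-CoA", "x"),
    list("4hbzcoa", "C28H36N7O18P3S", -4, "4-hydroxybenzoyl-CoA", "x"),
    list("4hbz", "C7H5O3", -1, "4-hydroxybenzoate", c("c", "x", "m")),
    list("34dhbz", "C7H5O4", -1, "protocatechuate (3,4-dihydroxybenzoate)", "c"),
    list("3cmuc", "C7H3O6", -3, "3-carboxy-cis,cis-muconate", "c"),
    list("cmuclac", "C7H4O6", -2, "4-carboxymuconolactone", "c"),
    list("3oxoadp", "C6H6O5", -2, "3-oxoadipate", c("c", "m")),
    list("3oxoadpcoa", "C27H37N7O20P3S", -5, "3-oxoadipyl-CoA", "m")
  )
  for (m in M) {
    for (comp in m[[5]]) {
      model <- add_metabolite(model, paste0(m[[1]], "_", comp),
                              name = m[[4]], formula = m[[2]],
                              charge = m[[3]], compartment = comp)
    }
  }

  rx <- function(id, st, lb = 0, ub = 1000, gpr = NULL, kind = "metabolic",
                 sub = "") {
    model <<- add_reaction(model, id, st, lower_bound = lb, upper_bound = ub,
                           gpr = gpr, kind = kind, subsystem = sub)
  }

  ## exchanges (uptake bounds define the default glucose minimal medium)
  ex <- function(met, lb) rx(paste0("EX_", met), stats::setNames(-1, met),
                             lb = lb, ub = 1000, kind = "exchange",
                             sub = "Exchange")
  ex("glc__D_e", -10); ex("xyl__D_e", 0); ex("arab__L_e", 0)
  ex("abt__D_e", 0); ex("T4hcinnm_e", 0)
  ex("nh4_e", -1000); ex("pi_e", -1000); ex("o2_e", -1000)
  ex("co2_e", 0); ex("h2o_e", -1000); ex("h_e", -1000)

  ## plasma-membrane transport
  rx("GLCt", c(glc__D_e = -1, glc__D_c = 1), gpr = "10452", kind = "transport",
     sub = "Transport")
  rx("XYLt", c(xyl__D_e = -1, xyl__D_c = 1), gpr = "12976", kind = "transport",
     sub = "Transport")
  rx("ARABt", c(arab__L_e = -1, arab__L_c = 1), gpr = "12976",
     kind = "transport", sub = "Transport")
  rx("ABTt", c(abt__D_e = -1, abt__D_c = 1), gpr = "12976",
     kind = "transport", sub = "Transport")
  rx("COUMt", c(T4hcinnm_e = -1, T4hcinnm_c = 1), gpr = "13229",
     kind = "transport", sub = "Transport")
  rx("NH4t", c(nh4_e = -1, nh4_c = 1), kind = "transport", sub = "Transport")
  rx("PIt", c(pi_e = -1, pi_c = 1), kind = "transport", sub = "Transport")
  rx("O2t", c(o2_e = -1, o2_c = 1), lb = -1000, kind = "transport",
     sub = "Transport")
  rx("CO2t", c(co2_c = -1, co2_e = 1), lb = -1000, kind = "transport",
     sub = "Transport")
  rx("H2Ot", c(h2o_e = -1, h2o_c = 1), lb = -1000, kind = "transport",
     sub = "Transport")
  rx("Ht", c(h_e = -1, h_c = 1), lb = -1000, kind = "transport",
     sub = "Transport")

  ## glycolysis / gluconeogenesis / anaplerosis
  rx("HEX1", c(glc__D_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1, h_c = 1),
     gpr = "10001", sub = "Glycolysis")
  rx("PGI", c(g6p_c = -1, f6p_c = 1), lb = -1000, gpr = "10002",
     sub = "Glycolysis")
  rx("PFK", c(f6p_c = -1, atp_c = -1, fdp_c = 1, adp_c = 1, h_c = 1),
     gpr = "10003", sub = "Glycolysis")
  rx("FBP", c(fdp_c = -1, h2o_c = -1, f6p_c = 1, pi_c = 1), gpr = "10004",
     sub = "Glycolysis")
  rx("FBA", c(fdp_c = -1, dhap_c = 1, g3p_c = 1), lb = -1000, gpr = "10005",
     sub = "Glycolysis")
  rx("TPI", c(dhap_c = -1, g3p_c = 1), lb = -1000, gpr = "10006",
     sub = "Glycolysis")
  rx("GAPD", c(g3p_c = -1, nad_c = -1, pi_c = -1, `13dpg_c` = 1,
               nadh_c = 1, h_c = 1), lb = -1000, gpr = "10007",
     sub = "Glycolysis")
  rx("PGK", c(`13dpg_c` = -1, adp_c = -1, `3pg_c` = 1, atp_c = 1),
     lb = -1000, gpr = "10008", sub = "Glycolysis")
  rx("PGM", c(`3pg_c` = -1, `2pg_c` = 1), lb = -1000, gpr = "10009",
     sub = "Glycolysis")
  rx("ENO", c(`2pg_c` = -1, pep_c = 1, h2o_c = 1), lb = -1000, gpr = "10010",
     sub = "Glycolysis")
  rx("PYK", c(pep_c = -1, adp_c = -1, h_c = -1, pyr_c = 1, atp_c = 1),
     gpr = "10011", sub = "Glycolysis")
  rx("PC", c(pyr_c = -1, atp_c = -1, co2_c = -1, h2o_c = -1, oaa_c = 1,
             adp_c = 1, pi_c = 1, h_c = 2), gpr = "10012",
     sub = "Anaplerosis")
  rx("PPCK", c(oaa_c = -1, atp_c = -1, pep_c = 1, co2_c = 1, adp_c = 1),
     gpr = "10013", sub = "Anaplerosis")

  ## pentose phosphate pathway
  rx("G6PDH2", c(g6p_c = -1, nadp_c = -1, `6pgl_c` = 1, nadph_c = 1, h_c = 1),
     gpr = "10014", sub = "Pentose phosphate pathway")
  rx("PGL", c(`6pgl_c` = -1, h2o_c = -1, `6pgc_c` = 1, h_c = 1),
     gpr = "10015", sub = "Pentose phosphate pathway")
  rx("GND", c(`6pgc_c` = -1, nadp_c = -1, ru5p__D_c = 1, co2_c = 1,
              nadph_c = 1), gpr = "10016", sub = "Pentose phosphate pathway")
  rx("PPPNOX", c(ru5p__D_c = -3, f6p_c = 2, g3p_c = 1), lb = -1000,
     gpr = "10017", sub = "Pentose phosphate pathway")

  ## pentose sugar and alcohol utilization (arabinitol/ribulose route)
  rx("XYLR", c(xyl__D_c = -1, nadph_c = -1, h_c = -1, xylt_c = 1,
               nadp_c = 1), gpr = "9774 or 13562",
     sub = "Pentose utilization")
  rx("XYLTD", c(xylt_c = -1, nad_c = -1, xylu__D_c = 1, nadh_c = 1, h_c = 1),
     gpr = "12977 or 12974", sub = "Pentose utilization")
  rx("XYLUR", c(xylu__D_c = -1, nadph_c = -1, h_c = -1, abt__D_c = 1,
                nadp_c = 1), gpr = "9837 or 8905", sub = "Pentose utilization")
  rx("ABTD2", c(abt__D_c = -1, nad_c = -1, rbl__D_c = 1, nadh_c = 1, h_c = 1),
     gpr = "9990", sub = "Pentose utilization")
  rx("RBK", c(rbl__D_c = -1, atp_c = -1, ru5p__D_c = 1, adp_c = 1, h_c = 1),
     gpr = "14368", sub = "Pentose utilization")
  rx("XYLK", c(xylu__D_c = -1, atp_c = -1, xu5p__D_c = 1, adp_c = 1, h_c = 1),
     gpr = "16850", sub = "Pentose utilization")
  rx("ARABR", c(arab__L_c = -1, nadph_c = -1, h_c = -1, abt__L_c = 1,
                nadp_c = 1), gpr = "13562 or 9774", sub = "Pentose utilization")
  rx("ABTLD", c(abt__L_c = -1, nad_c = -1, xylu__L_c = 1, nadh_c = 1,
                h_c = 1), gpr = "12974", sub = "Pentose utilization")
  rx("XYLLR", c(xylu__L_c = -1, nadph_c = -1, h_c = -1, xylt_c = 1,
                nadp_c = 1), gpr = "8988", sub = "Pentose utilization")

  ## pyruvate oxidation and TCA cycle (mitochondrion)
  rx("PYRtm", c(pyr_c = -1, h_c = -1, pyr_m = 1, h_m = 1), kind = "transport",
     sub = "Transport, mitochondrial")
  rx("PDHm", c(pyr_m = -1, coa_m = -1, nad_m = -1, accoa_m = 1, co2_m = 1,
               nadh_m = 1), gpr = "10021 and 10022", sub = "TCA cycle")
  rx("CSm", c(accoa_m = -1, h2o_m = -1, oaa_m = -1, cit_m = 1, coa_m = 1,
              h_m = 1), gpr = "10023", sub = "TCA cycle")
  rx("ACONTm", c(cit_m = -1, icit_m = 1), lb = -1000, gpr = "10024",
     sub = "TCA cycle")
  rx("ICDHxm", c(icit_m = -1, nad_m = -1, akg_m = 1, co2_m = 1, nadh_m = 1),
     gpr = "10025", sub = "TCA cycle")
  rx("ICDHym", c(icit_m = -1, nadp_m = -1, akg_m = 1, co2_m = 1, nadph_m = 1),
     gpr = "10057", sub = "TCA cycle")
  rx("AKGDHm", c(akg_m = -1, coa_m = -1, nad_m = -1, succoa_m = 1, co2_m = 1,
                 nadh_m = 1), gpr = "10026 and 10027", sub = "TCA cycle")
  rx("SUCOAS", c(succoa_m = -1, adp_m = -1, pi_m = -1, succ_m = 1, coa_m = 1,
                 atp_m = 1), lb = -1000, gpr = "10028", sub = "TCA cycle")
  rx("SUCDm", c(succ_m = -1, q9_m = -1, fum_m = 1, q9h2_m = 1),
     gpr = "10029 and 10030", sub = "TCA cycle")
  rx("FUMm", c(fum_m = -1, h2o_m = -1, mal__L_m = 1), lb = -1000,
     gpr = "10031", sub = "TCA cycle")
  rx("MDHm", c(mal__L_m = -1, nad_m = -1, oaa_m = 1, nadh_m = 1, h_m = 1),
     lb = -1000, gpr = "10032", sub = "TCA cycle")

  ## mitochondrial transport and shuttles
  rx("CITtm", c(cit_m = -1, cit_c = 1), kind = "transport",
     sub = "Transport, mitochondrial")
  rx("MALtm", c(mal__L_c = -1, mal__L_m = 1), lb = -1000, kind = "transport",
     sub = "Transport, mitochondrial")
  rx("AKGMALtm", c(akg_m = -1, mal__L_c = -1, akg_c = 1, mal__L_m = 1),
     lb = -1000, gpr = "10047", kind = "transport",
     sub = "Transport, mitochondrial")
  rx("ATPADPtm", c(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1),
     gpr = "10042", kind = "transport", sub = "Transport, mitochondrial")
  rx("PItm", c(pi_c = -1, h_c = -1, pi_m = 1, h_m = 1), gpr = "10043",
     kind = "transport", sub = "Transport, mitochondrial")
  rx("O2tm", c(o2_c = -1, o2_m = 1), lb = -1000, kind = "transport",
     sub = "Transport, mitochondrial")
  rx("CO2tm", c(co2_m = -1, co2_c = 1), lb = -1000, kind = "transport",
     sub = "Transport, mitochondrial")
  rx("H2Otm", c(h2o_c = -1, h2o_m = 1), lb = -1000, kind = "transport",
     sub = "Transport, mitochondrial")

  ## oxidative phosphorylation (protons pumped to the cytosolic face)
  rx("NADH9m", c(nadh_m = -1, q9_m = -1, h_m = -5, nad_m = 1, q9h2_m = 1,
                 h_c = 4), gpr = "10035 and 10036 and 10037",
     sub = "Oxidative phosphorylation")
  rx("CYOO9m", c(q9h2_m = -2, o2_m = -1, h_m = -12, q9_m = 2, h2o_m = 2,
                 h_c = 12), gpr = "10038 and 10039",
     sub = "Oxidative phosphorylation")
  rx("ATPS4m", c(adp_m = -1, pi_m = -1, h_c = -4, atp_m = 1, h2o_m = 1,
                 h_m = 3), gpr = "10040 and 10041",
     sub = "Oxidative phosphorylation")
  # external (cytosolic-face) NADH dehydrogenase: no proton pumping
  rx("NDE1", c(nadh_c = -1, h_c = -1, q9_m = -1, nad_c = 1, q9h2_m = 1),
     gpr = "10058", sub = "Oxidative phosphorylation")

  ## cytosolic acetyl-CoA, amino acids, storage carbohydrate
  rx("ACITL", c(atp_c = -1, cit_c = -1, coa_c = -1, accoa_c = 1, adp_c = 1,
                oaa_c = 1, pi_c = 1), gpr = "10033",
     sub = "Cytosolic acetyl-CoA")
  rx("MDHc", c(mal__L_c = -1, nad_c = -1, oaa_c = 1, nadh_c = 1, h_c = 1),
     lb = -1000, gpr = "10034", sub = "Cytosolic acetyl-CoA")
  rx("GLUDy", c(akg_c = -1, nh4_c = -1, nadph_c = -1, h_c = -1, glu__L_c = 1,
                h2o_c = 1, nadp_c = 1), lb = -1000, gpr = "10044",
     sub = "Amino acid biosynthesis")
  rx("ALATA", c(pyr_c = -1, glu__L_c = -1, ala__L_c = 1, akg_c = 1),
     lb = -1000, gpr = "10045", sub = "Amino acid biosynthesis")
  rx("ASPTA", c(oaa_c = -1, glu__L_c = -1, asp__L_c = 1, akg_c = 1),
     lb = -1000, gpr = "10046", sub = "Amino acid biosynthesis")
  rx("GLYCS", c(g6p_c = -1, glucan_c = 1, pi_c = 1), gpr = "10048",
     sub = "Storage carbohydrate")

  ## lipid metabolism (lumped)
  rx("G3PD", c(dhap_c = -1, nadh_c = -1, h_c = -1, glyc3p_c = 1, nad_c = 1),
     gpr = "10049", sub = "Lipid metabolism")
  rx("G3PP", c(glyc3p_c = -1, h2o_c = -1, glyc_c = 1, pi_c = 1),
     gpr = "10050", sub = "Lipid metabolism")
  rx("FAS160", c(accoa_c = -8, atp_c = -7, nadph_c = -14, h_c = -6,
                 h2o_c = -1, hdca_c = 1, coa_c = 8, adp_c = 7, pi_c = 7,
                 nadp_c = 14), gpr = "10051", sub = "Lipid metabolism")
  rx("FAS181", c(accoa_c = -9, atp_c = -8, nadph_c = -16, nadh_c = -1,
                 o2_c = -1, h_c = -8, ocdcea_c = 1, coa_c = 9, adp_c = 8,
                 pi_c = 8, nadp_c = 16, nad_c = 1, h2o_c = 1),
     gpr = "10051", sub = "Lipid metabolism")
  rx("FAS182", c(accoa_c = -9, atp_c = -8, nadph_c = -16, nadh_c = -2,
                 o2_c = -2, h_c = -9, lnlc_c = 1, coa_c = 9, adp_c = 8,
                 pi_c = 8, nadp_c = 16, nad_c = 2, h2o_c = 3),
     gpr = "10051 and 10052", sub = "Lipid metabolism")
  rx("TAGS160", c(glyc_c = -1, hdca_c = -3, h_c = -3, tag_hdca_l = 1,
                  h2o_c = 3), gpr = "10053", sub = "Lipid metabolism")
  rx("TAGS181", c(glyc_c = -1, ocdcea_c = -3, h_c = -3, tag_ocdcea_l = 1,
                  h2o_c = 3), gpr = "10053", sub = "Lipid metabolism")
  rx("TAGS182", c(glyc_c = -1, lnlc_c = -3, h_c = -3, tag_lnlc_l = 1,
                  h2o_c = 3), gpr = "10053", sub = "Lipid metabolism")
  rx("ERGSYN", c(accoa_c = -18, atp_c = -18, nadph_c = -25, o2_c = -10,
                 h_c = -7, ergst_r = 1, coa_c = 18, adp_c = 18, pi_c = 18,
                 nadp_c = 25, co2_c = 8, h2o_c = 3),
     gpr = "10054 and 14213", sub = "Sterol biosynthesis")
  rx("SESYN", c(ergst_r = -1, ocdcea_c = -1, h_c = -1, se_l = 1, h2o_c = 1),
     gpr = "10055", sub = "Sterol biosynthesis")

  ## ubiquinone-9 biosynthesis from 4-hydroxybenzoate (lumped)
  rx("Q9SYN", c(`4hbz_m` = -1, accoa_m = -27, nadph_m = -23, h_m = -24,
                q9_m = 1, coa_m = 27, co2_m = 7, nadp_m = 23, h2o_m = 12),
     gpr = "10056", sub = "Quinone biosynthesis")

  ## peroxisomal p-coumarate degradation to 4-hydroxybenzoate
  rx("COUMtx", c(T4hcinnm_c = -1, T4hcinnm_x = 1), kind = "transport",
     sub = "Transport, peroxisomal")
  rx("COUACS", c(T4hcinnm_x = -1, atp_x = -1, coa_x = -1, coucoa_x = 1,
                 adp_x = 1, pi_x = 1), gpr = "12555 or 16635",
     sub = "p-Coumarate degradation")
  rx("COUECH", c(coucoa_x = -1, h2o_x = -1, hcoucoa_x = 1), gpr = "16515",
     sub = "p-Coumarate degradation")
  rx("COUHACD", c(hcoucoa_x = -1, nad_x = -1, ocoucoa_x = 1, nadh_x = 1,
                  h_x = 1), gpr = "9469", sub = "p-Coumarate degradation")
  rx("COUKAT", c(ocoucoa_x = -1, coa_x = -1, `4hbzcoa_x` = 1, accoa_x = 1),
     gpr = "9065", sub = "p-Coumarate degradation")
  rx("COUTES", c(`4hbzcoa_x` = -1, h2o_x = -1, `4hbz_x` = 1, coa_x = 1,
                 h_x = 1), gpr = "14934", sub = "p-Coumarate degradation")
  rx("4HBZtx", c(`4hbz_x` = -1, `4hbz_c` = 1), kind = "transport",
     sub = "Transport, peroxisomal")
  rx("4HBZtm", c(`4hbz_c` = -1, `4hbz_m` = 1), kind = "transport",
     sub = "Transport, mitochondrial")

  ## cytosolic protocatechuate (3-oxoadipate) pathway
  rx("POBA", c(`4hbz_c` = -1, nadph_c = -1, h_c = -1, o2_c = -1,
               `34dhbz_c` = 1, nadp_c = 1, h2o_c = 1), gpr = "12923",
     sub = "Protocatechuate pathway")
  rx("PCADOX", c(`34dhbz_c` = -1, o2_c = -1, `3cmuc_c` = 1, h_c = 2),
     gpr = "12623", sub = "Protocatechuate pathway")
  rx("PCALAC", c(`3cmuc_c` = -1, h_c = -1, cmuclac_c = 1), gpr = "12622",
     sub = "Protocatechuate pathway")
  rx("PCADC", c(cmuclac_c = -1, h2o_c = -1, `3oxoadp_c` = 1, co2_c = 1),
     gpr = "12620", sub = "Protocatechuate pathway")
  rx("ODC2tm", c(`3oxoadp_c` = -1, akg_m = -1, `3oxoadp_m` = 1, akg_c = 1),
     lb = -1000, gpr = "10635", kind = "transport",
     sub = "Transport, mitochondrial")
  rx("PCAIJ", c(`3oxoadp_m` = -1, succoa_m = -1, `3oxoadpcoa_m` = 1,
                succ_m = 1), gpr = "13090", sub = "Protocatechuate pathway")
  rx("PCAF", c(`3oxoadpcoa_m` = -1, coa_m = -1, succoa_m = 1, accoa_m = 1),
     gpr = "15228", sub = "Protocatechuate pathway")

  ## peroxisomal shuttles
  rx("ATPtx", c(atp_c = -1, atp_x = 1), kind = "transport",
     sub = "Transport, peroxisomal")
  rx("ADPtx", c(adp_x = -1, adp_c = 1), kind = "transport",
     sub = "Transport, peroxisomal")
  rx("PItx", c(pi_x = -1, pi_c = 1), kind = "transport",
     sub = "Transport, peroxisomal")
  rx("ACCOACOAtx", c(accoa_x = -1, coa_c = -1, accoa_c = 1, coa_x = 1),
     kind = "transport", sub = "Transport, peroxisomal")
  rx("NADHtx", c(nadh_x = -1, nad_c = -1, nad_x = 1, nadh_c = 1),
     kind = "transport", sub = "Transport, peroxisomal")
  rx("H2Otx", c(h2o_c = -1, h2o_x = 1), lb = -1000, kind = "transport",
     sub = "Transport, peroxisomal")
  rx("Htx", c(h_c = -1, h_x = 1), lb = -1000, kind = "transport",
     sub = "Transport, peroxisomal")

  if (with_biomass) {
    fit <- fit_segmented(demo_fame_data())
    model <- assemble_biomass(
      model, demo_biomass_spec(model), fit = fit,
      lipid_species = list(C18_1 = "ocdcea_c", C16_0 = "hdca_c",
                           C18_2 = "lnlc_c"),
      tag_species = c(C18_1 = "tag_ocdcea_l", C16_0 = "tag_hdca_l",
                      C18_2 = "tag_lnlc_l"),
      se_species = "se_l")
  }
  model
}

#' Maximum ATP yield per glucose the demo fixture can reach
#'
#' The stoichiometric ceiling implied by the fixture's wiring: 2 ATP from
#' glycolysis, 2 from the TCA succinyl-CoA synthetase step, 10 NADH worth
#' 4+6 pumped protons each and 2 ubiquinol worth 6 each, at 4 protons per
#' ATP at the synthase: 4 + 10*(10/4) + 2*(6/4) = 32.
#' @return a number (mol ATP per mol glucose).
#' @export
demo_atp_ceiling <- function() 32

#' Packaged fatty-acid composition data of the demo organism
#'
#' Noise-free per-condition fatty-acid contents (wt% CDW) following the
#' lean/lipid-body line `y_k = m_k (x - x0) + b_k` with lean contents
#' `b = (3, 1, 1)` (C18:1, C16:0, C18:2), lipid-body composition
#' `m = (0.7, 0.2, 0.1)` and lean total `x0 = 5` wt%, sampled at total
#' contents 5 (rich medium), 10, 20 and 40 (nitrogen-limited) wt%.
#'
#' @return a `fame_dataset` with conditions YPD, SD, M9, YNB_CN120.
#' @export
demo_fame_data <- function() {
  b <- c(C18_1 = 3, C16_0 = 1, C18_2 = 1)
  m <- c(C18_1 = 0.7, C16_0 = 0.2, C18_2 = 0.1)
  x0 <- 5
  x <- c(YPD = 5, SD = 10, M9 = 20, YNB_CN120 = 40)
  y <- t(vapply(x, function(xi) m * (xi - x0) + b, numeric(3)))
  fame_dataset(y)
}

#' Biomass composition specification of the demo fixture
#'
#' Protein 45% (alanine/glutamate/aspartate stand-ins), storage
#' carbohydrate 50% (glucan), lean lipid 5% of cell dry weight -- the
#' lean lipid total matching the x0 of the packaged fatty-acid data --
#' with 30 mmol/gDW growth-associated maintenance ATP.  Residue masses
#' are derived from the model's metabolite formulas so the 1 g/gDW mass
#' audit is exact.
#'
#' @param model the demo fixture (pre-biomass) supplying formulas.
#' @return a `biomass_spec`.
#' @export
demo_biomass_spec <- function(model) {
  rm <- function(id) met_residue_mass(model, id)
  biomass_spec(
    macromolecules = c(protein = 0.45, carbohydrate = 0.50, lipid = 0.05),
    monomers = list(
      protein = data.frame(
        metabolite = c("ala__L_c", "glu__L_c", "asp__L_c"),
        mol_fraction = c(0.5, 0.3, 0.2),
        residue_mass = c(rm("ala__L_c"), rm("glu__L_c"), rm("asp__L_c")),
        stringsAsFactors = FALSE),
      carbohydrate = data.frame(
        metabolite = "glucan_c", mol_fraction = 1,
        residue_mass = rm("glucan_c"), stringsAsFactors = FALSE),
      lipid = "lipid"),
    gam = 30)
}

#' Substrate map for the demo fixture
#'
#' Maps phenotype-array substrate labels to exchanged metabolites of the
#' demo fixture; substrates with `NA` are known but not representable in
#' the network (counted, never simulated).  User-extensible: rbind more
#' rows.
#'
#' @return data.frame with columns `substrate`, `metabolite_id`.
#' @export
demo_substrate_map <- function() {
  data.frame(
    substrate = c("glucose", "D-glucose", "xylose", "D-xylose",
                  "arabinose", "L-arabinose", "arabinitol", "D-arabinitol",
                  "pcoumarate", "p-coumarate", "Tween 40", "Tween 80"),
    metabolite_id = c("glc__D_e", "glc__D_e", "xyl__D_e", "xyl__D_e",
                      "arab__L_e", "arab__L_e", "abt__D_e", "abt__D_e",
                      "T4hcinnm_e", "T4hcinnm_e", NA, NA),
    stringsAsFactors = FALSE)
}

#' Minimal media for the demo fixture
#'
#' Single-carbon-source minimal media: the named carbon exchange opens at
#' the default uptake rate (10 mmol/gDW/h), ammonium, phosphate, oxygen,
#' water and protons are free.
#'
#' @param carbon_uptake carbon-source uptake bound, mmol/gDW/h.
#' @return named list of media (named numeric vectors for
#'   [apply_medium()]): glucose, xylose, arabinose, arabinitol,
#'   pcoumarate.
#' @export
demo_media <- function(carbon_uptake = 10) {
  minerals <- c(EX_nh4_e = -1000, EX_pi_e = -1000, EX_o2_e = -1000,
                EX_h2o_e = -1000, EX_h_e = -1000)
  carbon <- c(glucose = "EX_glc__D_e", xylose = "EX_xyl__D_e",
              arabinose = "EX_arab__L_e", arabinitol = "EX_abt__D_e",
              pcoumarate = "EX_T4hcinnm_e")
  lapply(carbon, function(ex) {
    c(stats::setNames(-carbon_uptake, ex), minerals)
  })
}
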