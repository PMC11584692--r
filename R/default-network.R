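#' @include network-build.R
NULL

#' Control culture environment
#'
#' Standard incubator conditions: 21\% O2 and 5.05 mmol/L glucose, no
#' exogenous ligands beyond trace baseline levels.
#' @return list(O2_fraction, glucose_mmol_L).
#' @export
controlEnvironment <- function() list(O2_fraction = 0.21, glucose_mmol_L = 5.05)

#' Build the default BMEC signaling network
#'
#' Constructs the multi-pathway reaction network of brain microvascular
#' endothelial cell signaling: inflammatory TNFR/TLR4-TRAF6/RIPK1-TAK1-IKK-
#' NFkB signaling with A20 negative feedback and cytokine secretion;
#' growth-factor survival signaling (VEGFR pY1175/pY951, PLCg/MEK/ERK,
#' PI3K/AKT, Tie2, FGFR/PKC, Wnt/beta-catenin, ER calcium, eNOS, AMPK/ULK);
#' PHD-mediated oxygen sensing with HIF1a/HIF2a and their transcriptional
#' targets (Lon, BDNF, SEMA3G, Ang2) plus the p53-MDM2-BAX-Caspase3 axis
#' with TIGAR/NADPH coupling; glucose/ATP metabolism with aerobic and
#' anaerobic ATP regeneration and PFKFB3; and the oxidative-stress core in
#' which hypoxia reverses SDH flux so succinate accumulates, reoxygenation
#' rapidly oxidizes it into a ROS burst, ROS drives iNOS/NO/peroxynitrite,
#' oxidizes BH4 to BH2 (which feeds back on ROS), activates Keap1/NRF2,
#' damages the tight junction proteins ZO-1 and Claudin5, activates IKK,
#' and perturbs ER calcium exchange.
#'
#' Protein species are in copies per cell; metabolites and radicals in
#' relative units with quiescent value 1; O2 as fraction (0.21 control);
#' glucose in mmol/L (5.05 control). Rate constants are balanced at build
#' time so the declared baseline state is an exact steady state under the
#' control environment.
#'
#' @return a \code{ReactionNetwork} whose metadata carries the balanced
#'   default \code{ParameterSet}.
#' @export
buildDefaultNetwork <- function() {
  b <- networkBuilder()
  env <- controlEnvironment()

  ## ---- species -------------------------------------------------------
  addSpecies(b, "O2", "environment", env$O2_fraction, "fraction",
             c("environment"), clamped = TRUE)
  addSpecies(b, "Glc", "environment", env$glucose_mmol_L, "mmol_L",
             c("environment", "metabolite"), clamped = TRUE)

  lig <- function(id, base) addSpecies(b, id, "medium", base,
                                       "molecules_per_cell", "ligand")
  lig("TNFa", 10); lig("LPS", 10); lig("VEGF", 10)
  lig("FGF", 10); lig("Ang1", 100); lig("Wnt", 100)

  pr <- function(id, base, comp = "cytosol", roles = "kinase")
    addSpecies(b, id, comp, base, "copies_per_cell", roles)

  # inflammation
  pr("TNFR", 1e4, "membrane", "receptor"); pr("TNFR_act", 500, "membrane", "receptor")
  pr("TLR4", 1e4, "membrane", "receptor"); pr("TLR4_act", 500, "membrane", "receptor")
  pr("TRAF6", 1e4); pr("TRAF6_Ub", 500)
  pr("RIPK1", 1e4); pr("RIPK1_Ub", 500)
  pr("TAK1", 1e4); pr("TAK1p", 1000)
  pr("IKK", 1e4); pr("IKKp", 1000)
  pr("NFkB_IkB", 1e5); pr("NFkB_nuc", 5e3, "nucleus", "transcription_factor")
  pr("IkB", 1e4); addSpecies(b, "IkB_mRNA", "nucleus", 100, "copies_per_cell")
  pr("A20", 1000)
  pr("p38", 1e4); pr("p38p", 1000)
  pr("JNK", 1e4); pr("JNKp", 1000)
  pr("ERK", 1e4); pr("ERKp", 1000)
  pr("IL6", 1000, "medium", "marker"); pr("IL1b", 1000, "medium", "marker")
  pr("CCL2", 1000, "medium", "marker")

  # survival
  pr("VEGFR", 1e4, "membrane", "receptor")
  pr("VEGFR_pY1175", 200, "membrane", "receptor")
  pr("VEGFR_pY951", 200, "membrane", "receptor")
  pr("PLCg", 1e4); pr("PLCgp", 500)
  pr("MEK", 1e4); pr("MEKp", 1000)
  pr("PI3K", 1e4); pr("PI3Kp", 500)
  pr("AKT", 1e4); pr("AKTp", 1000)
  pr("Tie2", 1e4, "membrane", "receptor"); pr("Tie2p", 500, "membrane", "receptor")
  pr("FGFR", 1e4, "membrane", "receptor"); pr("FGFRp", 200, "membrane", "receptor")
  pr("PKC", 1e4); pr("PKCp", 500)
  pr("bCatenin", 1e4, "cytosol", "transcription_factor")
  addSpecies(b, "Ca_cyt", "cytosol", 1, "relative", "metabolite")
  addSpecies(b, "Ca_ER", "ER", 10, "relative", "metabolite")
  pr("eNOS", 1e4); pr("eNOSp", 500)
  pr("AMPK", 1e4); pr("AMPKp", 2500)
  pr("ULK", 1e4); pr("ULKp", 500)

  # hypoxia
  pr("PHD_i", 1000); pr("PHD", 800)
  pr("HIF1a", 1000, "cytosol", "transcription_factor")
  pr("HIF1a_nuc", 200, "nucleus", "transcription_factor")
  pr("HIF2a", 1000, "cytosol", "transcription_factor")
  pr("HIF2a_nuc", 200, "nucleus", "transcription_factor")
  pr("Lon", 1000, "mitochondrion")
  pr("BDNF", 1000, "medium", "marker"); pr("SEMA3G", 1000, "medium", "marker")
  pr("Ang2", 1000, "medium", "marker")
  pr("p53", 1000, "nucleus", "marker")
  pr("MDM2", 1000, "nucleus")
  pr("BAX", 1000, "mitochondrion")
  pr("Casp3", 1000, "cytosol", "marker")

  # metabolism
  addSpecies(b, "ATP", "cytosol", 1, "relative", "metabolite")
  addSpecies(b, "AMP", "cytosol", 0.2, "relative", "metabolite")
  pr("PFKFB3", 1000); pr("TIGAR", 1000)
  addSpecies(b, "NADPH", "cytosol", 1, "relative", "metabolite")

  # oxidative stress
  pr("SDH", 1000, "mitochondrion")
  addSpecies(b, "Succinate", "mitochondrion", 1, "relative", "metabolite")
  addSpecies(b, "ROS", "cytosol", 1, "relative", c("radical", "marker"))
  pr("iNOS", 1000)
  addSpecies(b, "NO", "cytosol", 1, "relative", "radical")
  addSpecies(b, "ONOO", "cytosol", 1, "relative", c("radical", "marker"))
  addSpecies(b, "BH4", "cytosol", 50, "relative", "metabolite")
  addSpecies(b, "BH2", "cytosol", 0.5, "relative", "metabolite")
  pr("Keap1", 1000); pr("NRF2", 1e4); pr("NRF2act", 1000, "nucleus",
                                         "transcription_factor")
  pr("ZO1", 1000, "membrane", "marker"); pr("Claudin5", 1000, "membrane", "marker")

  ## ---- reaction helpers ---------------------------------------------
  syn <- function(prod, param, regs = list(), module, k = 1,
                  balances = prod) {
    kind <- if (!length(regs)) "zeroth_order_synthesis"
            else if (regs[[1]]$mode == "act") "hill_activation"
            else "hill_inhibition"
    addReaction(b, param, module, products = stats::setNames(1, prod),
                law = rateLaw(kind, param, regs), k = k, balances = balances)
  }
  dec <- function(spec, k, param = paste0("kd_", spec), regs = list(),
                  module, balances = NULL) {
    kind <- if (!length(regs)) "first_order_decay"
            else if (regs[[1]]$mode == "act") "hill_activation"
            else "hill_inhibition"
    addReaction(b, param, module, reactants = stats::setNames(1, spec),
                law = rateLaw(kind, param, regs), k = k, balances = balances)
  }
  conv <- function(from, to, param, regs = list(), module, k = 1,
                   balances = NULL) {
    kind <- if (!length(regs)) "mass_action"
            else if (regs[[1]]$mode == "act") "hill_activation"
            else "hill_inhibition"
    addReaction(b, param, module, reactants = stats::setNames(1, from),
                products = stats::setNames(1, to),
                law = rateLaw(kind, param, regs), k = k, balances = balances)
  }
  # activation/deactivation cycle; activation balances the active form
  cyc <- function(inact, act, actParam, actRegs, kdp,
                  kdpParam = paste0("kdp_", inact), module) {
    conv(inact, act, actParam, actRegs, module, balances = act)
    conv(act, inact, kdpParam, module = module, k = kdp)
  }

  ## ---- environment / ligand turnover --------------------------------
  for (l in c("TNFa", "LPS", "VEGF", "FGF", "Ang1", "Wnt")) {
    syn(l, paste0("kt_", l), module = "environment")
    dec(l, 0.3, module = "environment")
  }

  ## ---- inflammation module ------------------------------------------
  cyc("TNFR", "TNFR_act", "kon_TNFR",
      list(reg("TNFa", "act", 5e4, 1, relative = FALSE)), 2, "koff_TNFR",
      "inflammation")
  cyc("TLR4", "TLR4_act", "kon_TLR4",
      list(reg("LPS", "act", 5e4, 1, relative = FALSE)), 2, "koff_TLR4",
      "inflammation")
  # ubiquitination driven by the active receptor; A20 promotes removal
  conv("TRAF6", "TRAF6_Ub", "ku_TRAF6", list(reg("TLR4_act", "act", 4, 1)),
       "inflammation", balances = "TRAF6_Ub")
  conv("TRAF6_Ub", "TRAF6", "kdu_TRAF6", list(reg("A20", "act", 1, 1)),
       "inflammation", k = 2)
  conv("RIPK1", "RIPK1_Ub", "ku_RIPK1", list(reg("TNFR_act", "act", 4, 1)),
       "inflammation", balances = "RIPK1_Ub")
  conv("RIPK1_Ub", "RIPK1", "kdu_RIPK1", list(reg("A20", "act", 1, 1)),
       "inflammation", k = 2)
  cyc("TAK1", "TAK1p", "kp_TAK1", list(reg("TRAF6_Ub", "act", 4, 2)), 4,
      module = "inflammation")
  conv("TAK1", "TAK1p", "kp_TAK1_RIPK1", list(reg("RIPK1_Ub", "act", 4, 2)),
       "inflammation", k = 1)
  cyc("IKK", "IKKp", "kp_IKK", list(reg("TAK1p", "act", 3, 2)), 4,
      module = "inflammation")
  # ROS-driven IKK activation couples oxidative stress into NFkB signaling
  # switch-like redox activation of IKK: quiet at baseline, strong in the
  # reoxygenation ROS burst
  conv("IKK", "IKKp", "kp_IKK_ROS", list(reg("ROS", "act", 4, 4)),
       "oxidative_stress", k = 10)
  # hypoxia-NFkB crosstalk: HIF accumulation mildly activates IKK
  conv("IKK", "IKKp", "kp_IKK_HIF", list(reg("HIF1a_nuc", "act", 3, 2)),
       "hypoxia", k = 0.6)
  # IKK-triggered IkB phosphorylation/degradation frees nuclear NFkB
  conv("NFkB_IkB", "NFkB_nuc", "kp_NFkB", list(reg("IKKp", "act", 2, 2)),
       "inflammation", k = 0.5)
  addReaction(b, "kon_NFkB", "inflammation",
              reactants = c(NFkB_nuc = 1, IkB = 1),
              products = c(NFkB_IkB = 1),
              law = rateLaw("mass_action", "kon_NFkB"),
              balances = "NFkB_nuc")
  syn("IkB_mRNA", "kt_IkB_mRNA", list(reg("NFkB_nuc", "act", 2, 2)),
      "inflammation")
  dec("IkB_mRNA", 1, "kd_IkB_mRNA", module = "inflammation")
  syn("IkB", "kt_IkB", list(reg("IkB_mRNA", "act", 1, 1)), "inflammation")
  dec("IkB", 0.25, module = "inflammation")
  syn("A20", "kt_A20", list(reg("NFkB_nuc", "act", 2, 2)), "inflammation")
  dec("A20", 0.5, module = "inflammation")
  for (ck in c("IL6", "IL1b", "CCL2")) {
    syn(ck, paste0("kt_", ck), list(reg("NFkB_nuc", "act", 3, 2)),
        "inflammation")
    dec(ck, 0.05, module = "inflammation")
  }
  cyc("p38", "p38p", "kp_p38", list(reg("TAK1p", "act", 3, 2)), 4,
      module = "inflammation")
  cyc("JNK", "JNKp", "kp_JNK", list(reg("TAK1p", "act", 3, 2)), 4,
      module = "inflammation")
  cyc("ERK", "ERKp", "kp_ERK", list(reg("MEKp", "act", 3, 2)), 4,
      module = "survival")
  conv("ERK", "ERKp", "kp_ERK_TAK1", list(reg("TAK1p", "act", 3, 2)),
       "inflammation", k = 0.5)
  conv("ERK", "ERKp", "kp_ERK_Tie2", list(reg("Tie2p", "act", 3, 1)),
       "survival", k = 0.2)

  ## ---- survival module ----------------------------------------------
  cyc("VEGFR", "VEGFR_pY1175", "kp_VEGFR_Y1175",
      list(reg("VEGF", "act", 1e5, 1, relative = FALSE)), 2,
      "kdp_VEGFR_Y1175", "survival")
  cyc("VEGFR", "VEGFR_pY951", "kp_VEGFR_Y951",
      list(reg("VEGF", "act", 1e5, 1, relative = FALSE)), 2,
      "kdp_VEGFR_Y951", "survival")
  cyc("PLCg", "PLCgp", "kp_PLCg", list(reg("VEGFR_pY1175", "act", 5, 1)), 2,
      module = "survival")
  conv("PLCg", "PLCgp", "kp_PLCg_FGFR", list(reg("FGFRp", "act", 5, 1)),
       "survival", k = 0.2)
  cyc("MEK", "MEKp", "kp_MEK", list(reg("PLCgp", "act", 4, 2)), 2,
      module = "survival")
  conv("MEK", "MEKp", "kp_MEK_PKC", list(reg("PKCp", "act", 4, 2)),
       "survival", k = 0.5)
  cyc("PI3K", "PI3Kp", "kp_PI3K", list(reg("VEGFR_pY951", "act", 5, 1)), 2,
      module = "survival")
  conv("PI3K", "PI3Kp", "kp_PI3K_FGFR", list(reg("FGFRp", "act", 5, 1)),
       "survival", k = 0.3)
  cyc("AKT", "AKTp", "kp_AKT", list(reg("PI3Kp", "act", 3, 2)), 2,
      module = "survival")
  conv("AKT", "AKTp", "kp_AKT_Tie2", list(reg("Tie2p", "act", 3, 1)),
       "survival", k = 0.3)
  cyc("Tie2", "Tie2p", "kp_Tie2",
      list(reg("Ang1", "act", 1e5, 1, relative = FALSE)), 1,
      module = "survival")
  cyc("FGFR", "FGFRp", "kp_FGFR",
      list(reg("FGF", "act", 1e5, 1, relative = FALSE)), 2,
      module = "survival")
  cyc("PKC", "PKCp", "kp_PKC", list(reg("PLCgp", "act", 4, 1)), 2,
      module = "survival")
  syn("bCatenin", "kt_bCat", module = "survival")
  dec("bCatenin", 0.3, "kd_bCat",
      list(reg("Wnt", "inh", 1e4, 1, relative = FALSE)), "survival")
  # ER calcium store exchange; release is promoted by PLCg and by ROS
  conv("Ca_ER", "Ca_cyt", "k_leak_Ca", module = "survival", k = 0.02)
  conv("Ca_ER", "Ca_cyt", "k_leak_Ca_PLCg", list(reg("PLCgp", "act", 4, 2)),
       "survival", k = 0.01)
  conv("Ca_ER", "Ca_cyt", "k_leak_Ca_ROS", list(reg("ROS", "act", 3, 2)),
       "oxidative_stress", k = 0.1)
  conv("Ca_cyt", "Ca_ER", "k_pump_Ca", module = "survival",
       balances = "Ca_cyt")
  cyc("eNOS", "eNOSp", "kp_eNOS", list(reg("Ca_cyt", "act", 2, 2)), 2,
      module = "survival")
  cyc("AMPK", "AMPKp", "kp_AMPK", list(reg("AMP", "act", 3, 2)), 2,
      module = "metabolism")
  conv("AMPK", "AMPKp", "kp_AMPK_Ca", list(reg("Ca_cyt", "act", 2, 3)),
       "survival", k = 2.7)
  cyc("ULK", "ULKp", "kp_ULK", list(reg("AMPKp", "act", 2, 2)), 2,
      module = "survival")

  ## ---- hypoxia module ------------------------------------------------
  cyc("PHD_i", "PHD", "kact_PHD",
      list(reg("O2", "act", 0.03, 1, relative = FALSE)), 1, "kdeact_PHD",
      "hypoxia")
  syn("HIF1a", "kt_HIF1a", module = "hypoxia")
  dec("HIF1a", 2.3, "koh_HIF1a", list(reg("PHD", "act", 1, 1)), "hypoxia")
  conv("HIF1a", "HIF1a_nuc", "kon_HIF1a", module = "hypoxia", k = 0.2)
  conv("HIF1a_nuc", "HIF1a", "koff_HIF1a", module = "hypoxia",
       balances = "HIF1a_nuc")
  syn("HIF2a", "kt_HIF2a", module = "hypoxia")
  dec("HIF2a", 2.3, "koh_HIF2a", list(reg("PHD", "act", 1, 1)), "hypoxia")
  conv("HIF2a", "HIF2a_nuc", "kin_HIF2a", module = "hypoxia", k = 0.2)
  conv("HIF2a_nuc", "HIF2a", "koff_HIF2a", module = "hypoxia",
       balances = "HIF2a_nuc")
  syn("Lon", "kt_Lon", list(reg("HIF1a_nuc", "act", 3, 2)), "hypoxia")
  addReaction(b, "kt_Lon_HIF2a", "hypoxia", products = c(Lon = 1),
              law = rateLaw("hill_activation", "kt_Lon_HIF2a",
                            list(reg("HIF2a_nuc", "act", 3, 2))), k = 100)
  dec("Lon", 0.3, module = "hypoxia")
  for (gf in c("BDNF", "SEMA3G", "Ang2")) {
    syn(gf, paste0("kt_", gf), list(reg("HIF2a_nuc", "act", 3, 2)),
        "hypoxia")
    addReaction(b, paste0("kt_", gf, "_HIF1a"), "hypoxia",
                products = stats::setNames(1, gf),
                law = rateLaw("hill_activation", paste0("kt_", gf, "_HIF1a"),
                              list(reg("HIF1a_nuc", "act", 3, 2))), k = 300)
    dec(gf, 0.3, module = "hypoxia")
  }
  syn("p53", "kt_p53_HIF", list(reg("HIF1a_nuc", "act", 3, 2)), "survival")
  addReaction(b, "kt_p53", "survival", products = c(p53 = 1),
              law = rateLaw("zeroth_order_synthesis", "kt_p53"), k = 250)
  dec("p53", 0.2, "kd_p53", module = "survival")
  dec("p53", 0.6, "kd_p53_MDM2", list(reg("MDM2", "act", 1, 1)), "survival")
  syn("MDM2", "kt_MDM2", list(reg("p53", "act", 2, 2)), "survival")
  dec("MDM2", 0.4, module = "survival")
  syn("BAX", "kt_BAX", list(reg("p53", "act", 2, 2)), "survival")
  dec("BAX", 0.3, module = "survival")
  syn("Casp3", "kt_Casp3", list(reg("BAX", "act", 2.5, 2)), "survival")
  # self-amplifying caspase activation: switch-like commitment to apoptosis
  addReaction(b, "kt_Casp3_self", "survival", products = c(Casp3 = 1),
              law = rateLaw("hill_activation", "kt_Casp3_self",
                            list(reg("Casp3", "act", 8, 4))), k = 3000)
  dec("Casp3", 0.15, module = "survival")

  ## ---- metabolism module --------------------------------------------
  conv("ATP", "AMP", "kd_ATP", module = "metabolism", k = 2)
  addReaction(b, "k_ATP_aerobic", "metabolism", reactants = c(AMP = 1),
              products = c(ATP = 1),
              law = rateLaw("hill_activation", "k_ATP_aerobic",
                            list(reg("Glc", "act", 1, 1, relative = FALSE),
                                 reg("O2", "act", 0.03, 1, relative = FALSE))),
              balances = "ATP")
  addReaction(b, "k_ATP_anaerobic", "metabolism", reactants = c(AMP = 1),
              products = c(ATP = 1),
              law = rateLaw("hill_activation", "k_ATP_anaerobic",
                            list(reg("Glc", "act", 1, 1, relative = FALSE))),
              k = 1.2)
  syn("PFKFB3", "kt_PFKFB3",
      list(reg("O2", "inh", 0.05, 2, relative = FALSE)), "metabolism")
  dec("PFKFB3", 0.3, module = "metabolism")
  syn("TIGAR", "kt_TIGAR", list(reg("p53", "act", 2, 2)), "metabolism")
  dec("TIGAR", 0.3, module = "metabolism")
  syn("NADPH", "kt_NADPH", list(reg("TIGAR", "act", 2, 1)), "metabolism")
  dec("NADPH", 0.5, module = "metabolism")

  ## ---- oxidative stress module --------------------------------------
  syn("SDH", "kt_SDH", module = "oxidative_stress")
  dec("SDH", 0.1, module = "oxidative_stress")
  # reversed SDH flux under low O2 accumulates succinate
  syn("Succinate", "kt_Succinate",
      list(reg("SDH", "act", 1, 1), reg("O2", "inh", 0.15, 2, relative = FALSE)),
      "oxidative_stress")
  # restored O2 oxidizes succinate; reverse electron transport yields ROS
  addReaction(b, "kd_Succinate", "oxidative_stress",
              reactants = c(Succinate = 1), products = c(ROS = 1),
              law = rateLaw("hill_activation", "kd_Succinate",
                            list(reg("SDH", "act", 1, 1),
                                 reg("O2", "act", 0.05, 2, relative = FALSE))),
              k = 1.2)
  addReaction(b, "kt_ROS", "oxidative_stress", products = c(ROS = 1),
              law = rateLaw("zeroth_order_synthesis", "kt_ROS"), k = 0.3)
  addReaction(b, "kt_ROS_BH2", "oxidative_stress", products = c(ROS = 1),
              law = rateLaw("hill_activation", "kt_ROS_BH2",
                            list(reg("BH2", "act", 3, 2))), k = 1)
  dec("ROS", 1, "kd_ROS", module = "oxidative_stress", balances = "ROS")
  dec("ROS", 0.3, "kd_ROS_NRF2", list(reg("NRF2act", "act", 2, 2)),
      "oxidative_stress")
  dec("ROS", 0.3, "kd_ROS_NADPH", list(reg("NADPH", "act", 1, 1)),
      "oxidative_stress")
  dec("ROS", 0.2, "kd_ROS_Lon", list(reg("Lon", "act", 1, 1)),
      "oxidative_stress")
  syn("iNOS", "kt_iNOS", list(reg("ROS", "act", 3, 2)), "oxidative_stress")
  dec("iNOS", 0.3, module = "oxidative_stress")
  syn("NO", "kt_NO", list(reg("iNOS", "act", 2, 2)), "oxidative_stress")
  addReaction(b, "kt_NO_eNOS", "oxidative_stress", products = c(NO = 1),
              law = rateLaw("hill_activation", "kt_NO_eNOS",
                            list(reg("eNOSp", "act", 2, 2))), k = 0.5)
  dec("NO", 2, module = "oxidative_stress")
  addReaction(b, "kon_ONOO", "oxidative_stress",
              reactants = c(NO = 1, ROS = 1), products = c(ONOO = 1),
              law = rateLaw("mass_action", "kon_ONOO"), k = 0.05)
  dec("ONOO", 1, module = "oxidative_stress", balances = "ONOO")
  conv("BH4", "BH2", "kox_BH4", list(reg("ROS", "act", 2, 4)),
       "oxidative_stress", balances = "BH2")
  conv("BH2", "BH4", "kred_BH2", module = "oxidative_stress", k = 0.1)
  syn("Keap1", "kt_Keap1", module = "oxidative_stress")
  dec("Keap1", 0.1, module = "oxidative_stress")
  conv("NRF2", "NRF2act", "kp_NRF2",
       list(reg("ROS", "act", 2, 2), reg("Keap1", "inh", 1, 1)),
       "oxidative_stress", balances = "NRF2act")
  conv("NRF2act", "NRF2", "kdp_NRF2", module = "oxidative_stress", k = 1)
  # tight junction proteins: AKT-supported synthesis; degradation enhanced
  # by the fast ROS burst and, persistently, by slowly-cleared peroxynitrite
  for (tj in c("ZO1", "Claudin5")) {
    # synthesis requires ATP, so junctions also erode during deprivation
    syn(tj, paste0("kt_", tj),
        list(reg("AKTp", "act", 1, 1),
             reg("ATP", "act", 0.3, 1, relative = FALSE)),
        "oxidative_stress")
    dec(tj, 0.002, paste0("kd_", tj), module = "oxidative_stress")
    dec(tj, 0.1, paste0("kd_", tj, "_ROS"), list(reg("ROS", "act", 3, 2)),
        "oxidative_stress")
    dec(tj, 0.08, paste0("kd_", tj, "_RNS"), list(reg("ONOO", "act", 3, 1)),
        "oxidative_stress")
  }

  finalizeNetwork(b, metadata = list(
    description = "BMEC multi-pathway signaling model",
    reference_counts = c(species = 108L, reactions = 145L),
    parameter_aliases = c(kp_IKK_ROS = "kp_IKK(ROS)",
                          kd_IkB_mRNA = "kd_IKB(mrna)",
                          kon_HIF1a = "kon_HIF1α",
                          kt_HIF1a = "kt_HIF1α",
                          koh_HIF2a = "koh_HIF2α",
                          kin_HIF2a = "kin_HIF2α"),
    species_aliases = c(VEGFR_pY1173 = "VEGFR_pY1175")))
}

#' Parameter groups addressed by in-silico target interventions
#'
#' Maps intervention targets to the rate constants they modulate:
#' succinate availability (synthesis via reversed SDH flux), p53
#' synthesis/activation, HIF1a synthesis and nuclear loading, and IkB
#' synthesis.
#'
#' @param network a ReactionNetwork (used to verify the ids exist).
#' @return named list of character vectors of parameter ids.
#' @export
targetGroups <- function(network = NULL) {
  groups <- list(
    succinate = c("kt_Succinate"),
    p53 = c("kt_p53", "kt_p53_HIF"),
    HIF1a = c("kt_HIF1a", "kon_HIF1a"),
    IkB = c("kt_IkB"))
  if (!is.null(network)) {
    pv <- parameterValues(defaultParameters(network))
    for (g in names(groups))
      if (!all(groups[[g]] %in% names(pv)))
        stop("target group ", g, " references unknown parameters")
  }
  groups
}

#' Default heterogeneity parameter registry
#'
#' The influential rate constants varied when generating virtual-cell
#' cohorts: the succinate/ROS axis, NFkB signaling, HIF loading, the
#' p53-apoptosis axis and tight-junction turnover, as ranked by the PRCC
#' sensitivity analysis of the cell-function score.
#'
#' @return character vector of parameter ids.
#' @export
defaultHeterogeneityParams <- function() {
  c("kt_Succinate", "kd_Succinate", "kp_IKK_ROS", "kp_NFkB", "kt_IkB",
    "kd_IkB_mRNA", "kt_HIF1a", "kon_HIF1a", "koh_HIF2a", "kin_HIF2a",
    "kt_p53_HIF", "kt_Casp3", "kd_ROS", "kt_ZO1", "kt_IL6")
}
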