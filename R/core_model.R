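#' Curated core metabolic network
#'
#' A compact, schematic central-metabolism network (glycolysis, TCA
#' cycle, oxidative phosphorylation, pentose phosphate pathway, amino
#' acid / nucleotide / lipid / sterol / glycogen / protein / RNA
#' synthesis and a biomass pseudo-reaction, across an extracellular
#' compartment `s` and a cytosolic compartment `c`).  It is the in-silico
#' stand-in for a genome-scale reference network: large enough to
#' support a library of metabolic tasks in all four task categories plus
#' growth, small enough that every solver call stays trivial.  The
#' chemistry is deliberately lumped (single reactions for multi-step
#' pathways; redox and energy stoichiometry schematic but cycle-safe:
#' no conversion can create ATP, redox power or mass from nothing).
#'
#' @param open_exchanges upper bound used for the uptake exchange
#'   reactions.
#' @return a `gem_model` with single-gene rules on enzymatic reactions
#'   (`gHEX`, `gPDH`, ...), spontaneous maintenance and exchange
#'   reactions, and subsystem annotations.
#' @export
core_model <- function(open_exchanges = 1000) {
  U <- open_exchanges
  r <- function(stoich, lb = 0, ub = 1000, gpr = "", subsystem = "")
    list(stoich = stoich, lb = lb, ub = ub, gpr = gpr,
         subsystem = subsystem)
  s <- function(...) {
    v <- c(...)
    setNames(as.numeric(v), names(v))
  }

  reactions <- list(
    # exchanges (extracellular <-> environment)
    EX_glc  = r(s(`glc[s]` = 1), ub = U, subsystem = "exchange"),
    EX_o2   = r(s(`o2[s]` = 1), ub = U, subsystem = "exchange"),
    EX_nh3  = r(s(`nh3[s]` = 1), ub = U, subsystem = "exchange"),
    EX_pi   = r(s(`pi[s]` = 1), ub = U, subsystem = "exchange"),
    EX_glyc = r(s(`glyc[s]` = 1), ub = U, subsystem = "exchange"),
    EX_fa   = r(s(`fa[s]` = 1), ub = U, subsystem = "exchange"),
    EX_lac  = r(s(`lac[s]` = -1), lb = -U, ub = U, subsystem = "exchange"),
    EX_co2  = r(s(`co2[s]` = -1), ub = U, subsystem = "exchange"),
    EX_h2o  = r(s(`h2o[s]` = -1), lb = -U, ub = U, subsystem = "exchange"),
    EX_biomass = r(s(`biomass[c]` = -1), ub = U, subsystem = "exchange"),

    # transport
    GLCt  = r(s(`glc[s]` = -1, `glc[c]` = 1), gpr = "gGLCT",
              subsystem = "transport"),
    O2t   = r(s(`o2[s]` = -1, `o2[c]` = 1), subsystem = "transport"),
    CO2t  = r(s(`co2[c]` = -1, `co2[s]` = 1), subsystem = "transport"),
    H2Ot  = r(s(`h2o[c]` = -1, `h2o[s]` = 1), lb = -1000,
              subsystem = "transport"),
    PIt   = r(s(`pi[s]` = -1, `pi[c]` = 1), gpr = "gPIT",
              subsystem = "transport"),
    NH3t  = r(s(`nh3[s]` = -1, `nh3[c]` = 1), lb = -1000,
              subsystem = "transport"),
    LACt  = r(s(`lac[c]` = -1, `lac[s]` = 1), lb = -1000, gpr = "gMCT",
              subsystem = "transport"),
    GLYCt = r(s(`glyc[s]` = -1, `glyc[c]` = 1), gpr = "gGLYCT",
              subsystem = "transport"),
    FAt   = r(s(`fa[s]` = -1, `fa[c]` = 1), gpr = "gFATP",
              subsystem = "transport"),

    # glycolysis / gluconeogenesis
    HEX    = r(s(`glc[c]` = -1, `atp[c]` = -1, `g6p[c]` = 1, `adp[c]` = 1),
               gpr = "gHEX", subsystem = "glycolysis"),
    PFKALD = r(s(`g6p[c]` = -1, `atp[c]` = -1, `t3p[c]` = 2, `adp[c]` = 1,
                 `pi[c]` = 1),
               gpr = "gPFK", subsystem = "glycolysis"),
    GLY2   = r(s(`t3p[c]` = -1, `adp[c]` = -2, `pi[c]` = -2, `nad[c]` = -1,
                 `pyr[c]` = 1, `atp[c]` = 2, `nadh[c]` = 1, `h2o[c]` = 1),
               gpr = "gGAPDH", subsystem = "glycolysis"),
    GNG    = r(s(`t3p[c]` = -2, `h2o[c]` = -1, `g6p[c]` = 1, `pi[c]` = 1),
               gpr = "gFBP", subsystem = "gluconeogenesis"),
    LDH    = r(s(`pyr[c]` = -1, `nadh[c]` = -1, `lac[c]` = 1, `nad[c]` = 1),
               lb = -1000, gpr = "gLDH", subsystem = "glycolysis"),

    # pyruvate / TCA
    PDH    = r(s(`pyr[c]` = -1, `coa[c]` = -1, `nad[c]` = -1,
                 `accoa[c]` = 1, `co2[c]` = 1, `nadh[c]` = 1),
               gpr = "gPDH", subsystem = "tca"),
    CS     = r(s(`accoa[c]` = -1, `oaa[c]` = -1, `h2o[c]` = -1,
                 `cit[c]` = 1, `coa[c]` = 1),
               gpr = "gCS", subsystem = "tca"),
    IDH    = r(s(`cit[c]` = -1, `nad[c]` = -1, `akg[c]` = 1, `co2[c]` = 1,
                 `nadh[c]` = 1),
               gpr = "gIDH", subsystem = "tca"),
    AKGDH  = r(s(`akg[c]` = -1, `nad[c]` = -2, `adp[c]` = -1, `pi[c]` = -1,
                 `oaa[c]` = 1, `co2[c]` = 1, `nadh[c]` = 2, `atp[c]` = 1,
                 `h2o[c]` = 1),
               gpr = "gAKGDH", subsystem = "tca"),
    PC     = r(s(`pyr[c]` = -1, `co2[c]` = -1, `atp[c]` = -1, `h2o[c]` = -1,
                 `oaa[c]` = 1, `adp[c]` = 1, `pi[c]` = 1),
               gpr = "gPC", subsystem = "anaplerosis"),
    OAADC  = r(s(`oaa[c]` = -1, `pyr[c]` = 1, `co2[c]` = 1),
               gpr = "gME", subsystem = "anaplerosis"),

    # oxidative phosphorylation and maintenance
    OXPHOS = r(s(`nadh[c]` = -2, `o2[c]` = -1, `adp[c]` = -5, `pi[c]` = -5,
                 `nad[c]` = 2, `atp[c]` = 5, `h2o[c]` = 7),
               gpr = "gNDU and gATPS", subsystem = "oxphos"),
    ATPM   = r(s(`atp[c]` = -1, `h2o[c]` = -1, `adp[c]` = 1, `pi[c]` = 1),
               subsystem = "maintenance"),
    ADK    = r(s(`amp[c]` = -1, `atp[c]` = -1, `adp[c]` = 2),
               lb = -1000, gpr = "gADK", subsystem = "nucleotide"),

    # pentose phosphate pathway
    PPP    = r(s(`g6p[c]` = -1, `nadp[c]` = -2, `h2o[c]` = -1,
                 `r5p[c]` = 1, `co2[c]` = 1, `nadph[c]` = 2),
               gpr = "gG6PD", subsystem = "ppp"),
    R5PX   = r(s(`r5p[c]` = -3, `g6p[c]` = 2, `t3p[c]` = 1),
               lb = -1000, gpr = "gTKT", subsystem = "ppp"),

    # nitrogen and amino acids
    GLUDH  = r(s(`akg[c]` = -1, `nh3[c]` = -1, `nadph[c]` = -1,
                 `glu[c]` = 1, `nadp[c]` = 1, `h2o[c]` = 1),
               gpr = "gGLUD", subsystem = "amino_acid"),
    GDHOX  = r(s(`glu[c]` = -1, `nad[c]` = -1, `h2o[c]` = -1,
                 `akg[c]` = 1, `nh3[c]` = 1, `nadh[c]` = 1),
               gpr = "gGLUD2", subsystem = "amino_acid"),
    GLNS   = r(s(`glu[c]` = -1, `nh3[c]` = -1, `atp[c]` = -1,
                 `gln[c]` = 1, `adp[c]` = 1, `pi[c]` = 1),
               gpr = "gGLNS", subsystem = "amino_acid"),
    GLNASE = r(s(`gln[c]` = -1, `h2o[c]` = -1, `glu[c]` = 1, `nh3[c]` = 1),
               gpr = "gGLS", subsystem = "amino_acid"),
    ALAT   = r(s(`pyr[c]` = -1, `glu[c]` = -1, `ala[c]` = 1, `akg[c]` = 1),
               lb = -1000, gpr = "gALT", subsystem = "amino_acid"),
    ASPT   = r(s(`oaa[c]` = -1, `glu[c]` = -1, `asp[c]` = 1, `akg[c]` = 1),
               lb = -1000, gpr = "gAST", subsystem = "amino_acid"),
    SERS   = r(s(`t3p[c]` = -1, `glu[c]` = -1, `nad[c]` = -1, `h2o[c]` = -1,
                 `ser[c]` = 1, `akg[c]` = 1, `nadh[c]` = 1, `pi[c]` = 1),
               gpr = "gPHGDH", subsystem = "amino_acid"),
    SHMT   = r(s(`ser[c]` = -1, `gly[c]` = 1, `c1[c]` = 1),
               lb = -1000, gpr = "gSHMT", subsystem = "one_carbon"),
    GCS    = r(s(`gly[c]` = -1, `nad[c]` = -1, `co2[c]` = 1, `nh3[c]` = 1,
                 `c1[c]` = 1, `nadh[c]` = 1),
               gpr = "gGLDC", subsystem = "one_carbon"),
    FDH    = r(s(`c1[c]` = -1, `nad[c]` = -1, `h2o[c]` = -1, `co2[c]` = 1,
                 `nadh[c]` = 1),
               gpr = "gALDH1L", subsystem = "one_carbon"),

    # nucleotides
    AMPS   = r(s(`r5p[c]` = -1, `gly[c]` = -1, `c1[c]` = -2, `gln[c]` = -2,
                 `asp[c]` = -1, `co2[c]` = -1, `atp[c]` = -4,
                 `amp[c]` = 1, `glu[c]` = 2, `oaa[c]` = 1, `adp[c]` = 4,
                 `pi[c]` = 4),
               gpr = "gPUR", subsystem = "nucleotide"),
    GMPS   = r(s(`amp[c]` = -1, `atp[c]` = -1, `nad[c]` = -1, `h2o[c]` = -2,
                 `gmp[c]` = 1, `adp[c]` = 1, `pi[c]` = 1, `nadh[c]` = 1),
               gpr = "gIMPDH", subsystem = "nucleotide"),
    UMPS   = r(s(`r5p[c]` = -1, `asp[c]` = -1, `gln[c]` = -1, `co2[c]` = -1,
                 `atp[c]` = -2, `nad[c]` = -1,
                 `ump[c]` = 1, `glu[c]` = 1, `adp[c]` = 2, `pi[c]` = 2,
                 `nadh[c]` = 1, `h2o[c]` = 1),
               gpr = "gCAD", subsystem = "nucleotide"),
    CTPS   = r(s(`ump[c]` = -1, `gln[c]` = -1, `atp[c]` = -1, `h2o[c]` = -1,
                 `cmp[c]` = 1, `glu[c]` = 1, `adp[c]` = 1, `pi[c]` = 1),
               gpr = "gCTPS", subsystem = "nucleotide"),

    # lipids and sterols
    FAS    = r(s(`accoa[c]` = -4, `nadph[c]` = -8, `atp[c]` = -7,
                 `fa[c]` = 1, `coa[c]` = 4, `nadp[c]` = 8, `adp[c]` = 7,
                 `pi[c]` = 7),
               gpr = "gFASN", subsystem = "lipid"),
    BOX    = r(s(`fa[c]` = -1, `coa[c]` = -4, `nad[c]` = -4, `atp[c]` = -1,
                 `h2o[c]` = -1,
                 `accoa[c]` = 4, `nadh[c]` = 4, `amp[c]` = 1, `pi[c]` = 2),
               gpr = "gCPT1 and gACAD", subsystem = "beta_oxidation"),
    GLYCK  = r(s(`glyc[c]` = -1, `atp[c]` = -1, `glyc3p[c]` = 1,
                 `adp[c]` = 1),
               gpr = "gGK", subsystem = "lipid"),
    G3PD   = r(s(`glyc3p[c]` = -1, `nad[c]` = -1, `t3p[c]` = 1,
                 `nadh[c]` = 1),
               lb = -1000, gpr = "gGPD", subsystem = "lipid"),
    LIPS   = r(s(`glyc3p[c]` = -1, `fa[c]` = -3, `atp[c]` = -3,
                 `lipid[c]` = 1, `adp[c]` = 3, `pi[c]` = 4),
               gpr = "gGPAT", subsystem = "lipid"),
    STERS  = r(s(`accoa[c]` = -6, `nadph[c]` = -5, `atp[c]` = -3,
                 `h2o[c]` = -2,
                 `sterol[c]` = 1, `coa[c]` = 6, `nadp[c]` = 5, `adp[c]` = 3,
                 `pi[c]` = 3),
               gpr = "gHMGCR", subsystem = "sterol"),

    # storage and polymers
    GLYCOGS = r(s(`g6p[c]` = -1, `atp[c]` = -1, `glycogen[c]` = 1,
                  `adp[c]` = 1, `pi[c]` = 2),
                gpr = "gGYS", subsystem = "glycogen"),
    GLYCOGP = r(s(`glycogen[c]` = -1, `pi[c]` = -1, `g6p[c]` = 1),
                gpr = "gPYGL", subsystem = "glycogen"),
    PROTS  = r(s(`ala[c]` = -0.3, `asp[c]` = -0.2, `glu[c]` = -0.2,
                 `ser[c]` = -0.15, `gly[c]` = -0.15, `atp[c]` = -4,
                 `h2o[c]` = -4,
                 `prot[c]` = 1, `adp[c]` = 4, `pi[c]` = 4),
               gpr = "gRPL", subsystem = "protein"),
    RNAS   = r(s(`amp[c]` = -0.3, `gmp[c]` = -0.2, `ump[c]` = -0.3,
                 `cmp[c]` = -0.2, `atp[c]` = -2,
                 `rna[c]` = 1, `adp[c]` = 2, `pi[c]` = 2),
               gpr = "gPOLR", subsystem = "rna"),
    BIOM   = r(s(`prot[c]` = -0.5, `rna[c]` = -0.1, `lipid[c]` = -0.15,
                 `sterol[c]` = -0.05, `glycogen[c]` = -0.05,
                 `atp[c]` = -30, `h2o[c]` = -30,
                 `biomass[c]` = 1, `adp[c]` = 30, `pi[c]` = 30),
               gpr = "gBIOM", subsystem = "biomass")
  )

  gem_model(reactions, id = "core")
}
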