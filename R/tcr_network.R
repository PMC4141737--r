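## The reconstructed rule-based model of proximal TCR/CD28 signaling.
##
## Ten proteins carry the sixteen measured pTyr-site observables (CD3G,
## LCK, ZAP70, LAT, PLCG1, WAS, PTPN6, PAG1, DOK1, DOK2); seven additional
## proteins are required for their regulation (CD3E, CD247, CD28, CSK,
## NCK, GRAP2, LCP2).  The stimulus is a pre-crosslinked anti-CD3/anti-CD28
## antibody species injected at t = 0 after equilibration.
##
## Mechanism summary:
##  * CD28 recruits LCK constitutively; ligand-engaged, CD28-bound LCK
##    trans-autophosphorylates Y394 (activation), provided the inhibitory
##    C-terminal Y505 is unphosphorylated.
##  * Active LCK phosphorylates receptor-proximal sites without any ITAM
##    prerequisite (CD3G Y171, CD3E Y188, CD247 ITAM, PTPN6 Y566): class 1.
##  * ZAP70 docks on the phosphorylated CD247 ITAM; only docked ZAP70 is
##    phosphorylated by LCK (Y493 activation loop, Y292, Y319): class 2.
##    Active ZAP70 phosphorylates LAT and LCP2; LAT pY191 recruits GRAP2,
##    which carries LCP2; phospho-LCP2 recruits NCK and drives PLCG1 Y783.
##  * Negative regulation: PAG1 pY163 and DOK1 pY449 recruit CSK, which
##    phosphorylates LCK Y505; CD45-like background dephosphorylates it.
##  * PTPN6 positive feedback: LCK activates PTPN6 (Y566); active PTPN6
##    dephosphorylates the inhibitory sites LCK Y192, PAG1 Y163, DOK1
##    Y449 and DOK2 Y299 (class 3), releasing CSK and promoting LCK
##    activity.
##  * Shortcut: the NCK N-terminal SH3 binds the CD3E proline-rich
##    sequence while CD3E Y188 is unphosphorylated (mutual exclusion),
##    pre-positioning NCK-bound WAS for fast Y291 phosphorylation;
##    Y188 phosphorylation disengages the shortcut as the LCP2-dependent
##    route takes over.

#' Default reconstructed parameter table for the TCR/CD28 model
#'
#' Rate constants are in events/s (bimolecular constants are per reactant
#' pair, copy-number units; a single well-mixed volume is assumed) and
#' copy numbers in molecules per cell.  Values are reconstructed -- chosen
#' by fitting so that the model reproduces the qualitative site dynamics
#' and knockdown directions -- and should not be read as measured
#' kinetic constants.
#'
#' @return Named numeric vector of parameters (names starting with
#'   \code{N_} are seed copy numbers).
#' @export
default_tcr_params <- function() {
  c(
    ## copy numbers
    N_Lig = 400, N_CD3E = 300, N_CD3G = 300, N_CD247 = 300, N_CD28 = 300,
    N_LCK = 400, N_CSK = 300, N_PAG1 = 300, N_PTPN6 = 300, N_ZAP70 = 400,
    N_LAT = 500, N_GRAP2 = 300, N_LCP2 = 300, N_NCK = 400, N_WAS = 300,
    N_PLCG1 = 300, N_DOK1 = 200, N_DOK2 = 200,
    ## ligand engagement (irreversible antibody crosslinking)
    k_lig_cd3 = 2e-3, k_lig_cd28 = 2e-3,
    ## constitutive CD28-LCK recruitment
    k_cd28lck_on = 5e-4, k_cd28lck_off = 0.01,
    ## LCK activation loop Y394
    k_lck_act = 1.0, k_lck_basal = 0.004, k_lck_deact = 0.1,
    ## LCK substrates (class 1)
    k_cd3g = 4e-4, k_cd3e = 8e-4, k_itam = 3e-4, k_ptpn6_act = 1.5e-3,
    ## generic constitutive site phosphatase background
    k_site_dephos = 0.02, k_cd3e_dephos = 0.005,
    k_ptpn6_deact = 0.03,
    ## ZAP70 recruitment and activation (class 2)
    k_zap_on = 1e-3, k_zap_off = 0.1,
    k_zap_y493 = 1e-3, k_zap_y292 = 3e-4, k_zap_y319 = 3e-4,
    ## ZAP70 substrates
    k_lat = 3e-4, k_lcp2 = 3e-4,
    ## adaptor binding
    k_sh2_on = 1e-3, k_sh2_off = 0.05,
    k_gads_on = 1e-3, k_gads_off = 0.05,
    k_sh3_on = 1e-3, k_sh3_off = 0.05,
    k_nck_cd3e_on = 1e-3, k_nck_cd3e_off = 0.05,
    ## WAS and PLCG1
    k_was = 1e-3, k_plcg1 = 2e-4,
    ## inhibitory sites: basal phosphorylation pressure and slow decay
    k_y192_p = 1e-4, k_y192_basal = 0.03, k_y192_dephos = 0.005,
    k_pag_basal = 0.025, k_y163_dephos = 0.005,
    k_dok_basal = 0.025, k_dok_dephos = 0.005,
    ## PTPN6 catalysis on inhibitory sites
    k_ptpn6_cat = 1.5e-3,
    ## CSK / Y505 cycle
    k_csk = 1e-3, k_csk_off = 0.1, k_cd45 = 0.1
  )
}

#' Roster of phosphosites in the TCR/CD28 model
#'
#' The sixteen measured pTyr sites span ten proteins; three further sites
#' (CD3E Y188, CD247 Y142, LCP2 Y128) are modeled but not part of the
#' measured roster.  Site classes: 1 = phosphorylated without dependence
#' on prior receptor phosphorylation, 2 = phosphorylated only after ITAM
#' phosphorylation (ZAP70-dependent), 3 = dephosphorylated upon
#' stimulation.
#'
#' @return Data frame with columns \code{protein}, \code{residue},
#'   \code{observable} (model observable name), \code{site_class},
#'   \code{measured}.
#' @export
tcr_site_roster <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
protein residue observable site_class measured
CD3G    171 CD3G_Y171  1 TRUE
LCK     394 LCK_Y394   1 TRUE
PTPN6   566 PTPN6_Y566 1 TRUE
WAS     291 WAS_Y291   1 TRUE
ZAP70   292 ZAP70_Y292 2 TRUE
ZAP70   319 ZAP70_Y319 2 TRUE
ZAP70   493 ZAP70_Y493 2 TRUE
LAT     132 LAT_Y132   2 TRUE
LAT     191 LAT_Y191   2 TRUE
LAT     226 LAT_Y226   2 TRUE
PLCG1   783 PLCG1_Y783 2 TRUE
LCK     192 LCK_Y192   3 TRUE
LCK     505 LCK_Y505   3 TRUE
PAG1    163 PAG1_Y163  3 TRUE
DOK1    449 DOK1_Y449  3 TRUE
DOK2    299 DOK2_Y299  3 TRUE
CD3E    188 CD3E_Y188  1 FALSE
CD247   142 CD247_Y142 1 FALSE
LCP2    128 LCP2_Y128  2 FALSE
")
  df
}

#' Site class of a roster entry
#'
#' @param roster A roster data frame (default [tcr_site_roster()]).
#' @param protein Protein name, e.g. \code{"CD3G"}.
#' @param residue Tyrosine residue number, e.g. \code{171}.
#' @return Integer class label (1, 2 or 3).
#' @export
site_class_of <- function(roster = tcr_site_roster(), protein, residue) {
  hit <- roster$protein == protein & roster$residue == residue
  if (!any(hit)) stop("unknown site: ", protein, " Y", residue)
  roster$site_class[hit][1]
}

#' Build the TCR/CD28 signaling model
#'
#' Assembles the rule-based model as BNGL-subset text and parses it into a
#' validated \code{model_spec}.  The stimulus species \code{Lig(cd3,cd28)}
#' (pre-crosslinked anti-CD3/anti-CD28 antibody) is not seeded; inject it
#' at t = 0 through the protocol (see [tcr_protocol()]).
#'
#' @param params Named parameter vector, see [default_tcr_params()].
#' @param shortcut_enabled Include the NCK N-SH3 / CD3E PRS shortcut
#'   (mutually exclusive with CD3E Y188 phosphorylation).
#' @param ptpn6_feedback_enabled Include active-PTPN6 dephosphorylation of
#'   LCK Y192, PAG1 Y163, DOK1 Y449 and DOK2 Y299 (the positive-feedback
#'   mechanism).
#' @param ptpn6_direct_y505 Additionally let active PTPN6 dephosphorylate
#'   LCK Y505 directly (off by default; the default route is indirect,
#'   through PAG1 dephosphorylation and CSK release).
#' @return A validated \code{model_spec}.
#' @export
build_tcr_model <- function(params = default_tcr_params(),
                            shortcut_enabled = TRUE,
                            ptpn6_feedback_enabled = TRUE,
                            ptpn6_direct_y505 = FALSE) {
  need <- names(default_tcr_params())
  missing <- setdiff(need, names(params))
  if (length(missing) > 0L)
    stop("missing parameter(s): ", paste(missing, collapse = ", "))

  lines <- c("begin parameters")
  rates <- params[!grepl("^N_", names(params))]
  lines <- c(lines, sprintf("  %s %.15g", names(rates), unname(rates)),
             "end parameters", "", "begin molecule types",
    "  Lig(cd3,cd28) E",
    "  CD3E(lig,prs,y188~U~P) M",
    "  CD3G(y171~U~P) M",
    "  CD247(y142~U~P) M",
    "  CD28(lig,lck) M",
    "  LCK(cd28,y192~U~P,y394~U~P,y505~U~P) C",
    "  CSK(sh2) C",
    "  PAG1(y163~U~P) M",
    "  PTPN6(y566~U~P) C",
    "  ZAP70(sh2,y292~U~P,y319~U~P,y493~U~P) C",
    "  LAT(y132~U~P,y191~U~P,y226~U~P) M",
    "  GRAP2(sh2,sh3) C",
    "  LCP2(gads,y128~U~P) C",
    "  NCK(nsh3,sh2,csh3) C",
    "  WAS(prs,y291~U~P) C",
    "  PLCG1(y783~U~P) C",
    "  DOK1(y449~U~P) C",
    "  DOK2(y299~U~P) C",
    "end molecule types", "", "begin seed species")

  seed <- function(sp, n) sprintf("  %s %d", sp, as.integer(params[[n]]))
  lines <- c(lines,
    seed("CD3E(lig,prs,y188~U)", "N_CD3E"),
    seed("CD3G(y171~U)", "N_CD3G"),
    seed("CD247(y142~U)", "N_CD247"),
    seed("CD28(lig,lck)", "N_CD28"),
    seed("LCK(cd28,y192~P,y394~U,y505~P)", "N_LCK"),
    seed("CSK(sh2)", "N_CSK"),
    seed("PAG1(y163~P)", "N_PAG1"),
    seed("PTPN6(y566~U)", "N_PTPN6"),
    seed("ZAP70(sh2,y292~U,y319~U,y493~U)", "N_ZAP70"),
    seed("LAT(y132~U,y191~U,y226~U)", "N_LAT"),
    seed("GRAP2(sh2,sh3)", "N_GRAP2"),
    seed("LCP2(gads,y128~U)", "N_LCP2"),
    seed("NCK(nsh3,sh2,csh3)", "N_NCK"),
    seed("WAS(prs,y291~U)", "N_WAS"),
    seed("PLCG1(y783~U)", "N_PLCG1"),
    seed("DOK1(y449~P)", "N_DOK1"),
    seed("DOK2(y299~P)", "N_DOK2"),
    "end seed species", "", "begin observables")

  roster <- tcr_site_roster()
  comp_of <- c(CD3G_Y171 = "CD3G(y171~P!?)", LCK_Y394 = "LCK(y394~P!?)",
    PTPN6_Y566 = "PTPN6(y566~P!?)", WAS_Y291 = "WAS(y291~P!?)",
    ZAP70_Y292 = "ZAP70(y292~P!?)", ZAP70_Y319 = "ZAP70(y319~P!?)",
    ZAP70_Y493 = "ZAP70(y493~P!?)", LAT_Y132 = "LAT(y132~P!?)",
    LAT_Y191 = "LAT(y191~P!?)", LAT_Y226 = "LAT(y226~P!?)",
    PLCG1_Y783 = "PLCG1(y783~P!?)", LCK_Y192 = "LCK(y192~P!?)",
    LCK_Y505 = "LCK(y505~P!?)", PAG1_Y163 = "PAG1(y163~P!?)",
    DOK1_Y449 = "DOK1(y449~P!?)", DOK2_Y299 = "DOK2(y299~P!?)",
    CD3E_Y188 = "CD3E(y188~P!?)", CD247_Y142 = "CD247(y142~P!?)",
    LCP2_Y128 = "LCP2(y128~P!?)")
  stopifnot(all(roster$observable %in% names(comp_of)))
  lines <- c(lines,
    sprintf("  Molecules %s %s", names(comp_of), unname(comp_of)),
    "  Molecules NCK_CD3E NCK(nsh3!1).CD3E(prs!1)",
    "  Molecules NCK_pLCP2 NCK(sh2!1).LCP2(y128~P!1)",
    "  Molecules ACT_LCK LCK(y394~P,y505~U)",
    "end observables", "", "begin reaction rules")

  act_lck <- "LCK(y394~P,y505~U)"
  rules <- c(
    sprintf("lig_cd3: Lig(cd3) + CD3E(lig) -> Lig(cd3!1).CD3E(lig!1) k_lig_cd3"),
    sprintf("lig_cd28: Lig(cd28) + CD28(lig) -> Lig(cd28!1).CD28(lig!1) k_lig_cd28"),
    "cd28_lck_on: CD28(lck) + LCK(cd28) -> CD28(lck!1).LCK(cd28!1) k_cd28lck_on",
    "cd28_lck_off: CD28(lck!1).LCK(cd28!1) -> CD28(lck) + LCK(cd28) k_cd28lck_off",
    ## LCK activation: ligand-engaged CD28-bound LCK, plus a weak basal route
    paste0("lck_act_stim: LCK(cd28!1,y394~U,y505~U).CD28(lck!1,lig!2).Lig(cd28!2)",
           " -> LCK(cd28!1,y394~P,y505~U).CD28(lck!1,lig!2).Lig(cd28!2) k_lck_act"),
    "lck_act_basal: LCK(y394~U,y505~U) -> LCK(y394~P,y505~U) k_lck_basal",
    "lck_deact: LCK(y394~P) -> LCK(y394~U) k_lck_deact",
    ## class-1 substrates of active LCK
    sprintf("p_cd3g: %s + CD3G(y171~U) -> %s + CD3G(y171~P) k_cd3g", act_lck, act_lck),
    sprintf("p_cd3e: %s + CD3E(prs,y188~U) -> %s + CD3E(prs,y188~P) k_cd3e", act_lck, act_lck),
    sprintf("p_cd247: %s + CD247(y142~U) -> %s + CD247(y142~P) k_itam", act_lck, act_lck),
    sprintf("p_ptpn6: %s + PTPN6(y566~U) -> %s + PTPN6(y566~P) k_ptpn6_act", act_lck, act_lck),
    "u_cd3g: CD3G(y171~P) -> CD3G(y171~U) k_site_dephos",
    "u_cd3e: CD3E(y188~P) -> CD3E(y188~U) k_cd3e_dephos",
    "u_cd247: CD247(y142~P) -> CD247(y142~U) k_site_dephos",
    "u_ptpn6: PTPN6(y566~P) -> PTPN6(y566~U) k_ptpn6_deact",
    ## ZAP70 docking on the phospho-ITAM; docked ZAP70 is an LCK substrate
    "zap_on: ZAP70(sh2) + CD247(y142~P) -> ZAP70(sh2!1).CD247(y142~P!1) k_zap_on",
    "zap_off: ZAP70(sh2!1).CD247(y142~P!1) -> ZAP70(sh2) + CD247(y142~P) k_zap_off",
    sprintf("p_zap_y493: %s + ZAP70(sh2!+,y493~U) -> %s + ZAP70(sh2!+,y493~P) k_zap_y493", act_lck, act_lck),
    sprintf("p_zap_y292: %s + ZAP70(sh2!+,y292~U) -> %s + ZAP70(sh2!+,y292~P) k_zap_y292", act_lck, act_lck),
    sprintf("p_zap_y319: %s + ZAP70(sh2!+,y319~U) -> %s + ZAP70(sh2!+,y319~P) k_zap_y319", act_lck, act_lck),
    "u_zap_y493: ZAP70(y493~P) -> ZAP70(y493~U) k_site_dephos",
    "u_zap_y292: ZAP70(y292~P) -> ZAP70(y292~U) k_site_dephos",
    "u_zap_y319: ZAP70(y319~P) -> ZAP70(y319~U) k_site_dephos",
    ## active-ZAP70 substrates
    "p_lat_y132: ZAP70(y493~P) + LAT(y132~U) -> ZAP70(y493~P) + LAT(y132~P) k_lat",
    "p_lat_y191: ZAP70(y493~P) + LAT(y191~U) -> ZAP70(y493~P) + LAT(y191~P) k_lat",
    "p_lat_y226: ZAP70(y493~P) + LAT(y226~U) -> ZAP70(y493~P) + LAT(y226~P) k_lat",
    "p_lcp2: ZAP70(y493~P) + LCP2(y128~U) -> ZAP70(y493~P) + LCP2(y128~P) k_lcp2",
    "u_lat_y132: LAT(y132~P) -> LAT(y132~U) k_site_dephos",
    "u_lat_y191: LAT(y191~P) -> LAT(y191~U) k_site_dephos",
    "u_lat_y226: LAT(y226~P) -> LAT(y226~U) k_site_dephos",
    "u_lcp2: LCP2(y128~P) -> LCP2(y128~U) k_site_dephos",
    ## adaptor assembly: LAT -> GRAP2 -> LCP2 -> NCK -> WAS (long route)
    "grap2_lat_on: GRAP2(sh2) + LAT(y191~P) -> GRAP2(sh2!1).LAT(y191~P!1) k_sh2_on",
    "grap2_lat_off: GRAP2(sh2!1).LAT(y191~P!1) -> GRAP2(sh2) + LAT(y191~P) k_sh2_off",
    "grap2_lcp2_on: GRAP2(sh3) + LCP2(gads) -> GRAP2(sh3!1).LCP2(gads!1) k_gads_on",
    "grap2_lcp2_off: GRAP2(sh3!1).LCP2(gads!1) -> GRAP2(sh3) + LCP2(gads) k_gads_off",
    "nck_lcp2_on: NCK(sh2) + LCP2(y128~P) -> NCK(sh2!1).LCP2(y128~P!1) k_sh2_on",
    "nck_lcp2_off: NCK(sh2!1).LCP2(y128~P!1) -> NCK(sh2) + LCP2(y128~P) k_sh2_off",
    "nck_was_on: NCK(csh3) + WAS(prs) -> NCK(csh3!1).WAS(prs!1) k_sh3_on",
    "nck_was_off: NCK(csh3!1).WAS(prs!1) -> NCK(csh3) + WAS(prs) k_sh3_off",
    ## WAS Y291: phosphorylated when carried by NCK engaged at either end
    sprintf("p_was_long: %s + WAS(y291~U,prs!1).NCK(csh3!1,sh2!+) -> %s + WAS(y291~P,prs!1).NCK(csh3!1,sh2!+) k_was", act_lck, act_lck),
    "u_was: WAS(y291~P) -> WAS(y291~U) k_site_dephos",
    ## PLCG1 Y783 requires phospho-LCP2
    "p_plcg1: LCP2(y128~P!?) + PLCG1(y783~U) -> LCP2(y128~P!?) + PLCG1(y783~P) k_plcg1",
    "u_plcg1: PLCG1(y783~P) -> PLCG1(y783~U) k_site_dephos",
    ## inhibitory sites: basal kinase pressure, slow background decay
    "p_y192_zap: ZAP70(y493~P) + LCK(y192~U) -> ZAP70(y493~P) + LCK(y192~P) k_y192_p",
    "p_y192_basal: LCK(y192~U) -> LCK(y192~P) k_y192_basal",
    "u_y192_basal: LCK(y192~P) -> LCK(y192~U) k_y192_dephos",
    "p_y163_basal: PAG1(y163~U) -> PAG1(y163~P) k_pag_basal",
    "u_y163_basal: PAG1(y163~P) -> PAG1(y163~U) k_y163_dephos",
    "p_dok1_basal: DOK1(y449~U) -> DOK1(y449~P) k_dok_basal",
    "u_dok1_basal: DOK1(y449~P) -> DOK1(y449~U) k_dok_dephos",
    "p_dok2_basal: DOK2(y299~U) -> DOK2(y299~P) k_dok_basal",
    "u_dok2_basal: DOK2(y299~P) -> DOK2(y299~U) k_dok_dephos",
    ## CSK recruitment by PAG1 pY163 / DOK1 pY449 and the Y505 cycle
    "csk_pag_on: CSK(sh2) + PAG1(y163~P) -> CSK(sh2!1).PAG1(y163~P!1) k_sh2_on",
    "csk_pag_off: CSK(sh2!1).PAG1(y163~P!1) -> CSK(sh2) + PAG1(y163~P) k_csk_off",
    "csk_dok1_on: CSK(sh2) + DOK1(y449~P) -> CSK(sh2!1).DOK1(y449~P!1) k_sh2_on",
    "csk_dok1_off: CSK(sh2!1).DOK1(y449~P!1) -> CSK(sh2) + DOK1(y449~P) k_csk_off",
    "p_y505: CSK(sh2!+) + LCK(y505~U) -> CSK(sh2!+) + LCK(y505~P) k_csk",
    "u_y505: LCK(y505~P) -> LCK(y505~U) k_cd45"
  )
  ## p_was_short is always present but can only fire when the NCK N-SH3
  ## is engaged; disabling the shortcut removes only the NCK-CD3E binding
  ## rules, leaving every other rule unchanged.
  rules <- c(rules,
    sprintf("p_was_short: %s + WAS(y291~U,prs!1).NCK(csh3!1,nsh3!+) -> %s + WAS(y291~P,prs!1).NCK(csh3!1,nsh3!+) k_was", act_lck, act_lck))
  if (shortcut_enabled) {
    rules <- c(rules,
      "nck_cd3e_on: NCK(nsh3) + CD3E(prs,y188~U) -> NCK(nsh3!1).CD3E(prs!1,y188~U) k_nck_cd3e_on",
      "nck_cd3e_off: NCK(nsh3!1).CD3E(prs!1) -> NCK(nsh3) + CD3E(prs) k_nck_cd3e_off")
  }
  if (ptpn6_feedback_enabled) {
    rules <- c(rules,
      "shp1_y192: PTPN6(y566~P) + LCK(y192~P) -> PTPN6(y566~P) + LCK(y192~U) k_ptpn6_cat",
      "shp1_y163: PTPN6(y566~P) + PAG1(y163~P) -> PTPN6(y566~P) + PAG1(y163~U) k_ptpn6_cat",
      "shp1_dok1: PTPN6(y566~P) + DOK1(y449~P) -> PTPN6(y566~P) + DOK1(y449~U) k_ptpn6_cat",
      "shp1_dok2: PTPN6(y566~P) + DOK2(y299~P) -> PTPN6(y566~P) + DOK2(y299~U) k_ptpn6_cat")
  }
  if (ptpn6_direct_y505) {
    rules <- c(rules,
      "shp1_y505: PTPN6(y566~P) + LCK(y505~P) -> PTPN6(y566~P) + LCK(y505~U) k_ptpn6_cat")
  }
  lines <- c(lines, paste0("  ", rules), "end reaction rules")
  parse_model(lines)
}

#' Simulation protocol for the TCR/CD28 model
#'
#' Wraps [sim_protocol()] with the \{0, 5, 15, 30, 60\} s observation
#' grid and the antibody-crosslinker stimulus.
#'
#' @param params Parameter vector (used for the stimulus copy number).
#' @param t_eq Equilibration time (s).
#' @param n_runs Runs to average.
#' @param seed Base seed.
#' @return A \code{sim_protocol}.
#' @export
tcr_protocol <- function(params = default_tcr_params(), t_eq = 300,
                         n_runs = 100L, seed = 1L) {
  sim_protocol(t_eq = t_eq, grid = c(0, 5, 15, 30, 60), n_runs = n_runs,
               seed = seed,
               stimulus = list(list(species = "Lig(cd3,cd28)",
                                    count = as.integer(params[["N_Lig"]]))))
}

#' Apply an in-silico knockdown
#'
#' Sets the seed copy number of every seed species containing the given
#' protein to zero, leaving all rules untouched (the modeling analog of
#' RNAi depletion).  Idempotent.
#'
#' @param spec A \code{model_spec}.
#' @param protein Molecule type name, e.g. \code{"PTPN6"} or \code{"LCP2"}.
#' @return The modified \code{model_spec}.
#' @export
apply_knockdown <- function(spec, protein) {
  if (!protein %in% names(spec$molecule_types))
    stop("unknown protein: ", protein)
  hit <- FALSE
  for (k in seq_along(spec$seed_species)) {
    types <- vapply(spec$seed_species[[k]]$pattern, `[[`, "", "type")
    if (protein %in% types) {
      spec$seed_species[[k]]$count <- 0L
      hit <- TRUE
    }
  }
  if (!hit) warning("protein '", protein, "' has no seed species")
  spec
}

## ---- derived readouts ---------------------------------------------------

#' Phosphorylation relative to the unstimulated baseline
#'
#' Divides an observable's averaged time course by its t = 0 value (or an
#' externally supplied baseline, e.g. the wild-type baseline when
#' normalizing knockdown simulations).  When the baseline is zero, a
#' pseudocount \code{eps} is added to both numerator and denominator.
#'
#' @param ensemble A \code{kmc_ensemble} (or \code{kmc_trajectory}).
#' @param site Observable name, e.g. \code{"LCK_Y192"}.
#' @param baseline Optional external baseline count; defaults to the
#'   ensemble's own t = 0 mean.
#' @param eps Pseudocount guarding a zero baseline (default 0.5).
#' @return A \code{relative_timecourse}: list with \code{site},
#'   \code{times}, \code{values}.
#' @export
relative_timecourse <- function(ensemble, site, baseline = NULL, eps = 0.5) {
  vals <- if (inherits(ensemble, "kmc_trajectory")) ensemble$counts[, site]
          else ensemble$mean[, site]
  times <- ensemble$times
  b <- if (is.null(baseline)) vals[which(times == 0)[1]] else baseline
  rel <- if (b == 0) (vals + eps) / eps else vals / b
  structure(list(site = site, times = times, values = unname(rel)),
            class = "relative_timecourse")
}

#' Cumulative phosphorylation (area under the relative time course)
#'
#' Trapezoidal integral of relative phosphorylation over a window,
#' dimensionless times seconds.
#'
#' @param tc A \code{relative_timecourse} (or list with \code{times},
#'   \code{values}).
#' @param window Integration window in seconds (default 0--60 s).
#' @return The area.
#' @export
cumulative_auc <- function(tc, window = c(0, 60)) {
  if (window[1] < min(tc$times) || window[2] > max(tc$times))
    stop("integration window outside the observation grid")
  keep <- tc$times >= window[1] & tc$times <= window[2]
  x <- tc$times[keep]; y <- tc$values[keep]
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Scale a time course to its 60-s endpoint
#'
#' Divides every value by the value at the last grid time, so courses of
#' different amplitude can be compared by shape (each equals 1 at 60 s).
#'
#' @param tc A \code{relative_timecourse}.
#' @return The scaled course.
#' @export
scale_to_endpoint <- function(tc) {
  endv <- tc$values[which.max(tc$times)]
  if (endv == 0) stop("endpoint value is zero; cannot scale")
  tc$values <- tc$values / endv
  tc
}

#' Time of half-maximal rise
#'
#' First time at which a (relative) time course crosses the midpoint
#' between its initial and maximal value, by linear interpolation.
#'
#' @param tc A \code{relative_timecourse}.
#' @return Time in seconds (\code{NA} if the course never rises).
#' @export
half_rise_time <- function(tc) {
  v <- tc$values; t <- tc$times
  vmax <- max(v)
  if (vmax <= v[1]) return(NA_real_)
  target <- v[1] + (vmax - v[1]) / 2
  for (i in seq_len(length(v) - 1L)) {
    if (v[i] < target && v[i + 1L] >= target) {
      return(t[i] + (t[i + 1L] - t[i]) * (target - v[i]) / (v[i + 1L] - v[i]))
    }
  }
  NA_real_
}

#' @export
print.relative_timecourse <- function(x, ...) {
  cat(sprintf("relative_timecourse %s: %s\n", x$site,
              paste(sprintf("%g s: %.3g", x$times, x$values), collapse = ", ")))
  invisible(x)
}
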