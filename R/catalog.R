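#' The simulated biophysical score-term catalog
#'
#' Sixty named score terms emulating a molecular-mechanics scoring pipeline:
#' 20 full-atom energy terms (including the aggregate `total_score`), 13
#' centroid-level terms, and 27 structure-quality filter terms. Five of the
#' sixty are near-constant in practice and are removed by
#' [drop_excluded_terms()], leaving the 55 pretraining tasks.
#'
#' @return Character vector of 60 unique term names.
#' @seealso [binding_terms()], [excluded_terms()]
#' @export
score_terms <- function() {
  c(
    # full-atom energy terms
    "total_score", "fa_atr", "fa_rep", "fa_sol", "fa_intra_rep",
    "fa_intra_sol_xover4", "lk_ball_wtd", "fa_elec", "pro_close",
    "hbond_sr_bb", "hbond_lr_bb", "hbond_bb_sc", "hbond_sc", "dslf_fa13",
    "omega", "fa_dun", "p_aa_pp", "yhh_planarity", "ref", "rama_prepro",
    # centroid-level terms
    "centroid_total_score", "vdw", "env", "pair", "cbeta", "cenpack",
    "hs_pair", "ss_pair", "rsigma", "sheet", "chainbreak",
    "linear_chainbreak", "overlap_chainbreak",
    # filter terms
    "filter_total_score", "res_count_all", "buried_np", "buried_np_per_res",
    "buried_over_exposed", "buried_minus_exposed", "contact_all",
    "contact_core_sasa", "contact_core_scn", "degree", "degree_core_sasa",
    "exposed_hydrophobics", "exposed_np_afilmvwy", "exposed_polars",
    "exposed_total", "frac_sheet", "n_charged", "n_hydrophobic",
    "n_polar_core", "nres_helix", "nres_loop", "nres_sheet", "pack",
    "ss_sc", "total_sasa", "unsat_hbond", "mismatch_probability"
  )
}

#' @rdname score_terms
#' @details `excluded_terms()` names the five terms dropped before
#'   pretraining: one full-atom term, two centroid chain-break terms, the
#'   aggregate filter score, and the constant residue count.
#' @export
excluded_terms <- function() {
  c("dslf_fa13", "linear_chainbreak", "overlap_chainbreak",
    "filter_total_score", "res_count_all")
}

#' @rdname score_terms
#' @details `binding_terms()` names the 17 optional interface/binding score
#'   terms; enabling them alongside the 55 retained terms yields 72
#'   pretraining tasks.
#' @export
binding_terms <- function() {
  c("complex_normalized", "dG_cross", "dG_separated",
    "dG_separated_per_dSASA", "dSASA_hphobic", "dSASA_int", "dSASA_polar",
    "delta_unsat_hbonds", "hbond_E_fraction", "hbonds_int", "nres_int",
    "per_residue_energy_int", "side1_normalized", "side1_score",
    "side2_normalized", "side2_score", "packstat")
}
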