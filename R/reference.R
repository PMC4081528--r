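#' Comparative water permeabilities of AQP-expressing epithelia
#'
#' Literature reference table of diffusional (P_D) and osmotic (P_f) water
#' permeability coefficients and their ratio for epithelia commonly used
#' as comparators, together with the cochlear values computed by this
#' package's pipeline. Values are stated in the units conventionally
#' printed for each quantity (P_D in 1e-5 cm/s, P_f in 1e-4 cm/s). `NA`
#' marks quantities not reported for that tissue.
#'
#' @return A `data.frame` with columns `epithelium`, `Pd_1e5_cm_s`,
#'   `Pf_1e4_cm_s`, `ratio_Pf_Pd`, `citation_key`.
#' @export
reference_epithelia <- function() {
  df <- data.frame(
    epithelium = c("lung alveolar epithelium",
                   "corneal epithelium",
                   "cochlear duct epithelium (this pipeline)",
                   "conjunctival epithelium",
                   "salivary gland acinar epithelium",
                   "kidney cortical collecting duct (no ADH)",
                   "kidney proximal convoluted tubule",
                   "outer sulcus cell shunt, cochlear apex (this pipeline)",
                   "MDCK type I monolayer"),
    Pd_1e5_cm_s = c(1.30, 1.68, 8.18, 13, 300, NA, NA, 64.83, NA),
    Pf_1e4_cm_s = c(NA, NA, 6.15, 11, NA, NA, 5000, 1569.0, NA),
    ratio_Pf_Pd = c(1307.69, NA, 7.52, 8.46, 6.67, 2.03, NA, 242.02, 1),
    citation_key = c("alveolar", "cornea", "cde", "conjunctiva",
                     "salivary", "ccd", "pct", "osc_apex", "mdck"),
    stringsAsFactors = FALSE)
  df
}
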