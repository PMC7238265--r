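#' Unit conventions
#'
#' Internal amounts are micrograms everywhere; volumes are litres; time is
#' hours. Concentrations are reported in the unit each assay and potency
#' parameter is expressed in: nanograms per millilitre for budesonide
#' (1 ug/L == 1 ng/mL) and picograms per millilitre for formoterol
#' (1 ug/L == 1000 pg/mL). These factors convert a native ug/L concentration
#' into the drug's reporting unit and are used for plasma and lung
#' concentrations alike, so that IC50/EC50 and LLOQ values can be compared
#' directly against model output.
#'
#' @param drug_id `"budesonide"` or `"formoterol"`.
#' @return Multiplicative factor from ug/L to the drug's concentration unit.
#' @keywords internal
conc_unit_factor <- function(drug_id) {
  switch(match.arg(drug_id, c("budesonide", "formoterol")),
    budesonide = 1,      # ug/L -> ng/mL
    formoterol = 1000    # ug/L -> pg/mL
  )
}

#' Lower limits of quantification
#'
#' Assay LLOQs in each drug's reporting unit: 0.1 ng/mL (100 pg/mL) for
#' budesonide and 1 pg/mL for formoterol. Concentrations below these are
#' flagged below the limit of quantification (BLQ).
#'
#' @param drug_id `"budesonide"` or `"formoterol"`.
#' @return LLOQ in the drug's concentration unit.
#' @export
#' @examples
#' lloq("budesonide")  # 0.1 ng/mL
#' lloq("formoterol")  # 1 pg/mL
lloq <- function(drug_id) {
  switch(match.arg(drug_id, c("budesonide", "formoterol")),
    budesonide = 0.1,
    formoterol = 1
  )
}

#' @keywords internal
hours_per_week <- 168
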