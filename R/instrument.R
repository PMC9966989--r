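# Static description of the 29-item stress-reaction instrument and of the
# 39-nutrient intake panel used throughout the package.

#' The 29-item stress-reaction instrument
#'
#' Returns the item table of the Brief Job Stress Questionnaire (BJSQ)
#' stress-reaction block: 29 items answered on a 4-point Likert scale,
#' grouped into six published subscales.  Items Q01--Q03 (vigor items) are
#' positively worded and therefore reverse-keyed: a *low* response indicates
#' the unfavourable pole.  For all other items a high response is
#' unfavourable.
#'
#' The `factor` column carries the five-factor assignment used to define
#' minor health complaints (MHCs): the anxiety and depressed-mood subscales
#' merge (together with the appetite and sleep items Q27/Q29) into a single
#' anxiety--depression factor, and the remaining somatic items form their
#' own factor.
#'
#' @return A data frame with one row per item and columns `item` (Q01..Q29),
#'   `text`, `subscale` (published six-subscale membership), `reverse`
#'   (logical, `TRUE` for Q01--Q03), and `factor` (five-factor membership).
#' @export
#' @examples
#' instr <- bjsq_instrument()
#' table(instr$subscale)
bjsq_instrument <- function() {
  items <- sprintf("Q%02d", 1:29)
  text <- c(
    "I have been very active",
    "I have been full of energy",
    "I have been lively",
    "I have felt angry",
    "I have been inwardly annoyed or aggravated",
    "I have felt irritable",
    "I have felt extremely tired",
    "I have felt exhausted",
    "I have felt weary or listless",
    "I have felt tense",
    "I have felt worried or insecure",
    "I have felt restless",
    "I have been depressed",
    "I have thought that doing anything was a hassle",
    "I have been unable to concentrate",
    "I have felt gloomy",
    "I have been unable to handle work",
    "I have felt sad",
    "I have felt dizzy",
    "I have experienced joint pains",
    "I have experienced headaches",
    "I have had a stiff neck and/or shoulders",
    "I have had lower back pain",
    "I have had eyestrain",
    "I have experienced heart palpitations or shortness of breath",
    "I have experienced stomach and/or intestine problems",
    "I have lost my appetite",
    "I have experienced diarrhea and/or constipation",
    "I have not been able to sleep well"
  )
  subscale <- c(
    rep("lack_of_vigor", 3),
    rep("irritability", 3),
    rep("fatigue", 3),
    rep("anxiety", 3),
    rep("depressed_mood", 6),
    rep("somatic_symptoms", 11)
  )
  factor <- c(
    rep("lack_of_vigor", 3),
    rep("irritability", 3),
    rep("fatigue", 3),
    rep("anxiety_depression", 9),
    rep("somatic_symptoms", 8),  # Q19..Q26
    "anxiety_depression",        # Q27 (appetite)
    "somatic_symptoms",          # Q28 (diarrhea/constipation)
    "anxiety_depression"         # Q29 (sleep)
  )
  data.frame(item = items, text = text, subscale = subscale,
             reverse = seq_len(29) <= 3, factor = factor,
             stringsAsFactors = FALSE)
}

#' Published six-subscale item sets
#'
#' @return Named list of item-code vectors for the six published subscales.
#' @export
bjsq_subscales <- function() {
  instr <- bjsq_instrument()
  split(instr$item, instr$subscale)[
    c("lack_of_vigor", "irritability", "fatigue", "anxiety",
      "depressed_mood", "somatic_symptoms")]
}

#' Five-factor item sets (MHC factor structure)
#'
#' Item sets of the five factors retained for the MHC definition, in the
#' conventional ML1..ML5 order: anxiety--depression, lack of vigor,
#' irritability, fatigue, somatic symptoms.
#'
#' @return Named list of item-code vectors.
#' @export
mhc_factors <- function() {
  instr <- bjsq_instrument()
  split(instr$item, instr$factor)[
    c("anxiety_depression", "lack_of_vigor", "irritability", "fatigue",
      "somatic_symptoms")]
}

#' The four MHC scales
#'
#' Item sets of the four minor health complaints: the anxiety--depression
#' factor is excluded because those complaints emerge only at higher
#' psychosomatic-disorder levels.  Somatic symptoms use the nine items that
#' load on the somatic factor (Q19--Q26 and Q28).
#'
#' @return Named list of item-code vectors for `lack_of_vigor`,
#'   `irritability`, `fatigue`, `somatic_symptoms`.
#' @export
mhc_items <- function() {
  mhc_factors()[c("lack_of_vigor", "irritability", "fatigue",
                  "somatic_symptoms")]
}

#' Direction map of the MHC scales
#'
#' For lack of vigor a *high* score means better psychosomatic status (the
#' vigor items are summed in the keyed direction, more vigor = higher
#' score); for irritability, fatigue and somatic symptoms a *low* score is
#' better.
#'
#' @return Named character vector, values `"high"` or `"low"`, naming the
#'   better-status side of a median split.
#' @export
mhc_direction <- function() {
  c(lack_of_vigor = "high", irritability = "low", fatigue = "low",
    somatic_symptoms = "low")
}

#' The 39-nutrient intake panel
#'
#' Column names, units and typical daily intakes of the 39 nutrients
#' screened against MHC levels.  `location` holds a plausible cohort mean
#' daily intake for an adult Japanese population (used as the synthetic
#' generator's default log-normal location); `planted` marks the 17
#' nutrients that the default synthetic configuration couples to MHC
#' status.
#'
#' @return Data frame with columns `nutrient` (column name, unit suffix
#'   included), `label`, `unit`, `location`, `planted`.
#' @export
nutrient_panel <- function() {
  p <- function(nutrient, label, unit, location, planted)
    list(nutrient = nutrient, label = label, unit = unit,
         location = location, planted = planted)
  rows <- list(
    p("Na_mg", "sodium", "mg", 3800, FALSE),
    p("K_mg", "potassium", "mg", 2450, TRUE),
    p("Ca_mg", "calcium", "mg", 500, FALSE),
    p("Mg_mg", "magnesium", "mg", 268, TRUE),
    p("P_mg", "phosphorus", "mg", 1085, TRUE),
    p("Fe_mg", "iron", "mg", 8.1, TRUE),
    p("Zn_mg", "zinc", "mg", 8.45, TRUE),
    p("Cu_mg", "copper", "mg", 1.15, TRUE),
    p("VA_ugRE", "vitamin A", "ugRE", 570, TRUE),
    p("Retinol_ug", "retinol", "ug", 250, FALSE),
    p("bCx_ug", "beta-cryptoxanthin", "ug", 225, TRUE),
    p("bCt_ug", "beta-carotene equivalents", "ug", 3100, TRUE),
    p("VD_ug", "vitamin D", "ug", 7.0, FALSE),
    p("VE_mg", "vitamin E", "mg", 7.0, FALSE),
    p("VK_ug", "vitamin K", "ug", 230, FALSE),
    p("VB1_mg", "vitamin B1", "mg", 0.97, TRUE),
    p("VB2_mg", "vitamin B2", "mg", 1.2, FALSE),
    p("Niacin_mgNE", "niacin", "mgNE", 32.2, TRUE),
    p("VB6_mg", "vitamin B6", "mg", 1.22, TRUE),
    p("VB12_ug", "vitamin B12", "ug", 6.0, FALSE),
    p("FA_ug", "folic acid", "ug", 300, TRUE),
    p("PA_mg", "pantothenic acid", "mg", 6.0, TRUE),
    p("VC_mg", "vitamin C", "mg", 95, FALSE),
    p("SFA_g", "saturated fatty acids", "g", 17, FALSE),
    p("MUFA_g", "monounsaturated fatty acids", "g", 20, FALSE),
    p("PUFA_g", "polyunsaturated fatty acids", "g", 12, FALSE),
    p("Chol_mg", "cholesterol", "mg", 330, FALSE),
    p("TDF_g", "total dietary fiber", "g", 18.3, TRUE),
    p("SDF_g", "soluble dietary fiber", "g", 3.5, FALSE),
    p("IDF_g", "insoluble dietary fiber", "g", 11.8, TRUE),
    p("n3FA_g", "n-3 fatty acids", "g", 2.2, FALSE),
    p("n6FA_g", "n-6 fatty acids", "g", 9.5, FALSE),
    p("TG_g", "triacylglycerol equivalents", "g", 55, FALSE),
    p("Mn_mg", "manganese", "mg", 3.8, FALSE),
    p("I_ug", "iodine", "ug", 150, FALSE),
    p("Se_ug", "selenium", "ug", 70, FALSE),
    p("Cr_ug", "chromium", "ug", 10, FALSE),
    p("Mo_ug", "molybdenum", "ug", 230, FALSE),
    p("Biotin_ug", "biotin", "ug", 41.3, TRUE)
  )
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
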