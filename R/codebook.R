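# The 26-disease codebook used by the medical-history questionnaire, in the
# reporting order of the source tables, plus the ICD-11-adapted organ-system
# grouping. Six indicators (artificial heart valve/pacemaker/hip,
# hyperventilation, epilepsy, allergy, chronic kidney disease, contagious
# disease) do not map cleanly onto a single ICD-11 chapter and stay ungrouped.

.codebook_table <- function() {
  data.frame(
    id = c(
      "angina_pectoris",
      "myocardial_infarction",
      "heart_murmur_valve_defect",
      "artificial_valve_pacemaker_hip",
      "heart_vascular_surgery",
      "cardiac_arrhythmia",
      "heart_weakness",
      "hyperventilation",
      "hypertension",
      "cerebrovascular_disease",
      "epilepsy",
      "asthma",
      "lung_disease",
      "allergic_rhinitis",
      "allergy",
      "diabetes_mellitus",
      "hyperthyroidism",
      "hypothyroidism",
      "liver_disease",
      "chronic_kidney_disease",
      "chronic_gastrointestinal_disease",
      "anemia",
      "malignant_lymph_blood_disease",
      "bleeding_diathesis",
      "radiation",
      "contagious_disease"
    ),
    label = c(
      "Angina pectoris",
      "Myocardial infarction",
      "Heart murmur or heart valve defect",
      "Artificial heart valve/pacemaker/hip",
      "Heart or vascular surgery",
      "Cardiac arrhythmia",
      "Heart weakness",
      "Hyperventilation",
      "Hypertension",
      "Cerebrovascular disease",
      "Epilepsy",
      "Asthma",
      "Lung disease",
      "Allergic rhinitis",
      "Allergy",
      "Diabetes mellitus",
      "Hyperthyroidism",
      "Hypothyroidism",
      "Liver disease",
      "Chronic kidney disease",
      "Chronic gastrointestinal disease",
      "Anemia",
      "Malignant lymph node or blood disease",
      "Bleeding diathesis",
      "Radiation",
      "Contagious disease"
    ),
    group = c(
      "cardiovascular",
      "cardiovascular",
      "cardiovascular",
      NA,
      "cardiovascular",
      "cardiovascular",
      "cardiovascular",
      NA,
      "cardiovascular",
      "cardiovascular",
      NA,
      "respiratory_tract",
      "respiratory_tract",
      "respiratory_tract",
      NA,
      "endocrine_nutritional_metabolic",
      "endocrine_nutritional_metabolic",
      "endocrine_nutritional_metabolic",
      "digestive_system",
      NA,
      "digestive_system",
      "blood",
      "neoplasms",
      "blood",
      "neoplasms",
      NA
    ),
    stringsAsFactors = FALSE
  )
}

#' Load the 26-disease codebook
#'
#' Returns the fixed questionnaire codebook: 26 disease indicators in table
#' order, each with a stable snake_case identifier, a display label, and
#' (for 20 of the 26) an ICD-11-adapted organ-system group. Group sizes are
#' cardiovascular 8, respiratory tract 3, endocrine/nutritional/metabolic 3,
#' digestive system 2, blood 2, neoplasms 2; the remaining 6 indicators are
#' ungrouped (`NA`).
#'
#' @return An object of class `disease_codebook`: a data.frame with columns
#'   `id`, `label`, `group`.
#' @examples
#' cb <- load_codebook()
#' nrow(cb)                      # 26
#' table(cb$group)               # ICD-11-adapted group sizes
#' @export
load_codebook <- function() {
  tab <- .codebook_table()
  stopifnot(nrow(tab) == 26L, !anyDuplicated(tab$id))
  class(tab) <- c("disease_codebook", "data.frame")
  tab
}

#' Diseases belonging to an ICD-11-adapted group
#'
#' @param codebook a `disease_codebook`.
#' @param group group label, one of the six labels in `codebook$group`.
#' @return character vector of disease ids.
#' @export
group_members <- function(codebook, group) {
  if (!group %in% stats::na.omit(unique(codebook$group))) {
    stop("unknown disease group: ", group)
  }
  codebook$id[!is.na(codebook$group) & codebook$group == group]
}

#' Write a codebook to JSON
#'
#' Serialises as `{"diseases": [{"id", "label", "group"}, ...]}` with `null`
#' for ungrouped diseases.
#'
#' @param codebook a `disease_codebook`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(codebook, path) {
  diseases <- lapply(seq_len(nrow(codebook)), function(i) {
    list(
      id = codebook$id[i],
      label = codebook$label[i],
      group = if (is.na(codebook$group[i])) NULL else codebook$group[i]
    )
  })
  jsonlite::write_json(list(diseases = diseases), path,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a codebook from JSON
#'
#' @param path file written by [write_codebook()].
#' @return a `disease_codebook`.
#' @export
read_codebook <- function(path) {
  raw <- jsonlite::read_json(path)
  tab <- data.frame(
    id = vapply(raw$diseases, function(d) d$id, character(1)),
    label = vapply(raw$diseases, function(d) d$label, character(1)),
    group = vapply(raw$diseases, function(d) d$group %||% NA_character_,
                   character(1)),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("disease_codebook", "data.frame")
  tab
}
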