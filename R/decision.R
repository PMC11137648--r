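# Clinical pathway and treatment-advice rules.
#
# The pathway gates each step on the previous one: discs diagnosed as not
# herniated get conservative advice; herniated discs are graded by MSU size
# and zone; degeneration grading informs the fusion consideration. The rule
# table is total and purely deterministic, and every advice records the rule
# identifiers that fired.

DISCLAIMER <- paste("Advisory output for decision support only;",
                    "not a substitute for clinical judgment.")

#' Registry of advice rules
#'
#' @return data.frame with columns \code{id} and \code{description}.
#' @export
adviceRules <- function() {
  data.frame(
    id = c("R-DIAG-NEG", "R-MSU1-CONS", "R-MSU23-SURG",
           "R-ZONE-A-POST", "R-ZONE-BC-LAT", "R-PF-GT3-FUSION"),
    description = c(
      "No herniation diagnosed: conservative management.",
      "MSU size 1: suitable for non-surgical treatment (size dominates zone).",
      "MSU size 2 or 3: surgical treatment should be in consideration.",
      "MSU zone A: microendoscopic discectomy / posterior approach.",
      "MSU zone B or C: percutaneous transforaminal endoscopic discectomy or oblique lateral interbody fusion (lateral approaches).",
      "Pfirrmann grade above 3 (IV or V) suggests reoperation risk: consider interbody fusion."),
    stringsAsFactors = FALSE)
}

#' Per-disc assessment
#'
#' @param levelIndex 1-based disc level.
#' @param herniated logical diagnosis.
#' @param msuSize,msuZone MSU label (size 1..3, zone A/B/C); required iff
#'   herniated.
#' @param pfirrmann grade 1..5 or NA; by the pathway gating it is only
#'   assessed for MSU size 2/3 discs unless \code{forcePfirrmann}.
#' @param forcePfirrmann allow a grade outside the gating (the grader can be
#'   run on any disc; the pipeline applies the gating).
#' @return validated assessment list.
#' @export
discAssessment <- function(levelIndex, herniated, msuSize = NA_integer_,
                           msuZone = NA_character_, pfirrmann = NA_integer_,
                           forcePfirrmann = FALSE) {
  hasMsu <- !is.na(msuSize) && !is.na(msuZone)
  if (herniated != hasMsu)
    stopf("spineDSS_validation_error",
          "MSU label must be present exactly when the disc is herniated")
  if (hasMsu && (!msuSize %in% 1:3 || !msuZone %in% c("A", "B", "C")))
    stopf("spineDSS_validation_error", "MSU size must be 1..3 and zone A/B/C")
  if (!is.na(pfirrmann)) {
    if (!pfirrmann %in% 1:5)
      stopf("spineDSS_validation_error", "pfirrmann must be in 1..5")
    if (!forcePfirrmann && (!hasMsu || !msuSize %in% 2:3))
      stopf("spineDSS_validation_error",
            "pfirrmann is only assessed for MSU size 2/3 discs (use forcePfirrmann to override)")
  }
  list(levelIndex = as.integer(levelIndex), herniated = isTRUE(herniated),
       msuSize = as.integer(msuSize), msuZone = as.character(msuZone),
       pfirrmann = as.integer(pfirrmann))
}

#' Treatment advice for one disc assessment
#'
#' Deterministic rule table: no herniation or MSU size 1 maps to
#' conservative management (approach n/a); size 2/3 maps to surgical
#' consideration with the approach chosen by zone (A: posterior /
#' microendoscopic discectomy; B or C: lateral / endoscopic or oblique
#' lateral interbody fusion). The fusion flag is set exactly when the
#' Pfirrmann grade exceeds 3.
#'
#' @param a a [discAssessment()].
#' @return list(management, approach, fusionFlag, rationale) where rationale
#'   lists the fired rule ids.
#' @examples
#' advise(discAssessment(3, TRUE, msuSize = 2, msuZone = "B", pfirrmann = 4))
#' @export
advise <- function(a) {
  rationale <- character(0)
  if (!a$herniated) {
    management <- "conservative"; approach <- "n/a"
    rationale <- "R-DIAG-NEG"
  } else if (a$msuSize == 1) {
    management <- "conservative"; approach <- "n/a"
    rationale <- "R-MSU1-CONS"
  } else {
    management <- "surgical-consideration"
    rationale <- "R-MSU23-SURG"
    if (a$msuZone == "A") {
      approach <- "posterior/MED"
      rationale <- c(rationale, "R-ZONE-A-POST")
    } else {
      approach <- "lateral/PTED-or-OLIF"
      rationale <- c(rationale, "R-ZONE-BC-LAT")
    }
  }
  fusion <- !is.na(a$pfirrmann) && a$pfirrmann > 3
  if (fusion) rationale <- c(rationale, "R-PF-GT3-FUSION")
  list(management = management, approach = approach,
       fusionFlag = fusion, rationale = rationale)
}

#' Assemble a per-study report document
#'
#' One JSON-serializable document per study: per-disc assessment, advice and
#' rule trace, plus software version, provenance metadata and a fixed
#' advisory disclaimer.
#'
#' @param assessments list of [discAssessment()] objects.
#' @param advices list of matching [advise()] results.
#' @param provenance free-form run metadata (seeds, config hash, inputs).
#' @return report list.
#' @export
buildReport <- function(assessments, advices, provenance = list()) {
  if (length(assessments) != length(advices))
    stopf("spineDSS_validation_error",
          "assessments (%d) and advices (%d) are misaligned",
          length(assessments), length(advices))
  known <- adviceRules()$id
  discs <- Map(function(a, adv) {
    if (!all(adv$rationale %in% known))
      stopf("spineDSS_validation_error", "unknown rule id in advice rationale")
    list(level = a$levelIndex, herniated = a$herniated,
         msu = if (!is.na(a$msuSize)) list(size = a$msuSize, zone = a$msuZone) else NULL,
         pfirrmann = if (!is.na(a$pfirrmann)) a$pfirrmann else NULL,
         pfirrmannRoman = if (!is.na(a$pfirrmann)) pfirrmannRoman(a$pfirrmann) else NULL,
         advice = adv)
  }, assessments, advices)
  list(schemaVersion = "1.0",
       software = list(name = "spineDSS",
                       version = as.character(utils::packageVersion("spineDSS"))),
       disclaimer = DISCLAIMER,
       provenance = provenance,
       discs = unname(discs))
}

#' @describeIn buildReport write a report to JSON
#' @param report a report list
#' @param path output file
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @describeIn buildReport read a report back from JSON
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
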