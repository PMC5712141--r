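#' Bundled reference cohort tables
#'
#' Small plain-text tables transcribed from the clinical evaluation of this
#' method, shipped as worked-example fixtures: the patient characteristics
#' of the eight-subject stroke cohort, and the per-patient confusion counts
#' of the development and validation groups of the detector (counts are the
#' summed totals over all measurement trials within a patient).
#'
#' @param name one of `"demographics"`, `"confusion_development"`,
#'   `"confusion_validation"`.
#' @return a data frame.
#' @examples
#' counts <- reference_table("confusion_validation")
#' pooled <- pool_counts(Map(confusion_counts, counts$tp, counts$fn, counts$fp))
#' round_half_away(ppv(pooled))  # 87
#' @export
reference_table <- function(name = c("demographics", "confusion_development",
                                     "confusion_validation")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "gaitassist", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
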