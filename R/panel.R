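#' The 31-metabolite neurotransmitter panel
#'
#' Loads the packaged catalog of the 31 plasma metabolites measured by the
#' targeted electrochemistry (LCECA) platform, grouped into seven pathway
#' families: tryptophan, tyrosine, phenylalanine/tyrosine phenolic acids,
#' purine, one-carbon/glutathione, tocopherol, and other.
#'
#' @param file Path to a tab-separated panel definition with columns
#'   `metabolite_id`, `display_name`, `pathway`. Defaults to the packaged
#'   panel.
#' @return A `metabolite_panel` data frame with one row per metabolite.
#' @examples
#' panel <- metabolite_panel()
#' table(panel$pathway)
#' @export
metabolite_panel <- function(file = system.file("extdata", "metabolite_panel.tsv",
                                                package = "pcmnet")) {
  panel <- read.delim(file, stringsAsFactors = FALSE)
  validate_metabolite_panel(panel)
  class(panel) <- c("metabolite_panel", "data.frame")
  panel
}

#' Validate a metabolite panel
#'
#' Checks uniqueness and non-emptiness of metabolite ids and that every
#' entry carries exactly one recognised pathway label.
#'
#' @param panel A data frame with columns `metabolite_id`, `display_name`,
#'   `pathway`.
#' @return The panel, invisibly, if valid; otherwise an error.
#' @export
validate_metabolite_panel <- function(panel) {
  required <- c("metabolite_id", "display_name", "pathway")
  if (!all(required %in% names(panel))) {
    stop("panel must have columns: ", paste(required, collapse = ", "))
  }
  ids <- panel$metabolite_id
  if (anyNA(ids) || any(!nzchar(ids))) stop("metabolite ids must be non-empty")
  if (anyDuplicated(ids)) {
    stop("duplicated metabolite ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  allowed <- c("tryptophan", "tyrosine", "phenylalanine/tyrosine", "purine",
               "one_carbon_gsh", "tocopherol", "other")
  bad <- setdiff(unique(panel$pathway), allowed)
  if (length(bad)) stop("unknown pathway labels: ", paste(bad, collapse = ", "))
  invisible(panel)
}
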