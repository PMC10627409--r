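#' Default phecode category registry
#'
#' Phecodes are grouped into disease categories identified by a two-letter
#' prefix (e.g. `CV` for Cardiovascular, `ID` for Infectious Diseases). The
#' prefixed map dialect defines 18 categories. The registry shipped here uses
#' the prefixes attested in published worked examples (CV, ID, RE, GI, EM, GE)
#' together with conventional names for the remaining chapters; any deployment
#' against a real map release should load the release's own registry with
#' [read_category_registry()].
#'
#' @return data.frame with columns `prefix` (2-letter code) and `name`,
#'   in canonical display order.
#' @seealso [read_category_registry()]
#' @export
default_registry <- function() {
  reg <- data.frame(
    prefix = c("BI", "CA", "CM", "CV", "DE", "EM", "EY", "GE", "GI",
               "GU", "ID", "MB", "MS", "NN", "NS", "PG", "RE", "SS"),
    name = c("Blood/Immune", "Neoplasms", "Congenital Anomalies",
             "Cardiovascular", "Dermatological", "Endocrine/Metabolic",
             "Eye/Vision", "Genetic", "Gastrointestinal",
             "Genitourinary", "Infectious Diseases", "Mental/Behavioral",
             "Musculoskeletal", "Neonatal", "Neurological",
             "Pregnancy", "Respiratory", "Symptoms/Signs"),
    stringsAsFactors = FALSE
  )
  validate_registry(reg)
}

#' Read a category registry from a delimited file
#'
#' @param path path to a comma- or tab-delimited file with header columns
#'   `prefix` and `name`.
#' @return data.frame registry as in [default_registry()].
#' @export
read_category_registry <- function(path) {
  reg <- read_delimited(path)
  if (!all(c("prefix", "name") %in% names(reg)))
    stop("registry file must have columns 'prefix' and 'name'")
  validate_registry(reg[, c("prefix", "name")])
}

validate_registry <- function(reg) {
  reg$prefix <- toupper(trimws(reg$prefix))
  reg$name <- trimws(reg$name)
  if (any(!grepl("^[A-Z]{2}$", reg$prefix)))
    stop("registry prefixes must be 2 uppercase letters")
  if (anyDuplicated(reg$prefix)) stop("registry prefixes must be unique")
  if (anyDuplicated(reg$name)) stop("registry names must be unique")
  rownames(reg) <- NULL
  reg
}

# Category name for a vector of prefixes; NA where unregistered.
registry_name <- function(prefix, registry) {
  registry$name[match(prefix, registry$prefix)]
}
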