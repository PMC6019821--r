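#' Validate and build a species dataset
#'
#' A species dataset records, for every species in the flora: its genus,
#' whether it has at least one ethnomedicinal use report (`used`), the
#' number of use reports (intensity of traditional use), the number of
#' pharmacological/phytochemical publications (`n_studies`, research
#' effort), and optional therapeutic-application category codes
#' (semicolon-separated, e.g. `"DDS;DRS"`).
#'
#' Invariants enforced: unique species names; counts are non-negative
#' integers; an unused species has zero use reports.  Unknown category
#' codes trigger a warning, not an error.
#'
#' @param df A data frame with columns `species`, `genus`, `used`,
#'   `n_use_reports`, `n_studies` and optionally `categories`.
#' @return The validated data frame with class `"species_dataset"`.
#' @export
species_dataset <- function(df) {
  required <- c("species", "genus", "used", "n_use_reports", "n_studies")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (!"categories" %in% names(df)) df$categories <- rep("", nrow(df))
  df <- df[, c(required, "categories")]
  df$species <- as.character(df$species)
  df$genus <- as.character(df$genus)
  df$used <- as_logical_col(df$used, "used")
  df$n_use_reports <- as_count_col(df$n_use_reports, "n_use_reports")
  df$n_studies <- as_count_col(df$n_studies, "n_studies")
  df$categories <- as.character(ifelse(is.na(df$categories), "",
                                       as.character(df$categories)))

  dup <- duplicated(df$species)
  if (any(dup))
    stop("duplicate species at rows ", paste(which(dup), collapse = ", "),
         ": ", paste(unique(df$species[dup]), collapse = ", "))
  bad <- !df$used & df$n_use_reports > 0
  if (any(bad))
    stop("unused species with use reports at rows ",
         paste(which(bad), collapse = ", "))
  bad2 <- df$used & df$n_use_reports < 1
  if (any(bad2))
    stop("used species must have at least 1 use report; rows ",
         paste(which(bad2), collapse = ", "))

  codes <- unique(unlist(strsplit(df$categories[df$categories != ""], ";", fixed = TRUE)))
  unknown <- setdiff(codes, known_category_codes())
  if (length(unknown))
    warning("unknown category codes: ", paste(unknown, collapse = ", "))

  rownames(df) <- NULL
  class(df) <- c("species_dataset", "data.frame")
  df
}

# Therapeutic-application codes seen in the Brazilian legume use records,
# plus generic markers.
known_category_codes <- function() {
  c("DBI", "DCS", "DDS", "DEA", "DFS", "DGS", "DMC", "DNS", "DRS", "DSS",
    "ENM", "IPD", "NEO", "PCP", "Medicinal", "Other")
}

as_logical_col <- function(x, name) {
  if (is.logical(x)) return(ifelse(is.na(x), NA, x))
  if (is.numeric(x)) return(x != 0)
  lx <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "yes", "1")] <- TRUE
  out[lx %in% c("false", "f", "no", "0")] <- FALSE
  if (anyNA(out))
    stop("column ", name, " not interpretable as logical at rows ",
         paste(which(is.na(out)), collapse = ", "))
  out
}

as_count_col <- function(x, name) {
  x <- suppressWarnings(as.numeric(x))
  bad <- is.na(x) | x < 0 | x != floor(x)
  if (any(bad))
    stop("column ", name, " must be non-negative integers; bad rows ",
         paste(which(bad), collapse = ", "))
  as.integer(x)
}

#' Read a species dataset from CSV
#'
#' @param path CSV file (UTF-8) with the [species_dataset()] schema.
#' @return A `"species_dataset"` data frame.
#' @export
load_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  species_dataset(df)
}

#' Write a species dataset to CSV
#'
#' @param dataset A `"species_dataset"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "species_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' Read or write a hotnode membership table
#'
#' The membership CSV has columns `species` and `inside` (logical) and is
#' the hand-off between hotnode detection and the summary stage.
#'
#' @param hotnodes A `"hotnode_set"` (for writing).
#' @param path CSV path.
#' @return `read_membership()` returns a character vector of inside
#'   species; `write_membership()` returns `path` invisibly.
#' @export
write_membership <- function(hotnodes, path) {
  stopifnot(inherits(hotnodes, "hotnode_set"))
  df <- data.frame(species = c(hotnodes$inside, hotnodes$outside),
                   inside = c(rep(TRUE, length(hotnodes$inside)),
                              rep(FALSE, length(hotnodes$outside))))
  utils::write.csv(df[order(df$species), ], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_membership
#' @export
read_membership <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "inside") %in% names(df)))
  df$species[as_logical_col(df$inside, "inside")]
}
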