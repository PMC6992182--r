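#' Construct a fatty-acid profile
#'
#' A fatty-acid profile holds one species' composition as percent of total
#' fatty acids, keyed by canonical fatty-acid label, together with the set
#' of labels reported as not detected (ND). ND labels carry the value 0 so
#' that sums and indices treat them as absent mass.
#'
#' @param species species identifier (single string).
#' @param values named numeric vector, names are fatty-acid labels
#'   (canonicalized on construction), values in percent of total fatty acids.
#' @param nd character vector of labels recorded as not detected; their
#'   values must be 0.
#' @return An object of class `"fa_profile"`: a list with elements
#'   `species`, `values` and `nd`.
#' @examples
#' fa_profile("demo", c("C16:0" = 25, "C22:6n-3" = 10, "C20:4n-6" = 0),
#'            nd = "C20:4n-6")
#' @export
fa_profile <- function(species, values, nd = character()) {
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))
  if (length(values) == 0) stop("profile has no fatty-acid values", call. = FALSE)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("profile values must be named by fatty-acid label", call. = FALSE)
  }
  canon <- parse_fatty_acid(names(values))$label
  if (anyDuplicated(canon)) {
    stop("duplicate fatty-acid labels in profile for ", species, call. = FALSE)
  }
  values <- stats::setNames(as.numeric(values), canon)
  nd <- if (length(nd)) parse_fatty_acid(nd)$label else character()
  if (any(is.na(values)) || any(values < 0) || any(values > 100)) {
    stop("profile values for ", species,
         " must lie in [0, 100] percent", call. = FALSE)
  }
  if (sum(values) > 100.5) {
    stop("profile for ", species, " sums to ", round(sum(values), 2),
         "%, above 100% plus rounding tolerance", call. = FALSE)
  }
  if (any(values[nd] != 0)) {
    stop("not-detected labels must carry value 0 (", species, ")",
         call. = FALSE)
  }
  structure(list(species = species, values = values, nd = nd),
            class = "fa_profile")
}

#' @export
print.fa_profile <- function(x, ...) {
  cat("Fatty-acid profile:", x$species, "\n")
  cat(sprintf("  %d fatty acids, %.1f%% of total identified, %d ND\n",
              length(x$values), sum(x$values), length(x$nd)))
  invisible(x)
}

#' Bundle species records and profiles into a study dataset
#'
#' @param records data frame of species metadata as returned by
#'   [read_species()].
#' @param profiles list of [fa_profile()] objects, one per record.
#' @return An object of class `"study_dataset"`: list with elements
#'   `records` and `profiles` (profiles named and ordered as the records).
#' @export
study_dataset <- function(records, profiles) {
  stopifnot(is.data.frame(records), is.list(profiles))
  keys <- vapply(profiles, function(p) p$species, character(1))
  names(profiles) <- keys
  if (!setequal(records$scientific_name, keys) ||
      length(keys) != nrow(records)) {
    stop("species records and profiles must be keyed by the same species",
         call. = FALSE)
  }
  structure(list(records = records,
                 profiles = profiles[records$scientific_name]),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("Study dataset:", nrow(x$records), "species,",
      length(unique(unlist(lapply(x$profiles, function(p) names(p$values))))),
      "fatty acids\n")
  invisible(x)
}

#' Read fatty-acid profiles from CSV
#'
#' Expects a comma-separated table with a `fatty_acid` label column and one
#' numeric column per species; the token `"ND"` marks a fatty acid that was
#' not detected (stored as 0 and flagged). Labels are canonicalized through
#' [parse_fatty_acid()]; column order is preserved.
#'
#' @param path path to a CSV file.
#' @return A named list of [fa_profile()] objects, in column order.
#' @export
read_profiles <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!"fatty_acid" %in% names(tab)) {
    stop("profiles CSV must have a 'fatty_acid' column: ", path, call. = FALSE)
  }
  if (ncol(tab) < 2 || nrow(tab) == 0) return(list())
  labels <- tab$fatty_acid
  canon <- vapply(seq_along(labels), function(i) {
    tryCatch(parse_fatty_acid(labels[i])$label,
             error = function(e) stop("row ", i, " of ", path, ": ",
                                      conditionMessage(e), call. = FALSE))
  }, character(1))
  if (anyDuplicated(canon)) {
    stop("duplicate fatty-acid rows in ", path, ": ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "),
         call. = FALSE)
  }
  species <- setdiff(names(tab), "fatty_acid")
  out <- lapply(species, function(sp) {
    cells <- tab[[sp]]
    nd <- canon[cells == "ND"]
    vals <- suppressWarnings(as.numeric(ifelse(cells == "ND", "0", cells)))
    if (any(is.na(vals))) {
      stop("non-numeric cell for ", sp, " in ", path, call. = FALSE)
    }
    if (any(vals < 0)) {
      stop("negative fatty-acid percentage for ", sp, " in ", path,
           call. = FALSE)
    }
    fa_profile(sp, stats::setNames(vals, canon), nd = nd)
  })
  stats::setNames(out, species)
}

#' Read species metadata from CSV
#'
#' Expects one row per species with columns `scientific_name`,
#' `common_name`, `trophic_level`, `trophic_level_sd`, `lipid_content`
#' (g per 100 g wet weight), `length`, `length_sd` (cm), `weight`,
#' `weight_sd` (g), and optionally `n_individuals` (defaults to 10, the
#' usual pooled sample size behind each species mean).
#'
#' @param path path to a CSV file.
#' @return A data frame with the columns above, validated: trophic level in
#'   \[1, 5.5\], non-negative lipid content, positive sizes.
#' @export
read_species <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("scientific_name", "common_name", "trophic_level",
            "trophic_level_sd", "lipid_content", "length", "length_sd",
            "weight", "weight_sd")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("species CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"n_individuals" %in% names(tab)) tab$n_individuals <- 10L
  if (anyDuplicated(tab$scientific_name)) {
    stop("duplicate species in ", path, call. = FALSE)
  }
  if (nrow(tab)) {
    if (any(tab$trophic_level < 1 | tab$trophic_level > 5.5)) {
      stop("trophic levels must lie in [1, 5.5]", call. = FALSE)
    }
    if (any(tab$lipid_content < 0)) {
      stop("lipid content must be non-negative (g/100 g)", call. = FALSE)
    }
    if (any(tab$length <= 0) || any(tab$weight <= 0)) {
      stop("body lengths and weights must be positive", call. = FALSE)
    }
  }
  tab[, c(need, "n_individuals")]
}

#' Load the packaged Pearl River Estuary survey dataset
#'
#' Returns the packaged 22-species estuarine survey: per-species metadata
#' (trophic level, lipid content, sizes; species means over n = 10
#' individuals) and fatty-acid composition profiles over 26 fatty acids in
#' percent of total fatty acids.
#'
#' @return A [study_dataset()] with 22 species records and profiles.
#' @examples
#' ds <- load_study_fixture()
#' ds$records$scientific_name[1:3]
#' @export
load_study_fixture <- function() {
  p2 <- system.file("extdata", "pre_table2.csv", package = "lipidqual",
                    mustWork = TRUE)
  p1 <- system.file("extdata", "pre_table1.csv", package = "lipidqual",
                    mustWork = TRUE)
  study_dataset(read_species(p1), read_profiles(p2))
}

#' Write a result table to CSV
#'
#' Writes any tabular stage output as comma-separated text, full precision,
#' no row names. Reading the file back with [utils::read.csv()] returns
#' values equal to the originals to at least 6 decimals.
#'
#' @param rows a data frame.
#' @param path destination path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
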