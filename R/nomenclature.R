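#' lipidqual: lipid nutritional quality analysis of fish fatty-acid profiles
#'
#' Evaluates the lipid nutritional quality of fish species from tabulated
#' fatty-acid compositions (percent of total fatty acids, as quantified by
#' GC-FID peak areas). The package covers the full analysis chain: label
#' parsing and classification ([parse_fatty_acid()]), class and omega-series
#' aggregation ([class_summary()]), five nutritional quality indices
#' ([nutritional_indices()]), Ackman lipid-content categories
#' ([ackman_category()]), correlation of fatty-acid classes with trophic
#' level ([trophic_correlation()]), one-way ANOVA across lipid categories
#' ([lipid_class_anova()]), and hierarchical clustering of species on the
#' index matrix ([cluster_species()]). A 22-species estuarine survey is
#' included as plain-text data ([load_study_fixture()]) together with a
#' synthetic-profile generator ([simulate_dataset()]).
#'
#' @name lipidqual-package
#' @keywords internal
"_PACKAGE"

# Raw labels that appear in published tables but do not follow the
# C<carbons>:<double bonds>n-<series> pattern, mapped to their canonical
# form. "C20:5n-" is EPA with a truncated series suffix.
.fa_aliases <- c(
  "C20:5n-" = "C20:5n-3"
)

# Unicode hyphen/dash variants normalized to ASCII "-" before parsing.
.normalize_label <- function(x) {
  x <- gsub("[‐‑‒–—―−]", "-", x)
  x <- gsub("\\s+", "", x)
  x <- sub("^c", "C", x)
  x
}

#' Parse fatty-acid labels
#'
#' Parses shorthand fatty-acid labels of the form `"C<carbons>:<double
#' bonds>"` with an optional omega-series suffix `"n-<series>"` (e.g.
#' `"C22:6n-3"`, DHA) into their structural components. Parsing tolerates
#' surrounding whitespace, a lower-case leading `"c"` and typographic dash
#' variants, and resolves a small alias table of known malformed labels
#' (currently the truncated EPA label `"C20:5n-"`).
#'
#' @param labels character vector of fatty-acid labels.
#' @return A data frame of class `"fatty_acid"` with one row per input label
#'   and columns `label` (canonical re-rendered label), `carbons`,
#'   `double_bonds` (integer counts) and `series` (integer omega series, or
#'   `NA` when the label carries no `n-` suffix).
#' @examples
#' parse_fatty_acid(c("C22:6n-3", "C18:0", "C20:5n-"))
#' @export
parse_fatty_acid <- function(labels) {
  if (length(labels) == 0 || !is.character(labels) || any(is.na(labels)) ||
      any(!nzchar(trimws(labels)))) {
    stop("labels must be non-empty character strings", call. = FALSE)
  }
  x <- .normalize_label(labels)
  hit <- x %in% names(.fa_aliases)
  x[hit] <- .fa_aliases[x[hit]]
  m <- regmatches(x, regexec("^C([0-9]+):([0-9]+)(?:n-([0-9]+))?$", x))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) {
    stop("unparseable fatty-acid label(s): ",
         paste(sQuote(labels[bad]), collapse = ", "), call. = FALSE)
  }
  carbons <- vapply(m, function(g) as.integer(g[2]), integer(1))
  dbl <- vapply(m, function(g) as.integer(g[3]), integer(1))
  series <- vapply(m, function(g) {
    if (g[4] == "") NA_integer_ else as.integer(g[4])
  }, integer(1))
  ok <- carbons >= 4 & carbons <= 30 & dbl >= 0 & dbl <= 6 & dbl < carbons
  if (any(!ok)) {
    stop("fatty-acid label(s) outside the supported range: ",
         paste(sQuote(labels[!ok]), collapse = ", "), call. = FALSE)
  }
  canon <- paste0("C", carbons, ":", dbl,
                  ifelse(is.na(series), "", paste0("n-", series)))
  structure(
    data.frame(label = canon, carbons = carbons, double_bonds = dbl,
               series = series, stringsAsFactors = FALSE),
    class = c("fatty_acid", "data.frame")
  )
}

#' Classify fatty acids by saturation
#'
#' Assigns each fatty acid to the saturated (SFA, zero double bonds),
#' monounsaturated (MUFA, one) or polyunsaturated (PUFA, two or more) class.
#' The classification depends only on the double-bond count.
#'
#' @param fa a `"fatty_acid"` data frame from [parse_fatty_acid()], or a
#'   character vector of labels (parsed on the fly).
#' @return A factor with levels `SFA`, `MUFA`, `PUFA`.
#' @examples
#' fa_class(c("C16:0", "C16:1n-7", "C22:6n-3"))
#' @export
fa_class <- function(fa) {
  if (is.character(fa)) fa <- parse_fatty_acid(fa)
  stopifnot(inherits(fa, "fatty_acid"))
  cls <- ifelse(fa$double_bonds == 0, "SFA",
                ifelse(fa$double_bonds == 1, "MUFA", "PUFA"))
  factor(cls, levels = c("SFA", "MUFA", "PUFA"))
}

#' Omega-series membership of polyunsaturated fatty acids
#'
#' Assigns each PUFA to the omega-3 (`"n3"`) or omega-6 (`"n6"`) sum, or to
#' `"neither"`. Acids with an explicit `n-3` or `n-6` suffix are assigned by
#' their suffix. The series-less label `C22:4` is ambiguous in published
#' composition tables: under the `"default"` convention it is treated as
#' adrenic acid (C22:4 n-6) and counted in the omega-6 sum; under the
#' `"strict"` convention only explicitly annotated series count and `C22:4`
#' is `"neither"`. Other series (n-7, n-9) and unannotated PUFAs are
#' `"neither"` under both conventions.
#'
#' @param fa a `"fatty_acid"` data frame or character vector of labels; all
#'   entries must be PUFAs.
#' @param convention `"default"` or `"strict"` (see Details).
#' @return Character vector with elements in `c("n3", "n6", "neither")`.
#' @examples
#' omega_membership(c("C20:5n-3", "C18:2n-6", "C22:4"))
#' omega_membership("C22:4", convention = "strict")
#' @export
omega_membership <- function(fa, convention = c("default", "strict")) {
  convention <- match.arg(convention)
  if (is.character(fa)) fa <- parse_fatty_acid(fa)
  stopifnot(inherits(fa, "fatty_acid"))
  if (any(fa$double_bonds < 2)) {
    stop("omega_membership() is defined for PUFAs only; got ",
         paste(sQuote(fa$label[fa$double_bonds < 2]), collapse = ", "),
         call. = FALSE)
  }
  out <- rep("neither", nrow(fa))
  out[!is.na(fa$series) & fa$series == 3] <- "n3"
  out[!is.na(fa$series) & fa$series == 6] <- "n6"
  if (convention == "default") {
    out[is.na(fa$series) & fa$carbons == 22 & fa$double_bonds == 4] <- "n6"
  }
  out
}
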