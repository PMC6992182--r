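# Shared per-profile aggregation used by class_summary() and the index
# functions: class sums over the classified labels and omega sums under the
# chosen C22:4 convention.
.profile_parts <- function(profile, convention = "default") {
  stopifnot(inherits(profile, "fa_profile"))
  fa <- parse_fatty_acid(names(profile$values))
  cls <- fa_class(fa)
  v <- profile$values
  omega <- rep("neither", length(v))
  omega[cls == "PUFA"] <- omega_membership(fa[cls == "PUFA", , drop = FALSE],
                                           convention = convention)
  at <- function(lab) if (lab %in% names(v)) unname(v[lab]) else 0
  list(values = v, at = at,
       sfa = sum(v[cls == "SFA"]), mufa = sum(v[cls == "MUFA"]),
       pufa = sum(v[cls == "PUFA"]),
       n3 = sum(v[omega == "n3"]), n6 = sum(v[omega == "n6"]))
}

#' Summarize a fatty-acid profile by class
#'
#' Aggregates one species' profile into the saturated/monounsaturated/
#' polyunsaturated class sums, the omega-3 and omega-6 sums, the named
#' long-chain omega-3 acids EPA (C20:5 n-3), DHA (C22:6 n-3) and DPA
#' (C22:5 n-3), and the share of the omega-3 sum contributed by EPA + DHA.
#' All quantities are in percent of total fatty acids, on the same scale as
#' the input profile (profiles are never re-normalized to 100%).
#'
#' @param profile an [fa_profile()].
#' @param convention omega-series convention for the series-less `C22:4`
#'   label; see [omega_membership()].
#' @return An object of class `"class_summary"`: list with numeric elements
#'   `sfa`, `mufa`, `pufa`, `n3`, `n6`, `epa`, `dha`, `dpa`,
#'   `total_identified` (= sfa + mufa + pufa) and `epa_dha_share_of_n3`
#'   (fraction in \[0, 1\], `NA` when the omega-3 sum is zero).
#' @examples
#' ds <- load_study_fixture()
#' class_summary(ds$profiles[["Sillago sihama"]])
#' @export
class_summary <- function(profile, convention = c("default", "strict")) {
  convention <- match.arg(convention)
  p <- .profile_parts(profile, convention)
  epa <- p$at("C20:5n-3"); dha <- p$at("C22:6n-3"); dpa <- p$at("C22:5n-3")
  structure(list(
    species = profile$species,
    sfa = p$sfa, mufa = p$mufa, pufa = p$pufa,
    n3 = p$n3, n6 = p$n6, epa = epa, dha = dha, dpa = dpa,
    total_identified = p$sfa + p$mufa + p$pufa,
    epa_dha_share_of_n3 = if (p$n3 > 0) (epa + dha) / p$n3 else NA_real_
  ), class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat("Class summary:", x$species, "\n")
  cat(sprintf("  SFA %.1f  MUFA %.1f  PUFA %.1f  (total %.1f%%)\n",
              x$sfa, x$mufa, x$pufa, x$total_identified))
  cat(sprintf("  n-3 %.2f  n-6 %.2f  EPA %.2f  DHA %.2f  DPA %.2f\n",
              x$n3, x$n6, x$epa, x$dha, x$dpa))
  if (!is.na(x$epa_dha_share_of_n3)) {
    cat(sprintf("  EPA+DHA share of n-3: %.1f%%\n",
                100 * x$epa_dha_share_of_n3))
  }
  invisible(x)
}

# All class summaries of a dataset as one data frame (one row per species).
.dataset_summaries <- function(ds, convention = "default") {
  stopifnot(inherits(ds, "study_dataset"))
  rows <- lapply(ds$profiles, function(p) {
    s <- class_summary(p, convention)
    data.frame(species = s$species, sfa = s$sfa, mufa = s$mufa,
               pufa = s$pufa, n3 = s$n3, n6 = s$n6, epa = s$epa,
               dha = s$dha, dpa = s$dpa,
               total_identified = s$total_identified,
               epa_dha_share_of_n3 = s$epa_dha_share_of_n3,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ackman lipid-content categories
#'
#' Classifies fish by crude lipid content (g per 100 g wet weight) into the
#' four Ackman categories: lean (< 2%), low fat (2–4%), medium fat (4–8%)
#' and high fat (> 8%). The published bounds leave the boundary sides open;
#' here 2 falls in low fat, 4 and 8 in medium fat.
#'
#' @param lipid_content numeric vector, g per 100 g wet weight.
#' @return Factor with levels `lean`, `low_fat`, `medium_fat`, `high_fat`.
#' @examples
#' ackman_category(c(0.51, 2.0, 7.35, 9.1))
#' @export
ackman_category <- function(lipid_content) {
  if (any(is.na(lipid_content)) || any(lipid_content < 0)) {
    stop("lipid content must be non-negative (g/100 g)", call. = FALSE)
  }
  out <- ifelse(lipid_content < 2, "lean",
         ifelse(lipid_content < 4, "low_fat",
         ifelse(lipid_content <= 8, "medium_fat", "high_fat")))
  factor(out, levels = c("lean", "low_fat", "medium_fat", "high_fat"))
}

#' Count species per lipid category
#'
#' @param ds a [study_dataset()].
#' @return Named integer vector of species counts over the four Ackman
#'   categories; the counts partition the species.
#' @examples
#' categorize_dataset(load_study_fixture())
#' @export
categorize_dataset <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  table(ackman_category(ds$records$lipid_content))
}
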