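#' Nutritional quality indices of fish lipids
#'
#' Five dimensionless indices summarize the health relevance of a fatty-acid
#' profile, all computed from percent-of-total-fatty-acid values:
#'
#' * **n-6/n-3 ratio** — omega-6 PUFA sum over omega-3 PUFA sum; dietary
#'   guidance favours low values (below 4).
#' * **P/S ratio** — total PUFA over total SFA; values below 0.45 are
#'   considered undesirable.
#' * **IA**, the index of atherogenicity (Ulbricht–Southgate):
#'   \deqn{IA = (C12{:}0 + 4 \cdot C14{:}0 + C16{:}0) /
#'         (MUFA + n\text{-}6 + n\text{-}3)}
#' * **IT**, the index of thrombogenicity (Ulbricht–Southgate):
#'   \deqn{IT = (C14{:}0 + C16{:}0 + C18{:}0) /
#'         (0.5\,MUFA + 0.5\,n\text{-}6 + 3\,n\text{-}3 + n\text{-}3/n\text{-}6)}
#' * **HH**, the hypocholesterolemic/hypercholesterolemic ratio
#'   (Santos-Silva): the sum of C18:1 n-9, C18:2 n-6, C20:4 n-6, C18:3 n-3,
#'   C20:5 n-3, C22:5 n-3 and C22:6 n-3 over (C14:0 + C16:0).
#'
#' Lower IA and IT and higher HH and P/S are nutritionally favourable.
#' Fatty acids absent from a profile (or not detected) contribute 0. The
#' n-6/n-3 ratio, P/S ratio, IA and HH are ratios of linear forms and are
#' exactly invariant under uniform rescaling of the profile; IT is not,
#' because the dimensionless n-3/n-6 term in its denominator does not
#' scale with the profile (shrinking a profile uniformly lowers IT).
#' Degenerate inputs (zero denominators) raise errors rather than returning
#' sentinel values, except that a zero numerator with a zero-only trailing
#' term yields 0.
#'
#' @param summary a [class_summary()].
#' @param profile an [fa_profile()].
#' @param convention omega-series convention for `C22:4`; see
#'   [omega_membership()].
#' @return A single numeric value.
#' @seealso [nutritional_indices()] for the whole-dataset table.
#' @examples
#' ds <- load_study_fixture()
#' p <- ds$profiles[["Sillago sihama"]]
#' index_ia(p)                      # lowest IA in the survey, 0.56
#' ratio_ps(class_summary(p))
#' @name quality-indices
NULL

#' @rdname quality-indices
#' @export
ratio_n6_n3 <- function(summary) {
  stopifnot(inherits(summary, "class_summary"))
  if (summary$n3 <= 0) {
    stop("n-6/n-3 ratio undefined: omega-3 sum is zero", call. = FALSE)
  }
  summary$n6 / summary$n3
}

#' @rdname quality-indices
#' @export
ratio_ps <- function(summary) {
  stopifnot(inherits(summary, "class_summary"))
  if (summary$sfa <= 0) {
    stop("P/S ratio undefined: SFA sum is zero", call. = FALSE)
  }
  summary$pufa / summary$sfa
}

#' @rdname quality-indices
#' @export
index_ia <- function(profile, convention = c("default", "strict")) {
  convention <- match.arg(convention)
  p <- .profile_parts(profile, convention)
  den <- p$mufa + p$n6 + p$n3
  if (den <= 0) {
    stop("IA undefined for ", profile$species,
         ": unsaturated denominator is zero", call. = FALSE)
  }
  (p$at("C12:0") + 4 * p$at("C14:0") + p$at("C16:0")) / den
}

#' @rdname quality-indices
#' @export
index_it <- function(profile, convention = c("default", "strict")) {
  convention <- match.arg(convention)
  p <- .profile_parts(profile, convention)
  num <- p$at("C14:0") + p$at("C16:0") + p$at("C18:0")
  if (num == 0) return(0)
  if (p$n6 <= 0) {
    stop("IT undefined for ", profile$species,
         ": omega-6 sum is zero (the n-3/n-6 term diverges)", call. = FALSE)
  }
  den <- 0.5 * p$mufa + 0.5 * p$n6 + 3 * p$n3 + p$n3 / p$n6
  if (den <= 0) {
    stop("IT undefined for ", profile$species, ": denominator is zero",
         call. = FALSE)
  }
  num / den
}

#' @rdname quality-indices
#' @export
index_hh <- function(profile) {
  p <- .profile_parts(profile)
  den <- p$at("C14:0") + p$at("C16:0")
  if (den <= 0) {
    stop("HH undefined for ", profile$species,
         ": C14:0 + C16:0 is zero", call. = FALSE)
  }
  num <- p$at("C18:1n-9") + p$at("C18:2n-6") + p$at("C20:4n-6") +
    p$at("C18:3n-3") + p$at("C20:5n-3") + p$at("C22:5n-3") +
    p$at("C22:6n-3")
  num / den
}

#' Compute all five nutritional quality indices for a dataset
#'
#' Applies the five indices described in [quality-indices] to every profile
#' in the dataset. Any undefined index aborts with the offending species
#' named.
#'
#' @param ds a [study_dataset()].
#' @param convention omega-series convention for `C22:4`; see
#'   [omega_membership()].
#' @return A data frame of class `"nutritional_indices"` with columns
#'   `species`, `n6_n3`, `ps`, `ia`, `it`, `hh` (one row per species, full
#'   precision).
#' @examples
#' ind <- nutritional_indices(load_study_fixture())
#' round(colMeans(ind[, c("ia", "it")]), 2)
#' @export
nutritional_indices <- function(ds, convention = c("default", "strict")) {
  convention <- match.arg(convention)
  stopifnot(inherits(ds, "study_dataset"))
  rows <- lapply(ds$profiles, function(p) {
    tryCatch({
      s <- class_summary(p, convention)
      data.frame(species = p$species,
                 n6_n3 = ratio_n6_n3(s), ps = ratio_ps(s),
                 ia = index_ia(p, convention), it = index_it(p, convention),
                 hh = index_hh(p), stringsAsFactors = FALSE)
    }, error = function(e) {
      stop("indices failed for ", p$species, ": ", conditionMessage(e),
           call. = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("nutritional_indices", "data.frame")
  out
}

#' @export
print.nutritional_indices <- function(x, digits = 2, ...) {
  cat("Nutritional quality indices (", nrow(x), " species)\n", sep = "")
  shown <- x
  shown[, -1] <- round(shown[, -1], digits)
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}
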