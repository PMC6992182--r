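# Resolve a class-sum selector ("sfa", "mufa", "pufa", "n3", "n6", "epa",
# "dpa", "dha") to a per-species numeric vector.
.quantity_vector <- function(ds, quantity, convention = "default") {
  sm <- .dataset_summaries(ds, convention)
  if (!quantity %in% names(sm)[-1]) {
    stop("unknown quantity ", sQuote(quantity), call. = FALSE)
  }
  stats::setNames(sm[[quantity]], sm$species)
}

#' Across-species class means
#'
#' Mean and sample standard deviation (n − 1 denominator) of the SFA, MUFA
#' and PUFA class sums and of EPA, DPA and DHA across the species of a
#' dataset, on the percent-of-total-fatty-acids scale. This is the survey
#' summary usually reported when comparing fishing regions.
#'
#' @param ds a [study_dataset()] with at least two species.
#' @param convention omega-series convention for `C22:4`; see
#'   [omega_membership()].
#' @return A data frame with columns `quantity`, `mean`, `sd`, `n`.
#' @examples
#' class_means(load_study_fixture())
#' @export
class_means <- function(ds, convention = c("default", "strict")) {
  convention <- match.arg(convention)
  stopifnot(inherits(ds, "study_dataset"), nrow(ds$records) >= 2)
  sm <- .dataset_summaries(ds, convention)
  qs <- c("sfa", "mufa", "pufa", "epa", "dpa", "dha")
  data.frame(
    quantity = qs,
    mean = vapply(qs, function(q) mean(sm[[q]]), numeric(1)),
    sd = vapply(qs, function(q) stats::sd(sm[[q]]), numeric(1)),
    n = nrow(sm), row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Pearson correlation of a fatty-acid quantity with trophic level
#'
#' Correlates a class sum (e.g. the PUFA percentage) with the species'
#' trophic level across the dataset, using the species means as the
#' analysis unit. The two-sided p-value comes from the t transform of r
#' with n − 2 degrees of freedom.
#'
#' @param ds a [study_dataset()] with at least three species.
#' @param quantity one of `"sfa"`, `"mufa"`, `"pufa"`, `"n3"`, `"n6"`,
#'   `"epa"`, `"dpa"`, `"dha"`.
#' @param convention omega-series convention for `C22:4`.
#' @return An object of class `"trophic_correlation"`: list with elements
#'   `quantity`, `r`, `p_value`, `n`.
#' @examples
#' trophic_correlation(load_study_fixture(), "pufa")
#' @export
trophic_correlation <- function(ds, quantity = "pufa",
                                convention = c("default", "strict")) {
  convention <- match.arg(convention)
  stopifnot(inherits(ds, "study_dataset"))
  y <- .quantity_vector(ds, quantity, convention)
  x <- stats::setNames(ds$records$trophic_level,
                       ds$records$scientific_name)[names(y)]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) {
    stop("correlation needs at least 3 species with finite values",
         call. = FALSE)
  }
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    stop("correlation undefined: zero variance in trophic level or ",
         sQuote(quantity), call. = FALSE)
  }
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                        alternative = "two.sided")
  structure(list(quantity = quantity, r = unname(ct$estimate),
                 p_value = ct$p.value, n = sum(ok)),
            class = "trophic_correlation")
}

#' @export
print.trophic_correlation <- function(x, ...) {
  cat(sprintf("Pearson correlation, trophic level vs %s: r = %.2f, p = %.3g (n = %d)\n",
              x$quantity, x$r, x$p_value, x$n))
  invisible(x)
}

#' One-way ANOVA of a fatty-acid quantity across lipid categories
#'
#' Tests whether a class sum differs among the Ackman lipid-content
#' categories of the dataset's species, with Tukey HSD pairwise contrasts
#' at the 5% significance level. Empty categories are dropped; at least two
#' non-empty categories are required.
#'
#' @inheritParams trophic_correlation
#' @return An object of class `"lipid_class_anova"`: list with elements
#'   `quantity`, `f_stat`, `p_value`, `df_between`, `df_within`, `groups`
#'   (category sizes) and `tukey` (data frame: `pair`, `diff`, `p_adj`).
#' @examples
#' lipid_class_anova(load_study_fixture(), "pufa")
#' @export
lipid_class_anova <- function(ds, quantity = "pufa",
                              convention = c("default", "strict")) {
  convention <- match.arg(convention)
  stopifnot(inherits(ds, "study_dataset"))
  y <- .quantity_vector(ds, quantity, convention)
  g <- stats::setNames(ackman_category(ds$records$lipid_content),
                       ds$records$scientific_name)[names(y)]
  g <- droplevels(g)
  if (nlevels(g) < 2) {
    stop("degenerate design: fewer than 2 non-empty lipid categories",
         call. = FALSE)
  }
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  f_stat <- tab$`F value`[1]
  p_value <- tab$`Pr(>F)`[1]
  # no between-group spread at all (e.g. a constant response): F is 0 by
  # definition, not the 0/0 floating-point artifact aov produces
  ssb <- sum(tapply(y, g, length) * (tapply(y, g, mean) - mean(y))^2)
  if (is.nan(f_stat) || ssb == 0) {
    f_stat <- 0
    p_value <- 1
  }
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$g
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(quantity = quantity, f_stat = f_stat, p_value = p_value,
                 df_between = tab$Df[1], df_within = tab$Df[2],
                 groups = table(g), tukey = tukey),
            class = "lipid_class_anova")
}

#' @export
print.lipid_class_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA of %s across lipid categories: F(%d, %d) = %.2f, p = %.3g\n",
              x$quantity, x$df_between, x$df_within, x$f_stat, x$p_value))
  cat("Tukey HSD (adjusted p):\n")
  print.data.frame(transform(x$tukey, diff = round(diff, 2),
                             p_adj = round(p_adj, 3)), row.names = FALSE)
  invisible(x)
}
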