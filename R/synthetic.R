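# Frozen within-class allocation proportions (fraction of each class's mass
# carried by each fatty acid), estimated once from the packaged survey:
# C16:0 carries ~66% of the SFA mass, C18:1n-9 and C16:1n-7 dominate the
# MUFAs, DHA and EPA the omega-3 PUFAs.
.sfa_props <- c("C14:0" = 0.1104, "C15:0" = 0.0207, "C16:0" = 0.6567,
                "C17:0" = 0.0353, "C18:0" = 0.1769)
.mufa_props <- c("C14:1" = 0.0111, "C15:1" = 0.0089, "C16:1n-7" = 0.3298,
                 "C17:1" = 0.0272, "C18:1n-7" = 0.1369, "C18:1n-9" = 0.4207,
                 "C20:1" = 0.0347, "C22:1" = 0.0242, "C24:1" = 0.0066)
.n3_props <- c("C18:3n-3" = 0.0424, "C18:4n-3" = 0.0353, "C20:3n-3" = 0.1002,
               "C20:5n-3" = 0.3150, "C22:5n-3" = 0.0973, "C22:6n-3" = 0.4097)
.n6_props <- c("C18:2n-6" = 0.4985, "C18:3n-6" = 0.0530, "C20:2n-6" = 0.0897,
               "C20:4n-6" = 0.0599, "C22:5n-6" = 0.2078, "C22:4" = 0.0910)

# Fraction of the PUFA mass on the omega-6 side in the survey (C22:4
# counted as n-6).
.n6_share_of_pufa <- 0.129

#' Configuration for synthetic fish datasets
#'
#' Collects the knobs of the synthetic-data generator. The defaults emulate
#' the packaged 22-species estuarine survey: 22 species of 10 pooled
#' individuals each, trophic levels spread over 2.0–4.5, class sums around
#' SFA 38.9 / MUFA 31.1 / PUFA 20.9 percent (so ~91% of fatty acids
#' identified), lipid contents over the observed 0.5–7.5 g/100 g range, and
#' a multiplicative within-species coefficient of variation of 8%. The
#' trophic-level slopes are 0 by default (no built-in diet signal); set
#' `pufa_tl_slope` negative to emulate the decline of PUFA with trophic
#' level seen in estuarine surveys.
#'
#' @param n_species number of species.
#' @param n_individuals individuals pooled per species.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @param trophic_range length-2 interval for uniform trophic levels.
#' @param pufa_tl_slope change in the PUFA percentage per trophic-level
#'   unit (percentage points; negative = PUFA declines up the food web).
#' @param n6_tl_slope change in the omega-6 percentage per trophic-level
#'   unit (applied within the PUFA mass).
#' @param base_class_mix named numeric: target `sfa`, `mufa`, `pufa`
#'   percentages at the mid trophic level; must be positive and sum to
#'   less than 100.
#' @param within_species_cv coefficient of variation of the multiplicative
#'   (log-normal) noise on each fatty-acid value.
#' @param lipid_content_range length-2 interval (g/100 g) for uniform
#'   lipid contents.
#' @return A list of class `"simulation_config"`.
#' @examples
#' simulation_config(seed = 7, pufa_tl_slope = -4)
#' @export
simulation_config <- function(n_species = 22, n_individuals = 10, seed = 1,
                              trophic_range = c(2.0, 4.5),
                              pufa_tl_slope = 0, n6_tl_slope = 0,
                              base_class_mix = c(sfa = 38.9, mufa = 31.1,
                                                 pufa = 20.9),
                              within_species_cv = 0.08,
                              lipid_content_range = c(0.5, 7.5)) {
  stopifnot(n_species >= 1, n_individuals >= 1, within_species_cv >= 0,
            length(trophic_range) == 2, diff(trophic_range) >= 0,
            length(lipid_content_range) == 2, all(lipid_content_range >= 0))
  if (!all(c("sfa", "mufa", "pufa") %in% names(base_class_mix)) ||
      any(base_class_mix <= 0) || sum(base_class_mix) >= 100) {
    stop("base_class_mix must have positive sfa/mufa/pufa summing below 100",
         call. = FALSE)
  }
  structure(list(n_species = as.integer(n_species),
                 n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed), trophic_range = trophic_range,
                 pufa_tl_slope = pufa_tl_slope, n6_tl_slope = n6_tl_slope,
                 base_class_mix = base_class_mix[c("sfa", "mufa", "pufa")],
                 within_species_cv = within_species_cv,
                 lipid_content_range = lipid_content_range),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d species x %d individuals, seed %d\n",
              x$n_species, x$n_individuals, x$seed))
  cat(sprintf("  class mix SFA %.1f / MUFA %.1f / PUFA %.1f, cv %.2f\n",
              x$base_class_mix["sfa"], x$base_class_mix["mufa"],
              x$base_class_mix["pufa"], x$within_species_cv))
  cat(sprintf("  trophic %s, PUFA slope %.2f, n-6 slope %.2f\n",
              paste(x$trophic_range, collapse = "-"), x$pufa_tl_slope,
              x$n6_tl_slope))
  invisible(x)
}

# Multiplicative log-normal noise with mean 1 and coefficient of variation
# cv (exactly: sdlog chosen so that sd/mean = cv).
.ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a fish dataset with the survey's statistical structure
#'
#' Draws species trophic levels uniformly over the configured range, builds
#' species-mean class sums by shifting the base class mix linearly with
#' trophic level (centred at the mid-range), splits the PUFA mass into
#' omega-3 and omega-6 parts, allocates each class's mass across the 26
#' survey fatty-acid labels by frozen within-class proportions, perturbs
#' every value with multiplicative log-normal noise, and emits the species
#' means as profiles. Lipid contents are uniform over the configured range.
#' The result is byte-for-byte reproducible from the config seed.
#'
#' @param config a [simulation_config()].
#' @return A [study_dataset()] whose profiles pass all profile invariants.
#' @examples
#' ds <- simulate_dataset(simulation_config(n_species = 5, seed = 42))
#' categorize_dataset(ds)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  n <- config$n_species
  tl <- stats::runif(n, config$trophic_range[1], config$trophic_range[2])
  mid <- mean(config$trophic_range)
  pufa <- config$base_class_mix["pufa"] + config$pufa_tl_slope * (tl - mid)
  n6 <- .n6_share_of_pufa * config$base_class_mix["pufa"] +
    config$n6_tl_slope * (tl - mid)
  n3 <- pufa - n6
  if (any(pufa < 0) || any(n3 < 0) || any(n6 < 0)) {
    stop("configured slopes drive a class mass negative over the trophic ",
         "range; reduce the slope magnitudes", call. = FALSE)
  }
  sfa <- rep(config$base_class_mix["sfa"], n)
  mufa <- rep(config$base_class_mix["mufa"], n)
  cv <- config$within_species_cv
  species <- sprintf("Synthetic species %02d", seq_len(n))
  profiles <- lapply(seq_len(n), function(i) {
    vals <- c(sfa[i] * .sfa_props, mufa[i] * .mufa_props,
              n3[i] * .n3_props, n6[i] * .n6_props)
    vals <- pmax(vals * .ln_noise(length(vals), cv), 0)
    # percentages cannot exceed 100 in total; a rare large noise draw is
    # pulled back onto the simplex boundary
    if (sum(vals) > 100) vals <- vals * (100 / sum(vals))
    fa_profile(species[i], vals)
  })
  records <- data.frame(
    scientific_name = species, common_name = species,
    trophic_level = tl, trophic_level_sd = 0.2,
    lipid_content = stats::runif(n, config$lipid_content_range[1],
                                 config$lipid_content_range[2]),
    length = 20, length_sd = 2, weight = 100, weight_sd = 10,
    n_individuals = config$n_individuals, stringsAsFactors = FALSE
  )
  study_dataset(records, profiles)
}

#' Simulate individual fish around species means
#'
#' Draws `n_individuals` replicate profiles per species by applying
#' multiplicative log-normal noise (mean 1, coefficient of variation
#' `within_species_cv`) to each species-mean fatty-acid value, emulating
#' the pooled individual samples behind each published species mean.
#' Averaging the individuals recovers the species mean up to Monte-Carlo
#' error; with `within_species_cv = 0` every individual equals the mean.
#'
#' @param config a [simulation_config()].
#' @param ds a [study_dataset()] holding the species-mean profiles (e.g.
#'   from [simulate_dataset()]).
#' @return A long data frame with columns `species`, `individual`,
#'   `fatty_acid`, `value`.
#' @export
simulate_individuals <- function(config, ds) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(ds, "study_dataset"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed + 1L)
  cv <- config$within_species_cv
  rows <- lapply(ds$profiles, function(p) {
    m <- length(p$values)
    do.call(rbind, lapply(seq_len(config$n_individuals), function(j) {
      data.frame(species = p$species, individual = j,
                 fatty_acid = names(p$values),
                 value = unname(p$values * .ln_noise(m, cv)),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
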