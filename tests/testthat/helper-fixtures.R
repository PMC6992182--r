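# Printed class subtotals and totals from the published composition table,
# used to lock the transcription of the packaged fixture (the fixture
# stores individual entries; subtotals are always recomputed).
printed_subtotals <- data.frame(
  species = c("Sillago sihama", "Odontamblyopus rubicundus",
              "Harpadon nehereus", "Lateolabrax japonicus",
              "Selaroidea leptolepis", "Cynoglossus lida",
              "Branchiostegus albus", "Nemipterus virgatus",
              "Arius sinensis", "Larimichthys polyactis",
              "Trypauchen vagina", "Siganus fuscessens", "Mugil cephalus",
              "Ilisha elongata", "Collichthys lucidus",
              "Leiognathus brevirostris", "Coilia mystus",
              "Johnius belangerii", "Trichiurus lepturus",
              "Pampus argenteus", "Thryssa dussumieri",
              "Thryssa kammalensis"),
  sfa = c(34.5, 35.0, 38.6, 39.7, 47.7, 36.4, 40.0, 45.6, 44.0, 38.4, 34.5,
          42.6, 39.0, 33.5, 33.4, 37.4, 35.1, 35.2, 39.8, 44.0, 43.7, 37.9),
  mufa = c(34.7, 27.3, 38.7, 27.4, 24.3, 31.6, 34.4, 19.3, 35.8, 27.6, 26.8,
           24.0, 29.8, 30.6, 37.3, 31.9, 46.0, 35.4, 31.8, 29.0, 31.0, 28.7),
  pufa = c(23.9, 27.6, 15.2, 23.3, 19.3, 23.4, 15.3, 26.4, 14.7, 19.9, 28.4,
           25.6, 26.1, 22.0, 17.6, 21.3, 15.0, 21.0, 10.3, 19.7, 21.6, 21.4),
  total = c(93.2, 89.8, 92.5, 90.4, 91.3, 91.4, 89.7, 91.2, 94.5, 85.9, 89.7,
            92.2, 94.9, 86.1, 88.2, 90.6, 96.1, 91.6, 81.9, 92.8, 96.3, 88.1),
  stringsAsFactors = FALSE
)

# Independent spreadsheet-style recomputation of class sums and the five
# indices straight from the fixture CSV: base-R arithmetic over hard-coded
# label groups, sharing no code with the package's aggregation path.
oracle_from_csv <- function() {
  path <- system.file("extdata", "pre_table2.csv", package = "lipidqual")
  tab <- read.csv(path, check.names = FALSE)
  m <- as.matrix(tab[, -1])
  m[m == "ND"] <- "0"
  m <- apply(m, 2, as.numeric)
  rownames(m) <- sub("^C20:5n-$", "C20:5n-3", tab$fatty_acid)
  sfa_l <- c("C14:0", "C15:0", "C16:0", "C17:0", "C18:0")
  mufa_l <- c("C14:1", "C15:1", "C16:1n-7", "C17:1", "C18:1n-7",
              "C18:1n-9", "C20:1", "C22:1", "C24:1")
  n3_l <- c("C18:3n-3", "C18:4n-3", "C20:3n-3", "C20:5n-3", "C22:5n-3",
            "C22:6n-3")
  n6_l <- c("C18:2n-6", "C18:3n-6", "C20:2n-6", "C20:4n-6", "C22:5n-6",
            "C22:4")
  sfa <- colSums(m[sfa_l, ]); mufa <- colSums(m[mufa_l, ])
  n3 <- colSums(m[n3_l, ]); n6 <- colSums(m[n6_l, ])
  pufa <- n3 + n6
  list(
    values = m, sfa = sfa, mufa = mufa, pufa = pufa, n3 = n3, n6 = n6,
    n6_strict = n6 - m["C22:4", ],
    n6_n3 = n6 / n3, ps = pufa / sfa,
    ia = (4 * m["C14:0", ] + m["C16:0", ]) / (mufa + n6 + n3),
    it = (m["C14:0", ] + m["C16:0", ] + m["C18:0", ]) /
      (0.5 * mufa + 0.5 * n6 + 3 * n3 + n3 / n6),
    hh = (m["C18:1n-9", ] + m["C18:2n-6", ] + m["C20:4n-6", ] +
            m["C18:3n-3", ] + m["C20:5n-3", ] + m["C22:5n-3", ] +
            m["C22:6n-3", ]) / (m["C14:0", ] + m["C16:0", ])
  )
}

# Minimal hand-built profile: values over a handful of labels.
tiny_profile <- function(values, species = "tiny", nd = character()) {
  fa_profile(species, values, nd = nd)
}

# Dataset of hand-built profiles with minimal metadata.
tiny_dataset <- function(profiles, trophic_level = NULL,
                         lipid_content = NULL) {
  n <- length(profiles)
  sp <- vapply(profiles, function(p) p$species, character(1))
  if (is.null(trophic_level)) trophic_level <- seq(2, 4, length.out = n)
  if (is.null(lipid_content)) lipid_content <- rep(3, n)
  records <- data.frame(
    scientific_name = sp, common_name = sp,
    trophic_level = trophic_level, trophic_level_sd = 0.1,
    lipid_content = lipid_content, length = 10, length_sd = 1,
    weight = 50, weight_sd = 5, n_individuals = 10L,
    stringsAsFactors = FALSE
  )
  study_dataset(records, profiles)
}
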