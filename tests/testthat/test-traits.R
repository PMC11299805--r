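# Unit conversion, species aggregation, repeatability

test_that("brain mass -> volume follows the published conversion line", {
  expect_equal(brain_mass_to_volume(1), 10^-0.102)
  expect_equal(log10(brain_mass_to_volume(10)), -0.102 + 1.053)
  expect_equal(log10(brain_mass_to_volume(100)), 2.004)
  # strictly monotone increasing
  m <- 10^seq(-1, 3, length.out = 50)
  expect_true(all(diff(brain_mass_to_volume(m)) > 0))
  expect_error(brain_mass_to_volume(0), "positive")
  expect_error(brain_mass_to_volume(-3), "positive")
})

test_that("aggregate_species averages on the raw scale then logs", {
  rec <- data.frame(
    species = c("wolf", "wolf", "fox", "raccoon_dog"),
    source = c("s1", "s2", "s1", "s1"),
    body_mass_g = c(40000, 40000, 5000, 7000),
    brain_mass_g = c(NA, NA, NA, 30),
    brain_volume_ml = c(130, 120, 45, NA))
  tab <- aggregate_species(rec)
  expect_equal(nrow(tab), 3)
  wolf <- tab[tab$species == "wolf", ]
  expect_equal(wolf$log_body_mass, log10(40000), tolerance = 1e-12)
  expect_equal(round(wolf$log_body_mass, 3), 4.602)
  expect_equal(wolf$log_brain_volume, log10(125))
  expect_equal(wolf$n_sources, 2L)
  # converted brain mass fills in where volume is absent
  rd <- tab[tab$species == "raccoon_dog", ]
  expect_equal(rd$log_brain_volume, log10(brain_mass_to_volume(30)))

  # single-record species: table is just the log10 of the inputs
  one <- aggregate_species(rec[3, ])
  expect_equal(one$log_brain_volume, log10(45))

  # record order must not matter
  tab2 <- aggregate_species(rec[sample.int(4), ])
  expect_equal(tab, tab2, ignore_attr = TRUE)

  # observed volume wins over converted mass when both present
  both <- rec[1, ]
  both$brain_mass_g <- 500
  expect_equal(aggregate_species(both)$log_brain_volume, log10(130))
})

test_that("log-scale aggregation option averages log10 values", {
  rec <- data.frame(species = "wolf", source = c("a", "b"),
                    body_mass_g = c(10000, 40000), brain_mass_g = NA,
                    brain_volume_ml = c(100, 200))
  expect_equal(aggregate_species(rec, "log")$log_body_mass,
               mean(log10(c(10000, 40000))))
  expect_equal(aggregate_species(rec, "raw")$log_body_mass, log10(25000))
})

test_that("species without brain data are rejected with a reason, loudly", {
  rec <- data.frame(species = c("wolf", "mystery"), source = "s1",
                    body_mass_g = c(40000, 1000),
                    brain_mass_g = NA_real_, brain_volume_ml = c(130, NA))
  tab <- aggregate_species(rec)
  expect_equal(tab$species, "wolf")
  rej <- attr(tab, "rejected")
  expect_equal(rej$species, "mystery")
  expect_equal(rej$reason, "no_brain_data")
  expect_error(aggregate_species(rec[2, ]), "no species with usable")
})

test_that("trait CSV loader enforces the header and unit contract", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,source,body_mass_g,brain_volume_ml",
               "grey wolf,s1,40000,130"), path)
  rec <- read_trait_csv(path)
  expect_equal(rec$species, "grey_wolf")
  expect_true("brain_mass_g" %in% names(rec))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,source,body_mass_kg", "wolf,s1,40"), bad)
  expect_error(read_trait_csv(bad), "missing column|unsupported unit")
})

test_that("repeatability matches the hand-computed ANOVA oracle exactly", {
  # balanced toy: A = {1,1,3}, B = {7,9,8}
  rec <- data.frame(species = rep(c("A", "B"), each = 3), source = "s",
                    body_mass_g = c(1, 1, 3, 7, 9, 8),
                    brain_mass_g = NA_real_, brain_volume_ml = 1)
  res <- repeatability(rec, "body_mass", n_boot = 50, seed = 1)
  # MS_among = 60.1667, MS_within = 7/6, n0 = 3 -> R = 118/125
  expect_equal(res$R, 118 / 125, tolerance = 1e-12)
  # independent route: variance components from anova(lm(...))
  a <- anova(lm(v ~ g, data.frame(v = c(1, 1, 3, 7, 9, 8),
                                  g = rep(c("A", "B"), each = 3))))
  s2a <- (a$`Mean Sq`[1] - a$`Mean Sq`[2]) / 3
  expect_equal(res$R, s2a / (s2a + a$`Mean Sq`[2]), tolerance = 1e-12)
  expect_equal(res$n_species, 2L)
  expect_equal(res$n_measurements, 6L)
})

test_that("repeatability hits the degenerate endpoints", {
  # zero within-species variance, species means differ -> R = 1
  rec <- data.frame(species = rep(c("A", "B", "C"), each = 3), source = "s",
                    body_mass_g = rep(c(10, 100, 1000), each = 3),
                    brain_mass_g = NA_real_, brain_volume_ml = 1)
  expect_equal(repeatability(rec, "body_mass", n_boot = 20, seed = 1)$R, 1)

  # one common distribution, no group signal -> R near 0
  set.seed(42)
  rec2 <- data.frame(species = rep(paste0("sp", 1:10), each = 5),
                     source = "s", body_mass_g = exp(rnorm(50)),
                     brain_mass_g = NA_real_, brain_volume_ml = 1)
  expect_lt(repeatability(rec2, "body_mass", n_boot = 20, seed = 1)$R, 0.25)

  # fewer than two multi-measurement species -> precondition error
  rec3 <- data.frame(species = c("A", "B"), source = "s",
                     body_mass_g = c(1, 2), brain_mass_g = NA_real_,
                     brain_volume_ml = 1)
  expect_error(repeatability(rec3, "body_mass"), ">= 2 species")
})

test_that("repeatability is affine- and label-invariant, seed-reproducible", {
  set.seed(7)
  rec <- data.frame(species = rep(paste0("sp", 1:6), each = 4), source = "s",
                    body_mass_g = rep(runif(6, 10, 100), each = 4) +
                      rnorm(24, 0, 3),
                    brain_mass_g = NA_real_, brain_volume_ml = 1)
  base <- repeatability(rec, "body_mass", n_boot = 100, seed = 5)

  shifted <- rec; shifted$body_mass_g <- rec$body_mass_g + 1000
  expect_equal(repeatability(shifted, "body_mass", 100, 5)$R, base$R,
               tolerance = 1e-10)
  scaled <- rec; scaled$body_mass_g <- rec$body_mass_g * 7.3
  expect_equal(repeatability(scaled, "body_mass", 100, 5)$R, base$R,
               tolerance = 1e-10)
  relab <- rec; relab$species <- rep(paste0("zz", 6:1), each = 4)
  expect_equal(repeatability(relab, "body_mass", 100, 5)$R, base$R,
               tolerance = 1e-10)

  again <- repeatability(rec, "body_mass", n_boot = 100, seed = 5)
  expect_identical(base[c("R", "ci_low", "ci_high")],
                   again[c("R", "ci_low", "ci_high")])
  expect_true(base$ci_low <= base$R && base$R <= base$ci_high)
  expect_true(base$ci_low >= 0 && base$ci_high <= 1)
})

test_that("bootstrap CI narrows as measurements per species grow", {
  mean_width <- function(k) {
    mean(sapply(1:3, function(s) {
      spec <- simulation_spec(n_tips = 10, n_sources = k, cv = 0.6,
                              seed = 30 + s)
      study <- simulate_study(spec)
      r <- repeatability(study$records, "body_mass", n_boot = 200, seed = 2,
                         log_scale = TRUE)
      r$ci_high - r$ci_low
    }))
  }
  expect_lt(mean_width(16), mean_width(2))
})
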