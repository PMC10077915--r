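test_that("zero intraspecific variance makes conspecifics identical", {
  set.seed(71)
  cfg <- simulation_config(
    wild_itv_sd = c(itd = 0, tongue_length = 0, daytime_activity = 0),
    honeybee_itv_sd = c(itd = 0, tongue_length = 0, daytime_activity = 0)
  )
  g <- fnp_intensity_gradient("neutral", 1, 2, config = cfg,
                              inds_per_species = 3, n_honeybees = 5)
  expect_true(all(!is.na(g$fnp)))
  # regenerate the underlying individuals directly for the sharper check
  ts <- simulate_trait_space(cfg)
  inds <- beeniche:::draw_individuals(ts[2, ], 5, cfg$wild_itv_sd, "t")
  expect_equal(length(unique(inds$itd)), 1)
  expect_equal(length(unique(inds$daytime_activity)), 1)
  expect_error(simulation_config(wild_itv_sd = c(itd = -1, tongue_length = 0,
                                                 daytime_activity = 0)),
               "non-negative")
})

test_that("a dispersion-free pool collapses to one point with FNP equal to the centroid distance", {
  set.seed(72)
  cfg <- simulation_config(
    n_species = 5,
    pool = list(itd = c(1.5, 0), tongue_length = c(1.2, 0),
                phenology_start = c(8, 0), phenology_duration = c(12, 0),
                daytime_activity = c(6, 0)),
    oligolectic_prob = 0,
    wild_itv_sd = c(itd = 0, tongue_length = 0, daytime_activity = 0),
    honeybee_itv_sd = c(itd = 0, tongue_length = 0, daytime_activity = 0)
  )
  ts <- simulate_trait_space(cfg)
  wild <- ts[ts$group == "wild", ]
  expect_equal(nrow(unique(wild[, trait_axes])), 1)
  # with honeybee ITV 0, every wild-honeybee pair has the same distance,
  # so site FNP equals that common centroid distance (unscaled space: the
  # degenerate pool leaves several axes constant, which z-scaling rejects)
  tm <- beeniche:::new_trait_matrix(tibble::tibble(
    individual_id = sprintf("i%02d", 1:8),
    site_id = "s1",
    species_id = c(rep(wild$species_id[1], 4), rep("Apis mellifera", 4)),
    group = c(rep("wild", 4), rep("honeybee", 4))
  ) |> dplyr::bind_cols(dplyr::bind_rows(
    wild[rep(1, 4), trait_axes], ts[rep(1, 4), trait_axes])))
  d <- between_group_distances(tm, "s1")
  expect_equal(stats::sd(d), 0, tolerance = 1e-12)
  expect_equal(feeding_niche_partitioning(tm, "s1")$fnp, d[1], tolerance = 1e-12)
})

test_that("species-mean dispersion matches the generator within Monte-Carlo error", {
  set.seed(73)
  cfg <- simulation_config(n_species = 1000)
  wild <- simulate_trait_space(cfg)
  wild <- wild[wild$group == "wild", ]
  m <- cfg$pool$itd[1]; s <- cfg$pool$itd[2]
  # analytic moments of the left-truncated normal the pool is drawn from
  a <- (0.3 - m) / s
  lam <- dnorm(a) / (1 - pnorm(a))
  tn_sd <- s * sqrt(1 + a * lam - lam^2)
  se_sd <- tn_sd / sqrt(2 * (1000 - 1))
  expect_lt(abs(stats::sd(wild$itd) - tn_sd), 4 * se_sd)
})

test_that("assembly filtering moves FNP in the hypothesized directions", {
  set.seed(74)
  cfg <- simulation_config()
  ts <- simulate_trait_space(cfg)
  # intensity 0: no species removed
  none <- assemble_community(ts, "competition", intensity = 0)
  expect_equal(nrow(none), cfg$n_species)
  expect_error(assemble_community(ts, "competition", intensity = -1), ">= 0")

  d <- beeniche:::species_distance_to_honeybee(ts)
  strong <- 50 # saturating map ~ 1
  comp <- assemble_community(ts, "competition", intensity = strong, tau = median(d))
  env <- assemble_community(ts, "environmental", intensity = strong, tau = median(d))
  # survivors under competition are farther from honeybees than under
  # environmental filtering: compare mean distances of surviving species
  expect_gt(mean(d[comp$species_id]), mean(d))
  expect_lt(mean(d[env$species_id]), mean(d))
})

test_that("the covariate simulator realizes the configured standardized paths", {
  set.seed(75)
  cfg <- simulation_config(n_sites = 4000)
  d <- simulate_site_covariates(cfg)
  expect_equal(nrow(d), 4000)
  # implied unit variances
  for (v in c("management", "plant_richness", "honeybees", "wild_richness", "fnp")) {
    expect_lt(abs(stats::sd(d[[v]]) - 1), 0.08)
  }
  expect_lt(abs(cor(d$management, d$plant_richness) - (-0.597)), 0.05)
  truth <- attr(d, "truth")
  expect_equal(truth$paths, cfg$paths)

  # noise_scale 0 makes the structural relations deterministic
  set.seed(76)
  d0 <- simulate_site_covariates(simulation_config(n_sites = 50, noise_scale = 0))
  fit <- stats::lm(plant_richness ~ management, data = d0)
  expect_equal(unname(coef(fit)[2]), -0.597, tolerance = 1e-10)
  expect_equal(suppressWarnings(summary(fit))$r.squared, 1, tolerance = 1e-10)
})

test_that("overloaded path values are rejected", {
  paths <- default_truth_paths()
  paths$beta[paths$from == "plant_richness" & paths$to == "wild_richness"] <- 0.99
  paths$beta[paths$from == "green_100" & paths$to == "wild_richness"] <- 0.9
  cfg <- simulation_config(paths = paths)
  expect_error(simulate_site_covariates(cfg), "explained variance")
  paths$beta[1] <- 1.5
  expect_error(simulation_config(paths = paths), "(-1, 1)")
})

test_that("a synthetic study is reproducible and round-trips through the readers", {
  cfg <- simulation_config(seed = 77, n_sites = 6, n_species = 20,
                           mean_wild_per_site = 40, mean_honeybees_per_site = 8)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_equal(s1$individuals, s2$individuals)
  expect_equal(s1$covariates, s2$covariates)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(s1, d1); write_study(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = sprintf("checksum of %s", f))
  }

  back <- read_study(d1)
  expect_equal(nrow(back$individuals), nrow(s1$individuals))
  expect_equal(sort(back$species_traits$species_id),
               sort(s1$species_traits$species_id))

  # FNP computed from the written files equals FNP from the in-memory objects
  tm_mem <- zscale_traits(merge_traits(
    normalize_species(s1$individuals, setNames(s1$aliases$normalized_name,
                                               s1$aliases$raw_name)),
    s1$species_traits))
  tm_disk <- zscale_traits(merge_traits(
    normalize_species(back$individuals, back$aliases), back$species_traits))
  expect_equal(fnp_by_site(tm_mem)$fnp, fnp_by_site(tm_disk)$fnp,
               tolerance = 1e-9)

  blocked <- withr::local_tempfile(lines = "x") # a file, not a directory
  expect_error(write_study(s1, file.path(blocked, "sub")), "cannot create")
})
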