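test_that("between-group distances cover exactly the wild x honeybee pairs", {
  tm <- make_tm(wild = c(0, 0), honeybee = c(1, 0))
  expect_equal(between_group_distances(tm, "s1"), 1)
  tm0 <- make_tm(wild = c(0.3, -0.2, 1, 0, 0, 2), honeybee = c(0.3, -0.2, 1, 0, 0, 2))
  expect_equal(between_group_distances(tm0, "s1"), 0)

  set.seed(4)
  w <- matrix(rnorm(12), 2); h <- matrix(rnorm(18), 3)
  tm2 <- make_tm(wild = w, honeybee = h)
  d <- between_group_distances(tm2, "s1")
  expect_length(d, 6)
  oracle <- as.vector(t(sapply(1:2, function(i)
    sapply(1:3, function(j) sqrt(sum((w[i, ] - h[j, ])^2))))))
  expect_equal(sort(d), sort(oracle), tolerance = 1e-12)

  only_wild <- make_tm(wild = rbind(c(1, 1)), honeybee = c(0, 0),
                       sites_hb = "elsewhere")
  expect_warning(res <- between_group_distances(only_wild, "s1"), "honeybee")
  expect_length(res, 0)
  expect_equal(attr(res, "missing_group"), "honeybee")
})

test_that("the FNP statistic matches the hand-enumerated worked example", {
  tm <- make_tm(wild = rbind(c(0, 0), c(0, 2)),
                honeybee = rbind(c(1, 0), c(1, 2)))
  res <- feeding_niche_partitioning(tm, "s1")
  expect_equal(res$fnp, mean(c(1, sqrt(5), sqrt(5), 1)), tolerance = 1e-12)
  expect_equal(res$fnp, 1.618033988749895, tolerance = 1e-12)
  expect_equal(res$n_pairs, 4)

  # all points coincident -> complete overlap
  same <- make_tm(wild = rbind(c(1, 2), c(1, 2)), honeybee = c(1, 2))
  expect_equal(feeding_niche_partitioning(same, "s1")$fnp, 0)
})

test_that("FNP is invariant to honeybee replication and to row permutation", {
  set.seed(9)
  w <- matrix(rnorm(30), 5); h <- matrix(rnorm(24), 4)
  base <- feeding_niche_partitioning(make_tm(w, h), "s1")$fnp
  tripled <- feeding_niche_partitioning(make_tm(w, h[rep(1:4, 3), ]), "s1")$fnp
  expect_equal(tripled, base, tolerance = 1e-12)
  tm <- make_tm(w, h)
  perm <- beeniche:::new_trait_matrix(tm[sample(nrow(tm)), ])
  expect_equal(feeding_niche_partitioning(perm, "s1")$fnp, base, tolerance = 1e-12)
})

test_that("FNP is invariant under a common rotation and monotone under radial expansion", {
  set.seed(10)
  w <- matrix(rnorm(36), 6); h <- matrix(rnorm(18), 3)
  base <- feeding_niche_partitioning(make_tm(w, h), "s1")$fnp
  for (r in 1:5) {
    Q <- random_orthogonal(6)
    rot <- feeding_niche_partitioning(make_tm(w %*% Q, h %*% Q), "s1")$fnp
    expect_equal(rot, base, tolerance = 1e-10)
  }
  centroid <- colMeans(h)
  for (k in c(1.5, 2, 5)) {
    expanded <- sweep(sweep(w, 2, centroid) * k, 2, centroid, `+`)
    grown <- feeding_niche_partitioning(make_tm(expanded, h), "s1")$fnp
    expect_gte(grown, base - 1e-12)
  }
})

test_that("a site missing one group yields missing FNP, not zero", {
  tm <- make_tm(wild = rbind(c(1, 1)), honeybee = c(0, 0), sites_hb = "s2")
  res <- suppressWarnings(feeding_niche_partitioning(tm, "s1"))
  expect_true(is.na(res$fnp))
  expect_equal(res$n_honeybee, 0)
  both <- suppressWarnings(fnp_by_site(tm))
  expect_equal(nrow(both), 2)
  expect_true(all(is.na(both$fnp)))
})

test_that("species dissimilarity sorts ascending and matches the double-loop oracle", {
  tm <- make_tm(wild = rbind(c(2, 0), c(1, 0)), honeybee = c(0, 0),
                wild_species = c("far", "near"))
  res <- species_dissimilarity(tm)
  expect_equal(res$species_id, c("near", "far"))
  expect_equal(res$mean_distance_to_honeybees, c(1, 2))

  zero <- make_tm(wild = c(0, 0), honeybee = c(0, 0), wild_species = "coincident")
  expect_equal(species_dissimilarity(zero)$mean_distance_to_honeybees, 0)

  set.seed(12)
  w <- matrix(rnorm(60), 10); h <- matrix(rnorm(24), 4)
  sp <- rep(c("a", "b"), each = 5)
  tm2 <- make_tm(w, h, wild_species = sp)
  res2 <- species_dissimilarity(tm2)
  for (s in c("a", "b")) {
    rows <- w[sp == s, , drop = FALSE]
    oracle <- mean(sapply(seq_len(nrow(rows)), function(i)
      sapply(seq_len(nrow(h)), function(j) sqrt(sum((rows[i, ] - h[j, ])^2)))))
    expect_equal(res2$mean_distance_to_honeybees[res2$species_id == s], oracle,
                 tolerance = 1e-12)
  }
  expect_error(species_dissimilarity(make_tm(w, h[0, , drop = FALSE])), "honeybee")
})

test_that("trait contributions satisfy the single-axis and Pythagorean identities", {
  # groups differ on exactly one axis
  tm <- make_tm(wild = c(2, 0), honeybee = c(0, 0))
  contrib <- trait_contribution(tm)
  full <- feeding_niche_partitioning(tm, "s1")$fnp
  expect_equal(contrib$delta_fnp_leave_one_out[contrib$trait == "itd"], full)
  expect_equal(contrib$single_trait_fnp[contrib$trait != "itd"], rep(0, 5))
  expect_equal(contrib$rank[contrib$trait == "itd"], 1L)

  # constant (zero) axis contributes nothing
  expect_equal(contrib$delta_fnp_leave_one_out[contrib$trait == "phenology_end"], 0)

  # single pair: squared single-axis FNPs sum to the squared full distance
  set.seed(13)
  a <- rnorm(6); b <- rnorm(6)
  tm2 <- make_tm(wild = rbind(a), honeybee = rbind(b))
  c2 <- trait_contribution(tm2)
  expect_equal(sum(c2$single_trait_fnp^2),
               feeding_niche_partitioning(tm2, "s1")$fnp^2, tolerance = 1e-12)
})

test_that("community-weighted traits average the raw wild trait values", {
  tm <- make_tm(wild = rbind(c(1, 0), c(3, 0)), honeybee = c(10, 0),
                wild_species = c("spA", "spA"))
  expect_equal(community_weighted_trait(tm, "s1", "itd"), 2)
  expect_equal(community_weighted_trait(tm, "s1", "itd", weight = "presence"), 2)
  # presence weighting counts each species once
  tm2 <- make_tm(wild = rbind(c(1, 0), c(1, 0), c(4, 0)), honeybee = c(0, 0),
                 wild_species = c("a", "a", "b"))
  expect_equal(community_weighted_trait(tm2, "s1", "itd"), 2)
  expect_equal(community_weighted_trait(tm2, "s1", "itd", weight = "presence"), 2.5)
  expect_warning(res <- community_weighted_trait(
    make_tm(wild = rbind(c(1, 1)), honeybee = c(0, 0), sites_wild = "s9"),
    "s1", "itd"), "no wild")
  expect_true(is.na(res))
})

test_that("sites enriched with late-phenology species couple FNP to community phenology", {
  # construct sites where high FNP comes from adding late-flying species
  late <- rbind(c(0, 0, 0, 0, 6, 0), c(0, 0, 0, 0, 7, 0))
  early <- rbind(c(0, 0, 0, 0, 0.5, 0), c(0, 0, 0, 0, 0.3, 0))
  tm <- make_tm(wild = rbind(early, late), honeybee = rbind(c(0, 0), c(0, 0)),
                sites_wild = c("low", "low", "high", "high"),
                sites_hb = c("low", "high"),
                wild_species = c("e1", "e2", "l1", "l2"))
  fnp <- fnp_by_site(tm)
  cwm <- sapply(c("low", "high"), function(s)
    community_weighted_trait(tm, s, "phenology_end"))
  expect_gt(cor(fnp$fnp[match(c("low", "high"), fnp$site_id)], cwm), 0.99)
})
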