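#' Between-group pairwise distances at a site
#'
#' All Euclidean distances between wild-bee individuals and honeybee
#' individuals captured at one site, in the scaled six-axis trait space.
#' Within-group pairs (wild-wild, honeybee-honeybee) are never included.
#'
#' @param tm A scaled `trait_matrix`.
#' @param site A `site_id` present in `tm`.
#' @return A numeric vector of length `n_wild * n_honeybee`. When either
#'   group is absent at the site the vector is empty and carries attribute
#'   `missing_group` naming the absent group(s), with a warning.
#' @export
between_group_distances <- function(tm, site) {
  rows <- tm[tm$site_id == site, , drop = FALSE]
  if (nrow(rows) == 0) stop_beeniche(sprintf("site '%s' not present in trait matrix", site))
  w <- as.matrix(rows[rows$group == "wild", .trait_axes])
  h <- as.matrix(rows[rows$group == "honeybee", .trait_axes])
  absent <- c("wild", "honeybee")[c(nrow(w) == 0, nrow(h) == 0)]
  if (length(absent) > 0) {
    rlang::warn(sprintf("site '%s' has no %s individuals; no between-group pairs",
                        site, paste(absent, collapse = " or ")))
    return(structure(numeric(0), missing_group = absent))
  }
  as.vector(cross_distances(w, h))
}

#' Feeding niche partitioning at a site
#'
#' The FNP statistic: the arithmetic mean of all pairwise Euclidean distances
#' between wild-bee and honeybee individuals at a site in the scaled
#' six-trait space. Large values mean the wild community sits far from the
#' honeybee population in feeding-trait space (strong partitioning); small
#' values mean strong niche overlap. Sites lacking one of the groups get a
#' missing FNP rather than 0, since 0 would assert perfect overlap.
#'
#' @param tm A scaled `trait_matrix`.
#' @param site A `site_id` present in `tm`.
#' @return One-row tibble: `site_id`, `fnp`, `n_wild`, `n_honeybee`,
#'   `n_pairs`.
#' @export
feeding_niche_partitioning <- function(tm, site) {
  rows <- tm[tm$site_id == site, , drop = FALSE]
  if (nrow(rows) == 0) stop_beeniche(sprintf("site '%s' not present in trait matrix", site))
  n_w <- sum(rows$group == "wild")
  n_h <- sum(rows$group == "honeybee")
  fnp <- if (n_w >= 1 && n_h >= 1) {
    mean(suppressWarnings(between_group_distances(tm, site)))
  } else {
    NA_real_
  }
  tibble::tibble(site_id = site, fnp = fnp, n_wild = n_w, n_honeybee = n_h,
                 n_pairs = n_w * n_h)
}

#' Feeding niche partitioning for every site
#'
#' @param tm A scaled `trait_matrix`.
#' @return A tibble with one row per site (see
#'   [feeding_niche_partitioning()]); sites missing a group have `fnp = NA`.
#' @export
fnp_by_site <- function(tm) {
  sites <- unique(tm$site_id)
  dplyr::bind_rows(lapply(sites, function(s) feeding_niche_partitioning(tm, s)))
}

#' Species-level functional dissimilarity to honeybees
#'
#' For each wild species, the mean Euclidean distance between its individuals
#' and all honeybee individuals, pooled across sites (one ordering for the
#' whole study). Species are returned sorted from functionally similar
#' (small distance) to dissimilar (large distance), with ties kept in first
#' appearance order (stable sort).
#'
#' @param tm A scaled `trait_matrix`.
#' @param site Optionally restrict to one site's individuals.
#' @return A tibble `species_id`, `mean_distance_to_honeybees`,
#'   `n_individuals`, sorted ascending by distance.
#' @export
species_dissimilarity <- function(tm, site = NULL) {
  rows <- if (is.null(site)) tm else tm[tm$site_id == site, , drop = FALSE]
  h <- as.matrix(rows[rows$group == "honeybee", .trait_axes])
  if (nrow(h) == 0) stop_beeniche("no honeybee individuals to compare against")
  wild <- rows[rows$group == "wild", , drop = FALSE]
  res <- wild |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      mean_distance_to_honeybees =
        mean(cross_distances(dplyr::pick(dplyr::all_of(.trait_axes)), h)),
      n_individuals = dplyr::n(),
      .groups = "drop"
    )
  # stable ascending sort: keep first-appearance order among ties
  first_seen <- match(res$species_id, unique(wild$species_id))
  res[order(res$mean_distance_to_honeybees, first_seen), ]
}

#' Per-trait contribution to feeding niche partitioning
#'
#' Two transparent decompositions of the FNP statistic: for each axis,
#' (a) the change in FNP when that axis is removed and distances are
#' recomputed on the remaining five (`delta_fnp_leave_one_out`, full minus
#' reduced), and (b) FNP computed on that axis alone
#' (`single_trait_fnp`, the mean absolute between-group difference).
#' For any single pair of individuals the six single-axis distances obey the
#' Pythagorean identity: their squares sum to the squared full distance.
#'
#' @param tm A scaled `trait_matrix`.
#' @param site Optionally a single site; default pools all sites'
#'   between-group pairs (each site's pairs, concatenated).
#' @return A tibble `trait`, `single_trait_fnp`, `delta_fnp_leave_one_out`,
#'   `rank` (1 = largest absolute leave-one-out change).
#' @export
trait_contribution <- function(tm, site = NULL) {
  sites <- if (is.null(site)) unique(tm$site_id) else site
  pair_mats <- lapply(sites, function(s) {
    rows <- tm[tm$site_id == s, , drop = FALSE]
    w <- as.matrix(rows[rows$group == "wild", .trait_axes, drop = FALSE])
    h <- as.matrix(rows[rows$group == "honeybee", .trait_axes, drop = FALSE])
    if (nrow(w) == 0 || nrow(h) == 0) return(NULL)
    # per-pair signed differences on each axis, one row per pair
    do.call(rbind, lapply(seq_len(nrow(w)), function(i) {
      sweep(h, 2, w[i, ], FUN = function(a, b) b - a)
    }))
  })
  diffs <- do.call(rbind, pair_mats)
  if (is.null(diffs) || nrow(diffs) == 0) {
    stop_beeniche("no between-group pairs: FNP not computable")
  }
  full <- mean(sqrt(rowSums(diffs^2)))
  single <- vapply(seq_along(.trait_axes),
                   function(j) mean(abs(diffs[, j])), numeric(1))
  loo <- vapply(seq_along(.trait_axes), function(j) {
    full - mean(sqrt(rowSums(diffs[, -j, drop = FALSE]^2)))
  }, numeric(1))
  out <- tibble::tibble(
    trait = .trait_axes,
    single_trait_fnp = single,
    delta_fnp_leave_one_out = loo
  )
  out$rank <- rank(-abs(out$delta_fnp_leave_one_out), ties.method = "first")
  out
}

#' Community-weighted trait value of the wild bees at a site
#'
#' The mean of an unscaled trait over the wild-bee community at a site,
#' either weighted by individuals (abundance weighting) or by species
#' presence (each species' mean counted once).
#'
#' @param tm A `trait_matrix` (scaled input is inverted to raw units).
#' @param site A `site_id`.
#' @param trait One of the six trait names.
#' @param weight `"individuals"` or `"presence"`.
#' @return A number; `NA` with a warning when the site has no wild
#'   individuals.
#' @export
community_weighted_trait <- function(tm, site, trait,
                                     weight = c("individuals", "presence")) {
  weight <- match.arg(weight)
  trait <- match.arg(trait, .trait_axes)
  raw <- unscale_traits(tm)
  wild <- raw[raw$site_id == site & raw$group == "wild", , drop = FALSE]
  if (nrow(wild) == 0) {
    rlang::warn(sprintf("site '%s' has no wild individuals", site))
    return(NA_real_)
  }
  if (weight == "individuals") {
    mean(wild[[trait]])
  } else {
    sp_means <- tapply(wild[[trait]], wild$species_id, mean)
    mean(sp_means)
  }
}
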