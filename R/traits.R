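#' The six feeding-related functional traits
#'
#' Returns the definition table of the six-trait feeding niche space:
#' intertegular distance (ITD, a body-size proxy governing foraging range),
#' relative tongue length (flower-depth access), feeding specialization
#' (lecty: oligolectic vs. polylectic pollen diet), phenology start and end
#' (weeks from the start of the year), and daytime activity (hours per day).
#' ITD, tongue length and daytime activity are measured on each captured
#' individual; the remaining three are species-level values joined from a
#' trait table.
#'
#' @return A tibble with columns `trait`, `level` (`"individual"` or
#'   `"species"`), `kind` and `units`, one row per trait, in the canonical
#'   axis order used throughout the package.
#' @export
#' @examples
#' trait_definitions()
trait_definitions <- function() {
  tibble::tibble(
    trait = .trait_axes,
    level = c("individual", "individual", "species", "species", "species", "individual"),
    kind = c("continuous", "continuous", "binary-categorical",
             "continuous", "continuous", "continuous"),
    units = c("cm", "cm", "category (oligolectic = 1, polylectic = 0)",
              "weeks from year start", "weeks from year start", "hours/day")
  )
}

#' Read individual bee capture records
#'
#' Reads a tab-separated table of individually captured bees. Missing trait
#' measurements (damaged specimens) are encoded as `NA`.
#'
#' @param path Path to a TSV with columns `individual_id`, `site_id`,
#'   `species_raw`, `group` (`"wild"` or `"honeybee"`), `itd`,
#'   `tongue_length`, `daytime_activity` and optionally `capture_day`,
#'   `capture_window`, `phytometer_plant`.
#' @return A tibble of individual records.
#' @export
read_individuals <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, na = "NA", progress = FALSE)
  assert_cols(df, c("individual_id", "site_id", "species_raw", "group",
                    "itd", "tongue_length", "daytime_activity"),
              "individuals table")
  validate_individuals(df)
}

validate_individuals <- function(df) {
  if (anyDuplicated(df$individual_id)) {
    stop_beeniche("duplicate individual_id in individuals table")
  }
  bad_group <- setdiff(unique(df$group), c("wild", "honeybee"))
  if (length(bad_group) > 0) {
    stop_beeniche(sprintf("group must be 'wild' or 'honeybee'; found: %s",
                          paste(bad_group, collapse = ", ")))
  }
  if (any(!is.na(df$itd) & df$itd <= 0)) {
    stop_beeniche("itd must be positive where present")
  }
  for (tr in .individual_traits) {
    v <- df[[tr]]
    if (any(!is.na(v) & !is.finite(v))) {
      stop_beeniche(sprintf("non-finite values in trait '%s'", tr))
    }
  }
  hb <- unique(df$species_raw[df$group == "honeybee"])
  if (length(hb) > 1) {
    stop_beeniche("honeybee records must carry a single species label")
  }
  tibble::as_tibble(df)
}

#' Read the species-level trait table
#'
#' @param path Path to a TSV with columns `species_id`, `lecty`
#'   (`"oligolectic"` or `"polylectic"`), `phenology_start_week`,
#'   `phenology_end_week`.
#' @return A tibble of species-level traits.
#' @export
read_species_traits <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, na = "NA", progress = FALSE)
  assert_cols(df, c("species_id", "lecty", "phenology_start_week",
                    "phenology_end_week"), "species trait table")
  if (anyDuplicated(df$species_id)) {
    stop_beeniche("duplicate species_id in species trait table")
  }
  ok <- is.na(df$phenology_start_week) | is.na(df$phenology_end_week) |
    (df$phenology_start_week <= df$phenology_end_week &
       df$phenology_start_week >= 1 & df$phenology_end_week <= 53)
  if (!all(ok)) {
    stop_beeniche("phenology weeks must satisfy 1 <= start <= end <= 53")
  }
  bad <- setdiff(stats::na.omit(unique(df$lecty)), c("oligolectic", "polylectic"))
  if (length(bad) > 0) {
    stop_beeniche(sprintf("unknown lecty value(s): %s", paste(bad, collapse = ", ")))
  }
  tibble::as_tibble(df)
}

#' Read a species alias map
#'
#' Alias maps collapse raw determinations into the species or species-complex
#' labels used in analysis (for example workers of cryptic bumblebee species
#' pooled into one complex).
#'
#' @param path Path to a TSV with columns `raw_name`, `normalized_name`.
#' @return A named character vector mapping raw names to normalized names.
#' @export
read_aliases <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(df, c("raw_name", "normalized_name"), "alias table")
  aliases <- setNames(df$normalized_name, df$raw_name)
  validate_aliases(aliases)
}

validate_aliases <- function(aliases) {
  if (anyDuplicated(names(aliases))) {
    stop_beeniche("alias map has duplicate raw names")
  }
  # Idempotence: normalized names must map to themselves if they appear as keys.
  remapped <- aliases[names(aliases) %in% aliases]
  if (any(remapped != names(remapped))) {
    stop_beeniche("alias map is not idempotent: a normalized name maps elsewhere")
  }
  aliases
}

#' Normalize species names through an alias map
#'
#' Applies the alias map to raw determinations, collapsing species complexes.
#' Names absent from the map pass through unchanged and are recorded in the
#' `unmapped` attribute. The operation is idempotent.
#'
#' @param records Individual records (see [read_individuals()]).
#' @param aliases Named character vector from [read_aliases()], or `NULL` for
#'   the identity map.
#' @return The records with a `species_id` column of normalized names;
#'   attribute `unmapped` lists raw names that passed through.
#' @export
normalize_species <- function(records, aliases = NULL) {
  raw <- if ("species_id" %in% names(records)) records$species_id else records$species_raw
  if (is.null(aliases)) aliases <- character(0)
  aliases <- validate_aliases(aliases)
  hit <- raw %in% names(aliases)
  out <- records
  out$species_id <- ifelse(hit, unname(aliases[raw]), raw)
  attr(out, "unmapped") <- sort(unique(raw[!hit]))
  out
}

#' Encode lecty as a numeric axis
#'
#' Fixes the numeric convention for the feeding-specialization axis:
#' oligolectic = 1, polylectic = 0. The binary axis is subsequently z-scored
#' like the continuous traits so that all six axes share one Euclidean space.
#'
#' @param value Character vector of `"oligolectic"` / `"polylectic"`.
#' @return Numeric vector of 0/1.
#' @export
#' @examples
#' encode_lecty(c("polylectic", "oligolectic"))
encode_lecty <- function(value) {
  bad <- setdiff(stats::na.omit(unique(value)), c("oligolectic", "polylectic"))
  if (length(bad) > 0) {
    stop_beeniche(sprintf("lecty must be 'oligolectic' or 'polylectic'; found: %s",
                          paste(bad, collapse = ", ")))
  }
  ifelse(is.na(value), NA_real_, as.numeric(value == "oligolectic"))
}

new_trait_matrix <- function(df, scaler = NULL, exclusions = NULL) {
  structure(
    tibble::as_tibble(df),
    scaler = scaler,
    exclusions = exclusions %||%
      tibble::tibble(individual_id = character(0), reason = character(0)),
    class = c("trait_matrix", class(tibble::tibble()))
  )
}

#' @export
print.trait_matrix <- function(x, ...) {
  sc <- tm_scaler(x)
  cat(sprintf("<trait_matrix> %d individuals x %d axes (%s)\n",
              nrow(x), length(.trait_axes),
              if (is.null(sc)) "unscaled" else "z-scored"))
  cat(sprintf("  groups: %s | sites: %d | excluded records: %d\n",
              paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                    collapse = ", "),
              length(unique(x$site_id)), nrow(tm_exclusions(x))))
  NextMethod()
  invisible(x)
}

#' Accessors for trait-matrix metadata
#'
#' `tm_scaler()` returns the per-axis mean/sd used for z-scoring (`NULL` when
#' unscaled); `tm_exclusions()` returns the log of dropped input records.
#'
#' @param tm A `trait_matrix`.
#' @return A tibble (or `NULL` for an unscaled matrix's scaler).
#' @export
tm_scaler <- function(tm) attr(tm, "scaler")

#' @rdname tm_scaler
#' @export
tm_exclusions <- function(tm) attr(tm, "exclusions")

#' Merge individual- and species-level traits into the trait matrix
#'
#' Joins the three species-level trait values onto each individual's three
#' measured values, producing the complete-case individuals-by-six-axes
#' matrix. Individuals missing any individual-level measurement (damaged
#' specimens) or belonging to a species with no complete species-level trait
#' row are dropped and logged; no imputation is performed.
#'
#' @param records Normalized individual records (see [normalize_species()]).
#' @param species_table Species-level trait table (see [read_species_traits()]).
#' @return An unscaled `trait_matrix`: row metadata (`individual_id`,
#'   `site_id`, `species_id`, `group`) plus the six numeric axes, with the
#'   exclusion log in attribute `exclusions`.
#' @export
merge_traits <- function(records, species_table) {
  assert_cols(records, c("individual_id", "site_id", "species_id", "group",
                         .individual_traits), "records")
  sp <- species_table
  sp$feeding_specialization <- encode_lecty(sp$lecty)
  sp <- dplyr::select(sp, "species_id", "feeding_specialization",
                      phenology_start = "phenology_start_week",
                      phenology_end = "phenology_end_week")

  joined <- dplyr::left_join(records, sp, by = "species_id")
  miss_ind <- !complete.cases(joined[, .individual_traits])
  miss_sp <- !complete.cases(joined[, .species_traits])

  reason <- dplyr::case_when(
    miss_ind ~ "missing individual-level trait",
    miss_sp ~ "missing species-level traits",
    TRUE ~ NA_character_
  )
  excl <- tibble::tibble(
    individual_id = joined$individual_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  keep <- joined[is.na(reason),
                 c("individual_id", "site_id", "species_id", "group", .trait_axes)]
  if (nrow(keep) == 0) {
    stop_beeniche("no complete-case individuals")
  }
  new_trait_matrix(keep, scaler = NULL, exclusions = excl)
}

#' Z-score the six trait axes
#'
#' Centers and scales every axis by the pooled mean and sample standard
#' deviation (n - 1 denominator) over all retained individuals, across sites
#' and groups, so that all axes share the same unit before distances are
#' taken. The transform is recorded in the `scaler` attribute and is
#' invertible via [unscale_traits()]. Applying `zscale_traits()` to
#' already-standardized data leaves it unchanged up to numerical tolerance.
#'
#' @param tm A `trait_matrix` (typically unscaled, from [merge_traits()]).
#' @return A scaled `trait_matrix` whose every axis has pooled mean 0 and
#'   sample sd 1.
#' @export
zscale_traits <- function(tm) {
  mu <- vapply(tm[.trait_axes], mean, numeric(1))
  sig <- vapply(tm[.trait_axes], stats::sd, numeric(1))
  degenerate <- !is.finite(sig) | sig == 0
  if (any(degenerate)) {
    stop_beeniche(sprintf("zero-variance trait axis: %s",
                          paste(.trait_axes[degenerate], collapse = ", ")))
  }
  out <- tm
  for (tr in .trait_axes) out[[tr]] <- (tm[[tr]] - mu[tr]) / sig[tr]
  new_trait_matrix(out,
                   scaler = tibble::tibble(trait = .trait_axes,
                                           mean = unname(mu), sd = unname(sig)),
                   exclusions = tm_exclusions(tm))
}

#' Invert the z-scaling of a trait matrix
#'
#' @param tm A scaled `trait_matrix`.
#' @return The matrix on the original trait scales.
#' @export
unscale_traits <- function(tm) {
  sc <- tm_scaler(tm)
  if (is.null(sc)) {
    return(tm)
  }
  out <- tm
  for (i in seq_len(nrow(sc))) {
    tr <- sc$trait[i]
    out[[tr]] <- tm[[tr]] * sc$sd[i] + sc$mean[i]
  }
  new_trait_matrix(out, scaler = NULL, exclusions = tm_exclusions(tm))
}

#' Summarize traits on their original scales
#'
#' Pooled and per-species summaries of the unscaled trait values (scaled
#' input is inverted through its stored scaler first). Standard deviations of
#' single observations are reported as 0 with `sd_defined = FALSE`.
#'
#' @param tm A `trait_matrix`.
#' @param groups Which groups to include (default both).
#' @return A list with `pooled` (per trait: n, mean, sd, sd_defined, min,
#'   max) and `by_species` (per species and trait: n, mean).
#' @export
summarize_traits <- function(tm, groups = c("wild", "honeybee")) {
  if (nrow(tm) == 0) stop_beeniche("empty trait matrix")
  raw <- unscale_traits(tm)
  raw <- raw[raw$group %in% groups, ]
  long <- tidyr::pivot_longer(raw[, c("species_id", .trait_axes)],
                              dplyr::all_of(.trait_axes),
                              names_to = "trait", values_to = "value")
  pooled <- long |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), 0),
      sd_defined = dplyr::n() > 1,
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop"
    )
  by_species <- long |>
    dplyr::group_by(.data$species_id, .data$trait) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value), .groups = "drop")
  list(pooled = pooled, by_species = by_species)
}

#' Write / read a trait matrix and its sidecars
#'
#' `write_trait_matrix()` emits `trait_matrix.tsv` (row metadata plus the six
#' axes), `scaler.json` (per-axis mean/sd, or `null` when unscaled) and
#' `exclusions.tsv`. `read_trait_matrix()` reconstructs the object.
#'
#' @param tm A `trait_matrix`.
#' @param dir Output directory (created if absent).
#' @return `write_trait_matrix()` returns `dir` invisibly;
#'   `read_trait_matrix()` returns the `trait_matrix`.
#' @export
write_trait_matrix <- function(tm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tibble::as_tibble(tm), file.path(dir, "trait_matrix.tsv"))
  sc <- tm_scaler(tm)
  jsonlite::write_json(
    if (is.null(sc)) NULL else as.list(sc),
    file.path(dir, "scaler.json"),
    digits = NA, null = "null"
  )
  readr::write_tsv(tm_exclusions(tm), file.path(dir, "exclusions.tsv"))
  invisible(dir)
}

#' @rdname write_trait_matrix
#' @export
read_trait_matrix <- function(dir) {
  df <- readr::read_tsv(file.path(dir, "trait_matrix.tsv"),
                        show_col_types = FALSE, progress = FALSE)
  sc <- jsonlite::read_json(file.path(dir, "scaler.json"), simplifyVector = TRUE)
  scaler <- if (is.null(sc) || length(sc) == 0) NULL else tibble::as_tibble(sc)
  exf <- file.path(dir, "exclusions.tsv")
  excl <- if (file.exists(exf)) {
    readr::read_tsv(exf, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  } else {
    NULL
  }
  if (!is.null(excl)) excl <- tibble::as_tibble(excl)
  new_trait_matrix(df, scaler = scaler, exclusions = excl)
}
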