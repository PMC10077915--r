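#' Construct a land-cover grid
#'
#' A regular raster-like grid of land-cover class codes with a class-to-group
#' map. Cell (row, col) has its center at
#' `(x0 + (col - 0.5) * cell_size, y0 + (row - 0.5) * cell_size)` in a
#' projected metric CRS.
#'
#' @param cells Tibble/data frame with columns `row`, `col`, `class`.
#' @param cell_size Cell edge length in meters (> 0).
#' @param x0,y0 Coordinates of the grid origin (lower-left corner), meters.
#' @param class_groups Named character vector mapping every class code to
#'   `"green"`, `"impervious"` or `"other"`.
#' @return An object of class `land_cover_grid`.
#' @export
land_cover_grid <- function(cells, cell_size, x0 = 0, y0 = 0, class_groups) {
  assert_cols(cells, c("row", "col", "class"), "land-cover cells")
  if (!is.numeric(cell_size) || cell_size <= 0) {
    stop_beeniche("cell_size must be positive")
  }
  unmapped <- setdiff(unique(cells$class), names(class_groups))
  if (length(unmapped) > 0) {
    stop_beeniche(sprintf("land-cover class(es) not mapped to a group: %s",
                          paste(unmapped, collapse = ", ")))
  }
  bad <- setdiff(unique(class_groups), c("green", "impervious", "other"))
  if (length(bad) > 0) {
    stop_beeniche("class groups must be 'green', 'impervious' or 'other'")
  }
  structure(
    list(
      cells = tibble::as_tibble(cells),
      cell_size = cell_size, x0 = x0, y0 = y0,
      class_groups = class_groups
    ),
    class = "land_cover_grid"
  )
}

#' @export
print.land_cover_grid <- function(x, ...) {
  cat(sprintf("<land_cover_grid> %d cells of %g m, origin (%g, %g)\n",
              nrow(x$cells), x$cell_size, x$x0, x$y0))
  print(table(x$class_groups[x$cells$class]))
  invisible(x)
}

grid_cell_centers <- function(grid) {
  cbind(x = grid$x0 + (grid$cells$col - 0.5) * grid$cell_size,
        y = grid$y0 + (grid$cells$row - 0.5) * grid$cell_size)
}

#' Land-cover fraction within a circular buffer
#'
#' The fraction of grid cells of a class group among all cells whose centers
#' lie within `radius` of the site (cell-center membership rule, boundary
#' inclusive). Green fractions are the landscape resource-availability
#' proxy; impervious fractions proxy urban intensity.
#'
#' @param grid A `land_cover_grid`.
#' @param x,y Site coordinates, meters.
#' @param radius Buffer radius, meters (> 0).
#' @param group `"green"`, `"impervious"` or `"other"`.
#' @return A fraction in [0, 1].
#' @export
buffer_fraction <- function(grid, x, y, radius, group = "green") {
  if (radius <= 0) stop_beeniche("radius must be positive")
  group <- match.arg(group, c("green", "impervious", "other"))
  ctr <- grid_cell_centers(grid)
  inside <- (ctr[, "x"] - x)^2 + (ctr[, "y"] - y)^2 <= radius^2
  if (!any(inside)) {
    stop_beeniche(sprintf("empty buffer: no cell centers within %g m of (%g, %g)",
                          radius, x, y))
  }
  groups <- unname(grid$class_groups[grid$cells$class[inside]])
  mean(groups == group)
}

#' Count hives within a radius of a site
#'
#' Sums the hive counts of all register points within Euclidean distance
#' `radius` of the site; the boundary is inclusive. The conventional radii
#' for beekeeping-intensity predictors are 100, 250, 500, 1000 and 2000 m,
#' but any positive radius is accepted.
#'
#' @param hives Tibble with columns `x`, `y` (meters) and `n` (hives at the
#'   point, >= 1).
#' @param x,y Site coordinates, meters.
#' @param radius Radius in meters.
#' @return Integer hive count.
#' @export
hive_count <- function(hives, x, y, radius) {
  assert_cols(hives, c("x", "y", "n"), "hive table")
  if (nrow(hives) == 0) return(0L)
  if (any(hives$n < 1)) stop_beeniche("hive counts must be >= 1")
  inside <- (hives$x - x)^2 + (hives$y - y)^2 <= radius^2
  as.integer(sum(hives$n[inside]))
}

#' Assemble the per-site analysis table
#'
#' Joins per-site pieces (FNP results, richness counts, local covariates,
#' buffer fractions, hive counts, sampling effort, coordinates ...) into one
#' validated table with exactly one complete row per site, and attaches a
#' column dictionary recording which input each column came from.
#'
#' @param ... Named data frames, each with a `site_id` column and no
#'   duplicated sites.
#' @return A tibble keyed by `site_id` with attribute `dictionary` (tibble
#'   of `column`, `source`).
#' @export
assemble_site_table <- function(...) {
  pieces <- list(...)
  if (is.null(names(pieces)) || any(names(pieces) == "")) {
    stop_beeniche("all inputs to assemble_site_table() must be named")
  }
  sites <- NULL
  for (nm in names(pieces)) {
    p <- pieces[[nm]]
    assert_cols(p, "site_id", nm)
    if (anyDuplicated(p$site_id)) {
      stop_beeniche(sprintf("duplicate site_id in '%s'", nm))
    }
    if (is.null(sites)) {
      sites <- unique(p$site_id)
    } else {
      missing_here <- setdiff(sites, p$site_id)
      extra_here <- setdiff(p$site_id, sites)
      if (length(c(missing_here, extra_here)) > 0) {
        stop_beeniche(sprintf(
          "site mismatch in '%s': missing %s; unexpected %s", nm,
          paste(missing_here, collapse = ", ") %theni% "none",
          paste(extra_here, collapse = ", ") %theni% "none"
        ))
      }
    }
  }
  out <- purrr::reduce(pieces, dplyr::inner_join, by = "site_id")
  dict <- dplyr::bind_rows(lapply(names(pieces), function(nm) {
    tibble::tibble(column = setdiff(names(pieces[[nm]]), "site_id"), source = nm)
  }))
  dict <- dplyr::bind_rows(tibble::tibble(column = "site_id", source = "key"), dict)
  attr(out, "dictionary") <- dict
  out
}

#' Write / read a site table with its column dictionary
#'
#' @param site_table A site table from [assemble_site_table()].
#' @param dir Output directory.
#' @return `write_site_table()` returns `dir` invisibly;
#'   `read_site_table()` returns the table with its `dictionary` attribute
#'   restored.
#' @export
write_site_table <- function(site_table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tibble::as_tibble(site_table), file.path(dir, "site_table.tsv"))
  dict <- attr(site_table, "dictionary")
  if (!is.null(dict)) {
    readr::write_tsv(dict, file.path(dir, "site_table_dictionary.tsv"))
  }
  invisible(dir)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(dir) {
  st <- readr::read_tsv(file.path(dir, "site_table.tsv"),
                        show_col_types = FALSE, progress = FALSE)
  dpath <- file.path(dir, "site_table_dictionary.tsv")
  if (file.exists(dpath)) {
    attr(st, "dictionary") <- readr::read_tsv(dpath, show_col_types = FALSE,
                                              progress = FALSE)
  }
  st
}
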