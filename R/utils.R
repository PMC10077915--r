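#' @importFrom rlang abort warn inform %||%
#' @importFrom stats sd coef lm pchisq pt qt setNames rnorm runif var complete.cases quantile
#' @importFrom utils head
NULL

# Canonical axis order of the six-trait feeding niche space.
.trait_axes <- c(
  "itd", "tongue_length", "feeding_specialization",
  "phenology_start", "phenology_end", "daytime_activity"
)
.individual_traits <- c("itd", "tongue_length", "daytime_activity")
.species_traits <- c("feeding_specialization", "phenology_start", "phenology_end")

.honeybee_label <- "Apis mellifera"

`%theni%` <- function(x, y) if (length(x) == 0) y else x

stop_beeniche <- function(msg, class = "beeniche_error") {
  rlang::abort(msg, class = class)
}

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop_beeniche(sprintf(
      "%s is missing required column(s): %s", what, paste(miss, collapse = ", ")
    ))
  }
  invisible(df)
}

# Pairwise Euclidean cross-distance matrix between the rows of two numeric
# matrices sharing columns; the FNP primitive. Guard against tiny negative
# values from floating-point cancellation before the square root.
cross_distances <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  stopifnot(ncol(a) == ncol(b))
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
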