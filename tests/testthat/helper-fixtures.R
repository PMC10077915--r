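# Fixtures are built in code; no files are shipped.

trait_axes <- c("itd", "tongue_length", "feeding_specialization",
                "phenology_start", "phenology_end", "daytime_activity")

# A trait matrix directly from coordinate rows, treated as already scaled.
# `wild` and `honeybee` are matrices (or vectors) of axis coordinates; short
# rows are zero-padded to the six axes.
make_tm <- function(wild, honeybee, site = "s1",
                    wild_species = NULL, sites_wild = NULL, sites_hb = NULL) {
  pad <- function(m) {
    m <- rbind(m)
    cbind(m, matrix(0, nrow(m), 6 - ncol(m)))
  }
  w <- pad(wild); h <- pad(honeybee)
  df <- tibble::tibble(
    individual_id = sprintf("i%03d", seq_len(nrow(w) + nrow(h))),
    site_id = c(sites_wild %||% rep(site, nrow(w)),
                sites_hb %||% rep(site, nrow(h))),
    species_id = c(wild_species %||% sprintf("sp%02d", seq_len(nrow(w))),
                   rep("Apis mellifera", nrow(h))),
    group = c(rep("wild", nrow(w)), rep("honeybee", nrow(h)))
  )
  ax <- tibble::as_tibble(as.data.frame(rbind(w, h)))
  names(ax) <- trait_axes
  beeniche:::new_trait_matrix(dplyr::bind_cols(df, ax))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force double-loop FNP oracle.
fnp_oracle <- function(wild, honeybee) {
  wild <- rbind(wild); honeybee <- rbind(honeybee)
  total <- 0
  for (i in seq_len(nrow(wild))) {
    for (j in seq_len(nrow(honeybee))) {
      total <- total + sqrt(sum((wild[i, ] - honeybee[j, ])^2))
    }
  }
  total / (nrow(wild) * nrow(honeybee))
}

# Small tables for the trait-data pipeline.
make_individuals <- function(n = 12, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    individual_id = sprintf("ind%02d", seq_len(n)),
    site_id = rep(c("sA", "sB"), length.out = n),
    species_raw = rep(c("Wild one", "Wild two", "Apis mellifera"), length.out = n),
    group = ifelse(rep(c("Wild one", "Wild two", "Apis mellifera"),
                       length.out = n) == "Apis mellifera",
                   "honeybee", "wild"),
    itd = round(runif(n, 0.8, 3.5), 3),
    tongue_length = round(runif(n, 0.6, 2.5), 3),
    daytime_activity = round(runif(n, 4, 10), 3)
  )
}

make_species_table <- function() {
  tibble::tibble(
    species_id = c("Wild one", "Wild two", "Apis mellifera"),
    lecty = c("oligolectic", "polylectic", "polylectic"),
    phenology_start_week = c(10, 14, 10),
    phenology_end_week = c(20, 30, 44)
  )
}

random_orthogonal <- function(k) {
  qr.Q(qr(matrix(rnorm(k * k), k)))
}
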