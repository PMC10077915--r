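test_that("collinearity screen drops the lower-priority member of |r| > 0.7 pairs only", {
  set.seed(31)
  x <- rnorm(50)
  dup <- data.frame(a = x, b = x, c = rnorm(50))
  res <- collinearity_screen(dup, priority = c("a", "b", "c"))
  expect_equal(res$dropped, "b")
  expect_true("a" %in% res$retained)

  # |r| exactly at the threshold is retained ("more than 0.7" is strict)
  n <- 40
  x <- as.numeric(scale(rnorm(n)))
  z <- residuals(lm(rnorm(n) ~ x)); z <- as.numeric(scale(z))
  y <- 0.7 * x + sqrt(1 - 0.49) * z
  expect_equal(cor(x, y), 0.7, tolerance = 1e-12)
  res2 <- collinearity_screen(data.frame(x = x, y = y))
  expect_length(res2$dropped, 0)

  expect_error(collinearity_screen(data.frame(a = rep(1, 10), b = rnorm(10))),
               "constant")
})

test_that("independent covariates survive the screen", {
  set.seed(32)
  big <- as.data.frame(matrix(rnorm(1000 * 5), 1000))
  res <- collinearity_screen(big)
  expect_length(res$dropped, 0)
})

test_that("sub-model OLS recovers exact and offset relationships", {
  x <- seq(-3, 3, length.out = 20)
  d <- data.frame(y = 2 * x, x = x)
  fit <- fit_submodel(d, "y", "x")
  expect_equal(fit$paths$estimate, 2, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # offset enters the response with coefficient fixed at 1
  d2 <- data.frame(x = x, o = 5 * sin(x))
  d2$y <- d2$o + 3 * d2$x
  fit2 <- fit_submodel(d2, "y", "x", offset = "o")
  expect_equal(fit2$paths$estimate, 3, tolerance = 1e-12)

  # aliased columns are named
  d3 <- data.frame(y = rnorm(10), x1 = 1:10, x2 = 2 * (1:10))
  expect_error(fit_submodel(d3, "y", c("x1", "x2")), "x2")
})

test_that("sub-model OLS agrees with the normal-equations oracle", {
  set.seed(33)
  for (r in 1:5) {
    n <- 40; p <- 4
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- X %*% rnorm(p) + rnorm(n)
    d <- data.frame(y = y, X)
    fit <- fit_submodel(d, "y", colnames(X))
    Xi <- cbind(1, X)
    beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
    expect_equal(fit$paths$estimate, beta[-1, 1], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("slope estimates are unbiased on simulated data", {
  set.seed(34)
  n <- 10000
  x <- rnorm(n)
  d <- data.frame(x = x, y = 0.5 * x + rnorm(n))
  fit <- fit_submodel(d, "y", "x")
  expect_lt(abs(fit$paths$estimate - 0.5), 3 * fit$paths$se)
})

test_that("standardized paths equal raw on standardized data and resist unit changes", {
  set.seed(35)
  n <- 200
  x <- as.numeric(scale(rnorm(n))); y <- as.numeric(scale(0.6 * x + rnorm(n)))
  d <- data.frame(x = x, y = y)
  fit <- fit_submodel(d, "y", "x")
  std <- standardize_paths(fit, d)
  expect_equal(std$std_estimate, std$estimate, tolerance = 1e-10)

  for (r in 1:5) {
    sx <- runif(1, 0.1, 50); sy <- runif(1, 0.1, 50)
    d2 <- data.frame(x = d$x * sx + rnorm(1), y = d$y * sy + rnorm(1))
    std2 <- standardize_paths(fit_submodel(d2, "y", "x"), d2)
    expect_equal(std2$std_estimate, std$std_estimate, tolerance = 1e-10)
  }
  const <- data.frame(x = rep(1, 10) + 1e-30 * rnorm(10), y = rnorm(10))
  expect_error(standardize_paths(
    list(response = "y", offset = NULL,
         paths = tibble::tibble(response = "y", predictor = "x",
                                estimate = 0, se = 1)),
    data.frame(x = rep(1, 10), y = rnorm(10))), "zero-variance")
})

test_that("basis set handles saturated, chain, and the default bee DAG", {
  sat <- sem_model(y ~ x, z ~ x + y)
  expect_length(basis_set(sat), 0)

  chain <- sem_model(y ~ x, z ~ y)
  claims <- basis_set(chain)
  expect_length(claims, 1)
  expect_equal(claims[[1]]$x, "x")
  expect_equal(claims[[1]]$y, "z")
  expect_equal(claims[[1]]$cond, "y")

  # default model: brute-force enumeration of eligible non-adjacent pairs
  m <- bee_sem_model()
  adj <- unique(rbind(as.matrix(m$edges), as.matrix(m$edges[, 2:1])))
  pairs <- t(combn(m$nodes, 2))
  eligible <- apply(pairs, 1, function(pr) {
    non_adj <- !any(adj[, 1] == pr[1] & adj[, 2] == pr[2])
    both_exo <- all(pr %in% m$exogenous)
    non_adj && !both_exo
  })
  expect_equal(length(basis_set(m)), sum(eligible))
  expect_equal(length(basis_set(m)), 10)
})

test_that("basis set equals brute-force pair enumeration on random small DAGs", {
  set.seed(36)
  for (r in 1:20) {
    k <- sample(3:5, 1)
    nodes <- letters[1:k]
    # random DAG respecting the node order
    edges <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    edges <- edges[match(edges$from, nodes) < match(edges$to, nodes), ]
    edges <- edges[runif(nrow(edges)) < 0.5, ]
    if (nrow(edges) == 0) next
    responses <- unique(edges$to)
    forms <- lapply(responses, function(rsp) {
      stats::as.formula(paste(rsp, "~",
                              paste(edges$from[edges$to == rsp], collapse = "+")))
    })
    m <- sem_model(forms)
    exo <- setdiff(nodes, responses)
    pairs <- t(combn(m$nodes, 2))
    oracle_n <- sum(apply(pairs, 1, function(pr) {
      non_adj <- !any((edges$from == pr[1] & edges$to == pr[2]) |
                        (edges$from == pr[2] & edges$to == pr[1]))
      non_adj && !all(pr %in% exo)
    }))
    expect_equal(length(basis_set(m)), oracle_n)
  }
})

test_that("cyclic graphs are rejected", {
  expect_error(sem_model(y ~ x, x ~ y), "cyclic")
})

test_that("d-separation test returns the upstream coefficient's p-value", {
  set.seed(37)
  n <- 400
  x <- rnorm(n)
  d <- data.frame(x = x, y = x) # y identical to x
  expect_lt(dsep_test(d, list(x = "x", y = "y", cond = character(0))), 1e-10)
  # an exact copy in the conditioning set surfaces the rank deficiency
  d2 <- data.frame(x = x, x2 = x, z = rnorm(n))
  expect_error(dsep_test(d2, list(x = "x", y = "z", cond = "x2")), "aliased")
})

test_that("Fisher's C matches its closed form and the chi-square identity", {
  res <- fishers_c(c(0.5, 0.5))
  expect_equal(res$fisher_c, -2 * log(0.25), tolerance = 1e-12)
  expect_equal(res$fisher_c, 2.77259, tolerance = 1e-5)
  expect_equal(res$df, 4L)

  empty <- fishers_c(numeric(0))
  expect_equal(empty$fisher_c, 0)
  expect_equal(empty$p_model, 1)

  # for a single claim the model p equals the claim p
  one <- fishers_c(0.05)
  expect_equal(one$fisher_c, 5.99146, tolerance = 1e-5)
  expect_equal(one$p_model, 0.05, tolerance = 1e-10)

  expect_error(fishers_c(c(0.5, 0)), "0, 1")

  # arbitrary p-vector: closed form to 1e-10
  set.seed(38)
  p <- runif(20)
  expect_equal(fishers_c(p)$fisher_c, -2 * sum(log(p)), tolerance = 1e-10)
})

test_that("the chi-square upper tail agrees with an independent regularized gamma", {
  skip_if_not_installed("pracma")
  for (C in c(1, 5, 27.72)) {
    for (df in c(2, 10, 20)) {
      ours <- stats::pchisq(C, df, lower.tail = FALSE)
      indep <- pracma::gammainc(C / 2, df / 2)[["reginc"]]
      expect_equal(ours, 1 - indep, tolerance = 1e-10)
    }
  }
})

test_that("information criteria follow the C-based convention", {
  ic <- information_criteria(10, 5, 23)
  expect_equal(ic$aicc, 10 + 10 * 23 / 17, tolerance = 1e-12)
  expect_equal(ic$aic, 20)
  expect_equal(ic$bic, 10 + 5 * log(23), tolerance = 1e-12)
  expect_equal(information_criteria(0, 0, 10)$aicc, 0)
  expect_error(information_criteria(5, 9, 10), "n > K")
  # AICc converges to AIC as n grows
  expect_equal(information_criteria(10, 5, 1e6)$aicc,
               information_criteria(10, 5, 1e6)$aic, tolerance = 1e-4)
})

test_that("fit_sem output is invariant to site order and exposes the path table", {
  set.seed(39)
  cfg <- simulation_config(n_sites = 60)
  d <- simulate_site_covariates(cfg)
  m <- bee_sem_model()
  f1 <- fit_sem(d, m)
  f2 <- fit_sem(d[sample(nrow(d)), ], m)
  expect_equal(f1$paths$std_estimate, f2$paths$std_estimate, tolerance = 1e-10)
  expect_equal(f1$fisher_c, f2$fisher_c, tolerance = 1e-10)
  tab <- sem_path_table(f1)
  expect_setequal(unique(tab$response),
                  c("fnp", "wild_richness", "plant_richness", "honeybees"))
  expect_true(all(tab$r2 >= 0 & tab$r2 <= 1))
  expect_true(all(tab$stars[tab$p < 0.01] == "**"))
  expect_equal(f1$df, 20L)
})

test_that("d-sep p-values are honest under a true claim (quick calibration)", {
  set.seed(40)
  reps <- 400
  pvals <- replicate(reps, {
    x <- rnorm(100)
    y <- 0.5 * x + rnorm(100, 0, sqrt(0.75))
    z <- 0.5 * y + rnorm(100, 0, sqrt(0.75))
    dsep_test(data.frame(x = x, y = y, z = z),
              list(x = "x", y = "z", cond = "y"))
  })
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})
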