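#' Specify a piecewise structural equation model
#'
#' A piecewise SEM is a set of linear sub-models sharing one causal DAG:
#' each endogenous variable is the response of one ordinary least-squares
#' sub-model whose predictors are its parents in the graph. Sub-models are
#' given as formulas; an `offset(<variable>)` term declares a site-level
#' offset that enters the response with its coefficient fixed at 1 (the
#' model is fitted to response minus offset).
#'
#' @param ... Formulas, one per sub-model, e.g.
#'   `fnp ~ wild_richness + plant_richness`.
#' @return An object of class `sem_model`: nodes, edge list, sub-model
#'   specifications, and the exogenous node set.
#' @export
#' @examples
#' m <- sem_model(z ~ y, y ~ x)
#' basis_set(m)
sem_model <- function(...) {
  forms <- list(...)
  if (length(forms) == 1 && is.list(forms[[1]]) && !inherits(forms[[1]], "formula")) {
    forms <- forms[[1]]
  }
  if (length(forms) == 0) stop_beeniche("at least one sub-model formula required")
  submodels <- lapply(forms, parse_submodel)
  responses <- vapply(submodels, `[[`, character(1), "response")
  if (anyDuplicated(responses)) {
    stop_beeniche("each endogenous variable may be the response of only one sub-model")
  }
  edges <- dplyr::bind_rows(lapply(submodels, function(sm) {
    tibble::tibble(from = sm$predictors, to = sm$response)
  }))
  nodes <- unique(c(edges$from, edges$to, responses))
  offsets <- unlist(lapply(submodels, `[[`, "offset"))
  model <- structure(
    list(nodes = nodes, edges = edges, submodels = submodels,
         offsets = offsets %theni% character(0)),
    class = "sem_model"
  )
  model$order <- topo_sort(model) # errors on a cyclic graph
  model$exogenous <- setdiff(nodes, responses)
  model
}

parse_submodel <- function(f) {
  if (!inherits(f, "formula") || length(f) != 3) {
    stop_beeniche("each sub-model must be a two-sided formula")
  }
  response <- as.character(f[[2]])
  tt <- stats::terms(f, specials = "offset")
  labels <- attr(tt, "term.labels")
  off_idx <- attr(tt, "specials")$offset
  offset <- NULL
  if (!is.null(off_idx) && length(off_idx) > 0) {
    vars <- as.list(attr(tt, "variables"))[-1]
    off_exprs <- vars[off_idx]
    if (length(off_exprs) > 1) stop_beeniche("at most one offset per sub-model")
    offset <- as.character(off_exprs[[1]][[2]])
  }
  predictors <- labels[!grepl("^offset\\(", labels)]
  if (length(predictors) == 0) stop_beeniche(
    sprintf("sub-model for '%s' has no predictors", response)
  )
  list(response = response, predictors = predictors, offset = offset)
}

#' @export
print.sem_model <- function(x, ...) {
  cat(sprintf("<sem_model> %d nodes, %d edges, %d sub-models\n",
              length(x$nodes), nrow(x$edges), length(x$submodels)))
  for (sm in x$submodels) {
    cat(sprintf("  %s ~ %s%s\n", sm$response,
                paste(sm$predictors, collapse = " + "),
                if (is.null(sm$offset)) "" else paste0(" + offset(", sm$offset, ")")))
  }
  cat("  exogenous:", paste(x$exogenous, collapse = ", "), "\n")
  invisible(x)
}

dag_parents <- function(model, node) {
  model$edges$from[model$edges$to == node]
}

dag_ancestors <- function(model, node) {
  seen <- character(0)
  frontier <- dag_parents(model, node)
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(lapply(frontier, dag_parents, model = model))), seen)
  }
  seen
}

topo_sort <- function(model) {
  nodes <- model$nodes
  edges <- model$edges
  order <- character(0)
  indeg <- vapply(nodes, function(n) sum(edges$to == n), numeric(1))
  avail <- nodes[indeg == 0]
  while (length(avail) > 0) {
    n <- avail[1] # declaration order as the deterministic tie-break
    avail <- avail[-1]
    order <- c(order, n)
    children <- edges$to[edges$from == n]
    edges <- edges[edges$from != n, , drop = FALSE]
    newly <- children[vapply(children, function(c) sum(edges$to == c) == 0, logical(1))]
    avail <- c(avail, setdiff(newly, c(order, avail)))
  }
  if (length(order) < length(nodes)) {
    stop_beeniche("graph is cyclic: a piecewise SEM requires an acyclic DAG")
  }
  order
}

#' The default final bee SEM
#'
#' The four-sub-model site-level SEM linking feeding niche partitioning to
#' resource availability and beekeeping intensity: (1) FNP on wild richness,
#' plant richness, honeybee abundance, hives within 500 m and green fraction
#' within 500 m; (2) wild richness on plant richness, honeybee abundance,
#' hives within 500 m and green fraction within 100 m; (3) plant richness on
#' management intensity; (4) honeybee abundance on plant richness and green
#' fraction within 500 m. No offset is declared by default; pass
#' `offset_var` to subtract a sampling-effort variable from the two count
#' responses.
#'
#' @param offset_var Optional name of an effort variable used as an offset
#'   in the wild-richness and honeybee sub-models.
#' @return A `sem_model`.
#' @export
bee_sem_model <- function(offset_var = NULL) {
  if (is.null(offset_var)) {
    sem_model(
      fnp ~ wild_richness + plant_richness + honeybees + hives_500 + green_500,
      wild_richness ~ plant_richness + honeybees + hives_500 + green_100,
      plant_richness ~ management,
      honeybees ~ plant_richness + green_500
    )
  } else {
    f2 <- stats::as.formula(sprintf(
      "wild_richness ~ plant_richness + honeybees + hives_500 + green_100 + offset(%s)",
      offset_var))
    f4 <- stats::as.formula(sprintf(
      "honeybees ~ plant_richness + green_500 + offset(%s)", offset_var))
    sem_model(
      fnp ~ wild_richness + plant_richness + honeybees + hives_500 + green_500,
      f2,
      plant_richness ~ management,
      f4
    )
  }
}

#' D-separation basis set of a DAG
#'
#' Enumerates the independence claims implied by the missing edges of the
#' model's DAG, following Shipley's construction: for every non-adjacent
#' pair of variables of which at least one is endogenous, the claim that the
#' pair is independent conditional on the union of both members' parents.
#' Pairs in which both members are exogenous are omitted, since their
#' covariance is left free by the model. The claim is oriented so that the
#' tested response is the member that is not an ancestor of the other (the
#' topologically later one when neither is an ancestor).
#'
#' @param model A `sem_model`.
#' @return A list of claims, each a list with `x` (upstream variable), `y`
#'   (response), and `cond` (conditioning set, possibly empty).
#' @export
basis_set <- function(model) {
  nodes <- model$order
  claims <- list()
  adjacent <- function(a, b) {
    any((model$edges$from == a & model$edges$to == b) |
          (model$edges$from == b & model$edges$to == a))
  }
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (j <= i) next
      a <- nodes[i]; b <- nodes[j] # a precedes b topologically
      if (adjacent(a, b)) next
      if (a %in% model$exogenous && b %in% model$exogenous) next
      if (a %in% dag_ancestors(model, b)) {
        x <- a; y <- b
      } else if (b %in% dag_ancestors(model, a)) {
        x <- b; y <- a
      } else {
        x <- a; y <- b # neither an ancestor: later node is the response
      }
      cond <- setdiff(union(dag_parents(model, a), dag_parents(model, b)), c(x, y))
      claims[[length(claims) + 1]] <- list(x = x, y = y, cond = cond)
    }
  }
  claims
}
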