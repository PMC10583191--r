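## Piecewise (local-estimation) structural equation modelling: layered
## regressions, directed-separation tests, Fisher's C, and an iterative
## refinement loop that adds missing links and prunes weak ones.

#' Specify a layered structural equation model
#'
#' Nodes carry layer tags; directed edges must respect the layer order
#' (never pointing from a later to an earlier layer) and form an acyclic
#' graph. Correlated errors are unordered pairs of same-layer nodes and may
#' not duplicate an edge.
#'
#' @param nodes data frame with columns \code{node} and \code{layer}.
#' @param edges data frame with columns \code{from}, \code{to} (may be
#'   \code{NULL} for an empty edge set).
#' @param correlated_errors data frame with columns \code{a}, \code{b}
#'   (optional).
#' @param layer_order character vector giving the causal order of layers.
#' @return An object of class \code{"sem_spec"}.
#' @export
sem_spec <- function(nodes, edges = NULL, correlated_errors = NULL,
                     layer_order = c("niche", "trait", "phenology",
                                     "outcome")) {
  stopifnot(all(c("node", "layer") %in% names(nodes)))
  if (anyDuplicated(nodes$node)) stop("specification error: duplicate nodes")
  if (!all(nodes$layer %in% layer_order))
    stop("specification error: unknown layer tag")
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    if (!all(c(edges$from, edges$to) %in% nodes$node))
      stop("specification error: edge endpoint not among nodes")
    if (any(edges$from == edges$to))
      stop("specification error: self-loop")
    li <- match(nodes$layer, layer_order)
    names(li) <- nodes$node
    if (any(li[edges$from] > li[edges$to]))
      stop("specification error: edge points from a later to an earlier layer")
    if (anyDuplicated(paste(edges$from, edges$to)))
      stop("specification error: duplicate edge")
  }
  if (is.null(correlated_errors))
    correlated_errors <- data.frame(a = character(), b = character(),
                                    stringsAsFactors = FALSE)
  correlated_errors <- as.data.frame(correlated_errors,
                                     stringsAsFactors = FALSE)
  if (nrow(correlated_errors)) {
    if (!all(c(correlated_errors$a, correlated_errors$b) %in% nodes$node))
      stop("specification error: correlated-error node not among nodes")
    if (any(correlated_errors$a == correlated_errors$b))
      stop("specification error: correlated error must join two distinct nodes")
    la <- nodes$layer[match(correlated_errors$a, nodes$node)]
    lb <- nodes$layer[match(correlated_errors$b, nodes$node)]
    if (any(la != lb))
      stop("specification error: correlated errors must join same-layer nodes")
    swap <- correlated_errors$a > correlated_errors$b
    tmp <- correlated_errors$a[swap]
    correlated_errors$a[swap] <- correlated_errors$b[swap]
    correlated_errors$b[swap] <- tmp
    if (anyDuplicated(paste(correlated_errors$a, correlated_errors$b)))
      stop("specification error: duplicate correlated error")
    ek <- c(paste(edges$from, edges$to), paste(edges$to, edges$from))
    if (any(paste(correlated_errors$a, correlated_errors$b) %in% ek))
      stop("specification error: pair appears both as edge and correlated error")
  }
  spec <- structure(list(nodes = nodes, edges = edges,
                         correlated_errors = correlated_errors,
                         layer_order = layer_order),
                    class = "sem_spec")
  .check_acyclic(spec)
  spec
}

.check_acyclic <- function(spec) {
  nodes <- spec$nodes$node
  adj <- split(spec$edges$to, factor(spec$edges$from, levels = nodes))
  state <- setNames(integer(length(nodes)), nodes)  # 0 new, 1 open, 2 done
  visit <- function(v) {
    if (state[[v]] == 1L) stop("specification error: cyclic edge graph")
    if (state[[v]] == 2L) return(invisible())
    state[[v]] <<- 1L
    for (w in adj[[v]]) visit(w)
    state[[v]] <<- 2L
  }
  for (v in nodes) visit(v)
  invisible(TRUE)
}

#' Causal (topological) order of a spec: layer order, ties alphabetical
#' @param spec a \code{"sem_spec"}.
#' @return Character vector of node names.
#' @export
causal_order <- function(spec) {
  li <- match(spec$nodes$layer, spec$layer_order)
  spec$nodes$node[order(li, spec$nodes$node)]
}

.parents <- function(spec, node) {
  sort(spec$edges$from[spec$edges$to == node])
}

#' Directed-separation basis set
#'
#' All ordered non-adjacent node pairs (earlier, later) in the causal order
#' that are not linked by a correlated error. Each claim conditions on the
#' parents of the later (downstream) variable. Deterministically ordered by
#' downstream then upstream node.
#'
#' @param spec a \code{"sem_spec"}.
#' @return Data frame: \code{upstream}, \code{downstream},
#'   \code{conditioning} (comma-separated parent set).
#' @export
sem_basis_set <- function(spec) {
  ord <- causal_order(spec)
  ek <- paste(spec$edges$from, spec$edges$to)
  ck <- paste(spec$correlated_errors$a, spec$correlated_errors$b)
  rows <- list()
  for (j in seq_along(ord)) for (i in seq_len(j - 1)) {
    u <- ord[i]; v <- ord[j]
    if (paste(u, v) %in% ek || paste(v, u) %in% ek) next
    pk <- paste(min(u, v), max(u, v))
    if (pk %in% ck) next
    rows[[length(rows) + 1]] <- data.frame(
      upstream = u, downstream = v,
      conditioning = paste(.parents(spec, v), collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(upstream = character(), downstream = character(),
                      conditioning = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$downstream, out$upstream), , drop = FALSE]
}

#' Combine independence-claim p-values by Fisher's C
#'
#' \eqn{C = -2 \sum \log p_i}, chi-square distributed with \eqn{2k} degrees
#' of freedom under the model. An empty claim set yields \eqn{C = 0} with
#' global p = 1.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return List: \code{C}, \code{df}, \code{p_global}.
#' @export
fishers_c <- function(p_values) {
  if (!length(p_values)) return(list(C = 0, df = 0L, p_global = 1))
  if (any(!is.finite(p_values)) || any(p_values > 1) || any(p_values < 0))
    stop("p-values must lie in (0, 1]")
  if (any(p_values == 0)) {
    bad <- which(p_values == 0)
    stop("Fisher's C is infinite: claim(s) ", paste(bad, collapse = ", "),
         " have p = 0")
  }
  C <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(C = C, df = df, p_global = pchisq(C, df, lower.tail = FALSE))
}

#' Fit a piecewise SEM by local estimation
#'
#' Each endogenous node is regressed (OLS on z-scored data) on its graph
#' parents; path coefficients are the standardized partial slopes. Every
#' directed-separation claim is tested by adding the upstream variable to
#' the downstream variable's parent regression and taking its t-test
#' p-value; the claims are combined by Fisher's C. Two whole-model AICs are
#' reported: the sum of the component-regression AICs (used for pruning in
#' \code{\link{sem_refine}}) and the C-based variant \eqn{C + 2K}.
#'
#' @param spec a \code{"sem_spec"}.
#' @param data data frame containing every node column; incomplete rows are
#'   dropped.
#' @return An object of class \code{"sem_fit"}: \code{paths},
#'   \code{claims}, \code{fisher_C}, \code{df}, \code{p_global},
#'   \code{aic_sum}, \code{aic_c}, \code{error_correlations}, \code{n}.
#' @export
sem_fit_local <- function(spec, data) {
  stopifnot(inherits(spec, "sem_spec"))
  vars <- spec$nodes$node
  if (!all(vars %in% names(data)))
    stop("specification error: data lacks node column(s): ",
         paste(setdiff(vars, names(data)), collapse = ", "))
  d <- data[, vars, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  z <- as.data.frame(scale(d))
  ## every node gets a component model (intercept-only when exogenous) so
  ## that whole-model AICs stay comparable when refinement changes which
  ## nodes are endogenous
  fits <- list()
  paths <- list()
  for (v in vars) {
    pa <- .parents(spec, v)
    fit <- if (length(pa)) lm(reformulate(pa, v), data = z)
           else lm(reformulate("1", v), data = z)
    fits[[v]] <- fit
    if (!length(pa)) next
    sm <- summary(fit)$coefficients
    paths[[v]] <- data.frame(from = pa, to = v,
                             estimate = unname(coef(fit)[pa]),
                             std_error = sm[pa, "Std. Error"],
                             p_value = sm[pa, "Pr(>|t|)"],
                             stringsAsFactors = FALSE)
  }
  paths <- if (length(paths)) do.call(rbind, paths)
           else data.frame(from = character(), to = character(),
                           estimate = numeric(), std_error = numeric(),
                           p_value = numeric(), stringsAsFactors = FALSE)
  rownames(paths) <- NULL

  basis <- sem_basis_set(spec)
  if (nrow(basis)) {
    basis$p_value <- NA_real_
    basis$estimate <- NA_real_
    for (i in seq_len(nrow(basis))) {
      v <- basis$downstream[i]; u <- basis$upstream[i]
      pa <- .parents(spec, v)
      fit <- lm(reformulate(c(pa, u), v), data = z)
      sm <- summary(fit)$coefficients
      basis$p_value[i] <- sm[u, "Pr(>|t|)"]
      basis$estimate[i] <- sm[u, "Estimate"]
    }
  } else {
    basis$p_value <- numeric(0)
    basis$estimate <- numeric(0)
  }
  fc <- fishers_c(basis$p_value)

  res_of <- function(v) if (v %in% names(fits)) resid(fits[[v]]) else z[[v]]
  ec <- spec$correlated_errors
  ec$correlation <- if (nrow(ec))
    vapply(seq_len(nrow(ec)), function(i)
      cor(res_of(ec$a[i]), res_of(ec$b[i])), numeric(1))
  else numeric(0)

  k_total <- sum(vapply(fits, function(f) attr(logLik(f), "df"), numeric(1)))
  structure(list(spec = spec, paths = paths, claims = basis,
                 fisher_C = fc$C, df = fc$df, p_global = fc$p_global,
                 aic_sum = sum(vapply(fits, AIC, numeric(1))),
                 aic_c = fc$C + 2 * k_total,
                 error_correlations = ec,
                 n = nrow(z), fits = fits),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("Piecewise SEM fit (n = %d): %d paths, %d independence claims\n",
              x$n, nrow(x$paths), nrow(x$claims)))
  cat(sprintf("  Fisher's C = %.2f, df = %d, P = %.3f;  sum-AIC = %.1f, C-AIC = %.1f\n",
              x$fisher_C, x$df, x$p_global, x$aic_sum, x$aic_c))
  invisible(x)
}

#' Iteratively refine a piecewise SEM
#'
#' Repeats: fit, test the directed-separation basis set; among claims with
#' \eqn{p <} \code{alpha_add} pick the smallest; a cross-layer pair adds a
#' directed edge (earlier layer to later layer), a same-layer pair adds a
#' correlated error. After each pass, any edge whose single removal lowers
#' the summed component AIC is pruned (best single removal per iteration).
#' Stops when no claim is significant and the global Fisher's C p-value
#' exceeds \code{stop_p}, or at the iteration cap.
#'
#' @param spec starting \code{"sem_spec"}.
#' @param data data frame with all node columns.
#' @param alpha_add significance threshold for adding a term.
#' @param stop_p required global p-value at convergence.
#' @param max_iter iteration cap.
#' @param prune whether to AIC-prune edges.
#' @return List: final \code{spec}, final \code{fit}, \code{trail} (audit
#'   data frame of additions/removals), \code{converged}, \code{iterations}.
#' @export
sem_refine <- function(spec, data, alpha_add = 0.05, stop_p = 0.2,
                       max_iter = 20L, prune = TRUE) {
  trail <- data.frame(iteration = integer(), action = character(),
                      from = character(), to = character(),
                      detail = numeric(), stringsAsFactors = FALSE)
  layer_of <- setNames(spec$nodes$layer, spec$nodes$node)
  fit <- sem_fit_local(spec, data)
  converged <- FALSE
  iter <- 0L
  repeat {
    sig <- fit$claims[!is.na(fit$claims$p_value) &
                        fit$claims$p_value < alpha_add, , drop = FALSE]
    if (!nrow(sig) && fit$p_global > stop_p) { converged <- TRUE; break }
    if (iter >= max_iter) break
    iter <- iter + 1L
    changed <- FALSE
    if (nrow(sig)) {
      top <- sig[which.min(sig$p_value), ]
      u <- top$upstream; v <- top$downstream
      if (layer_of[[u]] == layer_of[[v]]) {
        spec <- sem_spec(spec$nodes, spec$edges,
                         rbind(spec$correlated_errors,
                               data.frame(a = u, b = v,
                                          stringsAsFactors = FALSE)),
                         spec$layer_order)
        trail <- rbind(trail, data.frame(
          iteration = iter, action = "add_correlated_error",
          from = u, to = v, detail = top$p_value,
          stringsAsFactors = FALSE))
      } else {
        spec <- sem_spec(spec$nodes,
                         rbind(spec$edges,
                               data.frame(from = u, to = v,
                                          stringsAsFactors = FALSE)),
                         spec$correlated_errors, spec$layer_order)
        trail <- rbind(trail, data.frame(
          iteration = iter, action = "add_edge", from = u, to = v,
          detail = top$p_value, stringsAsFactors = FALSE))
      }
      changed <- TRUE
    }
    fit <- sem_fit_local(spec, data)
    if (prune && nrow(spec$edges)) {
      best_gain <- 0; best_e <- NULL
      for (e in seq_len(nrow(spec$edges))) {
        cand <- spec$edges[-e, , drop = FALSE]
        cand_spec <- sem_spec(spec$nodes, cand, spec$correlated_errors,
                              spec$layer_order)
        gain <- fit$aic_sum - sem_fit_local(cand_spec, data)$aic_sum
        if (gain > best_gain) { best_gain <- gain; best_e <- e }
      }
      if (!is.null(best_e)) {
        trail <- rbind(trail, data.frame(
          iteration = iter, action = "remove_edge",
          from = spec$edges$from[best_e], to = spec$edges$to[best_e],
          detail = best_gain, stringsAsFactors = FALSE))
        spec <- sem_spec(spec$nodes,
                         spec$edges[-best_e, , drop = FALSE],
                         spec$correlated_errors, spec$layer_order)
        fit <- sem_fit_local(spec, data)
        changed <- TRUE
      }
    }
    if (!changed) break  # nothing to add or remove but still not converged
  }
  list(spec = spec, fit = fit, trail = trail, converged = converged,
       iterations = iter)
}

#' Default layered SEM of season length
#'
#' Mirrors the package's causal hierarchy: niche variables (moisture, light,
#' soil reaction, disturbance frequency) drive the four functional traits,
#' traits drive the five phenological variables, and those determine season
#' length. All between-layer edges are present at the start; refinement adds
#' or removes links as the data demand.
#'
#' @return A \code{"sem_spec"}.
#' @export
default_sem_spec <- function() {
  nodes <- data.frame(
    node = c("moisture", "light", "reaction", "dist_frequency",
             "log_height", "log_lateral_spread", "sla", "ldmc",
             "peak_day", "log_b", "sen_date", "sen_pace", "sen_shape",
             "season_length"),
    layer = c(rep("niche", 4), rep("trait", 4), rep("phenology", 5),
              "outcome"),
    stringsAsFactors = FALSE)
  niche <- nodes$node[nodes$layer == "niche"]
  traits <- nodes$node[nodes$layer == "trait"]
  phen <- nodes$node[nodes$layer == "phenology"]
  edges <- rbind(
    expand.grid(from = niche, to = traits, stringsAsFactors = FALSE),
    expand.grid(from = traits, to = phen, stringsAsFactors = FALSE),
    data.frame(from = phen, to = "season_length", stringsAsFactors = FALSE))
  sem_spec(nodes, edges)
}

#' Simulate data from a layered SEM specification
#'
#' Generates standardized variables in causal order: exogenous nodes are
#' standard normal; each endogenous node is the coefficient-weighted sum of
#' its parents plus Gaussian noise scaled so the node variance stays near 1
#' (so the supplied coefficients are standardized path strengths).
#'
#' @param spec a \code{"sem_spec"}.
#' @param coefficients data frame with columns \code{from}, \code{to},
#'   \code{beta}; edges not listed get coefficient 0.
#' @param n number of rows.
#' @param resid_floor minimum residual variance.
#' @return Data frame with one column per node.
#' @export
simulate_sem_data <- function(spec, coefficients, n, resid_floor = 0.05) {
  stopifnot(inherits(spec, "sem_spec"),
            all(c("from", "to", "beta") %in% names(coefficients)))
  ord <- causal_order(spec)
  out <- as.data.frame(matrix(NA_real_, n, length(ord),
                              dimnames = list(NULL, ord)))
  for (v in ord) {
    pa <- .parents(spec, v)
    if (!length(pa)) { out[[v]] <- rnorm(n); next }
    beta <- vapply(pa, function(p) {
      hit <- coefficients$from == p & coefficients$to == v
      if (any(hit)) coefficients$beta[hit][1] else 0
    }, numeric(1))
    lp <- as.matrix(out[, pa, drop = FALSE]) %*% beta
    sd_e <- sqrt(max(1 - var(drop(lp)), resid_floor))
    out[[v]] <- drop(lp) + rnorm(n, 0, sd_e)
  }
  out
}
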