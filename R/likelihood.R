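# DEC likelihood by pruning on a time-calibrated tree.
#
# Branch propagation works in node age (Ma before present). A branch spanning
# [child age, parent age] is cut at epoch boundaries and per-segment
# transition matrices are chained oldest -> youngest; acting on the child's
# conditional vector this means applying the youngest segment first.
# Per-epoch propagators use the eigendecomposition of Q (one decomposition per
# likelihood evaluation, then only matrix-vector work per branch), falling
# back to dense scaling-and-squaring when Q is numerically defective.

#' Node ages of a time-calibrated tree
#'
#' Ages are measured backward from the youngest tip (0 Ma); trees that are not
#' perfectly ultrametric use the maximum tip depth as the present.
#'
#' @param tree An \code{ape::phylo} tree with branch lengths in My.
#' @return Numeric vector of ages (Ma) indexed by ape node number
#'   (tips first, then internal nodes).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

# normalize tip range input to a list of state indices keyed by tip label
.tip_state_indices <- function(tips, space, tree) {
  labels <- tree$tip.label
  if (is.character(tips) && !is.list(tips)) tips <- as.list(tips)
  if (is.null(names(tips)) || !all(labels %in% names(tips)))
    stop("tip ranges must be named and cover every tip of the tree",
         call. = FALSE)
  idx <- .state_index_map(space)
  out <- integer(length(labels))
  for (i in seq_along(labels)) {
    st <- tips[[labels[i]]]
    if (is.character(st)) {
      ai <- match(st, space$areas$code)
      if (anyNA(ai))
        stop("tip '", labels[i], "' observed in area(s) absent from the model: ",
             paste(st[is.na(ai)], collapse = ", "), call. = FALSE)
      st <- ai
    }
    st <- sort(unique(as.integer(st)))
    if (length(st) == 0L)
      stop("tip '", labels[i], "' has a null range; tips cannot be extinct",
           call. = FALSE)
    j <- idx[.state_key(st)]
    if (is.na(j))
      stop("range of tip '", labels[i], "' is not in the model's state space",
           call. = FALSE)
    out[i] <- j
  }
  out
}

# split the interval [age_lo, age_hi] at epoch boundaries; return segments
# youngest first as (epoch index, duration)
.edge_segments <- function(age_lo, age_hi, epochs) {
  if (age_hi > epochs$start_ages[1])
    stop("branch extends older than the oldest epoch (",
         format(epochs$start_ages[1]), " Ma)", call. = FALSE)
  segs <- list()
  for (k in rev(seq_len(epochs$n_epochs))) {  # youngest epoch last in list
    lo <- max(age_lo, epochs$end_ages[k])
    hi <- min(age_hi, epochs$start_ages[k])
    if (hi > lo) segs[[length(segs) + 1L]] <- c(k, hi - lo)
  }
  segs
}

# engine: everything about (tree, tips, model) that does not depend on rates
.dec_engine <- function(tree, tips, model) {
  stopifnot(inherits(model, "dec_model"))
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object", call. = FALSE)
  if (!ape::is.binary(tree)) {
    tab <- tabulate(tree$edge[, 1])
    bad <- which(tab > 2)[1]
    stop("tree is not binary: node ", bad, " has ", tab[bad], " children",
         call. = FALSE)
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  ages <- node_ages(tree)
  root_age <- max(ages)
  tip_dev <- max(abs(ages[seq_len(ape::Ntip(tree))]))
  if (root_age > 0 && tip_dev > 1e-3 * root_age)
    warning("tree is not ultrametric (max tip age deviation ",
            format(tip_dev, digits = 3), " Ma); treating max tip depth as the present")

  space <- model$space
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  edge <- po$edge

  segs <- vector("list", nrow(edge))
  for (i in seq_len(nrow(edge))) {
    segs[[i]] <- .edge_segments(ages[edge[i, 2]], ages[edge[i, 1]], model$epochs)
  }

  clado <- clado_event_table(space)
  anc <- integer(0); lf <- integer(0); rt <- integer(0); pr <- numeric(0)
  for (i in seq_along(clado)) {
    ev <- clado[[i]]
    if (is.null(ev)) next
    anc <- c(anc, rep.int(i, nrow(ev)))
    lf <- c(lf, ev$left); rt <- c(rt, ev$right); pr <- c(pr, ev$prob)
  }
  S <- space$n_states
  Csp <- Matrix::sparseMatrix(i = anc, j = seq_along(anc), x = pr,
                              dims = c(S, length(anc)))
  Lsp <- Matrix::sparseMatrix(i = lf, j = seq_along(lf), x = 1,
                              dims = c(S, length(anc)))

  tip_state <- .tip_state_indices(tips, space, tree)

  list(tree = tree, model = model, space = space, ages = ages, edge = edge,
       segs = segs, ntip = ntip, nnode = nnode, tip_state = tip_state,
       clado = list(anc = anc, left = lf, right = rt, prob = pr,
                    Csp = Csp, Lsp = Lsp),
       fingerprint = paste(ntip, nnode,
                           format(sum(tree$edge.length), digits = 12),
                           paste(sort(tree$tip.label), collapse = "|"),
                           paste(tip_state[order(tree$tip.label)], collapse = ","),
                           sep = ";"))
}

# per-epoch propagators for one (d, e): prefer eigendecomposition
.propagators <- function(model, params) {
  Qs <- epoch_matrices(model, params)
  lapply(Qs, function(Q) {
    prop <- tryCatch({
      eg <- eigen(Q)
      Vi <- solve(eg$vectors)
      err <- max(abs(Re(eg$vectors %*% (eg$values * Vi)) - Q))
      if (!is.finite(err) || err > 1e-8 * max(1, max(abs(Q)))) stop("defective")
      list(type = "eigen", V = eg$vectors, Vi = Vi, vals = eg$values, Q = Q)
    }, error = function(e) list(type = "expm", Q = Q))
    prop
  })
}

# apply P(dt) (up pass) or t(P(dt)) (down pass) to a vector
.propagate <- function(prop, x, dt, transpose = FALSE) {
  if (dt == 0) return(x)
  if (prop$type == "eigen") {
    if (transpose) {
      y <- Re(t(prop$Vi) %*% (exp(prop$vals * dt) * (t(prop$V) %*% x)))
    } else {
      y <- Re(prop$V %*% (exp(prop$vals * dt) * (prop$Vi %*% x)))
    }
  } else {
    P <- as.matrix(Matrix::expm(Matrix::Matrix(prop$Q * dt)))
    y <- if (transpose) crossprod(P, x) else P %*% x
  }
  y <- as.vector(y)
  y[y < 0] <- 0
  y
}

# full pruning pass; returns per-node conditional vectors and log scalers.
# tip_mode "observed" uses the observed indicator vectors; "nonnull" uses an
# any-surviving-range indicator (for survival conditioning).
.pruning_pass <- function(engine, params, keep = FALSE,
                          tip_mode = "observed", props = NULL) {
  model <- engine$model
  if (is.null(props)) props <- .propagators(model, params)
  S <- engine$space$n_states
  ntip <- engine$ntip
  nnodes_total <- ntip + engine$nnode
  bottoms <- vector("list", nnodes_total)  # branch-bottom vectors, by child id
  nodeL <- if (keep) matrix(NA_real_, nnodes_total, S) else NULL
  child_of <- vector("list", nnodes_total) # children ids per parent
  logscale <- 0
  edge <- engine$edge

  nonnull <- vapply(engine$space$states, length, 1L) > 0
  node_vec <- function(id) {
    if (id <= ntip) {
      v <- numeric(S)
      if (tip_mode == "nonnull") v[nonnull] <- 1 else v[engine$tip_state[id]] <- 1
      return(v)
    }
    ch <- child_of[[id]]
    Bl <- bottoms[[ch[1]]]; Br <- bottoms[[ch[2]]]
    cl <- engine$clado
    val <- Bl[cl$left] * Br[cl$right]
    v <- as.vector(cl$Csp %*% val)
    v
  }

  for (i in seq_len(nrow(edge))) {
    par <- edge[i, 1]; ch <- edge[i, 2]
    v <- node_vec(ch)
    s <- sum(v)
    if (s <= 0 || !is.finite(s)) return(list(logL = -Inf))
    v <- v / s
    logscale <- logscale + log(s)
    if (keep) nodeL[ch, ] <- v
    for (sg in engine$segs[[i]]) v <- .propagate(props[[sg[1]]], v, sg[2])
    bottoms[[ch]] <- v
    child_of[[par]] <- c(child_of[[par]], ch)
  }
  root <- ntip + 1L
  v <- node_vec(root)
  s <- sum(v)
  if (s <= 0 || !is.finite(s)) return(list(logL = -Inf))
  if (keep) nodeL[root, ] <- v / s
  list(root_vec = v / s, logscale = logscale + log(s), nodeL = nodeL,
       bottoms = bottoms, child_of = child_of, props = props)
}

#' DEC log-likelihood of tip ranges on a tree
#'
#' Computes the model likelihood by Felsenstein pruning: tip vectors are
#' indicators of the observed ranges; branch propagation chains per-epoch
#' transition matrices over the branch's age segments; at each internal node
#' the daughter vectors are combined over all cladogenetic events; the root
#' likelihood sums the root vector over non-null ranges (optionally averaging
#' under a uniform prior).
#'
#' @param tree Rooted binary time-calibrated \code{ape::phylo} tree,
#'   branch lengths in My.
#' @param tips Named list (by tip label) of ranges: character vectors of area
#'   codes or integer area indices.
#' @param model A \code{\link{dec_model}}.
#' @param params A \code{\link{dec_params}} pair.
#' @param root \code{"flat"} (default) sums the root vector over non-null
#'   ranges, the classic DEC convention; \code{"uniform"} averages it.
#' @param condition \code{"none"} (default, the classic DEC convention) or
#'   \code{"survival"}: divide the likelihood by the probability that no tip
#'   lineage is extinct (its range non-null), the appropriate sampling
#'   distribution when extinct lineages are pruned from the data, e.g. in
#'   simulation-based recovery experiments.
#' @return The log-likelihood (a single number; \code{-Inf} if the data have
#'   zero probability under the model).
#' @examples
#' tr <- ape::read.tree(text = "((t1:1,t2:1):1,t3:2);")
#' m <- dec_model(3, name = "toy")
#' compute_log_likelihood(tr, list(t1 = 1L, t2 = 2L, t3 = 1L), m,
#'                        dec_params(0.1, 0.05))
#' @export
compute_log_likelihood <- function(tree, tips, model, params,
                                   root = c("flat", "uniform"),
                                   condition = c("none", "survival")) {
  root <- match.arg(root)
  condition <- match.arg(condition)
  engine <- if (inherits(tree, "dec_engine_bundle")) tree else
    .dec_engine(tree, tips, model)
  .engine_loglik(engine, params, root, condition)
}

.engine_loglik <- function(engine, params, root = "flat", condition = "none") {
  props <- .propagators(engine$model, params)
  pass <- .pruning_pass(engine, params, keep = FALSE, props = props)
  if (!is.finite(pass$logL %||% 0)) return(-Inf)
  w <- as.numeric(vapply(engine$space$states, length, 1L) > 0)
  if (root == "uniform") w <- w / sum(w)
  tot <- sum(w * pass$root_vec)
  if (tot <= 0) return(-Inf)
  ll <- log(tot) + pass$logscale
  if (condition == "survival") {
    surv <- .pruning_pass(engine, params, keep = FALSE,
                          tip_mode = "nonnull", props = props)
    if (!is.finite(surv$logL %||% 0)) return(-Inf)
    stot <- sum(w * surv$root_vec)
    if (stot <= 0) return(-Inf)
    ll <- ll - (log(stot) + surv$logscale)
  }
  ll
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Optimizer settings for \code{\link{fit_dec}}
#'
#' @param lower,upper Box constraints on each rate (events/My).
#' @param starts Matrix of starting points (columns d, e); default four fixed
#'   points log-spaced in each rate.
#' @param n_optimize Number of screened starts to polish with Nelder-Mead
#'   (starts are ranked by their initial log-likelihood; default 2).
#' @param reltol Relative convergence tolerance on the negative log-likelihood.
#' @param maxit Maximum Nelder-Mead iterations per start.
#' @return A list of class \code{"dec_fit_options"}.
#' @export
dec_fit_options <- function(lower = 1e-9, upper = 10,
                            starts = as.matrix(expand.grid(d = c(1e-3, 1e-1),
                                                           e = c(1e-3, 1e-1))),
                            n_optimize = 2, reltol = 1e-10, maxit = 500) {
  structure(list(lower = lower, upper = upper, starts = starts,
                 n_optimize = n_optimize, reltol = reltol, maxit = maxit),
            class = "dec_fit_options")
}

#' Fit a DEC model by maximum likelihood
#'
#' Maximizes the log-likelihood over the dispersal and extinction rates by
#' box-constrained Nelder-Mead search on log-scaled rates from multiple
#' deterministic starting points (the starts are screened by their initial
#' likelihood and the best ones polished). AIC is computed with k = 2: every
#' DEC model has two free parameters regardless of its constraint matrix.
#'
#' @inheritParams compute_log_likelihood
#' @param opts A \code{\link{dec_fit_options}} list.
#' @param tree_id Optional identifier recorded in the result.
#' @return An object of class \code{"dec_fit"}: list with \code{d}, \code{e},
#'   \code{logL}, \code{AIC}, \code{convergence} (0 = converged),
#'   \code{model}, \code{tree_id}, \code{starts} (per-start table) and
#'   \code{fingerprint} of the data.
#' @export
fit_dec <- function(tree, tips, model, opts = dec_fit_options(),
                    root = c("flat", "uniform"),
                    condition = c("none", "survival"), tree_id = "tree1") {
  root <- match.arg(root)
  condition <- match.arg(condition)
  engine <- .dec_engine(tree, tips, model)
  lo <- log(opts$lower); hi <- log(opts$upper)
  nll <- function(lp) {
    lpc <- pmin(pmax(lp, lo), hi)
    pen <- sum((lp - lpc)^2)
    ll <- .engine_loglik(engine, dec_params(exp(lpc[1]), exp(lpc[2])), root,
                         condition)
    if (!is.finite(ll)) return(1e10)
    -ll + pen * 100
  }
  starts <- log(opts$starts)
  init <- apply(starts, 1, nll)
  ord <- order(init)
  keep <- ord[seq_len(min(opts$n_optimize, nrow(starts)))]
  best <- NULL
  start_log <- data.frame(d0 = opts$starts[, 1], e0 = opts$starts[, 2],
                          logL0 = -init, optimized = FALSE,
                          logL = NA_real_, convergence = NA_integer_)
  for (j in keep) {
    res <- stats::optim(starts[j, ], nll, method = "Nelder-Mead",
                        control = list(reltol = opts$reltol,
                                       maxit = opts$maxit))
    start_log$optimized[j] <- TRUE
    start_log$logL[j] <- -res$value
    start_log$convergence[j] <- res$convergence
    if (is.null(best) || res$value < best$value) best <- res
  }
  est <- exp(pmin(pmax(best$par, lo), hi))
  logL <- -best$value
  if (!is.finite(logL))
    warning("optimizer failed to find a finite likelihood optimum")
  structure(list(d = unname(est[1]), e = unname(est[2]), logL = logL,
                 AIC = 2 * 2 - 2 * logL, convergence = best$convergence,
                 model = engine$model$name, tree_id = tree_id,
                 starts = start_log, fingerprint = engine$fingerprint),
            class = "dec_fit")
}

#' @export
print.dec_fit <- function(x, ...) {
  cat("DEC fit of '", x$model, "' (", x$tree_id, ")\n", sep = "")
  cat(sprintf("  d = %.4g  e = %.4g  logL = %.3f  AIC = %.2f  convergence = %d\n",
              x$d, x$e, x$logL, x$AIC, x$convergence))
  invisible(x)
}

#' Rank fitted DEC models by AIC
#'
#' Builds the standard model-comparison report: models sorted by ascending
#' AIC with the difference from the best model (delta AIC), -2 log-likelihood
#' and the rate estimates. All fits must be of the same tree and tip data.
#' Ties in AIC are broken by model name for determinism.
#'
#' @param fits List of \code{\link{fit_dec}} results.
#' @return Data frame with columns \code{model}, \code{neg2logL},
#'   \code{dAIC}, \code{d}, \code{e}, \code{logL}, \code{AIC}.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "dec_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "dec_fit")))
  fps <- vapply(fits, `[[`, "", "fingerprint")
  if (length(unique(fps)) > 1)
    stop("fits are not all of the same tree and tip data", call. = FALSE)
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    neg2logL = vapply(fits, function(f) -2 * f$logL, 1),
    AIC = vapply(fits, `[[`, 1, "AIC"),
    d = vapply(fits, `[[`, 1, "d"),
    e = vapply(fits, `[[`, 1, "e"))
  tab$logL <- -tab$neg2logL / 2
  tab <- tab[order(tab$AIC, tab$model), ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  tab[, c("model", "neg2logL", "dAIC", "d", "e", "logL", "AIC")]
}

#' Model-selection frequency across a set of trees
#'
#' Fits every model on every tree and reports, per model, the fraction of
#' trees on which it is AIC-best; exact ties split the credit equally, so the
#' frequencies sum to one.
#'
#' @param trees List of \code{phylo} trees (or a \code{multiPhylo}).
#' @param tips Tip ranges shared by all trees (see
#'   \code{\link{compute_log_likelihood}}).
#' @param models List of \code{\link{dec_model}}s.
#' @param opts Optimizer settings.
#' @param tol AIC difference below which two models are considered tied.
#' @return Named numeric vector of selection frequencies.
#' @export
selection_frequency <- function(trees, tips, models, opts = dec_fit_options(),
                                tol = 1e-8) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1, length(models) >= 1)
  nm <- vapply(models, `[[`, "", "name")
  freq <- stats::setNames(numeric(length(models)), nm)
  for (ti in seq_along(trees)) {
    aics <- vapply(models, function(m)
      fit_dec(trees[[ti]], tips, m, opts, tree_id = paste0("tree", ti))$AIC, 1)
    win <- which(aics <= min(aics) + tol)
    freq[win] <- freq[win] + 1 / length(win)
  }
  freq / length(trees)
}
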