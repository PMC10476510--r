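# Stochastic simulation of range evolution under a DEC process, used to
# validate every pipeline stage without external data: anagenetic events are
# drawn along branches by competing exponentials from the epoch-appropriate Q
# row, cladogenetic events at nodes from the DEC event distribution.

#' Simulate an ultrametric pure-birth tree
#'
#' A Yule tree conditioned on the number of tips, rescaled to a fixed root
#' depth so that simulated clades match a target age (default 20 My, the
#' approximate age of the Papuan study clade).
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate of the pure-birth process (its absolute
#'   value is irrelevant after rescaling; default 1).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param depth Root depth in My after rescaling (default 20).
#' @return An \code{ape::phylo} ultrametric tree.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed, depth = 20) {
  stopifnot(n_tips >= 2)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  H <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (depth / H)
  tree
}

#' Simulate a DEC history on a tree
#'
#' Simulates the full history of range evolution: the root lineage starts in
#' \code{root_range} at the root age; along each branch dispersal and local
#' extinction events are drawn by competing exponentials using the epoch-
#' appropriate Q row of the current range (epoch changes handled at boundary
#' ages); at each internal node a cladogenetic event is drawn from
#' \code{\link{enumerate_daughter_events}}. A lineage that loses its last
#' area enters the null range and stays extinct; tips of such lineages are
#' flagged.
#'
#' @param tree Time-calibrated \code{phylo} tree.
#' @param model A \code{\link{dec_model}}.
#' @param params True \code{\link{dec_params}}.
#' @param root_range Areas of the root lineage (codes or indices); non-null.
#' @param seed Integer seed.
#' @return An object of class \code{"dec_sim"}: list with \code{tree},
#'   \code{node_states} (state index per ape node id), \code{tip_ranges}
#'   (named list of area-code vectors; extinct tips are \code{character(0)}),
#'   \code{extinct_tips} (labels), and \code{events} (data frame: branch
#'   child id, age, from, to).
#' @export
simulate_dec_history <- function(tree, model, params, root_range, seed) {
  stopifnot(inherits(model, "dec_model"))
  set.seed(seed)
  space <- model$space
  if (is.character(root_range)) {
    root_range <- match(root_range, model$areas$code)
    if (anyNA(root_range)) stop("unknown area code in root_range", call. = FALSE)
  }
  if (length(root_range) == 0)
    stop("root_range must be non-null", call. = FALSE)
  root_state <- range_index(space, root_range)
  Qs <- epoch_matrices(model, params)
  ep <- model$epochs
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  Nall <- ntip + tree$Nnode
  root <- ntip + 1L
  if (ages[root] > ep$start_ages[1])
    stop("root older than the oldest epoch", call. = FALSE)

  clado <- clado_event_table(space)
  node_states <- integer(Nall)
  node_states[root] <- root_state
  events <- list()

  epoch_at <- function(age) {
    # epoch k covers (end_age, start_age]
    for (k in seq_len(ep$n_epochs)) {
      if (age <= ep$start_ages[k] && age > ep$end_ages[k]) return(k)
    }
    ep$n_epochs  # age == 0
  }

  # simulate along one branch from age_hi down to age_lo, return end state
  run_branch <- function(state, age_hi, age_lo, child_id) {
    t <- age_hi
    while (t > age_lo + 1e-12) {
      if (length(space$states[[state]]) == 0L) break  # extinct: absorbing
      k <- epoch_at(t)
      boundary <- max(age_lo, ep$end_ages[k])
      rates <- Qs[[k]][state, ]
      rates[state] <- 0
      tot <- sum(rates)
      if (tot <= 0) { t <- boundary; next }
      dt <- stats::rexp(1, tot)
      if (t - dt <= boundary) { t <- boundary; next }
      t <- t - dt
      dest <- sample.int(space$n_states, 1, prob = rates)
      events[[length(events) + 1L]] <<- data.frame(
        branch = child_id, age = t,
        from = space$labels[state], to = space$labels[dest])
      state <- dest
    }
    state
  }

  # preorder traversal drawing one cladogenetic event per parent
  # (both daughter start states at once), then simulating each branch
  children_of <- split(tree$edge[, 2], tree$edge[, 1])
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v > ntip) {
      ch <- children_of[[as.character(v)]]
      pstate <- node_states[v]
      if (length(space$states[[pstate]]) == 0L) {
        starts <- c(pstate, pstate)
      } else {
        ev <- clado[[pstate]]
        j <- sample.int(nrow(ev), 1, prob = ev$prob)
        starts <- c(ev$left[j], ev$right[j])
      }
      for (k in 1:2) {
        cid <- ch[k]
        end <- run_branch(starts[k], ages[v], ages[cid], cid)
        node_states[cid] <- end
        if (cid > ntip) stack <- c(stack, cid)
      }
    }
  }

  tip_states <- node_states[seq_len(ntip)]
  tip_ranges <- lapply(tip_states, function(s) model$areas$code[space$states[[s]]])
  names(tip_ranges) <- tree$tip.label
  extinct <- tree$tip.label[vapply(tip_ranges, length, 1L) == 0L]
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(branch = integer(0), age = numeric(0),
               from = character(0), to = character(0))
  structure(list(tree = tree, node_states = node_states,
                 tip_ranges = tip_ranges, extinct_tips = extinct,
                 events = events, model = model, params = params,
                 seed = seed),
            class = "dec_sim")
}

#' Configuration of a simulation / recovery experiment
#'
#' @param n_tips Tips per simulated tree (default 218, the study scale).
#' @param birth_rate Pure-birth rate before depth rescaling.
#' @param depth Root depth in My (default 20).
#' @param model Generating \code{\link{dec_model}}.
#' @param params True \code{\link{dec_params}}.
#' @param root_range Root range (codes or indices).
#' @param seed Integer seed (mandatory).
#' @param replicates Number of replicates.
#' @param tree Optional fixed tree; if supplied, \code{n_tips} etc. are
#'   ignored and every replicate reuses it.
#' @return A list of class \code{"dec_sim_config"}.
#' @export
simulation_config <- function(model, params, root_range, seed,
                              n_tips = 218, birth_rate = 1, depth = 20,
                              replicates = 1, tree = NULL) {
  stopifnot(inherits(model, "dec_model"), replicates >= 1)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  structure(list(model = model, params = params, root_range = root_range,
                 seed = as.integer(seed), n_tips = n_tips,
                 birth_rate = birth_rate, depth = depth,
                 replicates = replicates, tree = tree),
            class = "dec_sim_config")
}

#' Parameter- and model-recovery experiment
#'
#' For each replicate: simulate a tree (unless fixed) and a DEC history,
#' drop extinct (null-range) tips, fit every candidate model, and record the
#' rate estimates and the AIC-best model. Replicates with fewer than four
#' surviving tips are redrawn (with a message). The summary reports bias and
#' RMSE of the rate estimates and per-model selection frequencies.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param fit_models List of candidate \code{\link{dec_model}}s (default:
#'   just the generating model).
#' @param opts Optimizer settings for \code{\link{fit_dec}}.
#' @param condition Likelihood conditioning passed to \code{\link{fit_dec}};
#'   default \code{"survival"}, matching the pruning of extinct tips from
#'   the simulated data (the unconditioned fit is biased toward zero
#'   extinction on such data).
#' @return A list of class \code{"dec_recovery"} with \code{replicates}
#'   (a data frame: one row per replicate and model) and \code{summary}.
#' @export
recovery_experiment <- function(config, fit_models = list(config$model),
                                opts = dec_fit_options(),
                                condition = c("survival", "none")) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "dec_sim_config"))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, 10 * config$replicates)
  rows <- list()
  used <- 0
  for (r in seq_len(config$replicates)) {
    repeat {
      used <- used + 1
      if (used > length(sub_seeds)) stop("too many redraws", call. = FALSE)
      s <- sub_seeds[used]
      tree <- if (is.null(config$tree)) {
        simulate_tree(config$n_tips, config$birth_rate, seed = s,
                      depth = config$depth)
      } else config$tree
      sim <- simulate_dec_history(tree, config$model, config$params,
                                  config$root_range, seed = s + 1L)
      alive <- setdiff(tree$tip.label, sim$extinct_tips)
      if (length(alive) >= 4) break
      message("replicate ", r, ": fewer than 4 surviving tips; redrawing")
    }
    ftree <- if (length(alive) == ape::Ntip(tree)) tree else
      ape::drop.tip(tree, sim$extinct_tips)
    tips <- sim$tip_ranges[ftree$tip.label]
    fits <- lapply(fit_models, function(m)
      fit_dec(ftree, tips, m, opts, condition = condition,
              tree_id = paste0("rep", r)))
    aics <- vapply(fits, `[[`, 1, "AIC")
    best <- which(aics <= min(aics) + 1e-8)
    for (k in seq_along(fits)) {
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, model = fits[[k]]$model, n_tips = length(alive),
        d_true = config$params$d, e_true = config$params$e,
        d_hat = fits[[k]]$d, e_hat = fits[[k]]$e,
        logL = fits[[k]]$logL, AIC = fits[[k]]$AIC,
        aic_best = (k %in% best) / length(best))
    }
  }
  tab <- do.call(rbind, rows)
  gen <- tab[tab$model == config$model$name, , drop = FALSE]
  if (nrow(gen) == 0) gen <- tab[tab$aic_best > 0, , drop = FALSE]
  summ <- list(
    d_bias = mean(gen$d_hat - gen$d_true),
    e_bias = mean(gen$e_hat - gen$e_true),
    d_rmse = sqrt(mean((gen$d_hat - gen$d_true)^2)),
    e_rmse = sqrt(mean((gen$e_hat - gen$e_true)^2)),
    d_median_rel_error = stats::median(abs(gen$d_hat - gen$d_true) / gen$d_true),
    e_median_rel_error = stats::median(abs(gen$e_hat - gen$e_true) / gen$e_true),
    selection_frequency = tapply(tab$aic_best, tab$model, sum) / config$replicates)
  structure(list(replicates = tab, summary = summ, config = config),
            class = "dec_recovery")
}
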