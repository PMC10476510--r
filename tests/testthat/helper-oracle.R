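# Independent brute-force oracle for the DEC likelihood: explicit summation
# over all internal-node range assignments and cladogenetic events, with
# per-edge transition matrices from ape::matexpo (a different exponential
# route than the engine) and its own enumeration of DEC cladogenetic events
# (hand-coded for max range size 2). Exponential-time; use on tiny trees only.

oracle_edge_P <- function(tree, model, params) {
  space <- model$space
  S <- space$n_states
  dep <- ape::node.depth.edgelength(tree)
  ages <- max(dep[seq_len(ape::Ntip(tree))]) - dep
  ep <- model$epochs
  Pedge <- vector("list", ape::Ntip(tree) + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    a_lo <- ages[tree$edge[i, 2]]; a_hi <- ages[tree$edge[i, 1]]
    P <- diag(S)
    for (k in seq_len(ep$n_epochs)) {  # oldest epoch first
      lo <- max(a_lo, ep$end_ages[k]); hi <- min(a_hi, ep$start_ages[k])
      if (hi > lo) {
        Q <- build_q(space, params, model$multipliers, ep$available[k, ])
        P <- P %*% ape::matexpo(Q * (hi - lo))
      }
    }
    Pedge[[tree$edge[i, 2]]] <- P
  }
  Pedge
}

# hand-coded DEC cladogenetic events for ranges of size 1 or 2;
# returns data.frame(l, r, p) of state indices
oracle_events <- function(space, st_idx) {
  s <- space$states[[st_idx]]
  find <- function(x) {
    for (j in seq_len(space$n_states))
      if (identical(space$states[[j]], as.integer(sort(x)))) return(j)
    stop("state not found")
  }
  if (length(s) == 1) return(data.frame(l = st_idx, r = st_idx, p = 1))
  if (length(s) == 2) {
    a <- find(s[1]); b <- find(s[2]); ab <- st_idx
    return(data.frame(l = c(a, b, a, ab, b, ab),
                      r = c(b, a, ab, a, ab, b), p = rep(1 / 6, 6)))
  }
  stop("oracle only supports max range size 2")
}

# likelihood of the data in subtree(node) given the lineage is in
# `start_state` at the top of node's branch; `fixed` optionally pins one
# internal node to one state (for posterior computation)
oracle_subtree <- function(node, start_state, tree, space, Pedge, tipstate,
                           children, fixed = NULL) {
  P <- Pedge[[node]]
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(P[start_state, tipstate[node]])
  ch <- children[[as.character(node)]]
  states <- seq_len(space$n_states)[vapply(space$states, length, 1L) > 0]
  if (!is.null(fixed) && fixed[1] == node) states <- fixed[2]
  tot <- 0
  for (st in states) {
    evs <- oracle_events(space, st)
    for (q in seq_len(nrow(evs))) {
      tot <- tot + P[start_state, st] * evs$p[q] *
        oracle_subtree(ch[1], evs$l[q], tree, space, Pedge, tipstate,
                       children, fixed) *
        oracle_subtree(ch[2], evs$r[q], tree, space, Pedge, tipstate,
                       children, fixed)
    }
  }
  tot
}

oracle_root_sum <- function(tree, tips, model, params, fixed = NULL) {
  space <- model$space
  Pedge <- oracle_edge_P(tree, model, params)
  ntip <- ape::Ntip(tree)
  tipstate <- vapply(tree$tip.label, function(lb) {
    st <- tips[[lb]]
    if (is.character(st)) st <- match(st, model$areas$code)
    range_index(space, st)
  }, 1L)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  root <- ntip + 1L
  states <- seq_len(space$n_states)[vapply(space$states, length, 1L) > 0]
  rstates <- if (!is.null(fixed) && fixed[1] == root) fixed[2] else states
  tot <- 0
  for (st in rstates) {
    evs <- oracle_events(space, st)
    ch <- children[[as.character(root)]]
    for (q in seq_len(nrow(evs))) {
      tot <- tot + evs$p[q] *
        oracle_subtree(ch[1], evs$l[q], tree, space, Pedge, tipstate,
                       children, fixed) *
        oracle_subtree(ch[2], evs$r[q], tree, space, Pedge, tipstate,
                       children, fixed)
    }
  }
  tot
}

oracle_loglik <- function(tree, tips, model, params) {
  log(oracle_root_sum(tree, tips, model, params))
}

# brute-force marginal posterior of internal-node ranges
oracle_posteriors <- function(tree, tips, model, params) {
  total <- oracle_root_sum(tree, tips, model, params)
  ntip <- ape::Ntip(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  S <- model$space$n_states
  out <- matrix(0, length(internal), S,
                dimnames = list(internal, model$space$labels))
  for (v in internal) {
    for (st in seq_len(S)) {
      if (length(model$space$states[[st]]) == 0) next
      out[as.character(v), st] <-
        oracle_root_sum(tree, tips, model, params, fixed = c(v, st)) / total
    }
  }
  out
}

# random valid test instances under a fixed seed
random_toy_tree <- function(n_tips, seed) {
  set.seed(seed)
  tree <- ape::rcoal(n_tips)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree)) * 10
  tree
}

random_tips <- function(tree, space, seed, single_area_only = FALSE) {
  set.seed(seed)
  nonnull <- which(vapply(space$states, length, 1L) > 0)
  if (single_area_only)
    nonnull <- which(vapply(space$states, length, 1L) == 1)
  st <- sample(nonnull, ape::Ntip(tree), replace = TRUE)
  stats::setNames(lapply(st, function(i) space$states[[i]]), tree$tip.label)
}
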