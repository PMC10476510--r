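# Marginal ancestral-range reconstruction by the standard two-pass algorithm:
# an upward (pruning) pass collects tipward conditional likelihoods, a
# downward pass propagates rootward partials through the cladogenetic event
# distribution and the branch transition matrices; their product, normalized
# per node, is the marginal posterior over ranges.

#' Reconstruct ancestral range probabilities
#'
#' Computes, for every internal node, the marginal posterior probability of
#' each range given the tip data and the (typically fitted) rates, then
#' apportions multi-area probabilities equally among their member areas and
#' assigns each node a majority-rule area (the argmax of the apportioned
#' vector; ties broken by area order with a warning).
#'
#' @inheritParams compute_log_likelihood
#' @param params Rates at which to reconstruct; normally ML estimates from
#'   \code{\link{fit_dec}} (reconstruction at arbitrary rates is permitted,
#'   e.g. for testing).
#' @param mode \code{"marginal"} (default) gives per-node marginal
#'   posteriors; \code{"joint"} reports the single best joint history
#'   (max-product) instead, as a sensitivity check.
#' @return An object of class \code{"dec_ancestral"}: list with
#'   \code{node_probs} (internal nodes x ranges), \code{area_probs}
#'   (internal nodes x areas, equal apportionment), \code{mr_area}
#'   (majority-rule area code per node), \code{ages} (node ages, Ma),
#'   \code{nodes} (ape node ids), plus the model and tree.
#' @export
reconstruct_ancestral_ranges <- function(tree, tips, model, params,
                                         root = c("flat", "uniform"),
                                         mode = c("marginal", "joint")) {
  root <- match.arg(root); mode <- match.arg(mode)
  engine <- .dec_engine(tree, tips, model)
  S <- engine$space$n_states
  ntip <- engine$ntip
  Nall <- ntip + engine$nnode
  pass <- .pruning_pass(engine, params, keep = TRUE)
  if (is.null(pass$nodeL))
    stop("tip data have zero likelihood under this model and rates",
         call. = FALSE)

  w <- as.numeric(vapply(engine$space$states, length, 1L) > 0)
  if (root == "uniform") w <- w / sum(w)

  if (mode == "joint") {
    post <- .joint_reconstruction(engine, params, w)
  } else {
    post <- .marginal_posteriors(engine, pass, w)
  }

  internal <- (ntip + 1L):Nall
  node_probs <- post[internal, , drop = FALSE]
  rownames(node_probs) <- internal
  colnames(node_probs) <- engine$space$labels
  area_probs <- t(apply(node_probs, 1, apportion_to_areas,
                        space = engine$space))
  colnames(area_probs) <- engine$space$areas$code
  mr <- apply(area_probs, 1, function(p) {
    top <- which(p >= max(p) - 1e-12)
    if (length(top) > 1)
      warning("majority-rule tie; broken by area order", call. = FALSE)
    top[1]
  })
  structure(list(node_probs = node_probs, area_probs = area_probs,
                 mr_area = engine$space$areas$code[mr],
                 ages = engine$ages[internal], nodes = internal,
                 model = model, tree = tree, mode = mode),
            class = "dec_ancestral")
}

# marginal posteriors for all nodes (tips get their observed indicator)
.marginal_posteriors <- function(engine, pass, root_weights) {
  S <- engine$space$n_states
  ntip <- engine$ntip
  Nall <- ntip + engine$nnode
  edge <- engine$edge
  cl <- engine$clado
  root <- ntip + 1L

  D <- matrix(0, Nall, S)      # rootward partials, normalized per node
  D[root, ] <- root_weights
  post <- matrix(0, Nall, S)
  post[root, ] <- D[root, ] * pass$nodeL[root, ]
  post[root, ] <- post[root, ] / sum(post[root, ])

  # preorder = reverse postorder over edges
  for (i in rev(seq_len(nrow(edge)))) {
    par <- edge[i, 1]; ch <- edge[i, 2]
    sib <- setdiff(pass$child_of[[par]], ch)
    Bs <- pass$bottoms[[sib]]
    # distribute the parent's partial through the cladogenetic events whose
    # "left" daughter starts this branch (event sets are left/right symmetric)
    val <- cl$prob * D[par, cl$anc] * Bs[cl$right]
    Dstart <- as.vector(cl$Lsp %*% val)
    # then backward through the branch: oldest segment first on the way down
    for (sg in rev(engine$segs[[i]])) {
      Dstart <- .propagate(pass$props[[sg[1]]], Dstart, sg[2], transpose = TRUE)
    }
    s <- sum(Dstart)
    if (s > 0) Dstart <- Dstart / s
    D[ch, ] <- Dstart
    if (ch <= ntip) {
      post[ch, engine$tip_state[ch]] <- 1
    } else {
      p <- D[ch, ] * pass$nodeL[ch, ]
      tot <- sum(p)
      if (tot <= 0) stop("zero marginal at node ", ch, call. = FALSE)
      post[ch, ] <- p / tot
    }
  }
  post
}

# max-product joint reconstruction (Viterbi-style over ranges and events)
.joint_reconstruction <- function(engine, params, root_weights) {
  S <- engine$space$n_states
  ntip <- engine$ntip
  Nall <- ntip + engine$nnode
  edge <- engine$edge
  cl <- engine$clado
  props <- .propagators(engine$model, params)
  Pedge <- vector("list", nrow(edge))  # full P matrix per edge (chained)
  for (i in seq_len(nrow(edge))) {
    P <- diag(S)
    for (sg in engine$segs[[i]]) {
      Pk <- transition_probabilities(props[[sg[1]]]$Q, sg[2])
      P <- Pk %*% P   # older segment applied on the left
    }
    Pedge[[i]] <- P
  }
  # upward max-product with back-pointers
  Lmax <- matrix(0, Nall, S); Bmax <- vector("list", nrow(edge))
  child_of <- vector("list", Nall); edge_of <- integer(Nall)
  best_node <- function(id) {
    if (id <= ntip) { v <- numeric(S); v[engine$tip_state[id]] <- 1; return(list(v = v, bp = NULL)) }
    ch <- child_of[[id]]
    bl <- Lmax[ch[1], ]; br <- Lmax[ch[2], ]
    sc <- cl$prob * bl[cl$left] * br[cl$right]
    v <- numeric(S); bp <- integer(S)
    for (st in unique(cl$anc)) {
      ix <- which(cl$anc == st)
      k <- ix[which.max(sc[ix])]
      v[st] <- sc[k]; bp[st] <- k
    }
    list(v = v, bp = bp)
  }
  scale_log <- 0
  bp_node <- vector("list", Nall)
  up_best <- matrix(0, Nall, S)  # best start-state at branch bottom per node state
  for (i in seq_len(nrow(edge))) {
    par <- edge[i, 1]; ch <- edge[i, 2]
    bn <- best_node(ch); bp_node[[ch]] <- bn$bp
    v <- bn$v / max(bn$v)
    P <- Pedge[[i]]
    M <- P * rep(v, each = S)   # M[y, x] = P[y,x] * v[x]
    Lmax[ch, ] <- apply(M, 1, max)
    up_best[ch, ] <- apply(M, 1, which.max)
    child_of[[par]] <- c(child_of[[par]], ch); edge_of[ch] <- i
    # store branch-bottom max in Lmax[ch,]; back-pointer: for bottom state y,
    # the maximizing node state x
  }
  root <- ntip + 1L
  bn <- best_node(root); bp_node[[root]] <- bn$bp
  rootscore <- root_weights * bn$v
  post <- matrix(0, Nall, S)
  assign_state <- integer(Nall)
  assign_state[root] <- which.max(rootscore)
  # walk down: at node with state st, its clado back-pointer names the event;
  # each daughter's bottom state then selects the daughter's node state
  order_nodes <- c(root, rev(edge[, 2]))
  for (nd in order_nodes) {
    st <- assign_state[nd]
    post[nd, st] <- 1
    if (nd <= ntip) next
    ev <- bp_node[[nd]][st]
    ch <- child_of[[nd]]
    bottoms <- c(cl$left[ev], cl$right[ev])
    for (k in 1:2) {
      cid <- ch[k]
      assign_state[cid] <- up_best[cid, bottoms[k]]
    }
  }
  post
}

#' Apportion range probabilities equally to single areas
#'
#' Each k-area range contributes 1/k of its probability to each member area;
#' e.g. 10\% probability on the two-area range \{EPCT, Fold Belt\} adds 5\%
#' to each. Any mass on the null range is renormalized away with a warning.
#'
#' @param range_probs Probability vector over the ranges of \code{space}
#'   (must sum to 1).
#' @param space The owning \code{dec_range_space}.
#' @return Numeric vector of per-area probabilities summing to 1.
#' @examples
#' sp <- enumerate_ranges(3, 2)
#' p <- c(0, 0.9, 0, 0, 0.1, 0, 0)  # 0.9 on {1}, 0.1 on {1,2}
#' apportion_to_areas(p, sp)        # 0.95, 0.05, 0
#' @export
apportion_to_areas <- function(range_probs, space) {
  stopifnot(inherits(space, "dec_range_space"),
            length(range_probs) == space$n_states)
  sizes <- vapply(space$states, length, 1L)
  if (any(range_probs[sizes == 0] > 1e-12)) {
    warning("probability mass on the null range; renormalizing", call. = FALSE)
    range_probs[sizes == 0] <- 0
    range_probs <- range_probs / sum(range_probs)
  }
  out <- numeric(nrow(space$areas))
  for (i in which(range_probs > 0)) {
    st <- space$states[[i]]
    out[st] <- out[st] + range_probs[i] / length(st)
  }
  names(out) <- space$areas$code
  out
}
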