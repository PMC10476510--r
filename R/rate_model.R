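#' Dispersal and extinction rates of a DEC process
#'
#' @param d Dispersal rate, in expected dispersal events per source-area /
#'   destination-area pair per million years; must be >= 0.
#' @param e Local extinction rate per occupied area per million years;
#'   must be >= 0.
#' @return A list of class \code{"dec_params"}.
#' @examples
#' dec_params(0.0094, 0.021)
#' @export
dec_params <- function(d, e) {
  d <- as.numeric(d); e <- as.numeric(e)
  if (length(d) != 1 || length(e) != 1 || !is.finite(d) || !is.finite(e) ||
      d < 0 || e < 0)
    stop("d and e must be single finite non-negative numbers", call. = FALSE)
  structure(list(d = d, e = e), class = "dec_params")
}

#' Dispersal multiplier matrix
#'
#' Pairwise relative dispersal feasibilities: entry \code{m[b, a]} scales the
#' base dispersal rate for range expansion from source area \code{b} into
#' destination area \code{a}. Geological hypotheses are encoded here: connected
#' area pairs carry 1, disallowed pairs carry a small positive floor
#' (conventionally 0.001) rather than an exact zero so that fitted models
#' remain identifiable. The diagonal is ignored by the rate machinery.
#'
#' @param m Square non-negative numeric matrix.
#' @param areas Optional \code{\link{dec_areas}}; dimnames are set to its codes.
#' @return The validated matrix with class \code{"dec_multipliers"}.
#' @export
dispersal_multipliers <- function(m, areas = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("multiplier matrix must be square", call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0))
    stop("multiplier entries must be finite and >= 0", call. = FALSE)
  if (!is.null(areas)) {
    stopifnot(inherits(areas, "dec_areas"))
    if (nrow(m) != nrow(areas))
      stop("multiplier dimensions do not match the area set", call. = FALSE)
    dimnames(m) <- list(areas$code, areas$code)
  }
  class(m) <- c("dec_multipliers", class(m))
  m
}

#' Epoch stratification of area availability
#'
#' Splits the timespan of a tree into contiguous epochs, each with a mask of
#' areas available for occupancy. Ages are in Ma before present, listed from
#' oldest to youngest; the youngest epoch must end at 0 Ma and must have every
#' area available. A single dispersal-multiplier matrix is shared across all
#' epochs; availability is the only thing that changes through time.
#'
#' @param start_ages Numeric vector of epoch start ages (older bound, Ma).
#'   The first may be \code{Inf} to cover arbitrarily deep roots.
#' @param end_ages Numeric vector of epoch end ages (younger bound, Ma).
#' @param available Logical matrix, one row per epoch, one column per area:
#'   is the area available during the epoch?
#' @param area_codes Optional area codes for the columns of \code{available}.
#' @return An object of class \code{"dec_epochs"}.
#' @examples
#' epoch_stratification(c(Inf, 15), c(15, 0),
#'                      rbind(c(TRUE, FALSE), c(TRUE, TRUE)))
#' @export
epoch_stratification <- function(start_ages, end_ages, available,
                                 area_codes = NULL) {
  start_ages <- as.numeric(start_ages); end_ages <- as.numeric(end_ages)
  available <- as.matrix(available)
  n <- length(start_ages)
  if (length(end_ages) != n || nrow(available) != n)
    stop("start_ages, end_ages and available must describe the same epochs",
         call. = FALSE)
  if (any(start_ages <= end_ages))
    stop("each epoch must have start_age > end_age (ages in Ma)", call. = FALSE)
  if (n > 1 && any(abs(end_ages[-n] - start_ages[-1]) > 1e-9))
    stop("epochs must be contiguous, oldest first", call. = FALSE)
  if (end_ages[n] != 0)
    stop("the youngest epoch must end at 0 Ma", call. = FALSE)
  if (!all(available[n, ]))
    stop("every area must be available in the youngest epoch", call. = FALSE)
  if (any(rowSums(available) == 0))
    stop("each epoch must have at least one available area", call. = FALSE)
  if (!is.null(area_codes)) colnames(available) <- area_codes
  structure(list(start_ages = start_ages, end_ages = end_ages,
                 available = available, n_epochs = n),
            class = "dec_epochs")
}

#' A DEC model: range space, constraints and stratification
#'
#' Bundles everything that defines the Q-matrix family of a hypothesis:
#' the area set and range space, a dispersal-multiplier matrix, and an
#' optional epoch stratification of area availability.
#'
#' @param areas A \code{\link{dec_areas}} object (or an integer area count).
#' @param multipliers Optional \code{\link{dispersal_multipliers}} matrix;
#'   default all ones (unconstrained dispersal).
#' @param epochs Optional \code{\link{epoch_stratification}}; default a single
#'   epoch with all areas always available.
#' @param max_size Maximum range size (default 2).
#' @param name Model name used in comparison tables.
#' @return An object of class \code{"dec_model"}.
#' @export
dec_model <- function(areas, multipliers = NULL, epochs = NULL,
                      max_size = 2, name = "DEC") {
  if (!inherits(areas, "dec_areas")) areas <- dec_areas(as.character(seq_len(areas)))
  space <- enumerate_ranges(areas, max_size = max_size)
  n <- nrow(areas)
  if (is.null(multipliers)) {
    multipliers <- dispersal_multipliers(matrix(1, n, n), areas)
  } else {
    multipliers <- dispersal_multipliers(unclass(multipliers), areas)
  }
  if (is.null(epochs)) {
    epochs <- epoch_stratification(Inf, 0, matrix(TRUE, 1, n), areas$code)
  }
  if (ncol(epochs$available) != n)
    stop("epoch availability mask does not match the area count", call. = FALSE)
  structure(list(name = name, areas = areas, space = space,
                 multipliers = multipliers, epochs = epochs,
                 max_size = space$max_size),
            class = "dec_model")
}

#' @export
print.dec_model <- function(x, ...) {
  cat("DEC model '", x$name, "': ", nrow(x$areas), " areas, max range size ",
      x$max_size, ", ", x$epochs$n_epochs, " epoch(s)\n", sep = "")
  invisible(x)
}

#' Build the anagenetic DEC rate matrix Q
#'
#' Constructs the instantaneous rate matrix over the range space. Off-diagonal
#' rates are nonzero only for single-area gains (range expansion by dispersal)
#' and single-area losses (local extinction): the rate from range R to
#' R + \{a\} is \code{d * sum(m[b, a])} over occupied source areas b in R,
#' provided a is available; the rate from R to R - \{a\} is \code{e}, and a
#' single-area range contracts to the null range at rate \code{e}. The null
#' range is absorbing. Rows sum to zero.
#'
#' @param space A \code{\link{enumerate_ranges}} range space.
#' @param params A \code{\link{dec_params}} pair.
#' @param mult Dispersal multiplier matrix (default all ones).
#' @param available Logical vector of per-area availability (default all TRUE).
#' @return Square numeric matrix with range labels as dimnames; units events/My.
#' @examples
#' sp <- enumerate_ranges(3, 2)
#' Q <- build_q(sp, dec_params(0.01, 0.02))
#' all(abs(rowSums(Q)) < 1e-12)
#' @export
build_q <- function(space, params, mult = NULL, available = NULL) {
  stopifnot(inherits(space, "dec_range_space"))
  if (!inherits(params, "dec_params")) params <- do.call(dec_params, as.list(params))
  n <- nrow(space$areas)
  if (is.null(mult)) mult <- matrix(1, n, n)
  mult <- as.matrix(mult)
  if (nrow(mult) != n || ncol(mult) != n)
    stop("multiplier matrix dimensions do not match the area set", call. = FALSE)
  if (any(mult < 0)) stop("negative dispersal multipliers", call. = FALSE)
  if (is.null(available)) available <- rep(TRUE, n)
  if (length(available) != n)
    stop("availability mask length does not match the area count", call. = FALSE)

  S <- space$n_states
  Q <- matrix(0, S, S, dimnames = list(space$labels, space$labels))
  idx <- .state_index_map(space)
  for (i in seq_len(S)) {
    R <- space$states[[i]]
    k <- length(R)
    if (k == 0L) next  # null range is absorbing
    # expansions
    if (k < space$max_size) {
      for (a in setdiff(seq_len(n), R)) {
        if (!available[a]) next
        rate <- params$d * sum(mult[R, a])
        if (rate > 0) {
          j <- idx[[.state_key(sort(c(R, a)))]]
          Q[i, j] <- rate
        }
      }
    }
    # contractions (including loss of the last area into the null range)
    for (a in R) {
      j <- idx[[.state_key(setdiff(R, a))]]
      Q[i, j] <- Q[i, j] + params$e
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Finite-time transition probabilities P(t) = exp(Qt)
#'
#' Matrix exponential of the rate matrix over an elapsed time, computed by
#' dense scaling-and-squaring. Rows sum to one; P(0) is the identity.
#'
#' @param Q Rate matrix from \code{\link{build_q}}.
#' @param t Elapsed time in My; must be >= 0.
#' @return Stochastic matrix of the same dimension as \code{Q}.
#' @export
transition_probabilities <- function(Q, t) {
  if (length(t) != 1 || !is.finite(t) || t < 0)
    stop("t must be a single finite non-negative duration", call. = FALSE)
  if (t == 0) {
    P <- diag(nrow(Q))
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

#' Per-epoch rate matrices of a (possibly stratified) DEC model
#'
#' One Q per epoch, built with that epoch's availability mask and the single
#' shared multiplier matrix. Expansion into an unavailable area has rate
#' exactly zero (availability is a hard constraint, distinct from the
#' multiplier floor); ranges containing unavailable areas remain in the state
#' space but can only contract.
#'
#' @param model A \code{\link{dec_model}}.
#' @param params A \code{\link{dec_params}} pair.
#' @return Named list of rate matrices, one per epoch, oldest first.
#' @export
epoch_matrices <- function(model, params) {
  stopifnot(inherits(model, "dec_model"))
  ep <- model$epochs
  out <- vector("list", ep$n_epochs)
  for (k in seq_len(ep$n_epochs)) {
    out[[k]] <- build_q(model$space, params, model$multipliers,
                        available = ep$available[k, ])
  }
  names(out) <- paste0(ep$start_ages, "-", ep$end_ages, "Ma")
  out
}
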