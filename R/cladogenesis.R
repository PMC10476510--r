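#' Enumerate DEC cladogenetic range-inheritance events
#'
#' At a speciation node the ancestral range is partitioned between the two
#' daughters under the classic DEC event classes, all equiprobable:
#' \itemize{
#'   \item a single-area ancestor is copied to both daughters (sympatry);
#'   \item a wider ancestor either splits into two disjoint non-empty parts
#'     (vicariance) or one daughter inherits a single member area and the
#'     other the full range (subset sympatry).
#' }
#' Daughter pairs are ordered, so for a two-area ancestor \{a,b\} there are six
#' events -- (a|b), (b|a), (a|ab), (ab|a), (b|ab), (ab|b) -- each with
#' probability 1/6. No founder-event ("jump") transitions are modelled.
#'
#' @param ancestor Integer vector of area indices of the ancestral range;
#'   must be non-empty.
#' @param max_size Maximum range size of the owning space (daughters never
#'   exceed it; with the vicariance/subset-sympatry classes they cannot
#'   anyway, since one daughter is always a single area when the ancestor is
#'   wider than one).
#' @return A data frame of class \code{"dec_clado_events"} with list-columns
#'   \code{left} and \code{right} (integer area vectors) and numeric
#'   \code{prob}; probabilities sum to one.
#' @examples
#' enumerate_daughter_events(c(1, 2))
#' @export
enumerate_daughter_events <- function(ancestor, max_size = max(2L, length(ancestor))) {
  ancestor <- sort(unique(as.integer(ancestor)))
  if (length(ancestor) == 0L)
    stop("cladogenesis is undefined for the null range", call. = FALSE)
  if (length(ancestor) == 1L) {
    ev <- data.frame(prob = 1)
    ev$left <- list(ancestor); ev$right <- list(ancestor)
  } else {
    left <- list(); right <- list()
    # subset sympatry: one daughter a single member area, the other the full range
    for (a in ancestor) {
      left <- c(left, list(a), list(ancestor))
      right <- c(right, list(ancestor), list(a))
    }
    # vicariance: disjoint non-empty parts covering the ancestor, smaller part
    # a single area (for max_size 2 this is the complete set of splits; for
    # wider ranges it follows the standard DEC convention)
    for (a in ancestor) {
      rest <- setdiff(ancestor, a)
      if (length(rest) > max_size) next
      left <- c(left, list(a), list(rest))
      right <- c(right, list(rest), list(a))
    }
    # deduplicate ordered pairs (a two-area ancestor yields each vicariant
    # split from both of its member areas)
    key <- paste(vapply(left, paste, "", collapse = ","),
                 vapply(right, paste, "", collapse = ","), sep = "|")
    keep <- !duplicated(key)
    left <- left[keep]; right <- right[keep]
    ev <- data.frame(prob = rep(1 / length(left), length(left)))
    ev$left <- left; ev$right <- right
  }
  ev <- ev[, c("left", "right", "prob")]
  attr(ev, "ancestor") <- ancestor
  class(ev) <- c("dec_clado_events", "data.frame")
  ev
}

#' Cladogenetic event table for every range in a space
#'
#' @param space A \code{dec_range_space}.
#' @return List indexed by state number; entry for the null range is NULL.
#' @keywords internal
clado_event_table <- function(space) {
  idx <- .state_index_map(space)
  lapply(space$states, function(s) {
    if (length(s) == 0L) return(NULL)
    ev <- enumerate_daughter_events(s, max_size = space$max_size)
    data.frame(
      left = vapply(ev$left, function(x) idx[[.state_key(x)]], 1L),
      right = vapply(ev$right, function(x) idx[[.state_key(x)]], 1L),
      prob = ev$prob)
  })
}

#' Plain-text dump of cladogenetic events per ancestor
#'
#' @param space A \code{dec_range_space}.
#' @return Character vector, one line per event:
#'   "ancestor -> left | right : prob".
#' @export
format_clado_events <- function(space) {
  tab <- clado_event_table(space)
  out <- character(0)
  for (i in seq_along(tab)) {
    ev <- tab[[i]]
    if (is.null(ev)) next
    out <- c(out, sprintf("%s -> %s | %s : %.6g", space$labels[i],
                          space$labels[ev$left], space$labels[ev$right],
                          ev$prob))
  }
  out
}
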