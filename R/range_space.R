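#' Define a set of geographic areas
#'
#' An area set is the fixed geography of a DEC analysis: each area has a short
#' code, a human-readable name, and a category used when classifying dispersal
#' events (e.g. mainland-terrane vs island).
#'
#' @param codes Character vector of unique short area codes.
#' @param names Character vector of area names (defaults to the codes).
#' @param categories Character vector; each element one of
#'   \code{"mainland-terrane"}, \code{"island"} or \code{"outgroup-region"}.
#' @return A data frame of class \code{"dec_areas"} with columns
#'   \code{code}, \code{name}, \code{category}.
#' @examples
#' dec_areas(c("A", "B"), categories = c("mainland-terrane", "island"))
#' @export
dec_areas <- function(codes, names = codes,
                      categories = rep("mainland-terrane", length(codes))) {
  codes <- as.character(codes)
  if (anyDuplicated(codes))
    stop("area codes must be unique", call. = FALSE)
  if (length(names) != length(codes) || length(categories) != length(codes))
    stop("codes, names and categories must have equal length", call. = FALSE)
  ok <- c("mainland-terrane", "island", "outgroup-region")
  if (!all(categories %in% ok))
    stop("unknown area category; must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  out <- data.frame(code = codes, name = as.character(names),
                    category = as.character(categories),
                    stringsAsFactors = FALSE)
  class(out) <- c("dec_areas", "data.frame")
  out
}

#' Enumerate the DEC state space of geographic ranges
#'
#' Builds the discrete state space of a DEC model: all subsets of the area set
#' of size at most \code{max_size}, plus (by default) the null range, which
#' represents global extinction of a lineage. States are ordered canonically:
#' the null range first, then ranges grouped by increasing size, and within a
#' size lexicographically by area index. For three areas and a maximum range
#' size of two this yields the seven ranges
#' \{null, 1, 2, 3, 12, 13, 23\}.
#'
#' @param n_areas Number of areas, or a \code{\link{dec_areas}} object.
#' @param max_size Maximum number of areas a single range may occupy
#'   (default 2, the usual DEC restriction for single-area endemic clades).
#' @param include_null Include the null (empty) range as state 1? Default TRUE;
#'   the likelihood machinery requires it.
#' @return An object of class \code{"dec_range_space"}: a list with elements
#'   \code{areas} (a \code{dec_areas} data frame), \code{max_size},
#'   \code{states} (list of integer vectors of area indices; the null range is
#'   \code{integer(0)}), \code{labels}, and \code{n_states}.
#' @examples
#' sp <- enumerate_ranges(3, 2)
#' sp$n_states  # 7
#' @export
enumerate_ranges <- function(n_areas, max_size = 2, include_null = TRUE) {
  if (inherits(n_areas, "dec_areas")) {
    areas <- n_areas
  } else {
    n <- as.integer(n_areas)
    if (is.na(n) || n < 1) stop("n_areas must be >= 1", call. = FALSE)
    areas <- dec_areas(as.character(seq_len(n)))
  }
  n <- nrow(areas)
  max_size <- as.integer(max_size)
  if (max_size < 1 || max_size > n)
    stop("max_size must be between 1 and the number of areas", call. = FALSE)

  states <- list()
  if (include_null) states[[1L]] <- integer(0)
  for (k in seq_len(max_size)) {
    subs <- utils::combn(n, k, simplify = FALSE)
    # combn already emits subsets in lexicographic order by area index
    states <- c(states, lapply(subs, as.integer))
  }
  labels <- vapply(states, function(s) {
    if (length(s) == 0L) "0" else paste(areas$code[s], collapse = "+")
  }, character(1))
  structure(list(areas = areas, max_size = max_size, states = states,
                 labels = labels, n_states = length(states),
                 has_null = include_null),
            class = "dec_range_space")
}

#' @export
print.dec_range_space <- function(x, ...) {
  cat("DEC range space: ", nrow(x$areas), " areas, max range size ",
      x$max_size, ", ", x$n_states, " states\n", sep = "")
  cat("states:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Index of a range within a range space
#'
#' Returns the position of a range in the canonical enumeration of
#' \code{\link{enumerate_ranges}}. The null range has index 1 (R is
#' 1-based; state vectors returned by the space round-trip through this
#' function).
#'
#' @param space A \code{dec_range_space}.
#' @param state Integer vector of area indices, or a character vector of area
#'   codes; \code{integer(0)} / \code{character(0)} denotes the null range.
#' @return Integer index into \code{space$states}.
#' @examples
#' sp <- enumerate_ranges(3, 2)
#' range_index(sp, integer(0))  # 1 (null range)
#' range_index(sp, c(2, 3))     # 7 (last two-area state)
#' @export
range_index <- function(space, state) {
  stopifnot(inherits(space, "dec_range_space"))
  if (is.character(state)) {
    idx <- match(state, space$areas$code)
    if (anyNA(idx))
      stop("unknown area code: ",
           paste(state[is.na(idx)], collapse = ", "), call. = FALSE)
    state <- idx
  }
  state <- sort(unique(as.integer(state)))
  if (length(state) > space$max_size)
    stop("range exceeds max_size of the space", call. = FALSE)
  if (length(state) && (min(state) < 1 || max(state) > nrow(space$areas)))
    stop("area index outside the area set", call. = FALSE)
  keys <- vapply(space$states, .state_key, character(1))
  i <- match(.state_key(state), keys)
  if (is.na(i)) stop("state not present in the range space", call. = FALSE)
  i
}

# canonical key of a state vector ("0" for the null range)
.state_key <- function(s) if (length(s) == 0L) "0" else paste(s, collapse = ",")

# fast internal lookup table: state key -> index
.state_index_map <- function(space) {
  keys <- vapply(space$states, .state_key, character(1))
  stats::setNames(seq_along(keys), keys)
}

#' Serialize a range space as a plain-text table
#'
#' @param space A \code{dec_range_space}.
#' @return A character vector, one line per state: "index<TAB>label".
#' @export
format_range_space <- function(space) {
  stopifnot(inherits(space, "dec_range_space"))
  paste0(seq_len(space$n_states), "\t", space$labels)
}
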