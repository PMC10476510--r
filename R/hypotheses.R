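# Library of geological hypothesis models for the Papuan region.
#
# Each hypothesis is a declarative description (pairwise land connections,
# multi-way connection blocks, optional distance-class weights, optional
# epoch stratification) compiled into a DEC model. Connected pairs carry
# multiplier 1, everything else the small positive floor (0.001 by default);
# hard zeros are reserved for area unavailability in stratified models.

#' The thirteen Papuan georegions
#'
#' The area set of the Papuan Asterophryinae analysis: five mainland tectonic
#' terranes, seven offshore islands, and Southeast Asia as an outgroup region.
#' Letter codes are unambiguous (some published tables reuse letters):
#' V Vogelkop Peninsula, C Australian Craton, F Fold Belt, A Accreted
#' Terranes, E East Papua Composite Terrane (EPCT), Y Normanby, G Fergusson,
#' B New Britain, W Woodlark, M Misima, S Sudest, R Rossel, N Southeast Asia.
#'
#' @return A \code{\link{dec_areas}} data frame of 13 areas.
#' @export
papuan_areas <- function() {
  dec_areas(
    codes = c("V", "C", "F", "A", "E", "Y", "G", "B", "W", "M", "S", "R", "N"),
    names = c("Vogelkop Peninsula", "Australian Craton", "Fold Belt",
              "Accreted Terranes", "East Papua Composite Terrane",
              "Normanby Island", "Fergusson Island", "New Britain Island",
              "Woodlark Island", "Misima Island", "Sudest Island",
              "Rossel Island", "Southeast Asia"),
    categories = c(rep("mainland-terrane", 5), rep("island", 7),
                   "outgroup-region"))
}

#' Declarative description of a dispersal hypothesis
#'
#' @param name Model name.
#' @param pairwise List of length-2 character vectors: unordered area-code
#'   pairs connected by land (multiplier 1).
#' @param blocks List of character vectors: multi-way connection blocks; all
#'   pairs within a block get multiplier 1.
#' @param weights List of lists \code{list(from =, to =, value =)}: distance
#'   classes that override the multiplier for every pair between the two code
#'   sets (applied symmetrically, after connections).
#' @param epochs Optional \code{\link{epoch_stratification}}.
#' @param floor Multiplier for unconnected pairs; small and positive
#'   (default 0.001) so fitted models remain identifiable.
#' @return A list of class \code{"dec_hypothesis_spec"}.
#' @export
hypothesis_spec <- function(name, pairwise = list(), blocks = list(),
                            weights = list(), epochs = NULL, floor = 0.001) {
  if (floor <= 0 || floor >= 1)
    stop("floor must be in (0, 1)", call. = FALSE)
  structure(list(name = name, pairwise = pairwise, blocks = blocks,
                 weights = weights, epochs = epochs, floor = floor),
            class = "dec_hypothesis_spec")
}

#' Compile a hypothesis description into a DEC model
#'
#' Builds the symmetric dispersal-multiplier matrix: unit diagonal, 1 for any
#' pair connected pairwise or co-resident in a multi-way block, distance-class
#' weights where stated, and the floor value everywhere else.
#'
#' @param spec A \code{\link{hypothesis_spec}}.
#' @param areas A \code{\link{dec_areas}} set containing every referenced code.
#' @param max_size Maximum range size of the model (default 2).
#' @return A \code{\link{dec_model}}.
#' @export
build_hypothesis <- function(spec, areas, max_size = 2) {
  stopifnot(inherits(spec, "dec_hypothesis_spec"), inherits(areas, "dec_areas"))
  n <- nrow(areas)
  code_idx <- function(codes) {
    i <- match(codes, areas$code)
    if (anyNA(i))
      stop("unknown area code in hypothesis '", spec$name, "': ",
           paste(codes[is.na(i)], collapse = ", "), call. = FALSE)
    i
  }
  m <- matrix(spec$floor, n, n, dimnames = list(areas$code, areas$code))
  for (p in spec$pairwise) {
    i <- code_idx(p)
    if (length(i) != 2) stop("pairwise connections must name two areas", call. = FALSE)
    m[i[1], i[2]] <- m[i[2], i[1]] <- 1
  }
  for (b in spec$blocks) {
    i <- code_idx(b)
    m[i, i] <- 1
  }
  for (w in spec$weights) {
    i <- code_idx(w$from); j <- code_idx(w$to)
    m[i, j] <- w$value
    m[j, i] <- w$value
  }
  diag(m) <- 1
  ep <- spec$epochs
  if (!is.null(ep) && !is.null(colnames(ep$available))) {
    if (!all(colnames(ep$available) == areas$code))
      stop("epoch availability columns do not match the area set", call. = FALSE)
  }
  mod <- dec_model(areas, multipliers = m, epochs = ep, max_size = max_size,
                   name = spec$name)
  mod$spec <- spec
  mod
}

# shared building blocks of the builtin Papuan hypotheses
.papua_blocks <- function() {
  list(
    mainland_pairs = list(c("V", "C"), c("V", "F"), c("V", "A"), c("C", "F"),
                          c("F", "A"), c("F", "E"), c("A", "E")),
    dentrecasteaux = c("Y", "G"),
    louisiades = c("M", "S", "R"),
    louisiades_woodlark = c("W", "M", "S", "R"),
    islands = c("Y", "G", "B", "W", "M", "S", "R"))
}

# slow-and-steady stratification: Vogelkop docks onto the composite mainland
# in the mid-Miocene, so it is unavailable before 15 Ma. Interpretive default;
# override via hypothesis_spec(). The oldest epoch opens at Inf so roots of
# any age are covered.
.epochs_b <- function(areas, boundary = 15) {
  av <- matrix(TRUE, 2, nrow(areas))
  av[1, areas$code == "V"] <- FALSE
  epoch_stratification(c(Inf, boundary), c(boundary, 0), av, areas$code)
}

# mobile belt: the Accreted Terranes assembled offshore (25-23 Ma) and docked
# 15-11 Ma, so they only become occupiable at 11 Ma.
.epochs_c <- function(areas, boundary = 11) {
  av <- matrix(TRUE, 2, nrow(areas))
  av[1, areas$code == "A"] <- FALSE
  epoch_stratification(c(Inf, boundary), c(boundary, 0), av, areas$code)
}

# recent emergence: most of mainland New Guinea submerged until ~5 Ma; only
# the central mountains (Fold Belt) and the approaching EPCT, plus the
# non-mainland areas, are above water before then.
.epochs_d <- function(areas, boundary = 5) {
  av <- matrix(TRUE, 2, nrow(areas))
  av[1, areas$code %in% c("V", "C", "A")] <- FALSE
  epoch_stratification(c(Inf, boundary), c(boundary, 0), av, areas$code)
}

#' The builtin Papuan hypothesis models
#'
#' Constructs the thirteen competing models of range evolution for the Papuan
#' region: the mainland-assembly alternatives (a Current Connectivity,
#' b Slow and Steady, c Mobile Belt, d Recent Emergence), the island-history
#' refinements of b (e Louisiade Archipelago, f Woodlark with Louisiades,
#' g Owen Stanleys, h Historical Owen Stanleys, i Offshore with EPCT,
#' j Offshore with Nearest Mainland, k Offshore Islands with Accreted),
#' the hybrid l Island Distance model, and the Unconstrained DEC model.
#' Mainland pairwise connections follow the published current-connectivity
#' matrix; Normanby and Fergusson share the collapsed D'Entrecasteaux pattern
#' and are mutually connected; Southeast Asia sits at the floor throughout.
#' Epoch boundaries of the stratified models are interpretive defaults
#' (documented in the vignette) and can be overridden by building from
#' \code{\link{hypothesis_spec}} directly.
#'
#' @param areas Area set; default \code{\link{papuan_areas}}.
#' @param floor Multiplier floor for unconnected pairs (default 0.001).
#' @param max_size Maximum range size (default 2).
#' @return Named list of \code{\link{dec_model}}s, keyed
#'   \code{a}--\code{l} and \code{DEC} (unconstrained).
#' @export
builtin_hypotheses <- function(areas = papuan_areas(), floor = 0.001,
                               max_size = 2) {
  bl <- .papua_blocks()
  mp <- bl$mainland_pairs
  dent <- bl$dentrecasteaux
  eb <- .epochs_b(areas)
  epair <- function(targets, mainland = "E")
    lapply(targets, function(x) c(mainland, x))
  specs <- list(
    a = hypothesis_spec("a: Current Connectivity", pairwise = mp,
                        blocks = list(dent), floor = floor),
    b = hypothesis_spec("b: Slow and Steady", pairwise = mp,
                        blocks = list(dent), epochs = eb, floor = floor),
    c = hypothesis_spec("c: Mobile Belt", pairwise = mp,
                        blocks = list(dent), epochs = .epochs_c(areas),
                        floor = floor),
    d = hypothesis_spec("d: Recent Emergence", pairwise = mp,
                        blocks = list(dent), epochs = .epochs_d(areas),
                        floor = floor),
    e = hypothesis_spec("e: Louisiade Archipelago", pairwise = mp,
                        blocks = list(dent, bl$louisiades), epochs = eb,
                        floor = floor),
    f = hypothesis_spec("f: Woodlark w/ Louisiades", pairwise = mp,
                        blocks = list(dent, bl$louisiades_woodlark),
                        epochs = eb, floor = floor),
    g = hypothesis_spec("g: Owen Stanleys", pairwise = mp,
                        blocks = list(dent, c("E", bl$islands)),
                        epochs = eb, floor = floor),
    h = hypothesis_spec("h: Historical Owen Stanleys", pairwise = mp,
                        blocks = list(dent, c("E", setdiff(bl$islands, "B"))),
                        epochs = eb, floor = floor),
    i = hypothesis_spec("i: Offshore w/ EPCT",
                        pairwise = c(mp, epair(bl$islands)),
                        blocks = list(dent, bl$louisiades_woodlark),
                        epochs = eb, floor = floor),
    j = hypothesis_spec("j: Offshore w/ Nearest Mainland",
                        pairwise = c(mp, epair(setdiff(bl$islands, "B")),
                                     list(c("A", "B"))),
                        blocks = list(dent, bl$louisiades_woodlark),
                        epochs = eb, floor = floor),
    k = hypothesis_spec("k: Offshore Islands w/ Accreted",
                        pairwise = c(mp, epair(bl$islands, mainland = "A")),
                        blocks = list(dent, bl$louisiades_woodlark),
                        epochs = eb, floor = floor),
    l = hypothesis_spec("l: Island Distance", pairwise = mp,
                        blocks = list(dent, bl$louisiades_woodlark),
                        weights = list(
                          list(from = c("Y", "G", "B"),
                               to = c("V", "C", "F", "A", "E"), value = 0.1),
                          list(from = c("W", "M", "S", "R"),
                               to = c("V", "C", "F", "A", "E"), value = 0.001)),
                        epochs = eb, floor = floor))
  models <- lapply(specs, build_hypothesis, areas = areas, max_size = max_size)
  n <- nrow(areas)
  models$DEC <- dec_model(areas, multipliers = matrix(1, n, n),
                          max_size = max_size, name = "Unconstrained DEC")
  models
}

#' Collapse a multiplier matrix to the 11-region display layout
#'
#' Published displays of the Papuan multiplier matrices use 11 regions:
#' Normanby and Fergusson collapsed into a single D'Entrecasteaux region "D"
#' (their rows must agree) and Southeast Asia omitted, in the order
#' V C F A E D W M S R B. Floor entries can be shown as 0, matching the
#' printed convention that "0" stands for the small fitted floor.
#'
#' @param model A \code{\link{dec_model}} over the 13 Papuan georegions.
#' @param zero_floor Replace entries <= the floor by 0 for display
#'   (default TRUE).
#' @param floor The floor value (default 0.001).
#' @return An 11 x 11 matrix with display region codes as dimnames.
#' @export
display_multipliers <- function(model, zero_floor = TRUE, floor = 0.001) {
  stopifnot(inherits(model, "dec_model"))
  m <- unclass(model$multipliers)
  need <- c("V", "C", "F", "A", "E", "Y", "G", "B", "W", "M", "S", "R")
  if (!all(need %in% rownames(m)))
    stop("model does not cover the 13 Papuan georegions", call. = FALSE)
  others <- setdiff(need, c("Y", "G"))
  if (!isTRUE(all.equal(m["Y", others], m["G", others], check.attributes = FALSE)))
    stop("Normanby and Fergusson rows differ; cannot collapse to 'D'",
         call. = FALSE)
  ord <- c("V", "C", "F", "A", "E", "Y", "W", "M", "S", "R", "B")
  out <- m[ord, ord]
  dn <- c("V", "C", "F", "A", "E", "D", "W", "M", "S", "R", "B")
  dimnames(out) <- list(dn, dn)
  if (zero_floor) out[out <= floor] <- 0
  diag(out) <- 1
  out
}
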