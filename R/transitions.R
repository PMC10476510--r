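# Tabulation of inferred range shifts (dispersal events) through time.

#' Construct a transition table
#'
#' Counts of inferred range shifts indexed by source area, destination area
#' and time bin. Usually produced by \code{\link{count_transitions}}; the
#' constructor also accepts a long-format data frame (columns \code{from},
#' \code{to}, \code{bin}, \code{count}) so that published tables can be
#' loaded and summarized with the same machinery.
#'
#' @param counts 3-d array [from, to, bin] of non-negative counts, or a long
#'   data frame as described above.
#' @param areas The \code{\link{dec_areas}} set (categories drive the
#'   mainland/island marginals).
#' @param bins Character labels of the time bins, oldest first.
#' @return An object of class \code{"dec_transitions"}.
#' @export
transition_table <- function(counts, areas, bins = NULL) {
  stopifnot(inherits(areas, "dec_areas"))
  if (is.data.frame(counts)) {
    stopifnot(all(c("from", "to", "bin", "count") %in% names(counts)))
    if (is.null(bins)) bins <- unique(as.character(counts$bin))
    arr <- array(0, dim = c(nrow(areas), nrow(areas), length(bins)),
                 dimnames = list(areas$code, areas$code, bins))
    for (r in seq_len(nrow(counts))) {
      arr[as.character(counts$from[r]), as.character(counts$to[r]),
          as.character(counts$bin[r])] <-
        arr[as.character(counts$from[r]), as.character(counts$to[r]),
            as.character(counts$bin[r])] + counts$count[r]
    }
    counts <- arr
  }
  stopifnot(length(dim(counts)) == 3, all(counts >= 0))
  structure(list(counts = counts, areas = areas,
                 bins = dimnames(counts)[[3]]),
            class = "dec_transitions")
}

# half-open [older, younger) bin lookup; oldest bin closed at the root age
.bin_of <- function(age, breaks) {
  for (k in seq_len(length(breaks) - 1)) {
    if (age <= breaks[k] + 1e-9 && age > breaks[k + 1]) return(k)
  }
  if (age <= breaks[length(breaks)]) return(length(breaks) - 1L)  # age == youngest bound
  NA_integer_
}

#' Count range transitions along a reconstructed tree
#'
#' For every parent-to-child edge whose majority-rule (or, at tips, observed)
#' areas differ, one transition from the parent's area to the child's area is
#' recorded, assigned to the time bin containing the parent node's age --
#' i.e. the shift is attributed to the ancestral node along whose descendant
#' branch it occurred. Edges into tips are counted. Bins are half-open
#' [older, younger) Ma; ages older than the oldest break go to an "overflow"
#' bin with a warning.
#'
#' @param tree The tree used for the reconstruction.
#' @param reconstruction A \code{\link{reconstruct_ancestral_ranges}} result.
#' @param tips Tip ranges (single-area observed tips; wider tips use their
#'   first-listed area with a warning).
#' @param bins Numeric break ages in Ma, oldest first
#'   (default \code{c(20, 15, 10, 3, 0)}).
#' @return A \code{\link{transition_table}} object.
#' @export
count_transitions <- function(tree, reconstruction, tips,
                              bins = c(20, 15, 10, 3, 0)) {
  stopifnot(inherits(reconstruction, "dec_ancestral"))
  areas <- reconstruction$model$areas
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  bins <- sort(unique(as.numeric(bins)), decreasing = TRUE)
  bin_labels <- paste0(bins[-length(bins)], "-", bins[-1])

  # per-node assigned area code
  assigned <- character(ntip + tree$Nnode)
  assigned[reconstruction$nodes] <- reconstruction$mr_area
  if (is.character(tips) && !is.list(tips)) tips <- as.list(tips)
  for (i in seq_len(ntip)) {
    st <- tips[[tree$tip.label[i]]]
    if (is.numeric(st)) st <- areas$code[st]
    if (length(st) > 1)
      warning("multi-area tip '", tree$tip.label[i],
              "'; using its first area for transition counting", call. = FALSE)
    assigned[i] <- st[1]
  }

  labels <- c(bin_labels, "overflow")
  arr <- array(0, dim = c(nrow(areas), nrow(areas), length(labels)),
               dimnames = list(areas$code, areas$code, labels))
  overflow <- FALSE
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    from <- assigned[par]; to <- assigned[ch]
    if (from == to) next
    k <- .bin_of(ages[par], bins)
    if (is.na(k)) { k <- length(labels); overflow <- TRUE }
    arr[from, to, k] <- arr[from, to, k] + 1
  }
  if (overflow)
    warning("node age(s) older than the oldest bin; counted in 'overflow'",
            call. = FALSE)
  if (!overflow) arr <- arr[, , bin_labels, drop = FALSE]
  transition_table(arr, areas)
}

#' Summarize a transition table
#'
#' Reports the grand total of transitions, the mainland-to-mainland and
#' mainland-to-island totals (classified by area category), and per-source
#' percentages of each, rounded to the nearest integer percent.
#'
#' @param table A \code{\link{transition_table}}.
#' @return A list with \code{total}, \code{mainland_mainland},
#'   \code{mainland_island}, \code{by_bin} (matrix of the two marginals per
#'   bin), \code{source_pct_mainland} and \code{source_pct_island} (named
#'   integer percent vectors over mainland source areas).
#' @export
summarize_transitions <- function(table) {
  stopifnot(inherits(table, "dec_transitions"))
  cat_of <- table$areas$category
  main <- which(cat_of == "mainland-terrane")
  isl <- which(cat_of == "island")
  cts <- table$counts
  mm <- apply(cts[main, main, , drop = FALSE], 3, sum)
  mi <- apply(cts[main, isl, , drop = FALSE], 3, sum)
  src_mm <- apply(cts[main, main, , drop = FALSE], 1, sum)
  src_mi <- apply(cts[main, isl, , drop = FALSE], 1, sum)
  pct <- function(x) {
    tot <- sum(x)
    if (tot == 0) return(stats::setNames(rep(0L, length(x)), names(x)))
    round(100 * x / tot)
  }
  list(total = sum(cts),
       mainland_mainland = sum(mm),
       mainland_island = sum(mi),
       by_bin = rbind(mainland_mainland = mm, mainland_island = mi),
       source_pct_mainland = pct(src_mm),
       source_pct_island = pct(src_mi))
}

#' @export
print.dec_transitions <- function(x, ...) {
  s <- summarize_transitions(x)
  cat("Range transitions: ", s$total, " total (",
      s$mainland_mainland, " mainland-to-mainland, ",
      s$mainland_island, " mainland-to-island)\n", sep = "")
  print(s$by_bin)
  invisible(x)
}
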