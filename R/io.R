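# Readers and writers for the standard file formats of DEC analyses:
# Newick/Nexus trees (via ape), LAGRANGE/PHYLIP-style geography matrices,
# whitespace-delimited multiplier matrices, and epoch files.

#' Read a time-calibrated tree
#'
#' Wraps \code{ape::read.tree} / \code{ape::read.nexus}, validates that every
#' tree is rooted and binary (polytomies are rejected, naming the offending
#' node), and that branch lengths are present.
#'
#' @param path File path.
#' @param format \code{"newick"}, \code{"nexus"}, or \code{"auto"} (by file
#'   extension; default).
#' @return A \code{phylo} tree, or a \code{multiPhylo} list if the file
#'   contains several trees.
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(nex|nexus|trees)$", path, ignore.case = TRUE))
      "nexus" else "newick"
  }
  trees <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) stop("could not parse tree file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(trees))
    stop("could not parse tree file '", path, "': no tree found", call. = FALSE)
  check1 <- function(tr) {
    if (!ape::is.binary(tr)) {
      tab <- tabulate(tr$edge[, 1])
      bad <- which(tab > 2)[1]
      stop("tree in '", path, "' is not binary: node ", bad, " has ",
           tab[bad], " children", call. = FALSE)
    }
    if (is.null(tr$edge.length))
      stop("tree in '", path, "' has no branch lengths", call. = FALSE)
    tr
  }
  if (inherits(trees, "multiPhylo")) {
    out <- lapply(trees, check1)
    class(out) <- "multiPhylo"
    if (length(out) == 1) out <- out[[1]]
    out
  } else check1(trees)
}

#' Read a LAGRANGE/PHYLIP-style geography file
#'
#' Format: a header line "n_taxa n_areas (CODE1 CODE2 ...)" (the
#' parenthesized code list is optional), then one line per taxon with its
#' name and a binary presence string (optionally whitespace-separated).
#'
#' @param path File path.
#' @param areas Optional \code{\link{dec_areas}}; if absent, codes come from
#'   the header (or are auto-numbered).
#' @return Named list of character vectors of area codes (class
#'   \code{"dec_tip_ranges"}), with the area codes as attribute
#'   \code{"area_codes"}.
#' @export
read_geography <- function(path, areas = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 1) stop("empty geography file", call. = FALSE)
  hdr <- lines[1]
  mt <- regmatches(hdr, regexec("^(\\d+)\\s+(\\d+)\\s*(\\((.*)\\))?\\s*$", hdr))[[1]]
  if (length(mt) == 0)
    stop("malformed geography header: '", hdr, "'", call. = FALSE)
  n_taxa <- as.integer(mt[2]); n_areas <- as.integer(mt[3])
  codes <- if (nzchar(mt[5] %||% "")) strsplit(trimws(mt[5]), "\\s+")[[1]] else
    as.character(seq_len(n_areas))
  if (!is.null(areas)) {
    if (nrow(areas) != n_areas)
      stop("geography file has ", n_areas, " areas but the area set has ",
           nrow(areas), call. = FALSE)
    codes <- areas$code
  }
  if (length(codes) != n_areas)
    stop("header area-code list does not match the area count", call. = FALSE)
  body <- lines[-1]
  if (length(body) != n_taxa)
    stop("geography file declares ", n_taxa, " taxa but has ", length(body),
         " data rows", call. = FALSE)
  out <- vector("list", n_taxa)
  taxa <- character(n_taxa)
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], "\\s+")[[1]]
    taxa[i] <- parts[1]
    bits <- paste(parts[-1], collapse = "")
    if (nchar(bits) != n_areas || grepl("[^01]", bits))
      stop("row for taxon '", taxa[i], "' is not a ", n_areas,
           "-digit binary string", call. = FALSE)
    pres <- which(strsplit(bits, "")[[1]] == "1")
    if (length(pres) == 0)
      stop("taxon '", taxa[i], "' has an all-zero row; tips cannot have a ",
           "null range", call. = FALSE)
    out[[i]] <- codes[pres]
  }
  if (anyDuplicated(taxa))
    stop("duplicate taxon name(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "), call. = FALSE)
  names(out) <- taxa
  attr(out, "area_codes") <- codes
  class(out) <- "dec_tip_ranges"
  out
}

#' Write tip ranges as a LAGRANGE/PHYLIP-style geography file
#'
#' @param tips Named list of area-code (or index) vectors.
#' @param areas A \code{\link{dec_areas}} set defining column order.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_geography <- function(tips, areas, path) {
  stopifnot(inherits(areas, "dec_areas"))
  taxa <- names(tips)
  if (is.null(taxa) || any(!nzchar(taxa)))
    stop("tips must be a named list", call. = FALSE)
  rows <- vapply(tips, function(st) {
    if (is.character(st)) st <- match(st, areas$code)
    if (anyNA(st)) stop("unknown area code in tip ranges", call. = FALSE)
    bits <- rep("0", nrow(areas)); bits[st] <- "1"
    paste(bits, collapse = "")
  }, character(1))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("%d %d (%s)", length(taxa), nrow(areas),
                       paste(areas$code, collapse = " ")),
               paste0(taxa, "\t", rows)), con)
  invisible(path)
}

#' Read a dispersal-multiplier matrix file
#'
#' A square whitespace-delimited matrix with a header row and column of area
#' codes.
#'
#' @param path File path.
#' @param areas Optional \code{\link{dec_areas}} to validate/reorder against.
#' @return A \code{\link{dispersal_multipliers}} matrix.
#' @export
read_multipliers <- function(path, areas = NULL) {
  m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1,
                                   check.names = FALSE))
  if (!all(rownames(m) == colnames(m)))
    stop("multiplier file row and column codes disagree", call. = FALSE)
  if (!is.null(areas)) {
    if (!setequal(rownames(m), areas$code))
      stop("multiplier file codes do not match the area set", call. = FALSE)
    m <- m[areas$code, areas$code]
    return(dispersal_multipliers(m, areas))
  }
  dispersal_multipliers(m)
}

#' Write a dispersal-multiplier matrix file
#'
#' @param mult Multiplier matrix with area-code dimnames.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_multipliers <- function(mult, path) {
  m <- unclass(mult)
  utils::write.table(m, path, quote = FALSE, sep = "\t", col.names = NA)
  invisible(path)
}

#' Read an epoch-stratification file
#'
#' One line per epoch, oldest first: "start_age end_age code1,code2,..."
#' (ages in Ma; the code list names the areas available during the epoch;
#' "Inf" is accepted as the oldest start age).
#'
#' @param path File path.
#' @param areas The full \code{\link{dec_areas}} set.
#' @return An \code{\link{epoch_stratification}}.
#' @export
read_epochs <- function(path, areas) {
  stopifnot(inherits(areas, "dec_areas"))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  starts <- numeric(0); ends <- numeric(0)
  av <- matrix(FALSE, 0, nrow(areas))
  for (ln in lines) {
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) != 3)
      stop("malformed epoch line: '", ln, "'", call. = FALSE)
    starts <- c(starts, as.numeric(parts[1]))
    ends <- c(ends, as.numeric(parts[2]))
    codes <- strsplit(parts[3], ",")[[1]]
    i <- match(codes, areas$code)
    if (anyNA(i))
      stop("unknown area code in epoch file: ",
           paste(codes[is.na(i)], collapse = ", "), call. = FALSE)
    row <- rep(FALSE, nrow(areas)); row[i] <- TRUE
    av <- rbind(av, row)
  }
  epoch_stratification(starts, ends, av, areas$code)
}

#' Write a tree with post-order internal-node labels
#'
#' Internal nodes get their ape node ids as labels so ancestral-state tables
#' join unambiguously to the exported Newick.
#'
#' @param tree A \code{phylo}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_labelled_tree <- function(tree, path) {
  tree$node.label <- as.character((ape::Ntip(tree) + 1):(ape::Ntip(tree) + tree$Nnode))
  ape::write.tree(tree, file = path)
  invisible(path)
}
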