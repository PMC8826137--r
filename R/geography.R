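#' Taxon-by-area presence table
#'
#' Construct a geography table from a 0/1 presence matrix. Rows are taxa,
#' columns are areas; every taxon must occupy at least one area. Area order
#' is significant: bit `i` of every range refers to area `i` of this table,
#' and all downstream state indexing derives from it.
#'
#' @param presence 0/1 matrix or data.frame with taxon rownames.
#' @param areas area codes; default from column names.
#' @return an object of class `"geography_table"` with elements `areas` and
#'   `presence` (integer matrix).
#' @export
geography_table <- function(presence, areas = colnames(presence)) {
  presence <- as.matrix(presence)
  storage.mode(presence) <- "integer"
  if (is.null(areas)) areas <- LETTERS[seq_len(ncol(presence))]
  if (length(areas) != ncol(presence)) stop("areas must match the columns")
  if (is.null(rownames(presence))) stop("presence needs taxon rownames")
  if (anyDuplicated(rownames(presence))) stop("duplicate taxon names")
  if (!all(presence %in% c(0L, 1L))) stop("presence must be 0/1")
  empty <- rowSums(presence) == 0L
  if (any(empty))
    stop("empty range for taxon: ", paste(rownames(presence)[empty], collapse = ", "))
  colnames(presence) <- areas
  structure(list(areas = areas, presence = presence), class = "geography_table")
}

#' @export
print.geography_table <- function(x, ...) {
  cat("Geography table: ", nrow(x$presence), " taxa x ", length(x$areas),
      " areas (", paste(x$areas, collapse = ""), ")\n", sep = "")
  rs <- rowSums(x$presence)
  cat("  single-area taxa: ", sum(rs == 1L), ", multi-area: ", sum(rs > 1L),
      "\n", sep = "")
  invisible(x)
}

#' Read a geography file
#'
#' Parses the PHYLIP-style geography dialect used by the DEC software family:
#' a header `<ntaxa> <nareas> (<codes...>)` followed by one line per taxon,
#' `<taxon> <0/1 string of length nareas>`. Taxon order is preserved.
#'
#' @param path path to the geography file.
#' @return a [geography_table()].
#' @examples
#' f <- tempfile()
#' writeLines(c("2 3 (A B C)", "t1 100", "t2 011"), f)
#' read_geography(f)
#' @export
read_geography <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty geography file")
  hd <- regmatches(lines[1],
    regexec("^(\\d+)\\s+(\\d+)\\s*(?:\\(([^)]*)\\))?\\s*$", lines[1]))[[1]]
  if (!length(hd)) stop("line 1: malformed header '", lines[1], "'")
  ntaxa <- as.integer(hd[2]); nareas <- as.integer(hd[3])
  areas <- if (nzchar(hd[4])) strsplit(trimws(hd[4]), "\\s+")[[1]]
           else LETTERS[seq_len(nareas)]
  if (length(areas) != nareas) stop("line 1: expected ", nareas, " area codes")
  body <- lines[-1L]
  if (length(body) != ntaxa)
    stop("header declares ", ntaxa, " taxa but file has ", length(body), " rows")
  taxa <- character(ntaxa)
  pres <- matrix(0L, ntaxa, nareas)
  for (i in seq_len(ntaxa)) {
    parts <- strsplit(body[i], "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("line ", i + 1L, ": expected '<taxon> <bits>'")
    bits <- strsplit(parts[2], "")[[1]]
    if (length(bits) != nareas || !all(bits %in% c("0", "1")))
      stop("line ", i + 1L, ": bad bit string '", parts[2], "'")
    if (all(bits == "0"))
      stop("line ", i + 1L, ": empty range for taxon '", parts[1], "'")
    taxa[i] <- parts[1]
    pres[i, ] <- as.integer(bits)
  }
  if (anyDuplicated(taxa))
    stop("duplicate taxon: ", paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  rownames(pres) <- taxa
  geography_table(pres, areas)
}

#' Write a geography file
#' @param geog a [geography_table()].
#' @param path output path.
#' @seealso [read_geography()]
#' @export
write_geography <- function(geog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d (%s)", nrow(geog$presence), length(geog$areas),
                     paste(geog$areas, collapse = " ")), con)
  for (i in seq_len(nrow(geog$presence)))
    writeLines(paste(rownames(geog$presence)[i],
                     paste(geog$presence[i, ], collapse = "")), con)
  invisible(path)
}

# tip range bitmasks in the order of the tree's tip labels
tip_masks <- function(geog, tip_labels) {
  miss <- setdiff(tip_labels, rownames(geog$presence))
  if (length(miss))
    stop("tips missing from geography: ", paste(miss, collapse = ", "))
  m <- geog$presence[tip_labels, , drop = FALSE]
  as.integer(m %*% bitwShiftL(1L, seq_along(geog$areas) - 1L))
}
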