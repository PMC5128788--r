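# Reading and writing OTU count tables.
#
# mothur's .shared layout is tab-separated with header
#   label  Group  numOtus  <otu ids ...>
# and one row per sample; plain TSV tables are one header row plus one label
# column, in either orientation.

#' Read a mothur .shared OTU table
#'
#' Samples are taken from the \code{Group} column, taxa from the OTU column
#' headers. When the file carries several \code{label} blocks (multiple
#' clustering thresholds) only the first block is kept and a warning lists
#' the skipped labels.
#'
#' @param path path to a .shared file.
#' @return A \linkS4class{CommunityTable}.
#' @examples
#' f <- tempfile(fileext = ".shared")
#' ct0 <- communityTable(matrix(c(5, 1, 0, 0, 2, 3), nrow = 3,
#'                              dimnames = list(paste0("OTU", 1:3),
#'                                              c("A", "B"))))
#' writeShared(ct0, f)
#' ct <- readShared(f)
#' sampleSums(ct)
#' @export
readShared <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("malformed .shared file: need a header and at least one sample row",
         call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 4L)
    stop("malformed .shared header: expected 'label', 'Group', 'numOtus' ",
         "followed by OTU columns", call. = FALSE)
  expected <- c("label", "Group", "numOtus")
  for (k in 1:3) {
    if (tolower(header[k]) != tolower(expected[k]))
      stop("malformed .shared header: column ", k, " is '", header[k],
           "', expected '", expected[k], "'", call. = FALSE)
  }
  otuIds <- header[-(1:3)]
  if (anyDuplicated(otuIds))
    stop("malformed .shared header: duplicated OTU column '",
         otuIds[duplicated(otuIds)][1L], "'", call. = FALSE)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ncol <- length(header)
  bad <- which(vapply(rows, length, integer(1)) != ncol)
  if (length(bad))
    stop("malformed .shared file: row ", bad[1L] + 1L, " has ",
         length(rows[[bad[1L]]]), " fields, expected ", ncol, call. = FALSE)
  labels <- vapply(rows, `[[`, character(1), 1L)
  keep <- labels == labels[1L]
  if (!all(keep)) {
    warning("multiple label blocks in .shared file; keeping '", labels[1L],
            "', skipping: ", paste(unique(labels[!keep]), collapse = ", "))
    rows <- rows[keep]
  }
  groups <- vapply(rows, `[[`, character(1), 2L)
  if (anyDuplicated(groups))
    stop("duplicate Group (sample) id '", groups[duplicated(groups)][1L],
         "' within one label block", call. = FALSE)
  numOtus <- suppressWarnings(as.integer(vapply(rows, `[[`, character(1), 3L)))
  if (anyNA(numOtus) || any(numOtus != length(otuIds)))
    stop("malformed .shared file: 'numOtus' (",
         numOtus[which(is.na(numOtus) | numOtus != length(otuIds))[1L]],
         ") disagrees with the ", length(otuIds), " OTU columns",
         call. = FALSE)
  m <- matrix(0, nrow = length(otuIds), ncol = length(rows),
              dimnames = list(otuIds, groups))
  for (j in seq_along(rows)) {
    cell <- rows[[j]][-(1:3)]
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(val) | val < 0 | val != floor(val))
    if (length(bad))
      stop("invalid count '", cell[bad[1L]], "' at sample '", groups[j],
           "', OTU '", otuIds[bad[1L]], "'", call. = FALSE)
    m[, j] <- val
  }
  communityTable(m)
}

#' Write a CommunityTable as a mothur .shared file
#'
#' @param table a \linkS4class{CommunityTable}.
#' @param path output path.
#' @param label clustering-threshold label for the single block written
#'   (default \code{"0.97"}).
#' @return \code{path}, invisibly.
#' @export
writeShared <- function(table, path, label = "0.97") {
  stopifnot(is(table, "CommunityTable"))
  m <- counts(table)
  header <- c("label", "Group", "numOtus", rownames(m))
  body <- vapply(seq_len(ncol(m)), function(j) {
    paste(c(label, colnames(m)[j], nrow(m),
            format(m[, j], scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), body), path)
  invisible(path)
}

#' Read a plain TSV count table
#'
#' Rectangular tab-separated file with one header row and one leading label
#' column; orientation is normalized to taxa x samples.
#'
#' @param path path to the TSV file.
#' @param orientation \code{"taxa_by_samples"} (default) or
#'   \code{"samples_by_taxa"}.
#' @return A \linkS4class{CommunityTable}.
#' @export
readCountTsv <- function(path, orientation = c("taxa_by_samples",
                                               "samples_by_taxa")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("malformed TSV: need a header row and at least one data row",
         call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  widths <- vapply(parts, length, integer(1))
  if (length(unique(widths)) != 1L)
    stop("ragged TSV: row ", which(widths != widths[1L])[1L], " has ",
         widths[widths != widths[1L]][1L], " fields, expected ", widths[1L],
         call. = FALSE)
  if (widths[1L] < 2L)
    stop("malformed TSV: need a label column and at least one data column",
         call. = FALSE)
  colIds <- parts[[1L]][-1L]
  rowIds <- vapply(parts[-1L], `[[`, character(1), 1L)
  m <- matrix(0, nrow = length(rowIds), ncol = length(colIds),
              dimnames = list(rowIds, colIds))
  for (i in seq_along(rowIds)) {
    cell <- parts[[i + 1L]][-1L]
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(val) | val < 0 | val != floor(val))
    if (length(bad))
      stop("invalid count '", cell[bad[1L]], "' at row ", i + 1L,
           ", column ", bad[1L] + 1L, call. = FALSE)
    m[i, ] <- val
  }
  communityTable(m, taxaAreRows = orientation == "taxa_by_samples")
}

#' Write a CommunityTable as a plain TSV
#'
#' @param table a \linkS4class{CommunityTable}.
#' @param path output path.
#' @param orientation layout to write (see [readCountTsv()]).
#' @return \code{path}, invisibly.
#' @export
writeCountTsv <- function(table, path,
                          orientation = c("taxa_by_samples",
                                          "samples_by_taxa")) {
  orientation <- match.arg(orientation)
  stopifnot(is(table, "CommunityTable"))
  m <- counts(table)
  if (orientation == "samples_by_taxa")
    m <- t(m)
  lab <- if (orientation == "taxa_by_samples") "taxon" else "sample"
  header <- paste(c(lab, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i],
            format(m[i, ], scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname poolSamples
#' @export
setMethod("poolSamples", "CommunityTable", function(x, samples) {
  if (length(samples) == 0L)
    stop("'samples' must be non-empty", call. = FALSE)
  missing <- setdiff(samples, sampleIds(x))
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- counts(x)[, samples, drop = FALSE]
  abundanceVector(rowSums(m), taxonIds = taxonIds(x))
})
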