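#' @include AllClasses.R
NULL

#' Read a parcel time-series table
#'
#' Delimited text with a header row of region ids and one row per frame.
#'
#' @param path File path.
#' @param tr Repetition time in seconds.
#' @param sep Field separator (default `"\t"`).
#' @param segmentLabels Optional segment labels (see [makeSegmentLabels()]).
#' @return A [ParcelTimeSeries-class].
#' @export
readTimeSeries <- function(path, tr, sep = "\t", segmentLabels = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  ParcelTimeSeries(as.matrix(tab), tr = tr, regionIds = colnames(tab),
                   segmentLabels = segmentLabels)
}

#' Write a parcel time-series table
#'
#' @param series A [ParcelTimeSeries-class].
#' @param path File path.
#' @param sep Field separator (default `"\t"`).
#' @export
writeTimeSeries <- function(series, path, sep = "\t") {
  utils::write.table(as.matrix(series), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read rigid-body realignment parameters
#'
#' Six-column delimited text, one row per frame: three translations and
#' three rotations. Column order and rotation units vary between motion
#' correction tools, so both are configurable; the returned matrix is
#' always translations (mm) first, rotations in radians.
#'
#' @param path File path.
#' @param sep Field separator; `""` (default) splits on any whitespace.
#' @param order `"translations_first"` (default) or `"rotations_first"`.
#' @param rotationUnits `"radians"` (default) or `"degrees"`.
#' @return Numeric frames x 6 matrix.
#' @export
readRealignment <- function(path, sep = "",
                            order = c("translations_first",
                                      "rotations_first"),
                            rotationUnits = c("radians", "degrees")) {
  order <- match.arg(order)
  rotationUnits <- match.arg(rotationUnits)
  rp <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  if (ncol(rp) != 6L)
    stop("expected 6 columns of realignment parameters, got ", ncol(rp))
  if (order == "rotations_first") rp <- rp[, c(4:6, 1:3), drop = FALSE]
  if (rotationUnits == "degrees") rp[, 4:6] <- rp[, 4:6] * pi / 180
  dimnames(rp) <- NULL
  rp
}

#' Write / read a censoring mask
#'
#' One-column 0/1 text file (1 = censored), no header.
#'
#' @param mask A [CensorMask-class].
#' @param path File path.
#' @return `writeCensorMask` returns the path invisibly; `readCensorMask`
#'   returns a [CensorMask-class] (provenance is not stored in the file and
#'   is set to `"motion"` for censored frames).
#' @export
writeCensorMask <- function(mask, path) {
  stopifnot(is(mask, "CensorMask"))
  writeLines(as.character(as.integer(censored(mask))), path)
  invisible(path)
}

#' @rdname writeCensorMask
#' @export
readCensorMask <- function(path) {
  CensorMask(as.integer(readLines(path)) == 1L)
}

#' Write / read a connectivity matrix
#'
#' Delimited text: a header row of region ids followed by the n x n matrix
#' at 10 significant digits (round-tripping bit-exactly at that precision).
#' The frame count is stored in a `# nFramesUsed:` comment line.
#'
#' @param cm A [ConnectivityMatrix-class].
#' @param path File path.
#' @param sep Field separator (default `"\t"`).
#' @return `writeConnectivityMatrix` returns the path invisibly;
#'   `readConnectivityMatrix` a [ConnectivityMatrix-class].
#' @export
writeConnectivityMatrix <- function(cm, path, sep = "\t") {
  stopifnot(is(cm, "ConnectivityMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nFramesUsed: %d", nFramesUsed(cm)), con)
  writeLines(paste(regionIds(cm), collapse = sep), con)
  v <- as.matrix(cm)
  for (i in seq_len(nrow(v)))
    writeLines(paste(sprintf("%.10g", v[i, ]), collapse = sep), con)
  invisible(path)
}

#' @rdname writeConnectivityMatrix
#' @export
readConnectivityMatrix <- function(path, sep = "\t") {
  lines <- readLines(path)
  nf <- 0L
  if (startsWith(lines[1], "#")) {
    nf <- as.integer(sub("^#\\s*nFramesUsed:\\s*", "", lines[1]))
    lines <- lines[-1]
  }
  ids <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  v <- do.call(rbind, lapply(lines[-1], function(l)
    as.numeric(strsplit(l, sep, fixed = TRUE)[[1]])))
  ConnectivityMatrix(v, regionIds = ids, nFramesUsed = nf)
}

#' Export a weighted graph as an edge list
#'
#' Three-column delimited text (`node_a`, `node_b`, `weight`) with header.
#'
#' @param g A [WeightedGraph-class].
#' @param path File path.
#' @param sep Field separator (default `"\t"`).
#' @export
writeEdgeList <- function(g, path, sep = "\t") {
  stopifnot(is(g, "WeightedGraph"))
  e <- edgeList(g)
  names(e) <- c("node_a", "node_b", "weight")
  utils::write.table(e, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a metric panel
#'
#' Delimited text with a `subject` id column plus one column per condition.
#'
#' @param panel A [MetricPanel-class].
#' @param path File path.
#' @param sep Field separator (default `"\t"`).
#' @param metric,sample Labels attached on read.
#' @return `writePanel` returns the path invisibly; `readPanel` a
#'   [MetricPanel-class].
#' @export
writePanel <- function(panel, path, sep = "\t") {
  stopifnot(is(panel, "MetricPanel"))
  v <- panelValues(panel)
  out <- data.frame(subject = rownames(v), v, check.names = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePanel
#' @export
readPanel <- function(path, sep = "\t", metric = "average_connectivity",
                      sample = "sample") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  v <- as.matrix(tab[, -1, drop = FALSE])
  rownames(v) <- as.character(tab[[1]])
  MetricPanel(v, metric = metric, sample = sample)
}

#' Write / read a normative table
#'
#' Delimited text mirroring the norm-table columns; round-trips the
#' built-in constants bit-exactly.
#'
#' @param norms A [NormTable-class].
#' @param path File path.
#' @param sep Field separator (default `"\t"`).
#' @return `writeNorms` returns the path invisibly; `readNorms` a
#'   [NormTable-class].
#' @export
writeNorms <- function(norms, path, sep = "\t") {
  stopifnot(is(norms, "NormTable"))
  utils::write.table(normEntries(norms), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeNorms
#' @export
readNorms <- function(path, sep = "\t") {
  e <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  e$n <- as.integer(e$n)
  new("NormTable", entries = e)
}

#' Write a person report
#'
#' Emits the human-readable report (the `show()` rendering) and, when
#' `summaryPath` is given, a one-row delimited summary for batch scoring
#' (network columns of Fisher-Z, z-score and band).
#'
#' @param report A [PersonReport-class].
#' @param path Path for the text report.
#' @param summaryPath Optional path for the one-row delimited summary.
#' @param sep Field separator for the summary (default `"\t"`).
#' @export
writeReport <- function(report, path, summaryPath = NULL, sep = "\t") {
  stopifnot(is(report, "PersonReport"))
  txt <- utils::capture.output(methods::show(report))
  writeLines(txt, path)
  if (!is.null(summaryPath)) {
    t <- report@table
    row <- data.frame(age = report@age, stratum = report@stratum)
    for (i in seq_len(nrow(t))) {
      row[[paste0(t$network[i], "_fisherZ")]] <- t$fisherZ[i]
      row[[paste0(t$network[i], "_z")]] <- t$z[i]
      row[[paste0(t$network[i], "_band")]] <- t$band[i]
    }
    utils::write.table(row, summaryPath, sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
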