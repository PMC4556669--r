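#' Read a two-channel timelapse hyperstack from TIFF
#'
#' Reads a multi-page TIFF in the ImageJ-hyperstack page order (channel
#' fastest, then z, then time) into canonical (T,C,Z,Y,X) order.  Dimensions
#' and calibration are taken, in order of precedence, from (1) a JSON
#' sidecar \code{<stem>.json} written by \code{\link{writeHyperstack}},
#' (2) an ImageJ-style description string embedded in the TIFF, or (3) the
#' \code{axisOrderHint} / calibration arguments.  When no source states the
#' calibration, the assay defaults (32/150 um per pixel, 10 min per frame)
#' are used with a message.
#'
#' @param path TIFF file path.
#' @param axisOrderHint optional string \code{"T<t>C<c>Z<z>"} giving the
#'   counts of timepoints, channels and slices when no metadata is present,
#'   e.g. \code{"T10C2Z5"}.
#' @param pixelSizeUm,frameIntervalMin optional calibration overrides.
#' @param channelRoles named integer vector mapping "green"/"red" to channel
#'   indices; default green = 1, red = 2.
#' @return A \linkS4class{TimelapseStack}.
#' @export
readHyperstack <- function(path, axisOrderHint = NULL,
                           pixelSizeUm = NULL, frameIntervalMin = NULL,
                           channelRoles = c(green = 1L, red = 2L)) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1L]], "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  meta <- .readSidecar(path)
  if (is.null(meta)) {
    desc <- attr(pages[[1L]], "description")
    if (!is.null(desc)) meta <- parseImageJDescription(desc)
  }
  if (is.null(meta) && !is.null(axisOrderHint))
    meta <- .parseAxisHint(axisOrderHint)
  if (is.null(meta))
    .stopf("calibration required: no sidecar, ImageJ description or axisOrderHint for '%s'", path)
  nT <- meta$frames; nC <- meta$channels; nZ <- meta$slices
  if (is.null(nC) || nC < 2L)
    .stopf("channel count: hyperstack must carry >= 2 channels, found %s",
           if (is.null(nC)) "none declared" else nC)
  if (nT * nC * nZ != length(pages))
    .stopf("page count %d does not match declared T*C*Z = %d",
           length(pages), nT * nC * nZ)
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  arr <- array(0, c(nT, nC, nZ, ny, nx))
  maxv <- 2^bits - 1
  p <- 1L
  for (t in seq_len(nT)) for (z in seq_len(nZ)) for (ch in seq_len(nC)) {
    arr[t, ch, z, , ] <- round(pages[[p]] * maxv)
    p <- p + 1L
  }
  px <- pixelSizeUm %||% meta$pixelSizeUm
  fi <- frameIntervalMin %||% meta$frameIntervalMin
  if (is.null(px) || is.null(fi)) {
    message("calibration absent; using assay defaults (32/150 um/px, 10 min/frame)")
    px <- px %||% (32 / 150)
    fi <- fi %||% 10
  }
  roles <- meta$channelRoles %||% channelRoles
  TimelapseStack(arr, pixelSizeUm = px, frameIntervalMin = fi,
                 channelRoles = roles, bitDepth = bits)
}

#' Write a hyperstack to TIFF (with JSON metadata sidecar)
#'
#' Pages are emitted in ImageJ-hyperstack order (channel fastest, then z,
#' then time).  Because the TIFF backend cannot embed a description tag,
#' dimensions, calibration and channel roles go into \code{<stem>.json}
#' next to the TIFF; \code{\link{readHyperstack}} restores them losslessly.
#'
#' @param stack a \linkS4class{TimelapseStack}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeHyperstack <- function(stack, path) {
  d <- dim(frames(stack))
  maxv <- 2^bitDepth(stack) - 1
  pages <- vector("list", d[1L] * d[2L] * d[3L])
  p <- 1L
  for (t in seq_len(d[1L])) for (z in seq_len(d[3L])) for (ch in seq_len(d[2L])) {
    pages[[p]] <- frames(stack)[t, ch, z, , ] / maxv
    p <- p + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bitDepth(stack),
                  compression = "none", reduce = FALSE)
  meta <- list(frames = d[1L], channels = d[2L], slices = d[3L],
               pixelSizeUm = pixelSize(stack),
               frameIntervalMin = frameInterval(stack),
               channelRoles = as.list(channelRoles(stack)),
               bitDepth = bitDepth(stack))
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

.readSidecar <- function(path) {
  sp <- .sidecarPath(path)
  if (!file.exists(sp)) return(NULL)
  m <- jsonlite::read_json(sp, simplifyVector = TRUE)
  m$channelRoles <- unlist(m$channelRoles)
  storage.mode(m$channelRoles) <- "integer"
  m
}

#' Parse an ImageJ TIFF description string
#'
#' Extracts \code{frames}, \code{channels}, \code{slices} and, when present,
#' spatial/temporal calibration from the \code{ImageJ=...} description block
#' that ImageJ writes into hyperstack TIFFs.
#'
#' @param desc the description string (newline-separated key=value pairs).
#' @return list with elements frames, channels, slices, pixelSizeUm,
#'   frameIntervalMin (NULL when absent), or NULL if not ImageJ-style.
#' @export
parseImageJDescription <- function(desc) {
  if (!grepl("ImageJ=", desc, fixed = TRUE)) return(NULL)
  kv <- strsplit(strsplit(desc, "\n")[[1L]], "=")
  kv <- kv[lengths(kv) == 2L]
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  num <- function(k) if (k %in% names(vals)) as.numeric(vals[[k]]) else NULL
  n <- function(k) { v <- num(k); if (is.null(v)) 1L else as.integer(v) }
  interval <- num("finterval")
  if (!is.null(interval)) interval <- interval / 60  # ImageJ stores seconds
  list(frames = n("frames"), channels = n("channels"), slices = n("slices"),
       pixelSizeUm = num("spacing.xy") %||% num("pixelwidth"),
       frameIntervalMin = interval)
}

.parseAxisHint <- function(hint) {
  m <- regmatches(hint, regexec("^T(\\d+)C(\\d+)Z(\\d+)$", hint))[[1L]]
  if (length(m) != 4L)
    .stopf("axisOrderHint must look like 'T10C2Z5', got '%s'", hint)
  list(frames = as.integer(m[2L]), channels = as.integer(m[3L]),
       slices = as.integer(m[4L]), pixelSizeUm = NULL, frameIntervalMin = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read retrograde traces from CSV or SWC
#'
#' CSV files need columns \code{timepoint,y,x} (header required; coordinates
#' 0-based, tip first within each timepoint) and yield one
#' \linkS4class{TracePath} per timepoint.  SWC files follow the standard
#' format; parent links define the order, the root is taken as the
#' growth-cone tip and type/radius fields are ignored.  Branched SWC is
#' rejected: the assay's trace is a simple path.
#'
#' @param path input file.
#' @param format "csv" or "swc" (default guessed from the extension).
#' @return list of \linkS4class{TracePath}, named by timepoint index.
#' @export
readTrace <- function(path, format = c("auto", "csv", "swc")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.swc$", path, ignore.case = TRUE)) "swc" else "csv"
  if (format == "csv") .readTraceCsv(path) else .readTraceSwc(path)
}

.readTraceCsv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("timepoint", "y", "x")
  if (!all(need %in% names(df)))
    .stopf("trace CSV must have columns %s", paste(need, collapse = ","))
  out <- lapply(split(df, df$timepoint), function(g) {
    if (nrow(g) < 2L) .stopf("degenerate trace: timepoint %s has < 2 points",
                             g$timepoint[1L])
    TracePath(cbind(g$y, g$x), timepointIndex = g$timepoint[1L])
  })
  out[order(as.integer(names(out)))]
}

.readTraceSwc <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  if (length(ln) < 2L) .stopf("degenerate trace: SWC has < 2 points")
  m <- do.call(rbind, lapply(strsplit(trimws(ln), "\\s+"), as.numeric))
  colnames(m) <- c("id", "type", "x", "y", "z", "r", "parent")[seq_len(ncol(m))]
  parent <- m[, "parent"]
  kids <- table(parent[parent != -1])
  if (any(kids > 1L)) .stopf("non-linear trace: SWC contains a branch node")
  root <- m[parent == -1, "id"]
  if (length(root) != 1L) .stopf("non-linear trace: SWC must have exactly one root")
  ord <- integer(nrow(m)); ord[1L] <- which(m[, "id"] == root)
  childOf <- match(m[, "id"], m[, "parent"])  # row whose parent is id i
  for (i in seq_len(nrow(m) - 1L)) {
    nxt <- childOf[ord[i]]
    if (is.na(nxt)) .stopf("non-linear trace: broken parent chain")
    ord[i + 1L] <- nxt
  }
  TracePath(cbind(m[ord, "y"], m[ord, "x"]), timepointIndex = 1L)
}

#' Write traces to the package's CSV dialect
#'
#' @param traces a \linkS4class{TracePath} or list of them.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeTrace <- function(traces, path) {
  if (is(traces, "TracePath")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr) {
    p <- tracePoints(tr)
    data.frame(timepoint = timepointIndex(tr), y = p[, 1L], x = p[, 2L])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read nucleotide records from FASTA
#'
#' @param path FASTA file.
#' @param normalizeU replace U with T (both cases)?  Off by default; the
#'   zipcode scanner normalizes internally.
#' @return named character vector of sequences (names = record ids).
#' @export
readFastaRecords <- function(path, normalizeU = FALSE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) .stopf("empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    .warnf("duplicate FASTA ids (%s); all records kept",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  if (normalizeU) seqs <- chartr("Uu", "Tt", seqs)
  stats::setNames(seqs, ids)
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFastaRecords <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}
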