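# Streamline I/O: MRtrix TCK (the tractography interchange format the
# pipeline targets) plus a documented whitespace text fallback for fixtures.
#
# TCK layout: a text header starting "mrtrix tracks", "key: value" lines
# (datatype, count, file: . <offset>), an END line, then binary float triplets
# in world mm; streamlines are separated by a NaN triplet and the stream is
# terminated by an Inf triplet.

#' Read streamlines
#'
#' Reads a TCK file, or the plain-text fallback (one `x y z` point per line,
#' streamlines separated by blank lines, `#` comments) for any other
#' extension. Points are world mm.
#'
#' @param path input file.
#' @return a [StreamlineSet].
#' @export
readStreamlines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.tck$", path, ignore.case = TRUE)) .readTck(path)
  else .readStreamlineText(path)
}

#' Write streamlines
#'
#' TCK for `.tck` paths (Float32LE), text fallback otherwise. Round trips
#' preserve points to well under 1e-4 mm.
#'
#' @param set a [StreamlineSet].
#' @param path output file.
#' @export
writeStreamlines <- function(set, path) {
  stopifnot(is(set, "StreamlineSet"))
  if (grepl("\\.tck$", path, ignore.case = TRUE)) .writeTck(set, path)
  else .writeStreamlineText(set, path)
  invisible(path)
}

.readTck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, 1)
  if (!identical(trimws(first), "mrtrix tracks"))
    stop("malformed TCK header (missing magic line) in ", path, call. = FALSE)
  fields <- list()
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln)) stop("malformed TCK header (no END) in ", path,
                          call. = FALSE)
    if (identical(trimws(ln), "END")) break
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) fields[[trimws(kv[2])]] <- trimws(kv[3])
  }
  datatype <- fields[["datatype"]] %||% "Float32LE"
  size <- if (grepl("64", datatype)) 8L else 4L
  endian <- if (grepl("BE$", datatype)) "big" else "little"
  off <- fields[["file"]]
  if (is.null(off)) stop("malformed TCK header (no file offset)",
                         call. = FALSE)
  offset <- as.integer(sub("^\\.\\s*", "", off))
  close(con); on.exit(NULL)
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", offset)
  vals <- readBin(con, "numeric", n = file.size(path), size = size,
                  endian = endian)
  if (length(vals) %% 3 != 0)
    stop("truncated TCK stream in ", path, call. = FALSE)
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  streamlines <- list()
  cur <- 1L
  i <- 1L
  nr <- nrow(pts)
  while (i <= nr) {
    if (all(is.infinite(pts[i, ]))) break
    if (all(is.nan(pts[i, ]))) {
      if (i > cur)
        streamlines[[length(streamlines) + 1L]] <- pts[cur:(i - 1L), ,
                                                       drop = FALSE]
      cur <- i + 1L
    }
    i <- i + 1L
  }
  if (i > nr)
    stop("truncated TCK stream (no terminator) in ", path, call. = FALSE)
  StreamlineSet(streamlines, provenance = paste0("tck:", basename(path)))
}

.writeTck <- function(set, path) {
  body <- c("mrtrix tracks", "datatype: Float32LE",
            paste0("count: ", length(set@streamlines)))
  # the offset line includes its own length; fixed-width keeps it stable
  offsetLine <- function(n) sprintf("file: . %d", n)
  n0 <- sum(nchar(body)) + length(body) + nchar("END") + 2 # newlines
  off <- n0  # fixed point: offset digits may change the header length
  repeat {
    newoff <- n0 + nchar(offsetLine(off))
    if (newoff == off) break
    off <- newoff
  }
  header <- paste0(paste(c(body, offsetLine(off), "END"), collapse = "\n"),
                   "\n")
  stopifnot(nchar(header) == off)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  for (s in set@streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

.readStreamlineText <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[!startsWith(lines, "#")]
  streamlines <- list()
  buf <- list()
  flush <- function() {
    if (length(buf))
      streamlines[[length(streamlines) + 1L]] <<-
        do.call(rbind, buf)
    buf <<- list()
  }
  for (ln in lines) {
    if (!nzchar(ln)) { flush(); next }
    v <- as.numeric(strsplit(ln, "\\s+")[[1]])
    if (length(v) != 3 || any(is.na(v)))
      stop("malformed streamline text line: '", ln, "'", call. = FALSE)
    buf[[length(buf) + 1L]] <- v
  }
  flush()
  StreamlineSet(streamlines, provenance = paste0("text:", basename(path)))
}

.writeStreamlineText <- function(set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# callosoplan streamlines: x y z per line, blank line between streamlines",
             con)
  for (s in set@streamlines) {
    writeLines(apply(s, 1, function(p)
      paste(formatC(p, format = "g", digits = 17), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
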