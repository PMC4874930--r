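# Minimal NRRD (nearly raw raster data) support: 3-D volumes, raw encoding,
# little-endian, axis-aligned space directions. Covers what PET label maps
# and uptake volumes need; detached headers, compression and oblique
# orientations are out of scope.

parse_nrrd_vector <- function(s) {
  s <- gsub("[()]", "", trimws(s))
  as.numeric(strsplit(s, ",")[[1]])
}

read_nrrd <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at the first blank line (\n\n); data block follows
  sep <- which(raw_all[-length(raw_all)] == as.raw(10L) &
               raw_all[-1] == as.raw(10L))
  if (length(sep) == 0)
    stop("read_nrrd: no header/data separator found in ", path)
  hdr_lines <- strsplit(rawToChar(raw_all[seq_len(sep[1] - 1)]), "\n",
                        fixed = TRUE)[[1]]
  data_raw <- raw_all[seq.int(sep[1] + 2, length(raw_all))]
  if (!grepl("^NRRD000", hdr_lines[1]))
    stop("not an NRRD file (bad magic): ", path)
  fields <- list()
  for (line in hdr_lines[-1]) {
    if (line == "" || grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) != 2) next
    fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  need <- function(key) {
    if (is.null(fields[[key]]))
      stop("read_nrrd: missing required header field '", key, "' in ", path)
    fields[[key]]
  }
  if (as.integer(need("dimension")) != 3L)
    stop("read_nrrd: only 3-D volumes are supported")
  sizes <- as.integer(strsplit(need("sizes"), "[ \t]+")[[1]])
  type <- need("type")
  enc <- need("encoding")
  if (enc != "raw")
    stop("read_nrrd: only raw encoding is supported, got '", enc, "'")
  if (is.null(fields[["space directions"]]))
    stop("read_nrrd: missing required header field 'space directions' in ",
         path)
  dirs <- regmatches(fields[["space directions"]],
                     gregexpr("\\([^)]*\\)", fields[["space directions"]]))[[1]]
  if (length(dirs) != 3)
    stop("read_nrrd: expected 3 space direction vectors")
  dmat <- vapply(dirs, parse_nrrd_vector, numeric(3))
  if (max(abs(dmat - diag(diag(dmat)))) > 1e-9 * max(abs(dmat)))
    stop("read_nrrd: oblique space directions are not supported: ", path)
  spacing <- diag(dmat)
  if (any(spacing <= 0))
    stop("read_nrrd: negative axis directions are not supported: ", path)
  origin <- if (!is.null(fields[["space origin"]]))
    parse_nrrd_vector(fields[["space origin"]]) else c(0, 0, 0)
  n <- prod(sizes)
  rtype <- switch(type,
    "double" = list(what = "double", size = 8),
    "float"  = list(what = "double", size = 4),
    "int" = , "signed int" = , "int32" = list(what = "integer", size = 4),
    "short" = , "int16" = list(what = "integer", size = 2),
    "unsigned short" = , "uint16" = list(what = "integer", size = 2,
                                         signed = FALSE),
    "unsigned char" = , "uchar" = , "uint8" = list(what = "integer", size = 1,
                                                   signed = FALSE),
    stop("read_nrrd: unsupported type '", type, "'"))
  endian <- if (!is.null(fields[["endian"]])) fields[["endian"]] else "little"
  if (length(data_raw) < n * rtype$size)
    stop("read_nrrd: truncated data block in ", path)
  vals <- readBin(data_raw, what = rtype$what, n = n, size = rtype$size,
                  signed = if (is.null(rtype$signed)) TRUE else rtype$signed,
                  endian = endian)
  if (length(vals) != n)
    stop("read_nrrd: truncated data block in ", path)
  list(data = array(vals, dim = sizes), spacing = spacing, origin = origin)
}

write_nrrd <- function(data, spacing, origin, path, integer_type = FALSE) {
  dm <- dim(data)
  stopifnot(length(dm) == 3L)
  fmt_vec <- function(v) paste0("(", paste(sprintf("%.17g", v), collapse = ","),
                                ")")
  hdr <- c(
    "NRRD0004",
    "# written by petoss",
    paste0("type: ", if (integer_type) "int" else "double"),
    "dimension: 3",
    paste0("sizes: ", paste(dm, collapse = " ")),
    "encoding: raw",
    "endian: little",
    "space dimension: 3",
    paste("space directions:",
          fmt_vec(c(spacing[1], 0, 0)),
          fmt_vec(c(0, spacing[2], 0)),
          fmt_vec(c(0, 0, spacing[3]))),
    paste0("space origin: ", fmt_vec(origin)),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL,
            useBytes = TRUE)
  if (integer_type) {
    writeBin(as.integer(data), con, size = 4, endian = "little")
  } else {
    writeBin(as.double(data), con, size = 8, endian = "little")
  }
  invisible(path)
}
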