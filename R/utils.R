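#' @keywords internal
"_PACKAGE"

# Shared validation helpers. All user-facing errors name the offending file,
# line or identifier so a failed pipeline run is diagnosable from the message.

msg <- function(...) message(sprintf(...))

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

warn2 <- function(...) warning(sprintf(...), call. = FALSE)

assert_file_exists <- function(path) {
  if (!file.exists(path)) stop2("input file does not exist: '%s'", path)
  invisible(path)
}

# Read a tab-separated table with one header line, skipping '#' comments.
# Returns a character data.frame; callers coerce columns as needed.
read_tsv_table <- function(path, n_cols_min = 2L) {
  assert_file_exists(path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop2("file '%s' has no header line", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  body_no <- line_no[-1L]
  if (length(body) == 0L) {
    out <- as.data.frame(matrix(character(0), ncol = length(header)),
                         stringsAsFactors = FALSE)
    names(out) <- header
    attr(out, "line_numbers") <- integer(0)
    return(out)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  lens <- lengths(parts)
  bad <- which(lens < n_cols_min)
  if (length(bad) > 0L) {
    stop2("malformed row in '%s' at line %d: expected >= %d tab-separated fields, found %d",
          path, body_no[bad[1L]], n_cols_min, lens[bad[1L]])
  }
  ncol_use <- max(lens)
  mat <- vapply(parts, function(p) c(p, rep(NA_character_, ncol_use - length(p))),
                character(ncol_use))
  out <- as.data.frame(t(matrix(mat, nrow = ncol_use)), stringsAsFactors = FALSE)
  names(out) <- c(header, paste0("V", seq_len(max(0L, ncol_use - length(header)))))[seq_len(ncol_use)]
  attr(out, "line_numbers") <- body_no
  out
}

# deterministic ordering used by every writer
order_chr <- function(...) order(..., method = "radix")
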