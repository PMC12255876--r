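# Internal helpers shared across modules.

.datatable.aware <- TRUE

# Typed conditions: the service layer maps these onto HTTP status codes
# (unknown-name / constraint errors -> 400, snapshot and config errors -> 500).
stop_onehop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "onehop_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' @importFrom stats median setNames
#' @importFrom utils head tail
NULL

# Biolink-style names are accepted with or without the "biolink:" prefix and
# compared case-sensitively on the bare form.
norm_name <- function(x) {
  if (is.null(x) || length(x) == 0L) return(character(0))
  sub("^biolink:", "", as.character(x))
}

emit_name <- function(x) {
  if (length(x) == 0L) return(character(0))
  paste0("biolink:", norm_name(x))
}

is_curie <- function(x) {
  nzchar(x) & grepl(":", x, fixed = TRUE)
}

# Scalar coalesce for optional list fields.
`%||%` <- function(a, b) if (is.null(a)) b else a

# A ring-buffer-ish structured log kept in an environment; the /logs endpoint
# returns its tail, never raw files.
new_log <- function(capacity = 2000L) {
  env <- new.env(parent = emptyenv())
  env$lines <- character(0)
  env$capacity <- capacity
  env
}

log_msg <- function(log, level, msg, ...) {
  if (is.null(log)) return(invisible(NULL))
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  level, sprintf(msg, ...))
  log$lines <- c(log$lines, line)
  n <- length(log$lines)
  if (n > log$capacity) log$lines <- log$lines[(n - log$capacity + 1L):n]
  invisible(line)
}

log_tail <- function(log, k = 500L) {
  n <- length(log$lines)
  if (n == 0L) return(character(0))
  log$lines[max(1L, n - k + 1L):n]
}

# Deterministic ordering for character keys regardless of user locale.
sort_c <- function(x) {
  if (length(x) == 0L) return(character(0))
  sort(x, method = "radix")
}

# Stable sha1-based id for edges lacking one in the source file.
synth_edge_id <- function(subject, predicate, object, source) {
  vapply(paste(subject, predicate, object, source, sep = "\x1f"),
         function(s) substr(digest::digest(s, algo = "sha1", serialize = FALSE), 1L, 16L),
         character(1), USE.NAMES = FALSE)
}
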