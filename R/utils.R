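#' Read a plain-text key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and
#' blank lines ignored. Values that parse as numbers are returned
#' numeric, `true`/`false` as logical, everything else as character.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3L) stop("unparseable config line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
    else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
    else val
  }
  out
}

# keep only the entries of cfg that name formals of fn
config_args <- function(cfg, fn) cfg[intersect(names(cfg), names(formals(fn)))]

# run code with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}
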