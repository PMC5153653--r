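# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stopf("`%s` must be a single number in [%s, %s]", name,
          format(lower), format(upper))
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  assert_number(x, name, lower = lower)
  if (x != as.integer(x)) stopf("`%s` must be an integer", name)
  invisible(as.integer(x))
}

# normalize the Greek omega so fatty-acid names can be written either way
normalize_fa_names <- function(x) gsub("\u03c9", "w", x)

# tiny rolling hash over a deparsed object; used only for provenance headers
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%010.0f", h)
}
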