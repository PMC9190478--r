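# internal helpers shared across modules

# uppercase, trim, drop empties/NA; gene symbols are compared
# case-insensitively everywhere in the package
norm_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- x[!is.na(x) & nzchar(x)]
  x
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min)
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stopf("`%s` must be a single number in [0, 1]", name)
  as.numeric(x)
}

read_symbol_list <- function(path) {
  norm_symbols(readLines(path, warn = FALSE))
}

write_symbol_list <- function(x, path) {
  writeLines(norm_symbols(x), path)
  invisible(path)
}
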