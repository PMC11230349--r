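# internal helpers

# Run code with a temporary RNG state so package functions are deterministic
# given `seed` without clobbering the caller's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Detect comma vs tab delimiter from the first line of a file.
detect_sep <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) == 0L) stop("empty file: ", path)
  n_tab <- lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE)))
  n_com <- lengths(regmatches(line, gregexpr(",", line, fixed = TRUE)))
  if (n_tab >= n_com && n_tab > 0L) "\t" else if (n_com > 0L) "," else "\t"
}

# 15-significant-digit formatting shared by all writers (diff-able, lossless
# round trip for values that were themselves read from this format).
fmt_num <- function(x) sprintf("%.15g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
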