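# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is untouched. All stochastic package code funnels through this so a
# single integer seed pins every draw.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seed from a parent seed and a stream label, kept within
# 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":", seed))) {
    h <- (h * 31 + ch) %% 2147483563
  }
  as.integer(h + 1L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_mcv <- function(msg, class) {
  rlang::abort(msg, class = c(class, "mcvbmd_error"))
}

assert_same_shape <- function(a, b, what = "inputs") {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db))) {
    stop_mcv(
      sprintf("%s must share a grid shape (%s vs %s)", what,
              paste(da, collapse = "x"), paste(db, collapse = "x")),
      "mcv_shape_error"
    )
  }
  invisible(TRUE)
}

is_binary_array <- function(x) {
  all(x == 0 | x == 1)
}

# MD5 of an R object via its serialized bytes (base tools only).
object_hash <- function(x) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf), add = TRUE)
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}
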