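# internal helpers shared across modules

# run `code` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic 31-bit sub-seed derived from a master seed and integer keys
derive_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  h <- 0
  for (k in keys) h <- (h * 69069 + (as.numeric(k) %% 2147483647)) %% 2147483647
  as.integer(h %% 2147483629L + 1L)
}

# convert a sample mask string over {'1','0','9'} to a logical in-cluster vector
mask_to_logical <- function(mask) {
  strsplit(mask, "", fixed = TRUE)[[1]] == "1"
}

mask_chars <- function(mask) strsplit(mask, "", fixed = TRUE)[[1]]

# canonical edge key used across modules
edge_key <- function(gene_a, gene_b, cluster_index) {
  paste(gene_a, gene_b, cluster_index, sep = "|")
}

assert_that <- function(ok, msg) {
  if (!ok) stop(msg, call. = FALSE)
  invisible(TRUE)
}
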