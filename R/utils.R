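# internal helpers shared across modules

# Run expr with a temporarily-seeded RNG, restoring any prior state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a reproducible sub-seed below 2^31 from a master seed and a tag,
# so pipeline stages (generator, folds, learner inits, shuffles) are
# independently reproducible from one master seed.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 12345) %% 2147483629L)
}

# Centered rolling maximum with window w (odd effective span), O(n) van
# Herk/Gil-Werman two-pass scheme; used by the adaptive R-peak threshold.
rolling_max <- function(x, w) {
  n <- length(x)
  if (w >= n) return(rep(max(x), n))
  half <- w %/% 2
  xp <- c(rep(-Inf, half), x, rep(-Inf, half))
  np <- length(xp)
  k <- 2L * half + 1L
  nblk <- ceiling(np / k)
  pad <- nblk * k - np
  xp <- c(xp, rep(-Inf, pad))
  m <- matrix(xp, nrow = k)
  fwd <- apply(m, 2, cummax)
  bwd <- apply(m[k:1, , drop = FALSE], 2, cummax)[k:1, , drop = FALSE]
  fwd <- as.vector(fwd); bwd <- as.vector(bwd)
  # window centred at original i spans padded [i, i + k - 1]
  pmax(bwd[seq_len(n)], fwd[seq_len(n) + k - 1L])
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# md5 of a canonical JSON rendering; used as the pipeline config hash so
# artifacts from different configurations are never mixed.
config_hash <- function(x) {
  strip_classes <- function(v) {
    if (is.list(v)) {
      v <- lapply(v, strip_classes)
      class(v) <- NULL
      v
    } else unclass(v)
  }
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(strip_classes(x), f, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(f))
}
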