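#' Derive a reproducible per-item seed from a master seed
#'
#' Deterministically hashes the master seed together with any number of key
#' strings (condition id, modality, replicate...) into an integer seed below
#' 2^31. Adding new conditions to an experiment therefore never perturbs the
#' seeds, and hence the outputs, of existing items.
#'
#' @param master_seed Integer master seed.
#' @param ... Character or numeric keys identifying the item.
#' @return A single integer seed in `[1, 2147483562]`.
#' @export
derive_seed <- function(master_seed, ...) {
  keys <- paste(vapply(list(...), function(k) paste(format(k), collapse = "|"),
                       character(1)), collapse = "/")
  M <- 2147483563
  h <- as.numeric(master_seed) %% M
  for (code in utf8ToInt(keys)) h <- (h * 131 + code) %% M
  as.integer(h) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# mean-one multiplicative lognormal draws with coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
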