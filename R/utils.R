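# Internal helpers: seeded evaluation, parameter-tree algebra, Adam.

# Evaluate `expr` under a private RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one parent seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# ---- parameter trees -------------------------------------------------------
# Model parameters are nested named lists whose leaves are numeric arrays.

ptree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) ptree_map(f, e)) else f(x)
}

ptree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- ptree_map2(f, x[[i]], y[[i]])
    out
  } else f(x, y)
}

ptree_leaves <- function(x) {
  if (is.list(x)) unlist(lapply(x, ptree_leaves), use.names = FALSE) else list(x)
}

ptree_sqnorm <- function(x) {
  if (is.list(x)) sum(vapply(x, ptree_sqnorm, numeric(1))) else sum(x^2)
}

ptree_zeros_like <- function(x) ptree_map(function(v) v * 0, x)

ptree_add <- function(x, y) ptree_map2(`+`, x, y)

ptree_scale <- function(x, s) ptree_map(function(v) v * s, x)

# Rescale a gradient tree so its global L2 norm is at most `max_norm`.
clip_global_norm <- function(grads, max_norm) {
  nrm <- sqrt(ptree_sqnorm(grads))
  if (is.finite(nrm) && nrm > max_norm) ptree_scale(grads, max_norm / nrm) else grads
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = ptree_zeros_like(params), v = ptree_zeros_like(params),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  opt$m <- ptree_map2(function(m, g) opt$beta1 * m + (1 - opt$beta1) * g, opt$m, grads)
  opt$v <- ptree_map2(function(v, g) opt$beta2 * v + (1 - opt$beta2) * g^2, opt$v, grads)
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  step <- ptree_map2(function(m, v) opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps),
                     opt$m, opt$v)
  list(params = ptree_map2(`-`, params, step), opt = opt)
}

# Plain SGD step (used by the inner adaptation loop).
sgd_step <- function(params, grads, lr) {
  ptree_map2(function(p, g) p - lr * g, params, grads)
}
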