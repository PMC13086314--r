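# Weight initialisation and seeded-RNG helpers.

# Evaluate `code` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(as.double(seed) %% 2147483629))
  force(code)
}

# He (Kaiming) normal initialisation for a conv weight (Cout, Cin, KH, KW).
he_conv <- function(cout, cin, kh, kw = kh) {
  fan_in <- cin * kh * kw
  array(stats::rnorm(cout * cin * kh * kw, 0, sqrt(2 / fan_in)),
        c(cout, cin, kh, kw))
}

# Truncated-normal initialisation (resampled beyond 2 sd), for linear and
# attention weights.
trunc_normal <- function(dims, sd = 0.02) {
  n <- prod(dims)
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  array(x, dims)
}

new_conv <- function(cin, cout, k, bias = FALSE) {
  p <- list(w = nn_parameter(he_conv(cout, cin, k, k)))
  if (bias) p$b <- nn_parameter(rep(0, cout))
  p
}

new_bn <- function(channels) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- rep(0, channels)
  st$running_var <- rep(1, channels)
  list(g = nn_parameter(rep(1, channels)),
       b = nn_parameter(rep(0, channels)),
       state = st)
}

new_linear <- function(cin, cout, sd = 0.02) {
  list(w = nn_parameter(trunc_normal(c(cin, cout), sd)),
       b = nn_parameter(rep(0, cout)))
}

# Collect every trainable parameter node in a nested structure, with
# dot-separated path names (used by the optimizer and the checkpoint format).
flatten_params <- function(x, prefix = "") {
  if (is.environment(x) && isTRUE(x$param)) {
    out <- list(x)
    names(out) <- prefix
    return(out)
  }
  if (is.list(x)) {
    out <- list()
    nm <- names(x) %||% as.character(seq_along(x))
    for (i in seq_along(x)) {
      child <- flatten_params(x[[i]],
        if (prefix == "") nm[i] else paste(prefix, nm[i], sep = "."))
      out <- c(out, child)
    }
    return(out)
  }
  list()
}

# Collect batch-norm running-stat environments, with path names.
flatten_states <- function(x, prefix = "") {
  if (is.environment(x) && !is.null(x$running_mean)) {
    out <- list(x)
    names(out) <- prefix
    return(out)
  }
  if (is.list(x)) {
    out <- list()
    nm <- names(x) %||% as.character(seq_along(x))
    for (i in seq_along(x)) {
      out <- c(out, flatten_states(x[[i]],
        if (prefix == "") nm[i] else paste(prefix, nm[i], sep = ".")))
    }
    return(out)
  }
  list()
}
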