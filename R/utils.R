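## Small internal helpers shared across modules.

## log(sum(exp(x))) without overflow; x may contain -Inf.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Row-wise logsumexp for a matrix (rows = observations).
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- mx[!is.finite(mx)]
  out
}

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

## Timestamped structured log line.  `code` is a machine-readable reason
## code used for exclusion logging throughout the package.
log_msg <- function(code, msg, file = NULL) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  code, msg)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE, sep = "")
  message(line)
  invisible(line)
}

## Central-difference gradient, step h on each coordinate.
num_grad <- function(f, x, h = 1e-5, ...) {
  p <- length(x)
  g <- numeric(p)
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- h
    g[j] <- (f(x + e, ...) - f(x - e, ...)) / (2 * h)
  }
  g
}

## Central-difference Hessian of a scalar function.
num_hessian <- function(f, x, h = 1e-4, ...) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x, ...)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h
    H[i, i] <- (f(x + ei, ...) - 2 * f0 + f(x - ei, ...)) / h^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- numeric(p); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej, ...) - f(x + ei - ej, ...) -
         f(x - ei + ej, ...) + f(x - ei - ej, ...)) / (4 * h^2)
    }
  }
  (H + t(H)) / 2
}
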