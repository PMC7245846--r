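#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif median cor.test quantile
#' @importFrom utils write.csv read.csv packageVersion
#' @importFrom randomForest randomForest
#' @importFrom rpart rpart rpart.control
NULL

# round half up: round(0.5) in base R rounds to even, which would make the
# byte-conversion contract platform-ambiguous at .5 boundaries
round_half_up <- function(x) floor(x + 0.5)

# clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# FNV-1a 32-bit hash over the serialized (deparsed) form of an R object;
# used to stamp model files and run logs with a stable config fingerprint
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256); h may exceed .Machine$integer.max
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619; split into
    # 16-bit halves to stay within exact double arithmetic
    hi <- floor(h / 65536); lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 4294967296
  }
  paste0(format(as.hexmode(floor(h / 65536)), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

# evaluate `expr` under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
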