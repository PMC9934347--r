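## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate expr under a local RNG state seeded with `seed`, restoring the
## caller's RNG afterwards. seed = NULL leaves the RNG alone.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Integer-pixel translation of a matrix: content moves dy rows down and dx
## columns right; exposed pixels take `fill`.
shiftMatrix <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  srcR <- seq_len(nr) - dy
  srcC <- seq_len(nc) - dx
  okR <- srcR >= 1L & srcR <= nr
  okC <- srcC >= 1L & srcC <= nc
  if (any(okR) && any(okC))
    out[which(okR), which(okC)] <- m[srcR[okR], srcC[okC], drop = FALSE]
  out
}

## In-frame mask after translating by (dy, dx): TRUE where the translated
## image carries original content rather than fill.
shiftValidMask <- function(nr, nc, dy, dx) {
  v <- matrix(FALSE, nr, nc)
  rows <- intersect(seq_len(nr), seq_len(nr) + dy)
  cols <- intersect(seq_len(nc), seq_len(nc) + dx)
  if (length(rows) && length(cols)) v[rows, cols] <- TRUE
  v
}

## FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used only to
## fingerprint configurations in run manifests.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- bitwXor(h %% 2147483648, b) + (h >= 2147483648) * 2147483648
    ## 32-bit modular multiply, split to stay within double precision
    hi <- floor(h / 65536); lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}
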