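## Internal utilities: deterministic hashing, scoped RNG, argument checks.

## 32-bit multiplicative string/int-sequence hash (Java-style, base 31),
## implemented in doubles; all intermediates stay < 2^37 so exact in IEEE754.
.hash32 <- function(ints) {
  h <- 17
  for (x in ints) {
    h <- (h * 31 + (x %% 4294967296)) %% 4294967296
  }
  h
}

.hashString <- function(s) {
  .hash32(utf8ToInt(s))
}

## Hash a character vector deterministically (order-sensitive).
.hashStrings <- function(v) {
  h <- 17
  for (s in v) h <- (h * 31 + .hashString(s)) %% 4294967296
  h
}

## Evaluate `expr` under a fixed seed without clobbering the caller's RNG.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a base seed and a stream label; stays < 2^31.
.deriveSeed <- function(seed, label) {
  as.integer((.hash32(c(seed, utf8ToInt(label)))) %% 2147483647L)
}

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}

.assertBinaryVector <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || any(!(x %in% c(0, 1)))) {
    bad <- which(!(x %in% c(0, 1)))[1]
    stop(sprintf("'%s' must be a 0/1 vector (offending position %s)",
                 name, ifelse(length(x) < 1L, "none: empty", bad)),
         call. = FALSE)
  }
}

## Pearson correlation that tolerates zero-variance inputs by returning NA
## (plain stats::cor warns); callers decide how to treat NA.
.safeCor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}
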