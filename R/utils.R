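#' @keywords internal
"_PACKAGE"

# Derive a reproducible sub-stream seed for one artifact so modules can be
# regenerated independently from the master seed. Kept below 2^31 - 1.
sub_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 131 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# Population (n) or sample (n-1) standard deviation.
sd2 <- function(x, type = c("population", "sample")) {
  type <- match.arg(type)
  if (type == "sample") return(stats::sd(x))
  sqrt(mean((x - mean(x))^2))
}
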