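## Grouped scan helpers for panels sorted by (subject, quarter).
## `gstart` holds the first row index of each subject's block.

## Cumulative product within groups; exact zeros propagate (absorbing).
grp_cumprod <- function(x, gstart, glen) {
  .grp_cumprod(as.numeric(x), as.integer(gstart), FALSE)
}

## Lagged within-group cumulative product: the value carried into the next
## quarter (first quarter of each subject gets 1).
grp_cumprod_lag <- function(x, gstart, glen) {
  .grp_cumprod(as.numeric(x), as.integer(gstart), TRUE)
}

## One-step lag within groups (value carried into the next quarter).
grp_lag <- function(x, gstart, fill = 1) {
  n <- length(x)
  if (!n) return(x)
  out <- c(fill, x[-n])
  out[gstart] <- fill
  out
}

## Sum `x` by integer quarter `tq` onto a fixed grid 1..Tq.
sum_by_quarter <- function(x, tq, Tq) {
  if (!length(x)) return(numeric(Tq))
  .sum_by_q(as.numeric(x), as.integer(tq), as.integer(Tq))
}

## Deterministic hash of an R object (ascii serialization -> md5).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, ascii = TRUE, compress = FALSE)
  unname(tools::md5sum(f))
}
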