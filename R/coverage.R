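#' Expand dispensing records into day-level coverage
#'
#' Applies each dispensing record of one subject in order of start day to
#' build the day-level coverage calendar, with the stockpiling and
#' precedence rules:
#'
#' * if a record starts while 30 or fewer covered days remain from the prior
#'   supply, the remaining days are kept and the new supply is appended
#'   after the prior supply ends (stockpiling);
#' * if more than 30 covered days remain, the second prescription takes
#'   precedence: coverage runs from the new record's start for its days'
#'   supply and the earlier prescription's surplus beyond that is discarded
#'   (days already elapsed before the new start stay covered);
#' * coverage is clipped at `horizon_days`.
#'
#' Day 0 is the index date; quarter `t` is the half-open day interval
#' `[90(t-1), 90t)`.
#'
#' @param records a `data.frame`/`data.table` with columns `start_day`
#'   (integer, >= 0) and `days_supply` (integer, >= 1) for a single subject
#'   (a `subject_id` column, if present, must be constant).
#' @param horizon_days length of follow-up in days (>= 1).
#' @return an object of class `coverage_calendar`: a list with `covered`
#'   (logical vector of length `horizon_days`; `covered[d + 1]` refers to
#'   day `d`), `blocks` (two-column matrix of half-open covered intervals
#'   before clipping), and `horizon_days`.
#' @export
#' @examples
#' cal <- expand_daily_coverage(
#'   data.frame(start_day = c(0, 70), days_supply = c(90, 90)), 360)
#' sum(cal$covered)  # 180: the 20-day overlap is stockpiled
expand_daily_coverage <- function(records, horizon_days) {
  stopifnot(horizon_days >= 1)
  records <- as.data.frame(records)
  if ("subject_id" %in% names(records) &&
      length(unique(records$subject_id)) > 1L) {
    stop("expand_daily_coverage works on one subject's records", call. = FALSE)
  }
  s <- records$start_day
  ds <- records$days_supply
  if (length(s) && (any(s < 0) || any(ds < 1) || anyNA(s) || anyNA(ds))) {
    stop("invalid record: start_day must be >= 0 and days_supply >= 1",
         call. = FALSE)
  }
  blocks <- coverage_blocks(s, ds)
  covered <- rep(FALSE, horizon_days)
  if (nrow(blocks)) {
    for (i in seq_len(nrow(blocks))) {
      a <- max(blocks[i, 1L], 0L) + 1L
      b <- min(blocks[i, 2L], horizon_days)
      if (a <= b) covered[a:b] <- TRUE
    }
  }
  structure(list(covered = covered, blocks = blocks,
                 horizon_days = as.integer(horizon_days)),
            class = "coverage_calendar")
}

## Sequential block construction shared by the calendar and the fast
## per-quarter counter.  Returns a matrix of half-open [start, end) covered
## intervals.  Blocks are disjoint and ordered; only the last block can
## interact with a new record because records are processed by start day.
coverage_blocks <- function(start_day, days_supply) {
  o <- order(start_day)
  s <- as.numeric(start_day[o])
  ds <- as.numeric(days_supply[o])
  n <- length(s)
  if (!n) return(matrix(numeric(0), ncol = 2L))
  bs <- numeric(n); be <- numeric(n); k <- 1L
  bs[1L] <- s[1L]; be[1L] <- s[1L] + ds[1L]
  if (n > 1L) {
    for (i in 2L:n) {
      if (s[i] >= be[k]) {                # gap: start a new block
        k <- k + 1L
        bs[k] <- s[i]; be[k] <- s[i] + ds[i]
      } else if (be[k] - s[i] <= 30) {    # stockpile: append after prior end
        be[k] <- be[k] + ds[i]
      } else {                            # precedence: run from new start,
        be[k] <- s[i] + ds[i]             # discard the earlier surplus
      }
    }
  }
  cbind(start = bs[seq_len(k)], end = be[seq_len(k)])
}

## Covered days per quarter (1..n_quarters) for one subject, from blocks.
quarter_covered_days <- function(blocks, n_quarters) {
  out <- numeric(n_quarters)
  if (!nrow(blocks)) return(out)
  for (i in seq_len(nrow(blocks))) {
    a <- blocks[i, 1L]; bnd <- blocks[i, 2L]
    q1 <- max(1L, floor(a / 90) + 1L)
    q2 <- min(n_quarters, ceiling(bnd / 90))
    if (q1 > q2) next
    for (q in q1:q2) {
      lo <- 90 * (q - 1L); hi <- 90 * q
      out[q] <- out[q] + max(0, min(bnd, hi) - max(a, lo))
    }
  }
  out
}

#' Proportion of days covered in a quarter
#'
#' @param calendar a `coverage_calendar` from [expand_daily_coverage()].
#' @param t quarter index (1-based); quarter `t` spans days
#'   `[90(t-1), 90t)`.
#' @return covered days in the window divided by 90.
#' @export
quarter_pdc <- function(calendar, t) {
  stopifnot(inherits(calendar, "coverage_calendar"))
  if (length(t) != 1L || is.na(t) || t < 1L) {
    stop("quarter index must be >= 1", call. = FALSE)
  }
  if (90 * t > calendar$horizon_days) {
    stop("quarter ", t, " lies beyond the coverage horizon", call. = FALSE)
  }
  sum(calendar$covered[(90 * (t - 1L) + 1L):(90 * t)]) / 90
}

#' Classify a quarter as on treatment from its PDC
#'
#' A quarter counts as on treatment when at least half of its 90 days are
#' covered, i.e. PDC of 0.50 or greater.
#'
#' @param pdc proportion of days covered, in `[0, 1]`.
#' @return logical vector, `TRUE` where `pdc >= 0.5`.
#' @export
classify_on_treatment <- function(pdc) {
  if (anyNA(pdc) || any(pdc < 0) || any(pdc > 1)) {
    stop("pdc must lie in [0, 1]", call. = FALSE)
  }
  pdc >= 0.5
}
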