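# Internal helpers shared across modules.

# Parse timestamps to numeric seconds since epoch (UTC). Accepts numeric
# (already seconds), ISO-8601 date-times, or plain dates (midnight).
parse_time <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (inherits(x, "POSIXt")) return(as.numeric(x))
  if (inherits(x, "Date")) return(as.numeric(as.POSIXct(as.character(x), tz = "UTC")))
  x_chr <- as.character(x)
  out <- rep(NA_real_, length(x_chr))
  num <- suppressWarnings(as.numeric(x_chr))
  is_num <- !is.na(num) & grepl("^\\s*-?[0-9.]+\\s*$", x_chr)
  out[is_num] <- num[is_num]
  rest <- !is_num & !is.na(x_chr)
  if (any(rest)) {
    p <- suppressWarnings(readr::parse_datetime(x_chr[rest]))
    dates_only <- is.na(p)
    if (any(dates_only)) {
      d <- suppressWarnings(readr::parse_date(x_chr[rest][dates_only]))
      p[dates_only] <- as.POSIXct(d, tz = "UTC")
    }
    out[rest] <- as.numeric(p)
  }
  out
}

# Seconds since epoch for a calendar date (UTC midnight).
date_seconds <- function(date) {
  as.numeric(as.POSIXct(as.character(as.Date(date)), tz = "UTC"))
}

DAY <- 86400

# Canonical unordered dyad ordering: id_a < id_b lexicographically.
order_dyad <- function(a, b) {
  swap <- a > b
  tibble::tibble(id_a = ifelse(swap, b, a), id_b = ifelse(swap, a, b))
}

# Sample-mode of a continuous vector via the half-sample mode estimator
# (recursively halves the sample to the densest half); deterministic.
half_sample_mode <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) return(NA_real_)
  while (n > 3) {
    h <- ceiling(n / 2)
    widths <- x[(h + 1):n] - x[1:(n - h)]
    i <- which.min(widths)
    x <- x[i:(i + h)]
    n <- length(x)
  }
  if (n == 3) {
    # densest pair among the three
    if (x[2] - x[1] <= x[3] - x[2]) mean(x[1:2]) else mean(x[2:3])
  } else {
    mean(x)
  }
}

# Mode of an integer-valued vector: most frequent value, smallest on ties.
integer_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

# Posterior point summary: kernel-density maximizer over retained samples.
posterior_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || stats::sd(x) == 0) return(x[1])
  d <- stats::density(x)
  d$x[which.max(d$y)]
}

check_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(glue::glue("`{name}` must be a single finite number"))
  }
  if (strict_min && x <= min) abort(glue::glue("`{name}` must be > {min}"))
  if (!strict_min && x < min) abort(glue::glue("`{name}` must be >= {min}"))
  invisible(x)
}
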