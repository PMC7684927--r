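# independent brute-force oracles, kept deliberately naive (explicit loops,
# explicit window enumeration) and separate from the package implementation

# UO staging by enumerating every trailing window at every hour
oracle_stage_uo <- function(rates, rules = staging_rules()) {
  n <- nrow(rates)
  x <- rates$rate_ml_kg_h
  ml <- rates$ml_per_h
  miss <- rates$missing
  stage <- rep(NA_integer_, n)
  for (h in seq_len(n)) {
    win <- function(w) {
      if (h < w) return(NULL)
      idx <- (h - w + 1):h
      if (any(miss[idx])) return(NULL)
      idx
    }
    s <- NA_integer_
    i6 <- win(rules$uo_stage1_window)
    if (!is.null(i6)) {
      s <- 0L
      # the staging contract compares window means with a 1e-9 guard: a mean
      # exactly at the threshold is not below it
      if (mean(x[i6]) < rules$uo_stage1_rate - 1e-9) s <- 1L
      i12 <- win(rules$uo_stage2_window)
      if (!is.null(i12) && mean(x[i12]) < rules$uo_stage2_rate - 1e-9) s <- 2L
      i24 <- win(rules$uo_stage3_window)
      if (!is.null(i24) && mean(x[i24]) < rules$uo_stage3_rate - 1e-9) s <- 3L
    }
    ia <- win(rules$anuria_window)
    if (!is.null(ia) && all(ml[ia] < rules$anuria_ml_per_h)) s <- 3L
    stage[h] <- s
  }
  keep <- which(!is.na(stage))
  if (length(keep) == 0) {
    return(tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                          stage = integer()))
  }
  st <- stage[keep]
  emit <- c(TRUE, st[-1] != st[-length(st)])
  tibble::tibble(timestamp = rates$time_end[keep[emit]],
                 stage = st[emit])
}

# discrete product-limit estimate by explicit daily bookkeeping
oracle_km <- function(time, event, max_day) {
  surv <- 1
  out <- data.frame(day = integer(), n_at_risk = integer(),
                    n_events = integer(), survival = numeric())
  for (d in seq_len(max_day)) {
    r <- sum(time >= d)
    e <- sum(time == d & event)
    if (r > 0) surv <- surv * (1 - e / r)
    out <- rbind(out, data.frame(day = d, n_at_risk = r, n_events = e,
                                 survival = surv))
  }
  out
}

# exact two-sided p under the pooled binomial null, full enumeration
oracle_exact_two_prop <- function(x1, n1, x2, n2) {
  pp <- (x1 + x2) / (n1 + n2)
  obs <- abs(x1 / n1 - x2 / n2)
  p1 <- stats::dbinom(0:n1, n1, pp)
  p2 <- stats::dbinom(0:n2, n2, pp)
  d <- abs(outer(0:n1, 0:n2, function(a, b) a / n1 - b / n2))
  sum(outer(p1, p2) * (d >= obs - 1e-12))
}

# daily maximum stage by explicit window scan over an evaluation series
oracle_daily_max <- function(series, t0, los_h, n_days = 5) {
  out <- rep(NA_integer_, n_days)
  for (k in seq_len(n_days)) {
    if ((k - 1) * 24 >= los_h) break
    w0 <- t0 + (k - 1) * 86400
    w1 <- t0 + k * 86400
    vals <- series$stage[series$timestamp >= w0 & series$timestamp < w1]
    prior <- series$stage[series$timestamp <= w0]
    if (length(prior)) vals <- c(vals, prior[length(prior)])
    if (length(vals)) out[k] <- max(vals)
  }
  out
}
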