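# Independent brute-force oracles, kept mechanically distinct from the
# package implementations they cross-check.

# strict local minima of a daily vector by direct index scanning; a minimum
# plateau is reported at its first day
oracle_segment_bounds <- function(v) {
  n <- length(v)
  mins <- integer()
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    if (j < n && v[i - 1L] > v[i] && v[j + 1L] > v[i]) mins <- c(mins, i)
    i <- j + 1L
  }
  unique(c(1L, mins, n))
}

oracle_cycles <- function(d, v, rise = 0.5) {
  b <- oracle_segment_bounds(v)
  out <- list()
  cur <- NULL
  for (k in seq_len(length(b) - 1L)) {
    a <- b[k]; bb <- b[k + 1L]
    pk <- a - 1L + which.max(v[a:bb])
    if (v[pk] - v[a] >= rise) {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- c(a, bb)
    } else if (!is.null(cur) && cur[2] == a && v[a] > v[cur[1]]) {
      cur[2] <- bb
    }
  }
  if (!is.null(cur)) out[[length(out) + 1L]] <- cur
  do.call(rbind, lapply(out, function(ab) {
    pk <- ab[1] - 1L + which.max(v[ab[1]:ab[2]])
    data.frame(t1 = d[ab[1]], t2 = d[pk], t3 = d[ab[2]])
  }))
}

# exhaustive single-split scan scored by explicitly computed segment SSE
oracle_amoc_split <- function(x, min_segment = 2L) {
  n <- length(x)
  best <- NULL; best_sse <- Inf
  for (s in seq(min_segment, n - min_segment)) {
    a <- x[1:s]; b <- x[(s + 1):n]
    sse <- sum((a - sum(a) / length(a))^2) + sum((b - sum(b) / length(b))^2)
    if (sse < best_sse) { best_sse <- sse; best <- s }
  }
  list(split = best, sse = best_sse)
}

# random piecewise daily curves with plateaus, for segmentation properties
random_daily_curve <- function(n, seed) {
  set.seed(seed)
  steps <- sample(c(-0.3, -0.1, 0, 0, 0.1, 0.3, 0.6), n - 1L, replace = TRUE)
  v <- pmax(0, cumsum(c(runif(1, 0.2, 1), steps)))
  daily_curve(100 + seq_len(n) - 1L, v)
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
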