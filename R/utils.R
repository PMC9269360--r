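`%||%` <- function(a, b) if (is.null(a)) b else a

# first start index of a run of at least `len` consecutive TRUEs, or NA
first_run_start <- function(x, len) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= len)
  if (length(hit) == 0L) return(NA_integer_)
  starts[hit[1L]]
}

# longest run of TRUEs
max_run_length <- function(x) {
  r <- rle(x)
  hits <- r$lengths[r$values]
  if (length(hits) == 0L) 0L else max(hits)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

rbind_all <- function(lst) {
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

station_year_key <- function(station_id, year) paste(station_id, year, sep = ":")
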