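# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All randomized paths in the package
# funnel through this so runs are reproducible and side-effect free.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}

is_scalar_num <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x)
}

# Zero-padded shift of a 3D array by (dr, dc, ds); out-of-bounds entries drop.
shift3 <- function(a, dr, dc, ds) {
  d <- dim(a)
  out <- array(0, d)
  r <- seq.int(max(1L, 1L - dr), min(d[1L], d[1L] - dr))
  c_ <- seq.int(max(1L, 1L - dc), min(d[2L], d[2L] - dc))
  s <- seq.int(max(1L, 1L - ds), min(d[3L], d[3L] - ds))
  if (length(r) < 1L || length(c_) < 1L || length(s) < 1L ||
      r[1L] > r[length(r)] || c_[1L] > c_[length(c_)] || s[1L] > s[length(s)])
    return(out)
  out[r + dr, c_ + dc, s + ds] <- a[r, c_, s]
  out
}

# Sum of `a` over a centred window (wr x wc x ws), truncated at the array
# boundary.  include_center = FALSE subtracts the centre term.
box_sum <- function(a, wr, wc, ws, include_center = TRUE) {
  hr <- (wr - 1L) %/% 2L
  hc <- (wc - 1L) %/% 2L
  hs <- (ws - 1L) %/% 2L
  out <- array(0, dim(a))
  for (ds in seq.int(-hs, hs))
    for (dc in seq.int(-hc, hc))
      for (dr in seq.int(-hr, hr))
        out <- out + shift3(a, dr, dc, ds)
  if (!include_center) out <- out - a
  out
}

# Nudge duplicated values apart deterministically, by the smallest
# representable step at the value's magnitude, until all are distinct.
make_distinct <- function(v) {
  for (pass in seq_len(64L)) {
    dup <- duplicated(v)
    if (!any(dup)) break
    step <- pmax(abs(v[dup]), 1) * .Machine$double.eps * 2^pass
    v[dup] <- v[dup] + step
  }
  v
}
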