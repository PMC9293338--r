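# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  }
  if (nonnegative && x < 0) {
    stop(sprintf("'%s' must be nonnegative", name), call. = FALSE)
  }
  invisible(x)
}

# periodic Hann window; neighbours of a bin-centred line are exactly half the peak
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

taper_window <- function(n, window = c("hanning", "rectangular", "hamming")) {
  window <- match.arg(window)
  switch(window,
    hanning     = hann_window(n),
    rectangular = rep(1, n),
    hamming     = 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / n)
  )
}

# Rectangular ROI in pixel coordinates, 0-based, half-open: c(x0, y0, x1, y1)
# with x along columns and y along rows. Returns row/col index vectors.
roi_indices <- function(dim_yx, roi) {
  if (is.null(roi)) {
    return(list(rows = seq_len(dim_yx[1]), cols = seq_len(dim_yx[2])))
  }
  if (length(roi) != 4L || any(!is.finite(roi))) {
    stop("ROI must be c(x0, y0, x1, y1), 0-based, half-open", call. = FALSE)
  }
  x0 <- roi[1]; y0 <- roi[2]; x1 <- roi[3]; y1 <- roi[4]
  if (x1 <= x0 || y1 <= y0) stop("empty ROI", call. = FALSE)
  if (x0 < 0 || y0 < 0 || x1 > dim_yx[2] || y1 > dim_yx[1]) {
    stop("ROI outside image bounds", call. = FALSE)
  }
  list(rows = (y0 + 1):y1, cols = (x0 + 1):x1)
}
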