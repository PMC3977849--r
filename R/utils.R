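## Low-level numerical utilities shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_param <- function(...) stop(..., call. = FALSE)

#' Otsu threshold for a grayscale image
#'
#' Histogram-based automatic threshold maximising between-class variance,
#' used to separate the dark cell contours / highway walls from the mid-gray
#' background of slightly defocused bright-field frames.
#'
#' @param x numeric vector or matrix of intensities.
#' @param levels number of histogram bins (integer images: number of gray
#'   levels, default 256).
#' @return threshold value; pixels strictly below it are "dark".
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) stop_param("otsu_threshold: no finite pixels")
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  br <- seq(r[1], r[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = levels)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[levels]
  denom <- omega * (1 - omega)
  denom[denom <= 0] <- NA_real_
  sigma_b <- (mu_t * omega - mu)^2 / denom
  k <- which.max(sigma_b)
  br[k + 1L]
}

#' Label connected components of a binary mask
#'
#' Run-length-encoded two-pass labelling with union-find; rows are scanned
#' along the image x axis, runs in adjacent rows are merged when they
#' overlap (8-connectivity by default).
#'
#' @param mask logical matrix (TRUE = foreground).
#' @param connectivity 4 or 8.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered 1..K.
#' @export
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  if (!any(mask)) return(out)
  s_list <- vector("list", nr); e_list <- vector("list", nr)
  for (r in seq_len(nr)) {
    d <- diff(c(FALSE, mask[r, ], FALSE))
    s_list[[r]] <- which(d == 1L)
    e_list[[r]] <- which(d == -1L) - 1L
  }
  counts <- lengths(s_list)
  total <- sum(counts)
  run_row <- rep.int(seq_len(nr), counts)
  run_s <- unlist(s_list, use.names = FALSE)
  run_e <- unlist(e_list, use.names = FALSE)

  parent <- seq_len(total)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8L) 1L else 0L
  idx_by_row <- split(seq_len(total), factor(run_row, levels = seq_len(nr)))
  for (r in seq_len(nr)[-1]) {
    a <- idx_by_row[[r - 1L]]; b <- idx_by_row[[r]]
    na <- length(a); nb <- length(b)
    if (!na || !nb) next
    i <- 1L; j <- 1L
    while (i <= nb && j <= na) {
      bi <- b[i]; aj <- a[j]
      if (run_e[bi] + slack < run_s[aj]) {
        i <- i + 1L
      } else if (run_e[aj] + slack < run_s[bi]) {
        j <- j + 1L
      } else {
        ri <- find(bi); rj <- find(aj)
        if (ri != rj) parent[ri] <- rj
        # advance whichever run ends first; the other may still overlap more
        if (run_e[bi] < run_e[aj]) i <- i + 1L else j <- j + 1L
      }
    }
  }
  roots <- vapply(seq_len(total), find, integer(1))
  lab <- match(roots, unique(roots))
  for (k in seq_len(total)) {
    out[run_row[k], run_s[k]:run_e[k]] <- lab[k]
  }
  out
}

#' Solve a square linear assignment problem
#'
#' Shortest-augmenting-path (Hungarian) algorithm with potentials,
#' O(n^3). Forbidden assignments should be encoded as a large finite
#' cost (see [lap_big()]); the bordered square matrix used by the global
#' tracker (real pairs plus per-cell no-match dummies) always admits a
#' feasible assignment.
#'
#' @param cost square numeric matrix of finite costs.
#' @return integer vector `a` with `a[i]` = column assigned to row `i`.
#' @export
solve_lap <- function(cost) {
  n <- nrow(cost)
  if (is.null(n) || ncol(cost) != n) stop_param("solve_lap: cost must be square")
  if (n == 0L) return(integer(0))
  if (any(!is.finite(cost))) stop_param("solve_lap: costs must be finite (use lap_big() for forbidden pairs)")
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1L)   # column potentials, index 1 = virtual column 0
  p <- integer(n + 1L)   # p[j+1] = row assigned to column j (0 = none)
  way <- integer(n + 1L)
  cols <- seq_len(n)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[cols + 1L])
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        fi <- free[upd]
        minv[fi] <- cur[upd]
        way[fi + 1L] <- j0
      }
      k <- which.min(minv[free])
      delta <- minv[free][k]
      j1 <- free[k]
      ui <- which(used)
      # rows on the alternating tree get their potential raised
      ru <- p[ui]; ru <- ru[ru > 0L]
      u[ru] <- u[ru] + delta
      v[ui] <- v[ui] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  a <- integer(n)
  a[p[cols + 1L]] <- cols
  a
}

#' Large finite cost marking a forbidden assignment
#' @export
lap_big <- function() 1e9

## running median with window 3, ends copied (used to de-glitch septum traces)
runmed3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  ok <- !is.na(x)
  y <- x
  if (sum(ok) >= 3L) {
    xs <- x
    xs[!ok] <- stats::median(x[ok])
    y <- stats::runmed(xs, 3L)
    y[!ok] <- NA_real_
  }
  y
}

## ordinary least squares slope/intercept for y ~ x (closed form, no lm overhead)
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(c(intercept = my, slope = 0))
  b <- sum((x - mx) * (y - my)) / sxx
  c(intercept = my - b * mx, slope = b)
}
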