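# Independent oracles used across the suite. These deliberately use naive
# exhaustive algorithms so they stay independent of the package's
# implementations.

# ---- exhaustive topographic-prominence maxima oracle -----------------------
# A candidate is a connected equal-value plateau (8-connectivity) with no
# strictly higher neighbour and at least one strictly lower neighbour. It is
# rejected exactly when a path to a strictly higher pixel exists that never
# descends more than `prominence` below the plateau value (path pixels with
# value >= h - prominence are allowed). Accepted candidates are reported as
# their rounded plateau centroid.
oracle_find_maxima <- function(img, prominence) {
  nr <- nrow(img); nc <- ncol(img)
  offs <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  visited <- matrix(FALSE, nr, nc)
  out <- list()
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (visited[i, j]) next
    h <- img[i, j]
    # flood the equal-value plateau
    stack <- matrix(c(i, j), 1)
    visited[i, j] <- TRUE
    plateau <- matrix(numeric(0), 0, 2)
    has_higher <- FALSE; has_lower <- FALSE
    while (nrow(stack) > 0) {
      p <- stack[nrow(stack), ]; stack <- stack[-nrow(stack), , drop = FALSE]
      plateau <- rbind(plateau, p)
      for (k in seq_len(nrow(offs))) {
        qi <- p[1] + offs[k, 1]; qj <- p[2] + offs[k, 2]
        if (qi < 1 || qi > nr || qj < 1 || qj > nc) next
        v <- img[qi, qj]
        if (v > h) has_higher <- TRUE
        else if (v < h) has_lower <- TRUE
        else if (!visited[qi, qj]) {
          visited[qi, qj] <- TRUE
          stack <- rbind(stack, c(qi, qj))
        }
      }
    }
    if (has_higher || !has_lower) next
    # path-rule BFS over the allowed sub-level band
    allowed <- img >= h - prominence
    seen <- matrix(FALSE, nr, nc)
    seen[plateau] <- TRUE
    stack <- plateau
    rejected <- FALSE
    while (nrow(stack) > 0 && !rejected) {
      p <- stack[nrow(stack), ]; stack <- stack[-nrow(stack), , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        qi <- p[1] + offs[k, 1]; qj <- p[2] + offs[k, 2]
        if (qi < 1 || qi > nr || qj < 1 || qj > nc) next
        if (seen[qi, qj] || !allowed[qi, qj]) next
        if (img[qi, qj] > h) { rejected <- TRUE; break }
        seen[qi, qj] <- TRUE
        stack <- rbind(stack, c(qi, qj))
      }
    }
    if (!rejected) {
      out[[length(out) + 1]] <- c(floor(mean(plateau[, 1] - 1) + 0.5),
                                  floor(mean(plateau[, 2] - 1) + 0.5), h)
    }
  }
  if (length(out) == 0) {
    return(data.frame(row = numeric(0), col = numeric(0),
                      value = numeric(0)))
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("row", "col", "value")
  df[order(-df$value, df$row, df$col), , drop = FALSE]
}

# ---- set-operation oracles -------------------------------------------------
oracle_jaccard <- function(a, b) {
  ia <- which(a != 0); ib <- which(b != 0)
  u <- union(ia, ib)
  if (length(u) == 0) return(1)
  length(intersect(ia, ib)) / length(u)
}

oracle_majority <- function(masks) {
  n <- length(masks)
  out <- masks[[1]] & FALSE
  for (idx in seq_along(out)) {
    votes <- sum(vapply(masks, function(m) m[idx] != 0, logical(1)))
    out[idx] <- votes > n / 2
  }
  out
}

# ---- misc builders ---------------------------------------------------------
# radiograph whose row-profiles are plateau + Gaussian excess
gaussian_peak_radiograph <- function(sigma_px, n_lines = 40, len = 256,
                                     plateau = 100, amplitude = 40,
                                     center = NULL, pitch = 0.05) {
  if (is.null(center)) center <- (len - 1) / 2
  x <- seq_len(len) - 1
  prof <- plateau + amplitude * exp(-(x - center)^2 / (2 * sigma_px^2))
  radiograph(matrix(prof, n_lines, len, byrow = TRUE), pitch)
}

# 1D brute-force Gaussian convolution (direct sum, reflected edges)
oracle_blur_profile <- function(prof, sigma) {
  n <- length(prof)
  l <- ceiling(5 * sigma)
  k <- dnorm(-l:l, sd = sigma); k <- k / sum(k)
  ext <- c(rev(prof[seq_len(l)]), prof, rev(prof[n - seq_len(l) + 1]))
  vapply(seq_len(n), function(i) sum(ext[i:(i + 2 * l)] * k), numeric(1))
}

expect_tf_equal <- function(fit, scale, rot, tr, tc, tol = 1e-9) {
  expect_equal(fit$scale, scale, tolerance = tol)
  drot <- (fit$rotation_deg - rot) %% 360
  if (drot > 180) drot <- drot - 360
  expect_lt(abs(drot), 1e-6 + tol * 360)
  expect_equal(fit$t_row, tr, tolerance = tol * max(1, abs(tr)))
  expect_equal(fit$t_col, tc, tolerance = tol * max(1, abs(tc)))
}

# random integer-valued test image with plateaus
random_plateau_image <- function(nr, nc, levels = 12, max_val = 60) {
  matrix(sample.int(levels, nr * nc, replace = TRUE) *
           (max_val / levels), nr, nc)
}
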