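# Independent brute-force oracles used to validate the fast implementations.

# Connected components by plain R flood fill (stack-based), independent of
# the package's labeling code.
flood_fill_labels <- function(mask, connectivity) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
  nl <- 0L
  for (i in seq_along(mask)) {
    if (!mask[i] || lab[i] > 0L) next
    nl <- nl + 1L
    stack <- i
    lab[i] <- nl
    while (length(stack)) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      z <- (j - 1L) %/% (d[1L] * d[2L])
      r <- (j - 1L) %% (d[1L] * d[2L])
      y <- r %/% d[1L]
      x <- r %% d[1L]
      for (k in seq_len(nrow(offs))) {
        a <- x + offs[k, 1L]; b <- y + offs[k, 2L]; cc <- z + offs[k, 3L]
        if (a < 0 || a >= d[1L] || b < 0 || b >= d[2L] || cc < 0 || cc >= d[3L])
          next
        jj <- 1L + a + d[1L] * (b + d[2L] * cc)
        if (mask[jj] && lab[jj] == 0L) {
          lab[jj] <- nl
          stack <- c(stack, jj)
        }
      }
    }
  }
  lab
}

# TRUE when two labelings induce the same partition of the foreground.
same_partition <- function(lab_a, lab_b) {
  fg <- lab_a > 0L
  if (!identical(fg, lab_b > 0L)) return(FALSE)
  key <- paste(lab_a[fg], lab_b[fg])
  length(unique(key)) == length(unique(lab_a[fg])) &&
    length(unique(key)) == length(unique(lab_b[fg]))
}
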