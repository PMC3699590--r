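# Independent brute-force oracles, written as plain voxel loops so they share
# no code path with the package implementations they check.

oracle_otsu_bin <- function(x, bins = 256L) {
  lo <- min(x); hi <- max(x)
  idx <- pmin(as.integer((x - lo) / (hi - lo) * bins), bins - 1L)
  best_t <- NA_integer_
  best_v <- -Inf
  n <- length(x)
  for (t in 1:(bins - 1L)) {
    c0 <- idx < t
    n0 <- sum(c0)
    if (n0 == 0L || n0 == n) next
    mids0 <- idx[c0] + 0.5
    mids1 <- idx[!c0] + 0.5
    w0 <- n0 / n
    v <- w0 * (1 - w0) * (mean(mids0) - mean(mids1))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

oracle_majority <- function(maps) {
  d <- dim(maps[[1]]$labels)
  out <- array(0L, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    votes <- vapply(maps, function(m) m$labels[i, j, k], 0L)
    tab <- table(votes)
    top <- max(tab)
    winners <- as.integer(names(tab)[tab == top])
    out[i, j, k] <- min(winners)
  }
  out
}

oracle_mean_displacement <- function(d) {
  dm <- dim(d$d)[1:3]
  acc <- 0
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3]))
    acc <- acc + sqrt(sum(d$d[i, j, k, ]^2))
  acc / prod(dm)
}

oracle_average_fields <- function(fields) {
  dm <- dim(fields[[1]]$d)
  out <- array(0, dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3]))
    for (c in 1:3)
      out[i, j, k, c] <- mean(vapply(fields, function(f) f$d[i, j, k, c], 0))
  out
}

oracle_global_index <- function(a, b, ids) {
  num <- 0; den <- 0
  d <- dim(a$labels)
  for (r in ids) {
    inter <- 0; na <- 0; nb <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      ar <- a$labels[i, j, k] == r
      br <- b$labels[i, j, k] == r
      if (ar && br) inter <- inter + 1
      if (ar) na <- na + 1
      if (br) nb <- nb + 1
    }
    num <- num + 2 * inter
    den <- den + na + nb
  }
  num / den
}

oracle_confusion <- function(ref, test, ids) {
  C <- matrix(0, length(ids), length(ids),
              dimnames = list(as.character(ids), as.character(ids)))
  d <- dim(ref$labels)
  for (ri in seq_along(ids)) {
    nref <- 0
    for (si in seq_along(ids)) {
      cnt <- 0
      for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
        if (ref$labels[i, j, k] == ids[ri] && test$labels[i, j, k] == ids[si])
          cnt <- cnt + 1
      C[ri, si] <- cnt
    }
    nref <- sum(ref$labels == ids[ri])
    if (nref > 0) C[ri, ] <- 100 * C[ri, ] / nref
  }
  C
}

oracle_prob_maps <- function(warped_label_arrays, ids) {
  n <- length(warped_label_arrays)
  d <- dim(warped_label_arrays[[1]])
  out <- array(0, c(d, length(ids)))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    for (ri in seq_along(ids)) {
      cnt <- 0
      for (s in seq_len(n))
        if (warped_label_arrays[[s]][i, j, k] == ids[ri]) cnt <- cnt + 1
      out[i, j, k, ri] <- cnt / n
    }
  out
}
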