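# Shared fixtures, all generated in code.

paper_te <- te_schedule()  # 12 echoes, 2.61..38.91 ms step 3.3

random_stack <- function(rows = 4, cols = 4, te = paper_te, seed = 1) {
  set.seed(seed)
  arr <- array(rexp(rows * cols * length(te), rate = 1 / 50),
               dim = c(rows, cols, length(te)))
  echo_stack(arr, te)
}

# stack whose every pixel is a * R + b
affine_stack <- function(ref, a, b, rows = 3, cols = 3) {
  v <- a * ref$values + b
  echo_stack(array(rep(v, each = rows * cols),
                   dim = c(rows, cols, length(v))),
             paper_te)
}

# independent least-squares oracle: per-pixel lm() fit of V on R
oracle_lm_fit <- function(stack, ref) {
  d <- dim(stack$intensities)
  lam <- xi <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    co <- stats::coef(stats::lm(stack$intensities[i, j, ] ~ ref$values))
    lam[i, j] <- co[2]; xi[i, j] <- co[1]
  }
  list(lambda = lam, xi = xi)
}

# naive two-loop CI oracle, written independently of the package's
# integral-image implementation
oracle_ci <- function(image, window = 7L) {
  half <- (window - 1L) %/% 2L
  vals <- c()
  for (i in (half + 1):(nrow(image) - half))
    for (j in (half + 1):(ncol(image) - half)) {
      win <- image[(i - half):(i + half), (j - half):(j + half)]
      if (anyNA(win)) next
      m_f <- win[half + 1, half + 1]
      m_b <- mean(win[-((half * window + half) + 1)])
      if (m_f + m_b <= 0) next
      vals <- c(vals, abs(m_f - m_b) / (m_f + m_b))
    }
  mean(vals)
}
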