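# independent DTW oracle: plain memoised recursion over the same step rules
# (diagonal/vertical/horizontal, absolute-difference local cost)
dtw_oracle_D <- function(x, y) {
  n <- length(x); m <- length(y)
  memo <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (i < 1 || j < 1) return(Inf)
    if (i == 1 && j == 1) return(abs(x[1] - y[1]))
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- abs(x[i] - y[j]) + min(rec(i - 1, j - 1), rec(i - 1, j), rec(i, j - 1))
    memo[i, j] <<- v
    v
  }
  rec(n, m)
}
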