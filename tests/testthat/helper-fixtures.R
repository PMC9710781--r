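# fixtures built in code; nothing is read from disk except where a test
# writes its own temp file first

`%||%` <- function(a, b) if (is.null(a)) b else a

# 3-area cycle with distinct strengths: a->b 5, b->c 1, c->a 3
toyTriangle <- function() {
  w <- matrix(0, 3, 3)
  w[1, 2] <- 5; w[2, 3] <- 1; w[3, 1] <- 3
  Connectome(w, labels = c("a", "b", "c"))
}

# shift (delay-line) reservoir: r_i(t) = r_{i-1}(t-1)
shiftMatrix <- function(n) {
  w <- matrix(0, n, n)
  w[cbind(2:n, 1:(n - 1))] <- 1
  w
}

# spearman over links of two matrices sharing a mask
linkSpearman <- function(a, b) {
  keep <- a != 0
  cor(a[keep], b[keep], method = "spearman")
}

randomConnectome <- function(n, density = 0.4, seed = 1) {
  synthConnectome(n, nModules = 1, density = density, seed = seed)
}
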