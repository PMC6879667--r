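set.seed(20260929)
run <- function(k, L, w, B) {
  hits <- 0; done <- 0
  while (done < B) {
    n <- min(2e5, B - done)
    u <- matrix(runif(n * L), n, L)
    sm <- t(apply(u, 1, function(r) sort.int(r, partial = 1:k)[1:k]))
    hits <- hits + sum(rowSums(log(sm)) <= log(w))
    done <- done + n
  }
  p <- hits / B
  cat(sprintf("k=%d L=%d w=%g: p=%.7f se=%.3g\n", k, L, w, p, sqrt(p*(1-p)/B)))
}
run(2, 4, 0.01, 1e7)
run(5, 20, 1e-6, 1e7)
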