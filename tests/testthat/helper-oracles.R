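# Independent reference implementation of sequential thresholded least
# squares: plain lm() fits, explicit loop, no shared code with stlsq().
stlsq_reference <- function(X, y, lambda) {
  p <- ncol(X)
  active <- seq_len(p)
  repeat {
    beta <- rep(0, p)
    if (length(active)) {
      df <- as.data.frame(X[, active, drop = FALSE])
      fit <- stats::lm(y ~ . - 1, data = df)
      beta[active] <- stats::coef(fit)
      beta[is.na(beta)] <- 0
    }
    keep <- which(abs(beta) >= lambda)
    if (identical(keep, active) || !length(keep)) {
      beta[setdiff(seq_len(p), keep)] <- 0
      return(beta)
    }
    active <- keep
  }
}
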